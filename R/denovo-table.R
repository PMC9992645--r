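# Display-column schema of the integrated de novo event table, in the
# order used on disk; names(.) are the internal column names.
TABLE_SCHEMA <- c(
  sample_id = "Sample ID", gdna_change = "gDNA change", function_class = "Function",
  coding_change = "Coding change", protein_change = "Protein change",
  sift = "SIFT", polyphen = "Polyphen", cadd = "CADD",
  mutation_taster = "MutationTaster", provean = "PROVEAN", mcap = "M-CAP",
  vest4 = "VEST4", gerp = "GERP", phylop = "phyloP",
  exac = "ExAC", kg = "1000 genomes", gnomad = "gnomAD",
  inheritance = "Inheritance", pmid = "PMID", cohort_size = "Cohort Size",
  primary_diagnosis = "Primary diagnosis")

NUMERIC_EVENT_COLS <- c("cadd", "vest4", "gerp", "phylop", "exac", "kg", "gnomad")

parse_gdna <- function(gdna) {
  m <- regmatches(gdna, regexec("g\\.?([0-9]+)([ACGT]+)\\s*>\\s*([ACGT]+)", gdna))
  bad <- vapply(m, length, 0L) != 4
  if (any(bad & !is.na(gdna))) {
    stop("unparseable gDNA change: ",
         paste(utils::head(gdna[bad], 3), collapse = ", "), call. = FALSE)
  }
  list(pos = as.integer(vapply(m, `[`, "", 2)),
       ref = vapply(m, `[`, "", 3),
       alt = vapply(m, `[`, "", 4))
}

normalize_function_class <- function(x) {
  y <- gsub(" ", "_", tolower(trimws(x)))
  y[y %in% c("stopgain", "stop_gained", "nonsense")] <- "stop_gain"
  y
}

#' Read / write de novo event tables
#'
#' The on-disk format is a TSV with the integrated-event column layout
#' (Sample ID, gDNA change, Function, Coding change, Protein change,
#' SIFT, Polyphen, CADD, MutationTaster, PROVEAN, M-CAP, VEST4, GERP,
#' phyloP, ExAC, 1000 genomes, gnomAD, Inheritance, PMID, Cohort Size,
#' Primary diagnosis). `read_denovo_events()` parses it into the internal
#' event schema, deriving the variant key (`chrom`, `pos`, `ref`, `alt`)
#' from the gDNA change; variant identity is genomic, never the protein
#' nomenclature.
#'
#' @param path TSV path.
#' @param chrom Chromosome of the locus (the gDNA column carries
#'   positions only).
#' @param events Event tibble in the internal schema.
#' @return `read_denovo_events()` returns a tibble with internal column
#'   names plus `chrom`, `pos`, `ref`, `alt`.
#' @export
read_denovo_events <- function(path, chrom = "5") {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  missing_cols <- setdiff(unname(TABLE_SCHEMA), names(raw))
  if (length(missing_cols)) {
    stop("event table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ev <- raw[, unname(TABLE_SCHEMA)]
  names(ev) <- names(TABLE_SCHEMA)
  for (col in NUMERIC_EVENT_COLS) ev[[col]] <- as.numeric(ev[[col]])
  ev$function_class <- normalize_function_class(ev$function_class)
  ev$inheritance <- tolower(ev$inheritance)
  key <- parse_gdna(ev$gdna_change)
  ev$chrom <- chrom
  ev$pos <- key$pos
  ev$ref <- key$ref
  ev$alt <- key$alt
  tibble::as_tibble(ev)
}

#' @rdname read_denovo_events
#' @export
write_denovo_events <- function(events, path) {
  out <- events
  cap <- function(x) paste0(toupper(substring(x, 1, 1)), substring(x, 2))
  out$function_class <- ifelse(out$function_class == "stop_gain", "Stop gain",
                               cap(out$function_class))
  out$inheritance <- ifelse(out$inheritance == "de novo", "De novo",
                            out$inheritance)
  out <- out[, names(TABLE_SCHEMA)]
  names(out) <- unname(TABLE_SCHEMA)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Bundled MAST4 de novo event table
#'
#' The nine integrated de novo MAST4 events (chr5, hg19; isoform
#' NM_001164664.1) assembled from a four-family trio-sequencing study and
#' published neurodevelopmental-disorder cohorts: eight missense events
#' and one stop gain, with SIFT/PolyPhen/CADD and related annotation
#' scores, inheritance, source and primary diagnosis.
#'
#' @return Tibble of 9 events in the internal schema (see
#'   [read_denovo_events()]).
#' @export
load_mast4_events <- function() {
  read_denovo_events(system.file("extdata", "mast4_denovo_events.tsv",
                                 package = "trioscreen", mustWork = TRUE),
                     chrom = "5")
}

#' Integrate study and published de novo events
#'
#' Concatenates two event tables in the same schema, rejects duplicated
#' (sample, variant) pairs — the same proband may not contribute the same
#' event twice — and orders the result by genomic position.
#'
#' @param study_events,published_events Event tibbles
#'   (see [read_denovo_events()]).
#' @return Integrated event tibble.
#' @export
integrate_cohorts <- function(study_events, published_events) {
  ev <- dplyr::bind_rows(study_events, published_events)
  id <- paste(ev$sample_id, ev$chrom, ev$pos, ev$ref, ev$alt, sep = "|")
  if (anyDuplicated(id)) {
    stop("duplicate proband-variant pair(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  dplyr::arrange(ev, .data$chrom, .data$pos, .data$ref, .data$alt,
                 .data$sample_id)
}

#' Count events by function class
#'
#' @param events Event tibble.
#' @return Named integer vector over at least `missense` and `stop_gain`
#'   (plus any other observed class); counts partition the events.
#' @export
count_by_function <- function(events) {
  classes <- union(c("missense", "stop_gain"), unique(events$function_class))
  counts <- vapply(classes, function(cl) sum(events$function_class == cl), 0L)
  counts
}

#' Find recurrent variant sites
#'
#' A recurrent site is an identical genomic variant (chrom, pos, ref,
#' alt) carried by two or more distinct probands. Detection is invariant
#' to input order; sites are returned by descending carrier count (ties
#' by position).
#'
#' @param events Event tibble.
#' @return Tibble with `chrom`, `pos`, `ref`, `alt`, `key`,
#'   `protein_change`, `n_probands`, `probands` (comma-separated, sorted).
#' @export
find_recurrent_sites <- function(events) {
  ev <- tibble::as_tibble(events)
  out <- ev |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::summarise(
      protein_change = .data$protein_change[1],
      n_probands = dplyr::n_distinct(.data$sample_id),
      probands = paste(sort(unique(.data$sample_id)), collapse = ","),
      .groups = "drop") |>
    dplyr::filter(.data$n_probands >= 2) |>
    dplyr::arrange(dplyr::desc(.data$n_probands), .data$pos)
  out$key <- paste(out$chrom, out$pos, out$ref, out$alt, sep = ":")
  out[, c("chrom", "pos", "ref", "alt", "key", "protein_change",
          "n_probands", "probands")]
}

#' Per-proband score lists split by recurrence
#'
#' Extracts one score value per proband (a recurrent site contributes its
#' score once per carrier) and splits the values by whether the proband's
#' variant lies in a recurrent site. Missense deleteriousness scores are
#' compared on missense rows only, so stop-gain events are excluded for
#' `cadd`, `sift` and `polyphen`.
#'
#' @param events Event tibble.
#' @param score Numeric score column name (e.g. `"cadd"`, `"vest4"`).
#' @return List with numeric vectors `recurrent` and `non_recurrent`.
#' @export
per_proband_scores <- function(events, score = "cadd") {
  if (!score %in% names(events)) stop("no such column: ", score, call. = FALSE)
  if (!is.numeric(events[[score]])) {
    stop("score column must be numeric: ", score, call. = FALSE)
  }
  ev <- tibble::as_tibble(events)
  if (score %in% c("cadd", "sift", "polyphen")) {
    ev <- ev[ev$function_class == "missense", ]
  }
  rec <- find_recurrent_sites(ev)
  key <- paste(ev$chrom, ev$pos, ev$ref, ev$alt, sep = ":")
  in_rec <- key %in% rec$key
  list(recurrent = ev[[score]][in_rec],
       non_recurrent = ev[[score]][!in_rec])
}
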