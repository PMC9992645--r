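#' Brain region code sets
#'
#' Region vocabularies used throughout the package, following the 16
#' dissection codes of the BrainSpan developmental transcriptome:
#' `brain_regions()` returns all 16 codes; `neocortex_regions()` the 11
#' neocortical codes used as the "developing cortex" (CC) group;
#' `prefrontal_regions()` the 4 prefrontal codes (FC group).
#'
#' @return Character vector of region codes.
#' @export
brain_regions <- function() {
  c("A1C", "AMY", "CBC", "DFC", "HIP", "IPC", "ITC", "M1C",
    "MD", "MFC", "OFC", "S1C", "STC", "STR", "V1C", "VFC")
}

#' @rdname brain_regions
#' @export
neocortex_regions <- function() {
  c("A1C", "DFC", "IPC", "ITC", "M1C", "MFC", "OFC", "S1C", "STC", "V1C", "VFC")
}

#' @rdname brain_regions
#' @export
prefrontal_regions <- function() {
  c("DFC", "MFC", "OFC", "VFC")
}

# Gestation length: birth is fixed at 280 post-conceptional days.
BIRTH_DAYS <- 280

#' Convert developmental ages to post-conceptional days
#'
#' Maps the age encodings used by developmental transcriptome atlases to a
#' single post-conceptional-day axis: post-conceptional weeks (`pcw`) are
#' `value * 7`; postnatal `months` are `280 + value * 30.4375`; postnatal
#' `years` are `280 + value * 365.25`. Birth sits at 280 days; samples with
#' `age_days < 280` are classified prenatal (so 40 pcw is still prenatal
#' under the strict rule).
#'
#' @param age_value Numeric vector of positive ages.
#' @param age_unit Character vector, one of `"pcw"`, `"months"`, `"years"`,
#'   recycled against `age_value`.
#' @return Numeric vector of post-conceptional days.
#' @examples
#' age_to_days(10, "pcw")   # 70
#' age_to_days(1, "years")  # 645.25
#' @export
age_to_days <- function(age_value, age_unit) {
  if (any(!is.finite(age_value)) || any(age_value <= 0)) {
    stop("`age_value` must be positive and finite", call. = FALSE)
  }
  n <- max(length(age_value), length(age_unit))
  age_value <- rep_len(age_value, n)
  age_unit <- rep_len(age_unit, n)
  bad <- !age_unit %in% c("pcw", "months", "years")
  if (any(bad)) {
    stop("unknown age unit: ", paste(unique(age_unit[bad]), collapse = ", "),
         call. = FALSE)
  }
  days <- numeric(n)
  days[age_unit == "pcw"] <- age_value[age_unit == "pcw"] * 7
  days[age_unit == "months"] <- BIRTH_DAYS + age_value[age_unit == "months"] * 30.4375
  days[age_unit == "years"] <- BIRTH_DAYS + age_value[age_unit == "years"] * 365.25
  days
}

#' Construct an expression atlas
#'
#' Bundles a gene-by-sample RPKM matrix with per-sample metadata (region
#' code, age) into an `expression_atlas` object, the container consumed by
#' the co-expression and trajectory analyses. `age_days` and `period`
#' (prenatal iff `age_days < 280`) are derived from `age_value`/`age_unit`
#' when absent.
#'
#' @param rpkm Numeric matrix, genes as rows (rownames = gene symbols),
#'   samples as columns (colnames = sample ids). All values must be finite
#'   and non-negative.
#' @param samples Data frame with columns `sample_id`, `region`,
#'   `age_value`, `age_unit` (and optionally `age_days`, `period`), one row
#'   per column of `rpkm`, in matching order of `sample_id`.
#' @return An `expression_atlas`: list with elements `rpkm` and `samples`.
#' @export
expression_atlas <- function(rpkm, samples) {
  rpkm <- as.matrix(rpkm)
  samples <- as.data.frame(samples)
  if (is.null(rownames(rpkm)) || is.null(colnames(rpkm))) {
    stop("`rpkm` must carry gene rownames and sample colnames", call. = FALSE)
  }
  if (any(!is.finite(rpkm)) || any(rpkm < 0)) {
    stop("RPKM values must be finite and non-negative", call. = FALSE)
  }
  req <- c("sample_id", "region", "age_value", "age_unit")
  miss <- setdiff(req, names(samples))
  if (length(miss)) {
    stop("sample metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!identical(colnames(rpkm), as.character(samples$sample_id))) {
    stop("colnames(rpkm) must equal samples$sample_id in order", call. = FALSE)
  }
  if (!"age_days" %in% names(samples)) {
    samples$age_days <- age_to_days(samples$age_value, samples$age_unit)
  }
  if (!"period" %in% names(samples)) {
    samples$period <- ifelse(samples$age_days < BIRTH_DAYS, "prenatal", "postnatal")
  }
  structure(list(rpkm = rpkm, samples = tibble::as_tibble(samples)),
            class = "expression_atlas")
}

#' @export
print.expression_atlas <- function(x, ...) {
  cat("<expression_atlas> ", nrow(x$rpkm), " genes x ", ncol(x$rpkm),
      " samples; ", length(unique(x$samples$region)), " regions, ",
      sum(x$samples$period == "prenatal"), " prenatal / ",
      sum(x$samples$period == "postnatal"), " postnatal samples\n", sep = "")
  invisible(x)
}

#' Read / write an expression atlas as TSV
#'
#' The on-disk layout mirrors the BrainSpan download format: an expression
#' matrix TSV (first column `gene`, one column per sample) and a sample
#' metadata TSV (`sample_id`, `region`, `age_value`, `age_unit`).
#'
#' @param expr_path,meta_path Paths to the expression matrix and sample
#'   metadata TSV files.
#' @param atlas An `expression_atlas`.
#' @return `read_atlas()` returns an `expression_atlas`; `write_atlas()`
#'   returns the paths invisibly.
#' @export
read_atlas <- function(expr_path, meta_path) {
  expr <- readr::read_tsv(expr_path, show_col_types = FALSE)
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE)
  m <- as.matrix(expr[, -1, drop = FALSE])
  rownames(m) <- expr[[1]]
  expression_atlas(m, meta)
}

#' @rdname read_atlas
#' @export
write_atlas <- function(atlas, expr_path, meta_path) {
  stopifnot(inherits(atlas, "expression_atlas"))
  expr <- tibble::as_tibble(atlas$rpkm, rownames = "gene")
  readr::write_tsv(expr, expr_path)
  readr::write_tsv(atlas$samples[, c("sample_id", "region", "age_value", "age_unit")],
                   meta_path)
  invisible(c(expr_path, meta_path))
}

#' Read / write gene-set files
#'
#' Gene sets are plain text, one gene symbol per line.
#'
#' @param path File path.
#' @param genes Character vector of gene symbols.
#' @return `read_gene_set()` returns a character vector.
#' @export
read_gene_set <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

#' @rdname read_gene_set
#' @export
write_gene_set <- function(genes, path) {
  writeLines(unique(as.character(genes)), path)
  invisible(path)
}
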