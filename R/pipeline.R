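#' Run the full candidate-gene evidence pipeline
#'
#' Orchestrates the analysis stages over file inputs: trio VCF quality
#' control and de novo calling; integration of study and published event
#' tables with recurrent-site detection and the recurrent-vs-non-recurrent
#' CADD rank test; de novo vs private score comparisons; co-expression
#' percentiles of a target gene against known gene sets; and
#' prenatal/postnatal trajectory fits. Stages whose inputs are `NULL` are
#' skipped. The returned summary (also written as JSON when `out_dir` is
#' given) embeds the package version, a hash of the configuration and the
#' seed, and is byte-identical across runs with the same inputs and seed.
#'
#' @param vcf_path Trio VCF for the QC stage.
#' @param study_events_path,published_events_path Event TSVs in the
#'   integrated-table layout (see [read_denovo_events()]).
#' @param private_events_path Private population cohort TSV, same layout.
#' @param expr_path,meta_path Expression atlas TSVs (see [read_atlas()]).
#' @param gene_set_paths Named character vector of gene-set file paths.
#' @param target_gene Target gene for co-expression and trajectory.
#' @param thresholds A [qc_thresholds()].
#' @param region_groups Region groups for trajectory fits.
#' @param seed Integer seed recorded in the summary and applied before
#'   any stage that draws random numbers.
#' @param out_dir Output directory; created if needed. Per-stage TSVs and
#'   `summary.json` are written there.
#' @return The summary as a nested list, invisibly when `out_dir` is
#'   given.
#' @export
run_pipeline <- function(vcf_path = NULL,
                         study_events_path = NULL,
                         published_events_path = NULL,
                         private_events_path = NULL,
                         expr_path = NULL, meta_path = NULL,
                         gene_set_paths = NULL, target_gene = NULL,
                         thresholds = qc_thresholds(),
                         region_groups = c("CC", "FC"),
                         seed = 1L, out_dir = NULL) {
  config <- list(vcf_path = vcf_path, study_events_path = study_events_path,
                 published_events_path = published_events_path,
                 private_events_path = private_events_path,
                 expr_path = expr_path, meta_path = meta_path,
                 gene_set_paths = gene_set_paths, target_gene = target_gene,
                 thresholds = unclass(thresholds),
                 region_groups = region_groups, seed = as.integer(seed))
  set.seed(config$seed)
  summary <- list(tool = "trioscreen",
                  version = as.character(utils::packageVersion("trioscreen")),
                  config_hash = rlang::hash(config), seed = config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  outputs <- list()

  qc <- NULL
  if (!is.null(vcf_path)) {
    qc <- stage("qc", run_qc_pipeline(vcf_path, thresholds))
    summary$qc <- list(funnel = as.data.frame(qc$funnel),
                       n_candidates = nrow(qc$events))
    outputs$qc_events.tsv <- qc$events
    outputs$qc_funnel.tsv <- qc$funnel
  }

  if (!is.null(study_events_path)) {
    study <- stage("table", read_denovo_events(study_events_path))
    integrated <- if (!is.null(published_events_path)) {
      stage("table", integrate_cohorts(study,
                                       read_denovo_events(published_events_path)))
    } else {
      study
    }
    rec <- stage("table", find_recurrent_sites(integrated))
    summary$table <- list(
      n_events = nrow(integrated),
      function_counts = as.list(count_by_function(integrated)),
      n_recurrent_sites = nrow(rec),
      max_recurrence = if (nrow(rec)) max(rec$n_probands) else 0L)
    scores <- stage("table", per_proband_scores(integrated, "cadd"))
    if (length(scores$recurrent) && length(scores$non_recurrent)) {
      w <- wilcoxon_ranksum(scores$recurrent, scores$non_recurrent)
      summary$table$recurrent_vs_nonrecurrent_cadd_p <- w$p_value
    }
    outputs$integrated_events.tsv <- integrated
    outputs$recurrent_sites.tsv <- rec

    if (!is.null(private_events_path)) {
      private <- stage("compare", read_denovo_events(private_events_path))
      cmp <- stage("compare", compare_denovo_vs_private(integrated, private))
      summary$compare <- lapply(cmp, function(r) {
        list(method = r$method, p_value = r$p_value, n1 = r$n1, n2 = r$n2)
      })
    }
  }

  atlas <- NULL
  if (!is.null(expr_path) && !is.null(meta_path)) {
    atlas <- stage("atlas", read_atlas(expr_path, meta_path))
  }
  if (!is.null(atlas) && !is.null(gene_set_paths) && !is.null(target_gene)) {
    sets <- lapply(gene_set_paths, read_gene_set)
    pct <- stage("coexpr",
                 coexpression_percentiles(target_gene, sets, atlas))
    summary$coexpression <- lapply(seq_len(nrow(pct)), function(i) {
      as.list(pct[i, c("gene", "set_name", "mean_abs_rho", "percentile",
                       "universe_size")])
    })
    outputs$coexpression_percentiles.tsv <- pct
  }
  if (!is.null(atlas) && !is.null(target_gene)) {
    fits <- list()
    for (rg in region_groups) {
      for (per in c("prenatal", "postnatal")) {
        fits[[length(fits) + 1]] <- stage("trajectory",
                                          fit_trajectory(atlas, target_gene,
                                                         rg, per))
      }
    }
    fits <- dplyr::bind_rows(fits)
    summary$trajectory <- lapply(seq_len(nrow(fits)), function(i) {
      as.list(fits[i, ])
    })
    outputs$trajectory_fits.tsv <- fits
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(outputs)) {
      readr::write_tsv(tibble::as_tibble(outputs[[nm]]), file.path(out_dir, nm))
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(summary))
  }
  summary
}
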