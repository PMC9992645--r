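#' Cortex-expressed gene universe
#'
#' The ranking universe of the co-expression statistic: genes with
#' RPKM strictly above `rpkm_min` in at least `fraction` of all
#' developing-cortex samples (all ages; default regions are the 11
#' neocortical codes).
#'
#' @param atlas An [expression_atlas()].
#' @param rpkm_min Expression cutoff (strict `>`; default 0.5 RPKM).
#' @param fraction Minimum fraction of cortex samples above the cutoff
#'   (inclusive `>=`; default 0.5).
#' @param cortex_regions Region codes counted as developing cortex.
#' @return Character vector of gene names.
#' @export
cortex_expressed_genes <- function(atlas, rpkm_min = 0.5, fraction = 0.5,
                                   cortex_regions = neocortex_regions()) {
  stopifnot(inherits(atlas, "expression_atlas"))
  idx <- atlas$samples$region %in% cortex_regions
  if (!any(idx)) stop("no samples from the given cortex regions", call. = FALSE)
  frac_expr <- rowMeans(atlas$rpkm[, idx, drop = FALSE] > rpkm_min)
  rownames(atlas$rpkm)[frac_expr >= fraction]
}

# Row-wise rank transform (average ranks for ties); Pearson correlation of
# ranks equals Spearman's rho.
rank_rows <- function(m) {
  t(apply(m, 1, rank))
}

#' Mean correlation of a gene with a gene set
#'
#' The mean over set members of the Spearman correlation (absolute value
#' by default) between the gene and each member, computed across all
#' atlas samples with average-rank tie handling. The gene itself is
#' excluded when it belongs to the set. Pairs involving a
#' constant expression vector are skipped (their correlation is
#' undefined); if every pair is skipped the statistic is undefined and an
#' error is raised.
#'
#' @param gene Gene name.
#' @param members Character vector of set members.
#' @param atlas An [expression_atlas()].
#' @param universe Genes eligible as correlation partners (default: all
#'   atlas genes); members outside it are ignored.
#' @param absolute Logical; use `|rho|` (default) or signed rho.
#' @return Scalar mean correlation.
#' @export
mean_set_correlation <- function(gene, members, atlas,
                                 universe = rownames(atlas$rpkm),
                                 absolute = TRUE) {
  stopifnot(inherits(atlas, "expression_atlas"))
  members <- setdiff(intersect(members, universe), gene)
  if (!length(members)) stop("no usable set members", call. = FALSE)
  if (!gene %in% rownames(atlas$rpkm)) stop("unknown gene: ", gene, call. = FALSE)
  g <- rank(atlas$rpkm[gene, ])
  if (stats::sd(g) == 0) stop("target gene has constant expression", call. = FALSE)
  rho <- suppressWarnings(
    stats::cor(g, t(rank_rows(atlas$rpkm[members, , drop = FALSE]))))
  rho <- as.numeric(rho)
  if (all(is.na(rho))) stop("all member correlations undefined", call. = FALSE)
  if (absolute) rho <- abs(rho)
  mean(rho, na.rm = TRUE)
}

#' Co-expression percentile of a gene within the cortex universe
#'
#' The candidate-prioritisation statistic: for every cortex-expressed
#' gene, compute the mean (absolute) Spearman correlation with the
#' members of a known disease gene set; the target's percentile is
#' `100 * #\{universe genes with strictly greater mean\} / universe size`,
#' with genes tied with the target contributing one half. Low percentile
#' means the target sits near the top of the co-expression ranking.
#'
#' @param target Target gene name (must be cortex-expressed).
#' @param members Character vector: the known gene set.
#' @param atlas An [expression_atlas()].
#' @param set_name Label stored in the result.
#' @inheritParams cortex_expressed_genes
#' @param absolute Logical; rank by `|rho|` (default) or signed rho.
#' @return One-row tibble: `gene`, `set_name`, `mean_abs_rho`,
#'   `percentile`, `universe_size`.
#' @export
percentile_of_gene <- function(target, members, atlas, set_name = "custom",
                               rpkm_min = 0.5, fraction = 0.5,
                               cortex_regions = neocortex_regions(),
                               absolute = TRUE) {
  stopifnot(inherits(atlas, "expression_atlas"))
  universe <- cortex_expressed_genes(atlas, rpkm_min, fraction, cortex_regions)
  if (!target %in% universe) {
    stop("target gene is not cortex-expressed: ", target, call. = FALSE)
  }
  members_in <- intersect(members, universe)
  if (!length(members_in)) stop("no set members in the universe", call. = FALSE)

  # Spearman rho between every universe gene and every set member, via
  # Pearson correlation of row ranks; constant rows give NA and are
  # skipped pair-wise.
  R <- rank_rows(atlas$rpkm[universe, , drop = FALSE])
  M <- R[members_in, , drop = FALSE]
  C <- suppressWarnings(stats::cor(t(R), t(M)))
  if (absolute) C <- abs(C)
  # exclude self-correlation for genes that are themselves set members
  for (m in members_in) C[m, m] <- NA
  means <- rowMeans(C, na.rm = TRUE)
  m_t <- means[target]
  if (is.na(m_t)) stop("mean correlation undefined for target", call. = FALSE)
  others <- means[names(means) != target]
  pct <- 100 * (sum(others > m_t, na.rm = TRUE) +
                  0.5 * sum(others == m_t, na.rm = TRUE)) / length(universe)
  tibble::tibble(gene = target, set_name = set_name, mean_abs_rho = m_t,
                 percentile = pct, universe_size = length(universe))
}

#' Percentiles of one or more targets over several gene sets
#'
#' Convenience wrapper around [percentile_of_gene()] for a vector of
#' targets and a named list of gene sets.
#'
#' @param targets Character vector of target genes.
#' @param gene_sets Named list of character vectors.
#' @inheritParams percentile_of_gene
#' @return Tibble with one row per (target, set).
#' @export
coexpression_percentiles <- function(targets, gene_sets, atlas,
                                     rpkm_min = 0.5, fraction = 0.5,
                                     cortex_regions = neocortex_regions(),
                                     absolute = TRUE) {
  rows <- list()
  for (set_name in names(gene_sets)) {
    for (tg in targets) {
      rows[[length(rows) + 1]] <- percentile_of_gene(
        tg, gene_sets[[set_name]], atlas, set_name = set_name,
        rpkm_min = rpkm_min, fraction = fraction,
        cortex_regions = cortex_regions, absolute = absolute)
    }
  }
  dplyr::bind_rows(rows)
}
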