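resolve_region_group <- function(regions) {
  if (length(regions) == 1 && regions %in% c("CC", "FC")) {
    list(label = regions,
         codes = if (regions == "CC") neocortex_regions() else prefrontal_regions())
  } else {
    list(label = paste(regions, collapse = "+"), codes = regions)
  }
}

#' Fit an expression trajectory by ordinary least squares
#'
#' Univariate linear regression (`lm()`) of a gene's RPKM on
#' post-conceptional age in days, within one developmental period and one
#' region group — the model used to contrast prenatal up-regulation with
#' postnatal behaviour. Region groups `"CC"` (cerebral cortex: the 11
#' neocortical codes) and `"FC"` (prefrontal cortex: DFC, MFC, OFC, VFC)
#' are built in; any character vector of region codes is accepted.
#'
#' @param atlas An [expression_atlas()].
#' @param gene Gene name.
#' @param regions `"CC"`, `"FC"`, or a vector of region codes.
#' @param period `"prenatal"` or `"postnatal"` (birth at 280
#'   post-conceptional days; prenatal is strictly before).
#' @param log_transform Logical; regress `log1p(RPKM)` instead of RPKM
#'   (off by default: the canonical analysis fits plain RPKM).
#' @return One-row tibble of class `trajectory_fit`: `slope` (RPKM/day),
#'   `intercept`, `r_squared`, `p_value` (two-sided slope t-test, n - 2
#'   df), `n`, `period`, `region_group`. A response with zero variance is
#'   reported as slope 0, R-squared 0, p 1.
#' @export
fit_trajectory <- function(atlas, gene, regions = "CC",
                           period = c("prenatal", "postnatal"),
                           log_transform = FALSE) {
  stopifnot(inherits(atlas, "expression_atlas"))
  period <- match.arg(period)
  if (!gene %in% rownames(atlas$rpkm)) stop("unknown gene: ", gene, call. = FALSE)
  rg <- resolve_region_group(regions)
  idx <- atlas$samples$region %in% rg$codes & atlas$samples$period == period
  n <- sum(idx)
  if (n < 3) {
    stop("need at least 3 samples in the stratum (have ", n, ")", call. = FALSE)
  }
  x <- atlas$samples$age_days[idx]
  y <- as.numeric(atlas$rpkm[gene, idx])
  if (log_transform) y <- log1p(y)
  if (stats::var(x) == 0) stop("no age variation in the stratum", call. = FALSE)

  if (stats::var(y) == 0) {
    slope <- 0; intercept <- y[1]; r2 <- 0; p <- 1
  } else {
    fit <- stats::lm(y ~ x)
    sm <- suppressWarnings(summary(fit))  # perfect fits warn harmlessly
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    r2 <- sm$r.squared
    p <- unname(sm$coefficients[2, 4])
  }
  structure(tibble::tibble(slope = slope, intercept = intercept,
                           r_squared = r2, p_value = p, n = n,
                           period = period, region_group = rg$label),
            class = c("trajectory_fit", "tbl_df", "tbl", "data.frame"))
}
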