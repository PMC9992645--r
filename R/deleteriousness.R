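comparison_result <- function(method, statistic, p_value, n1, n2,
                              tie_corrected, continuity_corrected) {
  structure(list(method = method, statistic = unname(statistic),
                 p_value = unname(p_value), n1 = n1, n2 = n2,
                 tie_corrected = tie_corrected,
                 continuity_corrected = continuity_corrected),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result> ", x$method, ": p = ", format(x$p_value, digits = 4),
      " (n1 = ", x$n1, ", n2 = ", x$n2,
      if (x$tie_corrected) ", tie-corrected normal approximation" else ", exact",
      ")\n", sep = "")
  invisible(x)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Rank-sum comparison of two independent samples, as used for CADD
#' score contrasts. With no ties and both samples below 50 observations
#' the exact rank-sum distribution is used; otherwise the normal
#' approximation with tie-corrected variance and continuity correction.
#' Two-sided by default.
#'
#' @param x,y Numeric vectors (each non-empty, finite).
#' @param two_sided Logical; `FALSE` gives the one-sided
#'   (greater) alternative.
#' @return A `comparison_result` with fields `method`, `statistic` (the
#'   Mann-Whitney U for `x`), `p_value`, `n1`, `n2`, `tie_corrected`,
#'   `continuity_corrected`.
#' @examples
#' wilcoxon_ranksum(c(26.3, 26.3, 26.3, 27.3, 27.3), c(25.5, 22.9, 23.4))
#' @export
wilcoxon_ranksum <- function(x, y, two_sided = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("samples must be finite", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) < 50 && length(y) < 50
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = if (two_sided) "two.sided" else "greater",
    exact = exact, correct = TRUE))
  comparison_result("wilcoxon_ranksum", wt$statistic, wt$p.value,
                    length(x), length(y),
                    tie_corrected = !exact, continuity_corrected = !exact)
}

#' Fisher's exact test on an r x c contingency table
#'
#' Exact conditional test of homogeneity for bin-count tables (SIFT D/T,
#' PolyPhen D/P/B). All-zero rows and columns are dropped first; a table
#' that collapses below 2 x 2 is degenerate. Tables with total count at
#' most 300 are evaluated by complete enumeration; larger tables by a
#' seeded Monte-Carlo estimate (at least 1e5 draws).
#'
#' @param tab Matrix (or table) of non-negative integer counts.
#' @param mc_draws Number of Monte-Carlo draws used beyond the
#'   enumeration limit.
#' @return A `comparison_result` (`statistic` is the conditional odds
#'   ratio for 2 x 2 tables, `NA` otherwise; `n1`, `n2` are row sums of
#'   the first two rows).
#' @examples
#' fisher_exact_rxc(matrix(c(5, 0, 0, 5), 2))
#' @export
fisher_exact_rxc <- function(tab, mc_draws = 1e5) {
  tab <- as.matrix(tab)
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab))) {
    stop("table must contain non-negative integer counts", call. = FALSE)
  }
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("degenerate table: need >= 2 rows and >= 2 columns with counts",
         call. = FALSE)
  }
  n <- sum(tab)
  if (n <= 300) {
    ft <- stats::fisher.test(tab)
  } else {
    ft <- stats::fisher.test(tab, simulate.p.value = TRUE, B = mc_draws)
  }
  est <- if (!is.null(ft$estimate)) ft$estimate else NA_real_
  comparison_result("fisher_exact", est, ft$p.value,
                    sum(tab[1, ]), sum(tab[2, ]),
                    tie_corrected = FALSE, continuity_corrected = FALSE)
}

bin_table <- function(a, b, levels) {
  rbind(table(factor(a, levels = levels)),
        table(factor(b, levels = levels)))
}

#' Compare de novo vs private cohorts on deleteriousness scores
#'
#' Missense-only group comparison between a de novo cohort and a private
#' population cohort: CADD by Wilcoxon rank-sum, SIFT (D/T) and PolyPhen
#' (D/P/B, or collapsed to damaging vs not) by Fisher's exact test on
#' bin-count tables.
#'
#' @param denovo,private Event tibbles (see [read_denovo_events()]).
#' @param collapse_polyphen Logical; collapse PolyPhen to D vs (P + B).
#' @return Named list of `comparison_result`s: `cadd`, `sift`,
#'   `polyphen`.
#' @export
compare_denovo_vs_private <- function(denovo, private,
                                      collapse_polyphen = FALSE) {
  d <- denovo[denovo$function_class == "missense", ]
  p <- private[private$function_class == "missense", ]
  if (!nrow(d) || !nrow(p)) {
    stop("both cohorts must contain missense events", call. = FALSE)
  }
  res <- list(cadd = wilcoxon_ranksum(d$cadd, p$cadd))
  res$sift <- fisher_exact_rxc(bin_table(d$sift, p$sift, c("D", "T")))
  pp_d <- d$polyphen
  pp_p <- p$polyphen
  if (collapse_polyphen) {
    pp_d <- ifelse(pp_d == "D", "D", "not_D")
    pp_p <- ifelse(pp_p == "D", "D", "not_D")
    res$polyphen <- fisher_exact_rxc(bin_table(pp_d, pp_p, c("D", "not_D")))
  } else {
    res$polyphen <- fisher_exact_rxc(bin_table(pp_d, pp_p, c("D", "P", "B")))
  }
  res
}
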