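#' Configuration for the synthetic expression atlas
#'
#' Parameters of the simulated developmental-brain expression grid. The
#' simulator plants two kinds of structure on top of independent
#' background genes:
#'
#' * a latent co-expression module (`n_module_genes` genes named
#'   `MOD...`) whose members share one latent trajectory, attenuated by
#'   `module_loading` — this is the signal the co-expression percentile
#'   statistic is meant to detect;
#' * developmental ramp genes (`n_ramp_genes` genes named `RAMP...`)
#'   whose RPKM rises linearly with post-conceptional age at
#'   `prenatal_slope` RPKM/day until birth and plateaus after — the
#'   signal the trajectory regression is meant to recover.
#'
#' Noise is multiplicative log-normal (log-scale standard deviation
#' `noise_sd`), keeping RPKM non-negative and right-skewed.
#'
#' @param n_genes Total number of genes (module + ramp + background).
#' @param n_module_genes Number of latent-module genes.
#' @param n_ramp_genes Number of prenatal-ramp genes.
#' @param regions Region codes; one sample is generated per
#'   (region, age) cell. Default: the 16 BrainSpan codes.
#' @param age_grid Data frame with columns `age_value`, `age_unit`
#'   spanning prenatal and postnatal ages. Default: 12 ages from 8 pcw
#'   to 40 years (6 prenatal, 6 postnatal).
#' @param noise_sd Log2-scale standard deviation of the multiplicative
#'   noise (> 0 unless exactly 0 for noise-free checks).
#' @param module_loading Strength of the latent module in `[0, 1]`.
#' @param prenatal_slope Prenatal ramp slope, RPKM per day.
#' @param low_expr_fraction Fraction of background genes simulated at
#'   sub-threshold expression (RPKM around 0.1), so the cortex-expressed
#'   filter has genes to exclude.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   atlases.
#' @return A list of class `atlas_config`.
#' @export
atlas_config <- function(n_genes = 500,
                         n_module_genes = 50,
                         n_ramp_genes = 10,
                         regions = brain_regions(),
                         age_grid = default_age_grid(),
                         noise_sd = 0.3,
                         module_loading = 0.7,
                         prenatal_slope = 0.05,
                         low_expr_fraction = 0.05,
                         seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_module_genes = as.integer(n_module_genes),
              n_ramp_genes = as.integer(n_ramp_genes),
              regions = as.character(regions),
              age_grid = as.data.frame(age_grid),
              noise_sd = noise_sd, module_loading = module_loading,
              prenatal_slope = prenatal_slope,
              low_expr_fraction = low_expr_fraction,
              seed = as.integer(seed))
  if (cfg$n_genes <= 0) stop("n_genes must be positive", call. = FALSE)
  if (cfg$n_module_genes < 0 || cfg$n_module_genes + cfg$n_ramp_genes > cfg$n_genes) {
    stop("module + ramp genes must fit within n_genes", call. = FALSE)
  }
  if (!length(cfg$regions)) stop("`regions` must be non-empty", call. = FALSE)
  if (!all(c("age_value", "age_unit") %in% names(cfg$age_grid))) {
    stop("`age_grid` needs columns age_value, age_unit", call. = FALSE)
  }
  days <- age_to_days(cfg$age_grid$age_value, cfg$age_grid$age_unit)
  if (!any(days < BIRTH_DAYS) || !any(days >= BIRTH_DAYS)) {
    stop("`age_grid` must span both prenatal and postnatal ages", call. = FALSE)
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (cfg$module_loading < 0 || cfg$module_loading > 1) {
    stop("module_loading must lie in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "atlas_config")
}

#' @rdname atlas_config
#' @export
default_age_grid <- function() {
  data.frame(age_value = c(8, 12, 16, 21, 24, 35, 4, 10, 1, 8, 18, 40),
             age_unit = c(rep("pcw", 6), rep("months", 2), rep("years", 4)))
}

#' Simulate a developmental expression atlas
#'
#' Generates one sample per (region, age) cell of the configured grid.
#' Module genes share a latent trajectory (a smooth function of log age
#' plus sample-level variation) with gene-specific positive loadings
#' scaled by `module_loading`; ramp genes rise linearly with prenatal age
#' and plateau after birth; background genes are independent noise around
#' gene-specific baselines. All values are strictly reproducible for a
#' fixed config.
#'
#' @param config An [atlas_config()].
#' @return An [expression_atlas()] with attributes `module_genes` and
#'   `ramp_genes` naming the planted genes.
#' @export
simulate_atlas <- function(config = atlas_config()) {
  if (!inherits(config, "atlas_config")) config <- do.call(atlas_config, config)
  set.seed(config$seed)

  grid <- expand.grid(region = config$regions,
                      age_idx = seq_len(nrow(config$age_grid)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ages <- config$age_grid[grid$age_idx, , drop = FALSE]
  samples <- tibble::tibble(
    sample_id = sprintf("S%03d_%s_%g%s", seq_len(nrow(grid)), grid$region,
                        ages$age_value, ages$age_unit),
    region = grid$region,
    age_value = ages$age_value,
    age_unit = ages$age_unit)
  samples$age_days <- age_to_days(samples$age_value, samples$age_unit)
  samples$period <- ifelse(samples$age_days < BIRTH_DAYS, "prenatal", "postnatal")
  ns <- nrow(samples)

  n_mod <- config$n_module_genes
  n_ramp <- config$n_ramp_genes
  n_bg <- config$n_genes - n_mod - n_ramp
  genes <- c(if (n_mod) sprintf("MOD%03d", seq_len(n_mod)),
             if (n_ramp) sprintf("RAMP%03d", seq_len(n_ramp)),
             if (n_bg) sprintf("G%04d", seq_len(n_bg)))

  # latent module trajectory: smooth in log age + sample-level variation,
  # standardised so module_loading is comparable across grids
  f <- as.numeric(scale(log(samples$age_days))) + stats::rnorm(ns, 0, 0.5)
  f <- as.numeric(scale(f))

  rpkm <- matrix(0, nrow = config$n_genes, ncol = ns,
                 dimnames = list(genes, samples$sample_id))

  if (n_mod) {
    base <- stats::runif(n_mod, 1, 5)        # log2 RPKM baseline: 2..32 RPKM
    lambda <- stats::runif(n_mod, 0.5, 1.5)  # positive gene loadings
    for (i in seq_len(n_mod)) {
      lg <- base[i] + config$module_loading * lambda[i] * f +
        stats::rnorm(ns, 0, config$noise_sd)
      rpkm[i, ] <- 2^lg
    }
  }
  if (n_ramp) {
    t0 <- min(samples$age_days[samples$period == "prenatal"])
    ramp_age <- pmax(0, pmin(samples$age_days, BIRTH_DAYS) - t0)
    for (i in seq_len(n_ramp)) {
      mu <- 1 + config$prenatal_slope * ramp_age
      # mean-one log-normal noise keeps the planted slope unbiased
      noise <- exp(stats::rnorm(ns, 0, config$noise_sd) - config$noise_sd^2 / 2)
      rpkm[n_mod + i, ] <- mu * noise
    }
  }
  if (n_bg) {
    n_low <- round(config$low_expr_fraction * n_bg)
    base <- c(rep(log2(0.1), n_low), stats::runif(n_bg - n_low, 1, 5))
    base <- sample(base)
    for (i in seq_len(n_bg)) {
      lg <- base[i] + stats::rnorm(ns, 0, max(config$noise_sd, 1e-8))
      rpkm[n_mod + n_ramp + i, ] <- 2^lg
    }
  }

  atlas <- expression_atlas(rpkm, samples)
  attr(atlas, "module_genes") <- genes[seq_len(n_mod)]
  attr(atlas, "ramp_genes") <- if (n_ramp) genes[n_mod + seq_len(n_ramp)] else character()
  atlas
}

#' Simulate gene sets anchored to the latent module
#'
#' Draws named gene sets from a simulated atlas, with a configurable
#' fraction of each set taken from the planted co-expression module (the
#' rest from non-module genes). Defaults mirror the known-gene sets used
#' for candidate prioritisation: 37 infantile-spasm genes, 126 epileptic
#' -encephalopathy genes (43 + 33 + 50), and up to 789 monoallelic
#' developmental-disorder genes, capped at the atlas size.
#'
#' @param atlas An atlas produced by [simulate_atlas()].
#' @param sizes Named integer vector of set sizes.
#' @param in_module_fraction Fraction of each set drawn from the latent
#'   module (rounded to the nearest count).
#' @param seed Integer seed.
#' @return Named list of character vectors.
#' @export
simulate_gene_sets <- function(atlas, sizes = NULL, in_module_fraction = 0.5,
                               seed = 1L) {
  stopifnot(inherits(atlas, "expression_atlas"))
  universe <- rownames(atlas$rpkm)
  if (is.null(sizes)) {
    sizes <- c(IS = 37L, EE = 126L, DD = min(789L, length(universe)))
  }
  if (any(sizes > length(universe))) {
    stop("requested set size exceeds the gene universe", call. = FALSE)
  }
  module <- intersect(attr(atlas, "module_genes"), universe)
  other <- setdiff(universe, module)
  set.seed(as.integer(seed))
  out <- lapply(sizes, function(k) {
    k <- as.integer(k)
    k_mod <- min(round(in_module_fraction * k), length(module))
    k_oth <- k - k_mod
    if (k_oth > length(other)) {
      stop("not enough non-module genes for the requested fraction", call. = FALSE)
    }
    sort(c(sample(module, k_mod), sample(other, k_oth)))
  })
  names(out) <- names(sizes)
  out
}
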