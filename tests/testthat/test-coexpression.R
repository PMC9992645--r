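test_that("cortex-expressed universe uses strict RPKM > 0.5 in >= half of cortex", {
  ns <- 8  # 2 regions x 4 ages in tiny_atlas
  atlas <- tiny_atlas(list(
    high = rep(1, ns),
    boundary = rep(0.5, ns),                 # never strictly above 0.5
    half = c(rep(1, 4), rep(0, 4)),          # exactly half the samples
    low = rep(0.1, ns)),
    regions = c("DFC", "V1C"))
  genes <- cortex_expressed_genes(atlas, cortex_regions = c("DFC", "V1C"))
  expect_setequal(genes, c("high", "half"))

  expect_error(cortex_expressed_genes(atlas, cortex_regions = "CBC"),
               "no samples")
})

test_that("universe membership equals a brute-force recount on synthetic data", {
  a <- simulate_atlas(atlas_config(n_genes = 120, n_module_genes = 20,
                                   low_expr_fraction = 0.3, seed = 14))
  got <- cortex_expressed_genes(a)
  cortex <- a$samples$region %in% neocortex_regions()
  manual <- rownames(a$rpkm)[vapply(rownames(a$rpkm), function(g) {
    mean(a$rpkm[g, cortex] > 0.5) >= 0.5
  }, TRUE)]
  expect_setequal(got, manual)
  expect_true(length(got) < 120)  # the low-expressed genes drop out
})

test_that("mean set correlation matches direct Spearman computation", {
  a <- simulate_atlas(atlas_config(n_genes = 40, n_module_genes = 10, seed = 6))
  members <- c("MOD002", "MOD003", "G0005")
  got <- mean_set_correlation("MOD001", members, a)
  manual <- mean(vapply(members, function(m) {
    abs(cor(a$rpkm["MOD001", ], a$rpkm[m, ], method = "spearman"))
  }, 0))
  expect_equal(got, manual, tolerance = 1e-12)

  signed <- mean_set_correlation("MOD001", members, a, absolute = FALSE)
  manual_signed <- mean(vapply(members, function(m) {
    cor(a$rpkm["MOD001", ], a$rpkm[m, ], method = "spearman")
  }, 0))
  expect_equal(signed, manual_signed, tolerance = 1e-12)
})

test_that("a gene co-monotone with the single set member scores rho = 1", {
  ns <- 8
  set.seed(1)
  v <- runif(ns, 1, 10)
  atlas <- tiny_atlas(list(g = v, m = 2 * v + 1, noise = runif(ns, 1, 10)))
  expect_equal(mean_set_correlation("g", "m", atlas), 1)
  # self is excluded when the gene belongs to the set
  expect_equal(mean_set_correlation("g", c("g", "m"), atlas), 1)
})

test_that("percentile ranks the strongest gene at exactly zero", {
  ns <- 8
  set.seed(2)
  v <- sort(runif(ns, 1, 10))
  rows <- list(target = v + 0.01 * rnorm(ns), m1 = v)
  for (i in 1:10) rows[[sprintf("bg%02d", i)]] <- runif(ns, 1, 10)
  atlas <- tiny_atlas(rows)
  res <- percentile_of_gene("target", "m1", atlas,
                            cortex_regions = c("DFC", "V1C"))
  expect_equal(res$percentile, 0)
  expect_equal(res$universe_size, 12)
  expect_gt(res$mean_abs_rho, 0.95)

  expect_error(percentile_of_gene("absent", "m1", atlas,
                                  cortex_regions = c("DFC", "V1C")),
               "not cortex-expressed")
})

test_that("percentiles average to the tie-convention mean over the universe", {
  a <- simulate_atlas(atlas_config(n_genes = 50, n_module_genes = 10,
                                   low_expr_fraction = 0, seed = 20))
  members <- sprintf("MOD%03d", 1:5)
  universe <- cortex_expressed_genes(a)
  pcts <- vapply(universe, function(g) {
    percentile_of_gene(g, members, a)$percentile
  }, 0)
  n <- length(universe)
  # all-distinct means give mean percentile 50 * (n - 1) / n
  expect_equal(mean(pcts), 50 * (n - 1) / n, tolerance = 100 / n)
})

test_that("planted-module percentile decreases with module loading", {
  # noise high enough that the intermediate loading is only partially
  # detectable; at saturation the target ranks uniformly among the
  # exchangeable module genes and the curve flattens
  med <- vapply(c(0, 0.5, 1), function(load) {
    p <- vapply(1:6, function(s) {
      a <- simulate_atlas(atlas_config(n_genes = 200, n_module_genes = 38,
                                       module_loading = load, noise_sd = 1.5,
                                       seed = 700 + 10 * load + s))
      gs <- simulate_gene_sets(a, sizes = c(IS = 37), in_module_fraction = 1,
                               seed = 800 + s)
      members <- setdiff(gs$IS, "MOD001")[1:36]
      percentile_of_gene("MOD001", members, a)$percentile
    }, 0)
    mean(p)
  }, 0)
  expect_true(med[2] < med[1] && med[3] < med[2])
  expect_lt(med[3], 15)
})
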