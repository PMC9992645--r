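ev9 <- load_mast4_events()

test_that("bundled event table matches the published summary cell-for-cell", {
  expect_equal(nrow(ev9), 9)
  expect_equal(ev9$cadd,
               c(25.5, 22.9, 38, 26.3, 26.3, 26.3, 27.3, 27.3, 23.4))
  expect_equal(ev9$sample_id[2], "Case 1")
  expect_equal(ev9$protein_change[2], "p.898I > T")
  expect_equal(ev9$pmid[2], "This study")
  expect_equal(ev9$function_class[3], "stop_gain")
  expect_true(all(ev9$inheritance == "de novo"))
  expect_equal(ev9$gnomad[1], 0.0000112)
  expect_true(all(is.na(ev9$gnomad[-1])))
  expect_equal(ev9$pos, c(66437967L, 66438324L, 66440524L, 66459419L,
                          66459419L, 66459419L, 66460439L, 66460439L,
                          66462662L))
  expect_equal(ev9$vest4[7], 0.965)
})

test_that("event tables round-trip through the TSV layout", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_denovo_events(ev9, path)
  back <- read_denovo_events(path)
  expect_equal(back, ev9)

  bad <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(data.frame(x = 1), bad)
  expect_error(read_denovo_events(bad), "missing column")
})

test_that("cohort integration concatenates, orders, and rejects duplicates", {
  study <- ev9[ev9$pmid == "This study", ]
  published <- ev9[ev9$pmid != "This study", ]
  expect_equal(nrow(study), 4)
  expect_equal(nrow(published), 5)

  merged <- integrate_cohorts(study, published)
  expect_equal(nrow(merged), 9)
  expect_false(is.unsorted(merged$pos))

  expect_equal(integrate_cohorts(study, study[0, ]),
               dplyr::arrange(study, chrom, pos, ref, alt, sample_id))
  expect_error(integrate_cohorts(study, study), "duplicate")
})

test_that("function counts partition any cohort", {
  counts <- count_by_function(ev9)
  expect_equal(counts[["missense"]], 8)
  expect_equal(counts[["stop_gain"]], 1)

  empty <- count_by_function(ev9[0, ])
  expect_true(all(empty == 0))

  set.seed(99)
  for (i in 1:5) {
    co <- simulate_variant_cohorts(cohort_config(n_denovo = sample(1:40, 1),
                                                 n_private = 0, seed = i))
    expect_equal(sum(count_by_function(co$denovo)), nrow(co$denovo))
  }
})

test_that("recurrent-site detection finds the two shared variants", {
  rec <- find_recurrent_sites(ev9)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$key, c("5:66459419:C:T", "5:66460439:C:T"))
  expect_equal(rec$n_probands, c(3L, 2L))
  expect_equal(rec$probands[1], "Case 2,Case 3,DDD13k.00269")

  shuffled <- ev9[sample(nrow(ev9)), ]
  expect_equal(find_recurrent_sites(shuffled), rec)

  expect_equal(nrow(find_recurrent_sites(ev9[c(1, 2, 9), ])), 0)
})

test_that("planting k carriers of one site yields multiplicity k", {
  base <- dplyr::bind_rows(lapply(1:6, function(i) {
    make_event(sprintf("P%02d", i), 1000 + i)
  }))
  planted <- dplyr::bind_rows(base, lapply(7:10, function(i) {
    make_event(sprintf("P%02d", i), 5000)
  }))
  rec <- find_recurrent_sites(planted)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$n_probands, 4L)
  expect_equal(rec$pos, 5000L)
})

test_that("per-proband score lists split missense carriers by recurrence", {
  s <- per_proband_scores(ev9, "cadd")
  expect_equal(sort(s$recurrent), c(26.3, 26.3, 26.3, 27.3, 27.3))
  expect_equal(sort(s$non_recurrent), c(22.9, 23.4, 25.5))
  # stop gain (CADD 38) is excluded; lists cover all missense probands
  expect_equal(length(s$recurrent) + length(s$non_recurrent), 8)

  all_unique <- dplyr::bind_rows(lapply(1:5, function(i) {
    make_event(sprintf("U%d", i), 2000 + i, cadd = 20 + i)
  }))
  s2 <- per_proband_scores(all_unique, "cadd")
  expect_length(s2$recurrent, 0)
  expect_length(s2$non_recurrent, 5)

  expect_error(per_proband_scores(ev9, "sift"), "numeric")
  expect_error(per_proband_scores(ev9, "nope"), "no such column")
})

test_that("recurrence partition is conserved on random synthetic cohorts", {
  set.seed(7)
  for (i in 1:5) {
    n <- sample(5:30, 1)
    pos <- sample(1000:1010, n, replace = TRUE)  # forced collisions
    ev <- dplyr::bind_rows(lapply(seq_len(n), function(j) {
      make_event(sprintf("S%03d", j), pos[j])
    }))
    rec <- find_recurrent_sites(ev)
    s <- per_proband_scores(ev, "cadd")
    expect_equal(sum(rec$n_probands), length(s$recurrent))
    expect_equal(length(s$recurrent) + length(s$non_recurrent), n)
  }
})
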