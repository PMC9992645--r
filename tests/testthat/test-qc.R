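t_def <- qc_thresholds()

test_that("site filter honours the stated boundary directions", {
  base <- vcf_record()
  expect_true(site_pass(base, t_def))
  expect_true(site_pass(vcf_record(MQ = 35), t_def))    # removal is MQ < 35
  expect_false(site_pass(vcf_record(MQ = 34.9), t_def))
  expect_false(site_pass(vcf_record(QD = 2), t_def))    # QD <= 2 removed
  expect_true(site_pass(vcf_record(SOR = 3), t_def))    # SOR > 3 removed
  expect_true(site_pass(vcf_record(FS = 60), t_def))
  expect_false(site_pass(vcf_record(FS = 60.1), t_def))
  expect_true(site_pass(vcf_record(MQRankSum = -12.5), t_def))
  expect_false(site_pass(vcf_record(ReadPosRankSum = -8), t_def))
  # missing metrics pass their single criterion
  expect_true(site_pass(vcf_record(MQRankSum = NA_real_,
                                   ReadPosRankSum = NA_real_), t_def))
})

test_that("genotype filter applies the het window and hom-ref purity rule", {
  gp <- function(gt, adr, ada, dp, gq) genotype_pass(gt, adr, ada, dp, gq, t_def)
  expect_true(gp("0/1", 10, 10, 20, 30))    # AB 0.5
  expect_false(gp("0/1", 15, 5, 20, 30))    # AB exactly 0.25: strict
  expect_false(gp("0/1", 5, 15, 20, 30))    # AB exactly 0.75
  expect_false(gp("0/1", 5, 5, 10, 30))     # DP exactly 10: strict >
  expect_false(gp("0/1", 10, 10, 20, 25))   # GQ exactly 25: strict >
  expect_true(gp("0/0", 30, 10, 40, 80))    # hom-ref AB 0.25 allowed (<=)
  expect_false(gp("0/0", 30, 11, 41, 80))
  expect_false(gp("0/1", 0, 0, 0, 99))      # no coverage
  expect_false(gp("./.", NA, NA, NA, NA))
  expect_true(gp("0|1", 10, 10, 20, 30))    # phased separator accepted
})

test_that("rarity and consequence rules follow the printed cutoffs", {
  rc <- function(...) rare_and_consequence_pass(vcf_record(...), t_def)
  expect_true(rc(CSQ_class = "missense", CADD = 22.9, AF_nonneuro = NA_real_))
  expect_false(rc(CSQ_class = "missense", CADD = 20))       # strict >
  expect_true(rc(CSQ_class = "stop_gain", CADD = NA_real_)) # LoF unconditional
  expect_true(rc(CSQ_class = "frameshift", CADD = NA_real_))
  expect_false(rc(CSQ_class = "synonymous", CADD = 30))
  expect_false(rc(CSQ_class = "missense", CADD = NA_real_))
  expect_false(rc(AF_nonneuro = 0.001))                     # strict <
  expect_true(rc(AF_nonneuro = 0.0009))
})

test_that("de novo calling needs a passing het child and clean hom-ref parents", {
  expect_true(call_denovo(vcf_record(), t_def))
  expect_false(call_denovo(vcf_record(gt_f = "0/1", adr_f = 15L, ada_f = 15L),
                           t_def))
  expect_false(call_denovo(vcf_record(gt_p = "0/0", adr_p = 30L, ada_p = 0L),
                           t_def))
  expect_false(call_denovo(vcf_record(gt_m = "./.", adr_m = NA_integer_,
                                      ada_m = NA_integer_, dp_m = NA_integer_,
                                      gq_m = NA_integer_), t_def))
  expect_false(call_denovo(vcf_record(gq_p = 10L), t_def))
})

test_that("pipeline funnel conserves records and handles an empty VCF", {
  vp <- withr::local_tempfile(fileext = ".vcf")
  simulate_trio_vcf(vp, n_sites = 120, seed = 31)
  res <- run_qc_pipeline(vp)
  f <- res$funnel
  expect_equal(f$remaining[1], 120)
  expect_equal(f$remaining[1] - sum(f$removed), f$remaining[nrow(f)])
  expect_equal(nrow(res$events), f$remaining[nrow(f)])

  empty <- withr::local_tempfile(fileext = ".vcf")
  keep <- readLines(vp)
  writeLines(keep[startsWith(keep, "#")], empty)
  res0 <- run_qc_pipeline(empty)
  expect_equal(nrow(res0$events), 0)
  expect_true(all(res0$funnel$remaining == 0))
})

test_that("loosening any threshold never shrinks the survivor set", {
  vp <- withr::local_tempfile(fileext = ".vcf")
  simulate_trio_vcf(vp, n_sites = 150, seed = 13)
  strict <- run_qc_pipeline(vp, qc_thresholds())
  # ab_low is dual-role (het lower bound and hom-ref purity cap), so only
  # raising ab_high is a pure loosening of the allele-balance rule
  loose_sets <- list(
    qc_thresholds(mq_min = 20), qc_thresholds(qd_min = 1),
    qc_thresholds(fs_max = 100), qc_thresholds(sor_max = 5),
    qc_thresholds(ab_high = 0.9), qc_thresholds(dp_min = 5),
    qc_thresholds(gq_min = 10), qc_thresholds(cadd_min = 10),
    qc_thresholds(af_max = 0.01))
  for (t in loose_sets) {
    loose <- run_qc_pipeline(vp, t)
    expect_true(all(strict$events$key %in% loose$events$key))
  }
})

test_that("the three study variants survive the full cascade", {
  recs <- dplyr::bind_rows(
    vcf_record(pos = 66438324L, ref = "T", alt = "C", CADD = 22.9),
    vcf_record(pos = 66459419L, ref = "C", alt = "T", CADD = 26.3),
    vcf_record(pos = 66462662L, ref = "C", alt = "G", CADD = 23.4))
  vp <- withr::local_tempfile(fileext = ".vcf")
  write_trio_vcf(recs, vp)
  res <- run_qc_pipeline(vp)
  expect_setequal(res$events$key,
                  c("5:66438324:T:C", "5:66459419:C:T", "5:66462662:C:G"))
})

test_that("schema violations are explicit errors naming the problem", {
  vp <- withr::local_tempfile(fileext = ".vcf")
  simulate_trio_vcf(vp, n_sites = 60, seed = 17)
  lines <- readLines(vp)

  no_cadd <- withr::local_tempfile(fileext = ".vcf")
  writeLines(lines[!grepl("##INFO=<ID=CADD,", lines, fixed = TRUE)], no_cadd)
  expect_error(run_qc_pipeline(no_cadd), "CADD")

  no_gq <- withr::local_tempfile(fileext = ".vcf")
  writeLines(lines[!grepl("##FORMAT=<ID=GQ,", lines, fixed = TRUE)], no_gq)
  expect_error(run_qc_pipeline(no_gq), "GQ")

  multi <- withr::local_tempfile(fileext = ".vcf")
  body <- which(!startsWith(lines, "#"))[1]
  fields <- strsplit(lines[body], "\t", fixed = TRUE)[[1]]
  fields[5] <- paste0(fields[5], ",", setdiff(c("A", "C"), fields[5])[1])
  lines[body] <- paste(fields, collapse = "\t")
  writeLines(lines, multi)
  expect_error(run_qc_pipeline(multi), "[Mm]ulti-allelic")

  expect_error(run_qc_pipeline(vp, proband = "CHILD"), "CHILD")
})
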