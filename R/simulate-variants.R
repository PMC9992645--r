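#' Configuration for synthetic variant cohorts
#'
#' Parameters for simulating a de novo cohort and a "private"
#' population-database cohort (allele count 1) with shifted
#' deleteriousness-score distributions, emulating the contrast between
#' de novo missense variants from integrated disease cohorts and private
#' missense variants from a population reference.
#'
#' @param n_denovo,n_private Cohort sizes (>= 0).
#' @param denovo_cadd_mean,denovo_cadd_sd,private_cadd_mean,private_cadd_sd
#'   Parameters of the CADD distributions: Normal truncated at 0.
#' @param damaging_fraction_denovo,damaging_fraction_private Probability
#'   that a variant's SIFT bin is "D" (and its PolyPhen bin "D"; the
#'   remaining PolyPhen mass is split evenly between "P" and "B").
#' @param seed Integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_denovo = 9, n_private = 100,
                          denovo_cadd_mean = 26, denovo_cadd_sd = 3,
                          private_cadd_mean = 18, private_cadd_sd = 5,
                          damaging_fraction_denovo = 0.9,
                          damaging_fraction_private = 0.4,
                          seed = 1L) {
  cfg <- list(n_denovo = as.integer(n_denovo), n_private = as.integer(n_private),
              denovo_cadd_mean = denovo_cadd_mean, denovo_cadd_sd = denovo_cadd_sd,
              private_cadd_mean = private_cadd_mean, private_cadd_sd = private_cadd_sd,
              damaging_fraction_denovo = damaging_fraction_denovo,
              damaging_fraction_private = damaging_fraction_private,
              seed = as.integer(seed))
  if (cfg$n_denovo < 0 || cfg$n_private < 0) stop("cohort sizes must be >= 0", call. = FALSE)
  if (cfg$denovo_cadd_sd <= 0 || cfg$private_cadd_sd <= 0) {
    stop("CADD standard deviations must be > 0", call. = FALSE)
  }
  for (f in c(cfg$damaging_fraction_denovo, cfg$damaging_fraction_private)) {
    if (f < 0 || f > 1) stop("damaging fractions must lie in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

# Normal truncated at zero by rejection; CADD-like scores are non-negative.
rtrunc_norm0 <- function(n, mean, sd) {
  if (n == 0) return(numeric())
  x <- stats::rnorm(n, mean, sd)
  while (any(neg <- x < 0)) x[neg] <- stats::rnorm(sum(neg), mean, sd)
  x
}

one_cohort <- function(n, prefix, cadd_mean, cadd_sd, damaging_fraction,
                       inheritance, source, pos_offset) {
  sift <- ifelse(stats::runif(n) < damaging_fraction, "D", "T")
  pp_u <- stats::runif(n)
  polyphen <- ifelse(pp_u < damaging_fraction, "D",
                     ifelse(pp_u < damaging_fraction + (1 - damaging_fraction) / 2,
                            "P", "B"))
  pos <- pos_offset + sample.int(50000, n)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  tibble::tibble(
    sample_id = sprintf("%s%04d", prefix, seq_len(n)),
    chrom = "5", pos = pos, ref = ref, alt = unname(alt),
    gdna_change = sprintf("g.%d%s > %s", pos, ref, alt),
    function_class = "missense",
    coding_change = NA_character_, protein_change = NA_character_,
    sift = sift, polyphen = polyphen,
    cadd = rtrunc_norm0(n, cadd_mean, cadd_sd),
    mutation_taster = NA_character_, provean = NA_character_,
    mcap = NA_character_, vest4 = NA_real_, gerp = NA_real_, phylop = NA_real_,
    exac = NA_real_, kg = NA_real_, gnomad = NA_real_,
    inheritance = inheritance, pmid = source, cohort_size = NA_character_,
    primary_diagnosis = NA_character_)
}

#' Simulate de novo and private variant cohorts
#'
#' Draws two variant tables in the de novo event schema (see
#' [read_denovo_events()]): a de novo cohort and a private
#' population-database cohort, with CADD scores from truncated normal
#' distributions and SIFT/PolyPhen bins from the configured damaging
#' fractions.
#'
#' @param config A [cohort_config()].
#' @return List with elements `denovo` and `private`, each a tibble.
#' @export
simulate_variant_cohorts <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  set.seed(config$seed)
  denovo <- one_cohort(config$n_denovo, "DN", config$denovo_cadd_mean,
                       config$denovo_cadd_sd, config$damaging_fraction_denovo,
                       "de novo", "simulated_cohort", 66400000L)
  private <- one_cohort(config$n_private, "PV", config$private_cadd_mean,
                        config$private_cadd_sd, config$damaging_fraction_private,
                        "unknown", "simulated_gnomad", 66450000L)
  list(denovo = denovo, private = private)
}

# ---- trio VCF simulation ----------------------------------------------------

# Nominal, clearly-passing record; boundary blocks perturb one aspect at a
# time so every QC threshold is exercised exactly at and on both sides of
# its cutoff.
nominal_vcf_record <- function() {
  list(MQ = 60, QD = 20, FS = 5, SOR = 1, MQRankSum = 0, ReadPosRankSum = 0,
       AF_nonneuro = NA_real_, CSQ_class = "missense", CADD = 28,
       gt_p = "0/1", adr_p = 15L, ada_p = 15L, dp_p = 30L, gq_p = 99L,
       gt_f = "0/0", adr_f = 30L, ada_f = 0L, dp_f = 30L, gq_f = 80L,
       gt_m = "0/0", adr_m = 30L, ada_m = 0L, dp_m = 30L, gq_m = 80L,
       site_pass = TRUE, genotype_pass = TRUE, is_denovo = TRUE,
       is_rare = TRUE, consequence_pass = TRUE)
}

# Each entry: modifications + the truth labels forced by them. Labels are
# assigned from the generator's own reading of each keep-rule (strict or
# non-strict, as stated), not by calling the QC code under test.
boundary_vcf_records <- function(t) {
  m <- function(...) utils::modifyList(nominal_vcf_record(), list(...))
  fail_site <- function(...) m(..., site_pass = FALSE)
  fail_geno <- function(...) m(..., genotype_pass = FALSE, is_denovo = FALSE)
  # proband het record at allele balance ~ab (depth 20); truth from the
  # realized AD ratio against the strict window
  het_ab <- function(ab) {
    ada <- as.integer(round(ab * 20))
    ok <- (ada / 20) > t$ab_low && (ada / 20) < t$ab_high
    m(adr_p = 20L - ada, ada_p = ada, dp_p = 20L,
      genotype_pass = ok, is_denovo = ok)
  }
  mid_ab <- (t$ab_low + t$ab_high) / 2
  # het record at a given proband depth, AD split near-even
  het_dp <- function(dp) {
    ada <- as.integer(floor(dp / 2))
    ok <- dp > t$dp_min
    m(adr_p = as.integer(dp) - ada, ada_p = ada, dp_p = as.integer(dp),
      genotype_pass = ok, is_denovo = ok)
  }
  # father hom-ref at alt fraction ~ab of depth 40
  dad_ab <- function(ab) {
    ada <- as.integer(round(ab * 40))
    ok <- (ada / 40) <= t$ab_low
    m(adr_f = 40L - ada, ada_f = ada, dp_f = 40L,
      genotype_pass = ok, is_denovo = ok)
  }
  list(
    # site metrics: keep iff MQ >= mq_min, QD > qd_min, FS <= fs_max,
    # SOR <= sor_max, MQRankSum >= min, ReadPosRankSum > min; missing passes
    fail_site(MQ = t$mq_min - 1), m(MQ = t$mq_min), m(MQ = t$mq_min + 1),
    fail_site(QD = t$qd_min - 0.5), fail_site(QD = t$qd_min), m(QD = t$qd_min + 0.5),
    m(FS = t$fs_max - 5), m(FS = t$fs_max), fail_site(FS = t$fs_max + 5),
    m(SOR = t$sor_max - 0.5), m(SOR = t$sor_max), fail_site(SOR = t$sor_max + 0.5),
    fail_site(MQRankSum = t$mq_rank_sum_min - 0.5), m(MQRankSum = t$mq_rank_sum_min),
    m(MQRankSum = t$mq_rank_sum_min + 0.5), m(MQRankSum = NA_real_),
    fail_site(ReadPosRankSum = t$read_pos_rank_sum_min - 0.5),
    fail_site(ReadPosRankSum = t$read_pos_rank_sum_min),
    m(ReadPosRankSum = t$read_pos_rank_sum_min + 0.5),
    m(ReadPosRankSum = NA_real_),
    # proband het allele balance: keep iff ab_low < AB < ab_high (strict)
    het_ab(t$ab_low - 0.15), het_ab(t$ab_low), het_ab(mid_ab),
    het_ab(t$ab_high), het_ab(t$ab_high + 0.15),
    # proband depth / genotype quality: keep iff DP > dp_min, GQ > gq_min
    het_dp(t$dp_min - 1), het_dp(t$dp_min), het_dp(t$dp_min + 1),
    fail_geno(gq_p = as.integer(t$gq_min - 1)),
    fail_geno(gq_p = as.integer(t$gq_min)),
    m(gq_p = as.integer(t$gq_min + 1)),
    fail_geno(adr_p = 0L, ada_p = 0L, dp_p = 0L),  # no coverage
    # parental hom-ref purity: keep iff AB <= ab_low
    dad_ab(t$ab_low), dad_ab(t$ab_low + 0.05),
    fail_geno(dp_m = as.integer(t$dp_min), adr_m = as.integer(t$dp_min), ada_m = 0L),
    # inheritance patterns
    m(gt_f = "0/1", adr_f = 15L, ada_f = 15L, is_denovo = FALSE),
    m(gt_p = "0/0", adr_p = 30L, ada_p = 0L, is_denovo = FALSE),
    fail_geno(gt_m = "./.", adr_m = NA_integer_, ada_m = NA_integer_,
              dp_m = NA_integer_, gq_m = NA_integer_),
    # rarity: keep iff AF < af_max (missing treated as absent -> pass)
    m(AF_nonneuro = t$af_max / 2), m(AF_nonneuro = t$af_max, is_rare = FALSE),
    m(AF_nonneuro = min(10 * t$af_max, 0.5), is_rare = FALSE),
    # consequence: LoF always; missense iff CADD > cadd_min
    m(CADD = t$cadd_min - 1, consequence_pass = FALSE),
    m(CADD = t$cadd_min, consequence_pass = FALSE),
    m(CADD = t$cadd_min + 1),
    m(CADD = NA_real_, consequence_pass = FALSE),
    m(CSQ_class = "stop_gain", CADD = NA_real_),
    m(CSQ_class = "frameshift", CADD = NA_real_),
    m(CSQ_class = "splice", CADD = 10),
    m(CSQ_class = "synonymous", consequence_pass = FALSE),
    m(CSQ_class = "other", CADD = 30, consequence_pass = FALSE)
  )
}

random_vcf_record <- function() {
  r <- nominal_vcf_record()
  # site stage
  if (stats::runif(1) < 0.2) {
    r$site_pass <- FALSE
    fail <- sample(c("MQ", "QD", "FS", "SOR", "MQRankSum", "ReadPosRankSum"), 1)
    r[[fail]] <- switch(fail, MQ = stats::runif(1, 5, 30), QD = stats::runif(1, 0, 1.9),
                        FS = stats::runif(1, 65, 200), SOR = stats::runif(1, 3.2, 9),
                        MQRankSum = stats::runif(1, -20, -13),
                        ReadPosRankSum = stats::runif(1, -15, -8.2))
  }
  # genotype stage
  sc <- sample(c("denovo", "inherited", "lowqual", "homref"), 1,
               prob = c(0.55, 0.15, 0.2, 0.1))
  if (sc == "inherited") {
    r$gt_f <- "0/1"; r$adr_f <- 14L; r$ada_f <- 16L
    r$is_denovo <- FALSE
  } else if (sc == "homref") {
    r$gt_p <- "0/0"; r$adr_p <- 28L; r$ada_p <- 0L
    r$is_denovo <- FALSE
  } else if (sc == "lowqual") {
    which_m <- sample(c("p", "f"), 1)
    if (which_m == "p") {
      r$gq_p <- sample(5:20, 1)
    } else {
      r$adr_f <- 20L; r$ada_f <- 12L; r$dp_f <- 32L  # AB 0.375 in a hom-ref call
    }
    r$genotype_pass <- FALSE; r$is_denovo <- FALSE
  }
  # rarity
  if (stats::runif(1) < 0.2) {
    r$AF_nonneuro <- stats::runif(1, 0.002, 0.2); r$is_rare <- FALSE
  } else if (stats::runif(1) < 0.5) {
    r$AF_nonneuro <- stats::runif(1, 0, 0.0009)
  }
  # consequence
  u <- stats::runif(1)
  if (u < 0.15) {
    r$CSQ_class <- sample(c("stop_gain", "frameshift", "splice"), 1)
  } else if (u < 0.3) {
    r$CSQ_class <- sample(c("synonymous", "other"), 1)
    r$consequence_pass <- FALSE
  } else if (u < 0.45) {
    r$CADD <- stats::runif(1, 0, 19.5); r$consequence_pass <- FALSE
  } else {
    r$CADD <- stats::runif(1, 20.5, 40)
  }
  r
}

#' Simulate a truth-labelled trio VCF
#'
#' Writes a three-sample (PROBAND, FATHER, MOTHER) VCF v4.1 with the
#' site metrics (MQ, QD, FS, SOR, MQRankSum, ReadPosRankSum), population
#' frequency (`AF_nonneuro`), consequence class (`CSQ_class`) and CADD
#' score in INFO, and GT:AD:DP:GQ genotypes. A deterministic block of
#' records places at least one record exactly at, strictly below and
#' strictly above every QC threshold; the remainder are randomized
#' scenarios. Returns the expected QC labels for every record, assigned
#' by construction, so the QC pipeline can be checked record-for-record.
#'
#' @param path Output VCF path.
#' @param n_sites Total number of records (must be at least the size of
#'   the boundary block, 50).
#' @param thresholds A [qc_thresholds()]; the boundary block is placed at
#'   these cutoffs and truth labels follow the stated strictness of each
#'   rule.
#' @param seed Integer seed.
#' @return A tibble truth table: `key`, `chrom`, `pos`, `ref`, `alt`,
#'   `site_pass`, `genotype_pass`, `is_denovo`, `is_rare`,
#'   `consequence_pass`.
#' @export
simulate_trio_vcf <- function(path, n_sites = 500, thresholds = qc_thresholds(),
                              seed = 1L) {
  set.seed(as.integer(seed))
  recs <- boundary_vcf_records(thresholds)
  if (n_sites < length(recs)) {
    stop("n_sites must be >= ", length(recs),
         " to cover every threshold boundary", call. = FALSE)
  }
  recs <- c(recs, replicate(n_sites - length(recs), random_vcf_record(),
                            simplify = FALSE))
  df <- dplyr::bind_rows(lapply(recs, tibble::as_tibble))
  df$chrom <- "5"
  df$pos <- 66400000L + sort(sample.int(2000000L, n_sites))
  df$ref <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  df$alt <- vapply(df$ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")

  write_trio_vcf(df, path)

  tibble::tibble(key = paste(df$chrom, df$pos, df$ref, df$alt, sep = ":"),
                 chrom = df$chrom, pos = df$pos, ref = df$ref, alt = df$alt,
                 site_pass = df$site_pass, genotype_pass = df$genotype_pass,
                 is_denovo = df$is_denovo, is_rare = df$is_rare,
                 consequence_pass = df$consequence_pass)
}

#' Write trio VCF records
#'
#' Low-level writer used by [simulate_trio_vcf()] and useful for
#' constructing small fixtures: takes a data frame with one row per
#' biallelic site (columns `chrom`, `pos`, `ref`, `alt`, the INFO metrics
#' `MQ`, `QD`, `FS`, `SOR`, `MQRankSum`, `ReadPosRankSum`,
#' `AF_nonneuro`, `CSQ_class`, `CADD`, and per-member genotype columns
#' `gt_*`, `adr_*`, `ada_*`, `dp_*`, `gq_*` for suffixes `p`/`f`/`m`) and
#' writes a VCF v4.1 file with samples PROBAND, FATHER, MOTHER. `NA`
#' INFO metrics are omitted from the record.
#'
#' @param records Data frame as described above.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(records, path) {
  info_num <- function(tag, x) ifelse(is.na(x), NA_character_,
                                      paste0(tag, "=", format(x, digits = 10,
                                                              scientific = FALSE,
                                                              trim = TRUE)))
  info <- apply(cbind(info_num("MQ", records$MQ), info_num("QD", records$QD),
                      info_num("FS", records$FS), info_num("SOR", records$SOR),
                      info_num("MQRankSum", records$MQRankSum),
                      info_num("ReadPosRankSum", records$ReadPosRankSum),
                      info_num("AF_nonneuro", records$AF_nonneuro),
                      ifelse(is.na(records$CSQ_class), NA,
                             paste0("CSQ_class=", records$CSQ_class)),
                      info_num("CADD", records$CADD)),
                1, function(v) paste(stats::na.omit(v), collapse = ";"))
  info[info == ""] <- "."
  gt_col <- function(s) {
    gt <- records[[paste0("gt_", s)]]
    adr <- records[[paste0("adr_", s)]]
    ada <- records[[paste0("ada_", s)]]
    dp <- records[[paste0("dp_", s)]]
    gq <- records[[paste0("gq_", s)]]
    ifelse(gt == "./." | is.na(gt), "./.:.:.:.",
           paste0(gt, ":", adr, ",", ada, ":", dp, ":", gq))
  }
  header <- c(
    "##fileformat=VCFv4.1",
    "##contig=<ID=5,length=180915260>",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Strand odds ratio\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
    "##INFO=<ID=AF_nonneuro,Number=1,Type=Float,Description=\"Population allele frequency, non-neuro subset\">",
    "##INFO=<ID=CSQ_class,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=CADD,Number=1,Type=Float,Description=\"CADD phred score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tPROBAND\tFATHER\tMOTHER")
  body <- paste(records$chrom, records$pos, ".", records$ref, records$alt,
                ".", ".", info, "GT:AD:DP:GQ",
                gt_col("p"), gt_col("f"), gt_col("m"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
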