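#' Hard-filter thresholds for trio variant QC
#'
#' Container for all cutoffs of the QC cascade. Defaults implement the
#' published trio-exome hard filters: remove sites with MQ < 35,
#' QD <= 2, FS > 60, SOR > 3, MQRankSum < -12.5 or
#' ReadPosRankSum <= -8 (the FS and rank-sum directions follow the GATK
#' hard-filter convention); keep genotypes with 0.25 < AB < 0.75 (for
#' heterozygous calls), DP > 10 and GQ > 25; keep variants with
#' population allele frequency < 0.1%; keep loss-of-function
#' consequences unconditionally and missense only with CADD > 20.
#'
#' @param mq_min,qd_min,fs_max,sor_max,mq_rank_sum_min,read_pos_rank_sum_min
#'   Site-metric cutoffs.
#' @param ab_low,ab_high Allele-balance window for heterozygous calls;
#'   homozygous-reference calls must have AB <= `ab_low`.
#' @param dp_min,gq_min Genotype depth and quality cutoffs (strict `>`).
#' @param cadd_min CADD cutoff for missense variants (strict `>`).
#' @param af_max Population allele-frequency cutoff (strict `<`; missing
#'   frequency means absent from the database and passes).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(mq_min = 35, qd_min = 2, fs_max = 60, sor_max = 3,
                          mq_rank_sum_min = -12.5, read_pos_rank_sum_min = -8,
                          ab_low = 0.25, ab_high = 0.75,
                          dp_min = 10L, gq_min = 25L,
                          cadd_min = 20, af_max = 0.001) {
  t <- list(mq_min = mq_min, qd_min = qd_min, fs_max = fs_max, sor_max = sor_max,
            mq_rank_sum_min = mq_rank_sum_min,
            read_pos_rank_sum_min = read_pos_rank_sum_min,
            ab_low = ab_low, ab_high = ab_high,
            dp_min = as.integer(dp_min), gq_min = as.integer(gq_min),
            cadd_min = cadd_min, af_max = af_max)
  if (!all(vapply(t, function(x) is.finite(x) && length(x) == 1, TRUE))) {
    stop("all thresholds must be finite scalars", call. = FALSE)
  }
  if (t$ab_low >= t$ab_high) stop("ab_low must be < ab_high", call. = FALSE)
  if (t$af_max <= 0 || t$af_max > 1) stop("af_max must lie in (0, 1]", call. = FALSE)
  structure(t, class = "qc_thresholds")
}

LOF_CLASSES <- c("stop_gain", "frameshift", "splice")

#' Site-level hard filter
#'
#' A site is kept iff `MQ >= mq_min`, `QD > qd_min`, `FS <= fs_max`,
#' `SOR <= sor_max`, `MQRankSum >= mq_rank_sum_min` and
#' `ReadPosRankSum > read_pos_rank_sum_min`. A missing metric passes that
#' single criterion: the caller (GATK) emits rank sums only when they are
#' computable, and filtering on absence would discard valid sites.
#' Vectorized over rows of `record`.
#'
#' @param record Data frame (or list) with numeric elements `MQ`, `QD`,
#'   `FS`, `SOR`, `MQRankSum`, `ReadPosRankSum` (NA allowed).
#' @param t A [qc_thresholds()].
#' @return Logical vector.
#' @export
site_pass <- function(record, t = qc_thresholds()) {
  ok <- function(x, test) is.na(x) | test(x)
  ok(record$MQ, function(x) x >= t$mq_min) &
    ok(record$QD, function(x) x > t$qd_min) &
    ok(record$FS, function(x) x <= t$fs_max) &
    ok(record$SOR, function(x) x <= t$sor_max) &
    ok(record$MQRankSum, function(x) x >= t$mq_rank_sum_min) &
    ok(record$ReadPosRankSum, function(x) x > t$read_pos_rank_sum_min)
}

#' Genotype-level filter for one trio member
#'
#' A call passes iff `DP > dp_min`, `GQ > gq_min`, and its allele balance
#' (alt depth / total AD) satisfies the rule for its genotype class:
#' strictly inside `(ab_low, ab_high)` for heterozygous calls,
#' `AB <= ab_low` for homozygous-reference calls (parental purity), and
#' `AB >= ab_high` for homozygous-alternate calls. Calls with zero or
#' missing total depth fail (no coverage); missing genotypes fail.
#' Vectorized.
#'
#' @param gt Genotype strings (`"0/0"`, `"0/1"`, `"1/1"`, `"./."`;
#'   phased separators accepted).
#' @param ad_ref,ad_alt Allelic depths.
#' @param dp Read depth (FORMAT DP).
#' @param gq Genotype quality.
#' @param t A [qc_thresholds()].
#' @return Logical vector.
#' @export
genotype_pass <- function(gt, ad_ref, ad_alt, dp, gq, t = qc_thresholds()) {
  gt <- gsub("|", "/", as.character(gt), fixed = TRUE)
  total <- ad_ref + ad_alt
  ab <- ifelse(!is.na(total) & total > 0, ad_alt / total, NA_real_)
  base <- !is.na(dp) & dp > t$dp_min & !is.na(gq) & gq > t$gq_min &
    !is.na(total) & total > 0
  ab_ok <- rep(FALSE, length(gt))
  het <- gt %in% c("0/1", "1/0")
  homref <- gt %in% "0/0"
  homalt <- gt %in% "1/1"
  ab_ok[het] <- ab[het] > t$ab_low & ab[het] < t$ab_high
  ab_ok[homref] <- ab[homref] <= t$ab_low
  ab_ok[homalt] <- ab[homalt] >= t$ab_high
  out <- base & ab_ok
  out[is.na(out)] <- FALSE
  out
}

#' Rarity and consequence filter
#'
#' Keeps a variant iff it is rare (population allele frequency below
#' `af_max`, or missing — absent from the database) and its consequence
#' is retained: loss-of-function classes (`stop_gain`, `frameshift`,
#' `splice`) unconditionally, missense only when `CADD > cadd_min`
#' (missense with missing CADD fails, since the score requirement cannot
#' be established). Vectorized over rows of `record`.
#'
#' @param record Data frame (or list) with elements `AF_nonneuro`
#'   (numeric, NA allowed), `CSQ_class` (character) and `CADD` (numeric,
#'   NA allowed).
#' @param t A [qc_thresholds()].
#' @return Logical vector.
#' @export
rare_and_consequence_pass <- function(record, t = qc_thresholds()) {
  rare <- is.na(record$AF_nonneuro) | record$AF_nonneuro < t$af_max
  lof <- record$CSQ_class %in% LOF_CLASSES
  mis <- record$CSQ_class %in% "missense" &
    !is.na(record$CADD) & record$CADD > t$cadd_min
  rare & (lof | mis)
}

# rarity alone (used for the funnel's stage split)
rare_pass <- function(record, t) {
  is.na(record$AF_nonneuro) | record$AF_nonneuro < t$af_max
}
consequence_pass_only <- function(record, t) {
  lof <- record$CSQ_class %in% LOF_CLASSES
  mis <- record$CSQ_class %in% "missense" &
    !is.na(record$CADD) & record$CADD > t$cadd_min
  lof | mis
}

#' De novo genotype call for a trio record
#'
#' A record is called de novo iff the proband genotype is heterozygous
#' alt and passes [genotype_pass()], and both parents are homozygous
#' reference and pass. A missing parental genotype makes the inheritance
#' unknown, never de novo. Vectorized over rows of `trio`.
#'
#' @param trio Data frame with per-member columns `gt_p`, `adr_p`,
#'   `ada_p`, `dp_p`, `gq_p` and the same with suffixes `f` (father) and
#'   `m` (mother).
#' @param t A [qc_thresholds()].
#' @return Logical vector.
#' @export
call_denovo <- function(trio, t = qc_thresholds()) {
  member <- function(s) genotype_pass(trio[[paste0("gt_", s)]],
                                      trio[[paste0("adr_", s)]],
                                      trio[[paste0("ada_", s)]],
                                      trio[[paste0("dp_", s)]],
                                      trio[[paste0("gq_", s)]], t)
  gt <- function(s) gsub("|", "/", as.character(trio[[paste0("gt_", s)]]),
                         fixed = TRUE)
  gt("p") %in% c("0/1", "1/0") & member("p") &
    gt("f") %in% "0/0" & member("f") &
    gt("m") %in% "0/0" & member("m")
}

#' Read a trio VCF into a flat record table
#'
#' Parses a biallelic, normalized trio VCF with vcfR and returns one row
#' per record carrying the site metrics, population frequency,
#' consequence class, CADD score and per-member GT/AD/DP/GQ fields.
#' Multi-allelic records are rejected with an error (they must be split
#' upstream); a required INFO or FORMAT field absent from the file is a
#' schema error naming the field.
#'
#' @param path VCF path (v4.1+).
#' @param proband,father,mother Sample column names in the VCF.
#' @param af_tag,csq_tag,cadd_tag INFO tag names for the population
#'   allele frequency, consequence class and CADD score.
#' @return Tibble with columns `chrom`, `pos`, `ref`, `alt`, `key`, the
#'   INFO metrics, and the trio genotype columns used by [call_denovo()].
#' @export
read_trio_vcf <- function(path, proband = "PROBAND", father = "FATHER",
                          mother = "MOTHER", af_tag = "AF_nonneuro",
                          csq_tag = "CSQ_class", cadd_tag = "CADD") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  if (n && any(grepl(",", fix$ALT, fixed = TRUE))) {
    stop("multi-allelic records found; split and normalize the VCF first",
         call. = FALSE)
  }
  meta <- vcf@meta
  need_info <- c("MQ", "QD", "FS", "SOR", "MQRankSum", "ReadPosRankSum",
                 af_tag, csq_tag, cadd_tag)
  for (tag in need_info) {
    if (!any(grepl(paste0("##INFO=<ID=", tag, ","), meta, fixed = TRUE))) {
      stop("VCF is missing required INFO field: ", tag, call. = FALSE)
    }
  }
  for (tag in c("GT", "AD", "DP", "GQ")) {
    if (!any(grepl(paste0("##FORMAT=<ID=", tag, ","), meta, fixed = TRUE))) {
      stop("VCF is missing required FORMAT field: ", tag, call. = FALSE)
    }
  }
  missing_samples <- setdiff(c(proband, father, mother), colnames(vcf@gt))
  if (n && length(missing_samples)) {
    stop("sample(s) not in VCF: ", paste(missing_samples, collapse = ", "),
         call. = FALSE)
  }

  info_num <- function(tag) {
    if (!n) return(numeric())
    suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = tag)))
  }
  info_chr <- function(tag) {
    if (!n) return(character())
    vcfR::extract.info(vcf, element = tag)
  }
  out <- tibble::tibble(
    chrom = as.character(fix$CHROM), pos = as.integer(fix$POS),
    ref = as.character(fix$REF), alt = as.character(fix$ALT),
    MQ = info_num("MQ"), QD = info_num("QD"), FS = info_num("FS"),
    SOR = info_num("SOR"), MQRankSum = info_num("MQRankSum"),
    ReadPosRankSum = info_num("ReadPosRankSum"),
    AF_nonneuro = info_num(af_tag),
    CSQ_class = info_chr(csq_tag),
    CADD = info_num(cadd_tag))
  out$key <- paste(out$chrom, out$pos, out$ref, out$alt, sep = ":")

  ext <- function(el, sample, fn = identity) {
    if (!n) return(fn(character()))
    x <- vcfR::extract.gt(vcf, element = el)[, sample]
    fn(unname(x))
  }
  as_int <- function(x) suppressWarnings(as.integer(x))
  members <- c(p = proband, f = father, m = mother)
  for (suf in names(members)) {
    s <- members[[suf]]
    ad <- ext("AD", s)
    adr <- as_int(sub(",.*", "", ad))
    ada <- as_int(sub(".*,", "", ad))
    out[[paste0("gt_", suf)]] <- ext("GT", s, as.character)
    out[[paste0("adr_", suf)]] <- adr
    out[[paste0("ada_", suf)]] <- ada
    out[[paste0("dp_", suf)]] <- ext("DP", s, as_int)
    out[[paste0("gq_", suf)]] <- ext("GQ", s, as_int)
  }
  out
}

#' Run the full QC cascade on a trio VCF
#'
#' Applies the filtering stages in order — rarity, site-level hard
#' filters, trio genotype / de novo calling, consequence — and reports
#' both the surviving candidate de novo events and a funnel of per-stage
#' removals (each stage counts only records that survived the previous
#' ones, so `n_in = n_out + sum(removed)`). Per-record labels for every
#' stage are returned for auditing.
#'
#' @param vcf_path Trio VCF path.
#' @param thresholds A [qc_thresholds()].
#' @inheritParams read_trio_vcf
#' @return List of class `qc_result`: `events` (surviving records),
#'   `per_record` (all records with stage labels `rare`, `site`,
#'   `denovo`, `consequence`, `pass`), `funnel` (stage, removed,
#'   remaining).
#' @export
run_qc_pipeline <- function(vcf_path, thresholds = qc_thresholds(),
                            proband = "PROBAND", father = "FATHER",
                            mother = "MOTHER", af_tag = "AF_nonneuro",
                            csq_tag = "CSQ_class", cadd_tag = "CADD") {
  rec <- read_trio_vcf(vcf_path, proband, father, mother,
                       af_tag, csq_tag, cadd_tag)
  t <- thresholds
  rec$rare <- rare_pass(rec, t)
  rec$site <- site_pass(rec, t)
  rec$genotype <- genotype_pass(rec$gt_p, rec$adr_p, rec$ada_p,
                                rec$dp_p, rec$gq_p, t) &
    genotype_pass(rec$gt_f, rec$adr_f, rec$ada_f, rec$dp_f, rec$gq_f, t) &
    genotype_pass(rec$gt_m, rec$adr_m, rec$ada_m, rec$dp_m, rec$gq_m, t)
  rec$denovo <- call_denovo(rec, t)
  rec$consequence <- consequence_pass_only(rec, t)
  rec$pass <- rec$rare & rec$site & rec$denovo & rec$consequence

  s1 <- rec$rare
  s2 <- s1 & rec$site
  s3 <- s2 & rec$denovo
  s4 <- s3 & rec$consequence
  funnel <- tibble::tibble(
    stage = c("input", "rarity", "site_filters", "genotype_denovo", "consequence"),
    removed = c(0L, sum(!s1), sum(s1) - sum(s2), sum(s2) - sum(s3),
                sum(s3) - sum(s4)),
    remaining = c(nrow(rec), sum(s1), sum(s2), sum(s3), sum(s4)))

  events <- rec[rec$pass, c("chrom", "pos", "ref", "alt", "key",
                            "CSQ_class", "CADD", "AF_nonneuro")]
  names(events) <- c("chrom", "pos", "ref", "alt", "key",
                     "function_class", "cadd", "af_nonneuro")
  structure(list(events = events, per_record = rec, funnel = funnel,
                 thresholds = t), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result> ", x$funnel$remaining[1], " records in, ",
      nrow(x$events), " candidate de novo events out\n", sep = "")
  print(as.data.frame(x$funnel), row.names = FALSE)
  invisible(x)
}
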