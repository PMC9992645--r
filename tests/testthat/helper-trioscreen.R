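# Tiny hand-built atlas: genes x (regions x ages) with explicit RPKM rows.
# `rows` is a named list of numeric vectors (one value per sample).
tiny_atlas <- function(rows, regions = c("DFC", "V1C"),
                       age_value = c(10, 20, 4, 2), age_unit = c("pcw", "pcw", "months", "years")) {
  grid <- expand.grid(region = regions, idx = seq_along(age_value),
                      stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("s%02d", seq_len(nrow(grid))),
    region = grid$region,
    age_value = age_value[grid$idx],
    age_unit = age_unit[grid$idx])
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- samples$sample_id
  expression_atlas(m, samples)
}

# Minimal event-table row in the internal schema.
make_event <- function(sample_id, pos, ref = "C", alt = "T",
                       function_class = "missense", cadd = 25,
                       sift = "D", polyphen = "D", protein_change = NA_character_) {
  tibble::tibble(
    sample_id = sample_id, chrom = "5", pos = as.integer(pos),
    ref = ref, alt = alt,
    gdna_change = sprintf("g.%d%s > %s", pos, ref, alt),
    function_class = function_class, coding_change = NA_character_,
    protein_change = protein_change, sift = sift, polyphen = polyphen,
    cadd = cadd, mutation_taster = NA_character_, provean = NA_character_,
    mcap = NA_character_, vest4 = NA_real_, gerp = NA_real_,
    phylop = NA_real_, exac = NA_real_, kg = NA_real_, gnomad = NA_real_,
    inheritance = "de novo", pmid = "test", cohort_size = NA_character_,
    primary_diagnosis = NA_character_)
}

# One fully-passing trio VCF record as a one-row data frame, with overrides.
vcf_record <- function(...) {
  rec <- list(chrom = "5", pos = 1000L, ref = "A", alt = "G",
              MQ = 60, QD = 20, FS = 5, SOR = 1, MQRankSum = 0,
              ReadPosRankSum = 0, AF_nonneuro = NA_real_,
              CSQ_class = "missense", CADD = 28,
              gt_p = "0/1", adr_p = 15L, ada_p = 15L, dp_p = 30L, gq_p = 99L,
              gt_f = "0/0", adr_f = 30L, ada_f = 0L, dp_f = 30L, gq_f = 80L,
              gt_m = "0/0", adr_m = 30L, ada_m = 0L, dp_m = 30L, gq_m = 80L)
  tibble::as_tibble(utils::modifyList(rec, list(...)))
}
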