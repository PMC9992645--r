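# trioscreen

Candidate-gene evidence analysis for trio-sequencing studies of
neurodevelopmental disorders (NDD). When a handful of de novo variants in
one gene turn up in probands with infantile spasms or developmental
disorders, the case for that gene rests on several independent lines of
computable evidence. trioscreen implements that chain as a tested,
reusable R pipeline:

* **Trio QC and de novo calling** — GATK-style hard filters on a trio VCF
  (site level: MQ ≥ 35, QD > 2, FS ≤ 60, SOR ≤ 3, MQRankSum ≥ −12.5,
  ReadPosRankSum > −8; genotype level: 0.25 < AB < 0.75 for hets,
  DP > 10, GQ > 25; rarity: population AF < 0.1%; consequence:
  loss-of-function, or missense with CADD > 20), then calls a candidate
  de novo event where the proband is a passing het and both parents are
  passing hom-ref.
* **Event integration and recurrence** — merges cohort events with
  published de novo events in a common table layout, counts function
  classes and finds recurrent sites (identical genomic variant in ≥ 2
  unrelated probands).
* **Deleteriousness comparisons** — Wilcoxon rank-sum on CADD (exact, or
  tie-corrected normal approximation with continuity correction) and
  Fisher's exact test on SIFT (D/T) and PolyPhen (D/P/B) bin tables,
  between groups such as de novo vs population-private missense variants,
  or recurrent vs non-recurrent carriers.
* **Co-expression percentile** — ranks a target gene among all
  cortex-expressed genes (RPKM > 0.5 in ≥ 50% of developing-cortex
  samples) by its mean |Spearman ρ| with known IS/EE/DD gene sets;
  a low percentile means the target co-varies with known disease genes.
* **Expression trajectory** — OLS regression of RPKM on
  post-conceptional age (birth at 280 days), per period and region
  group, to contrast prenatal up-regulation with postnatal behaviour.
* **Synthetic data** — seeded generators for expression atlases with a
  latent co-expression module and prenatal ramps, variant cohorts with
  shifted score distributions, and truth-labelled trio VCFs covering
  every QC threshold boundary, so the whole pipeline is testable with no
  downloads.

## Worked example

```r
library(trioscreen)

# bundled integrated de novo event table (9 events, chr5/hg19)
ev <- load_mast4_events()
count_by_function(ev)
#>  missense stop_gain
#>         8         1

find_recurrent_sites(ev)[, c("key", "protein_change", "n_probands")]
#>   key            protein_change n_probands
#> 1 5:66459419:C:T p.1471T > I             3
#> 2 5:66460439:C:T p.1811S > F             2

# recurrent vs non-recurrent carriers, per-proband CADD
s <- per_proband_scores(ev, "cadd")   # {26.3 x3, 27.3 x2} vs {25.5, 22.9, 23.4}
wilcoxon_ranksum(s$recurrent, s$non_recurrent)
#> <comparison_result> wilcoxon_ranksum: p = 0.0314 (n1 = 5, n2 = 3,
#>                     tie-corrected normal approximation)

# truth-labelled trio VCF through the QC cascade
vcf <- tempfile(fileext = ".vcf")
truth <- simulate_trio_vcf(vcf, n_sites = 500, seed = 1)
run_qc_pipeline(vcf)
#> <qc_result> 500 records in, 148 candidate de novo events out
#>            stage removed remaining
#>            input       0       500
#>           rarity      91       409
#>     site_filters      80       329
#>  genotype_denovo     128       201
#>      consequence      53       148

# co-expression percentile of a gene planted in the latent module
atlas <- simulate_atlas(atlas_config(module_loading = 1, seed = 1))
sets <- simulate_gene_sets(atlas, sizes = c(IS = 38), in_module_fraction = 1,
                           seed = 2)
percentile_of_gene("MOD001", setdiff(sets$IS, "MOD001"), atlas, set_name = "IS")
#>   gene   set_name mean_abs_rho percentile universe_size
#> 1 MOD001 IS              0.817       8.58           478

# prenatal trajectory of a planted 0.05 RPKM/day ramp
fit_trajectory(atlas, "RAMP001", "CC", "prenatal")
#>    slope intercept r_squared  p_value  n period   region_group
#> 1 0.0537     -2.24     0.846 1.19e-27 66 prenatal CC
```

The funnel shows how many records each stage removed (stages run in order
rarity → site filters → de novo genotype → consequence; counts always
conserve the input). The percentile of 8.6 places the planted gene in the
top decile of the 478-gene cortex-expressed universe for co-expression
with the planted set; the trajectory fit recovers the planted prenatal
slope (0.054 vs 0.05) with R² = 0.85 before birth.

`run_pipeline()` chains all stages over file inputs and writes per-stage
TSVs plus a seeded, hash-stamped `summary.json`.

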