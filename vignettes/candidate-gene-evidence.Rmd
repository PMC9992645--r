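---
title: "Candidate-gene evidence from trio sequencing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene evidence from trio sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioscreen)
```

## Scope

trioscreen implements the evidence chain used to nominate a candidate gene
from trio sequencing of neurodevelopmental disorders (NDD) with infantile
spasms: hard-filter quality control of trio VCFs with de novo calling,
integration of cohort events with published de novo events and
recurrent-site detection, deleteriousness-score group comparisons, a
developmental-brain co-expression percentile, and prenatal/postnatal
expression-trajectory regression. A synthetic-data module generates every
input with known ground truth, so the full pipeline is testable offline.
The exported functions are the interface; `run_pipeline()` orchestrates
the stages end to end over file inputs and emits a seeded, hash-stamped
JSON summary.

## The QC cascade

Variant-level filtering follows the GATK hard-filter tradition. A site is
kept iff

* MQ &ge; 35, QD &gt; 2, FS &le; 60, SOR &le; 3,
  MQRankSum &ge; &minus;12.5, ReadPosRankSum &gt; &minus;8.

Published descriptions of such filters are not always internally
consistent about comparator directions for FS and the rank sums; we adopt
the GATK-convention reading (remove FS &gt; 60, remove
MQRankSum &lt; &minus;12.5) and expose every cutoff and direction through
`qc_thresholds()`. A missing site metric passes its single criterion:
rank sums are emitted only when computable, and filtering on absence
would discard valid homozygous-context sites.

Genotype-level filtering keeps a call iff DP &gt; 10, GQ &gt; 25 and its
allele balance AB = alt-AD / total-AD satisfies the class rule: strictly
inside (0.25, 0.75) for heterozygous calls; AB &le; 0.25 for
homozygous-reference calls (parental purity — the published window only
makes sense for hets, and de novo calling needs a bound on parental alt
evidence); AB &ge; 0.75 for homozygous-alt calls. AB is always derived
from AD, never read from a FORMAT field. Zero or missing coverage fails.
One consequence worth knowing: `ab_low` is dual-role. Lowering it loosens
the het window but *tightens* the parental purity rule, so filter
monotonicity ("loosening never shrinks the survivor set") holds for every
threshold except downward moves of `ab_low`.

A candidate de novo event is a record where the proband is a passing het
and both parents are passing hom-ref; a missing parental genotype makes
inheritance unknown, never de novo. Rarity keeps variants with population
allele frequency &lt; 0.1% (missing frequency = absent from the database,
which passes); the consequence rule keeps loss-of-function classes
(stop-gain, frameshift, splice) unconditionally and missense only with
CADD &gt; 20 — missense with no CADD annotation fails, because the score
requirement cannot be established. Stages run in the order rarity &rarr;
site &rarr; genotype/de novo &rarr; consequence, and the funnel report
conserves records exactly. Multi-allelic records are rejected with an
explicit error: splitting and left-alignment belong upstream, and silent
mis-parsing of AD fields is worse than a refusal. Coordinates are 1-based
GRCh37/hg19 and variant identity is always the genomic key
(chrom, pos, ref, alt).

## Event integration and recurrence

`integrate_cohorts()` concatenates study and published event tables in the
common 21-column layout, rejects duplicated (proband, variant) pairs and
orders by position. Recurrent sites are genomic keys carried by two or
more distinct probands. Variant identity is deliberately genomic rather
than protein-level: published tables occasionally disagree between the
running text and the table itself on protein-level names for the same
genomic variant, and the bundled fixture stores the table form verbatim
without resolving such discrepancies.

For the recurrence score comparison the unit is the *proband*, not the
site: a site carried by three probands contributes its CADD three times.
With the bundled nine-event table this yields recurrent
{26.3, 26.3, 26.3, 27.3, 27.3} versus non-recurrent {25.5, 22.9, 23.4}
(the stop-gain is excluded from missense score comparisons), and the
tie-corrected, continuity-corrected rank test below returns p = 0.0314.

## Group-comparison statistics

`wilcoxon_ranksum()` uses the exact rank-sum distribution when the pooled
sample is tie-free and both groups have fewer than 50 observations;
otherwise the normal approximation with tie-corrected variance and a 0.5
continuity correction. All tests are two-sided by default — reported
contrasts here come with no sidedness statement, and the two-sided
corrected computation is the one that reproduces the worked example
above. `fisher_exact_rxc()` evaluates bin-count tables exactly (complete
enumeration) up to a total of 300 observations and by seeded Monte-Carlo
(&ge; 1e5 draws) beyond; all-zero rows/columns are dropped first and a
table collapsing below 2&times;2 is an error. SIFT is compared as a
2&times;2 (D/T) and PolyPhen as a 2&times;3 (D/P/B) table by default,
with an optional collapse to damaging-vs-not: the three-bin prediction is
what annotation engines emit, and collapsing discards the
possibly-damaging mass. "Private" population variants are operationalized
as allele count 1 in the non-neuro reference subset.

Calibration: the 2&times;3 default has empirical size within a point of
the nominal 5% under a shared multinomial null at n = 30 per cohort. An
exact conditional 2&times;2 test at that sample size is intrinsically
conservative (true size &approx; 2.7% under a balanced binomial null) —
this is a property of exact tests on discrete 2&times;2 tables, not an
implementation artifact, and is why the calibration suite exercises the
r&times;c shape the module actually runs.

## Co-expression percentile

The ranking universe is the set of cortex-expressed genes: RPKM strictly
&gt; 0.5 in at least half of all developing-cortex samples (the 11
neocortical region codes A1C, DFC, IPC, ITC, M1C, MFC, OFC, S1C, STC,
V1C, VFC, across all ages; the list is configurable). For each universe
gene we compute the mean over set members of |Spearman&rsquo;s &rho;|
across *all* atlas samples (average-rank ties; signed mode available);
a gene that is itself a set member is excluded from its own mean, and
pairs with constant expression are skipped. The target's percentile is

100 &times; #{universe genes with strictly greater mean} / universe size,

with genes exactly tied with the target counting one half; the target
itself is not counted, so the top-ranked gene scores exactly 0 and the
mean percentile over an all-distinct universe is 50(n&minus;1)/n rather
than exactly 50. Low percentile = stronger co-expression with the known
disease genes. Note a saturation property: when a latent module is
strong, all module genes are exchangeable near the top of the ranking, so
the best achievable mean percentile for a module member is about half the
module's share of the universe.

## Trajectory regression

Ages are mapped to post-conceptional days (pcw &times; 7; birth at 280
days; postnatal months &times; 30.4375 and years &times; 365.25 after
280), calendar-average constants that are configurable and logged.
Samples strictly before 280 days are prenatal. `fit_trajectory()` is
plain OLS of RPKM on age-in-days within one period and region group —
deliberately untransformed, matching the canonical `lm()` analysis; a
`log1p` option exists but is off. Region groups: CC = the 11 neocortical
codes, FC = {DFC, MFC, OFC, VFC}; the exact dissection codes behind
published "cerebral cortex" / "prefrontal cortex" aggregates are not
stated anywhere authoritative, so these lists are documented assumptions
and configurable. Strata need &ge; 3 samples and age variance; a
zero-variance response is reported as slope 0, R&sup2; 0, p 1 (the raw
least-squares quantities are undefined there).

## What the synthetic data emulates

`simulate_atlas()` builds one sample per (region, age) cell over the 16
canonical brain regions and a default 12-point age grid from 8 pcw to 40
years (6 prenatal, 6 postnatal ages). Structure planted on top of
independent background genes:

* a single latent factor (smooth in log age plus sample-level variation)
  shared by the module genes with positive gene-specific loadings scaled
  by `module_loading` &isin; [0, 1] — the simplest structure that makes
  the percentile statistic's power testable;
* linear prenatal ramps (default 0.05 RPKM/day, plateau after birth) in
  the designated ramp genes, with mean-one log-normal noise so the
  planted slope stays unbiased under OLS;
* log-normal multiplicative noise (log-scale SD 0.3 by default)
  everywhere — RPKM is non-negative and right-skewed, and no published
  noise model exists to copy;
* a 5% fraction of background genes at sub-threshold expression so the
  cortex-expressed filter has something to exclude.

`simulate_variant_cohorts()` draws a de novo and a private cohort with
truncated-normal CADD (defaults 26 &plusmn; 3 vs 18 &plusmn; 5 — a
separation of the size seen between disease-cohort de novo missense
variants and population-private missense variants) and SIFT/PolyPhen bins
at damaging fractions 0.9 vs 0.4. `simulate_trio_vcf()` writes a VCF
v4.1 trio with a deterministic block placing at least one record exactly
at, strictly below and strictly above every QC threshold, plus randomized
pass/fail scenarios; truth labels are assigned by construction from the
generator's own reading of each rule, which is what makes the
record-for-record QC equivalence check a genuine oracle test.

What the generator does *not* emulate: linkage disequilibrium, read-level
alignment artifacts, multi-allelic sites, realistic population site
spectra, region-specific expression programs beyond the single module, or
batch effects. Passing tests therefore demonstrate correctness of the
statistics and filters under their stated models, not robustness to every
pathology of real exomes or atlases.

## Problem sizes and numerical choices

The test suite runs desk-scale versions of every analysis: QC truth
recovery on 520-site VCFs across five seeds; percentile planted-signal
recovery on 100 replicates of a 500-gene, 16&times;12-sample atlas with a
37-gene set drawn from a 50-gene module (and 100 null replicates checked
against uniformity); trajectory recovery on 100 replicates of a 40-gene
atlas; calibration on 2,000 null simulations at n = 30 per group. Exact
enumeration in Fisher tests is bounded at N = 300; Monte-Carlo p-values
use &ge; 1e5 draws. External-atlas results (real BrainSpan percentiles
and R&sup2; values) require the real downloads and are documented
integration checks, not part of this suite.

## Known limitations

* The X chromosome is out of scope: hemizygous de novo logic and
  mosaicism are not modelled.
* The parental AB &le; 0.25 purity rule is an assumption; published
  descriptions do not state whether any AB window was applied to
  parents.
* Percentile tie handling (half-count, self excluded) is a convention;
  interpolated ranks would differ in the third decimal on realistic
  universes.
* The co-expression statistic is a marginal screen, not network
  inference; partial correlations are deliberately absent.
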