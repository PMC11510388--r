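---
title: "Stratified gut-microbiota analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified gut-microbiota analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asdgm)
```

`asdgm` implements an end-to-end analysis of 16S amplicon sequence
variant (ASV) tables for autism-spectrum cohorts stratified by
neuropsychological assessment. This vignette is the package's account of
the science: the procedures, their assumptions, the tunable parameters,
what the synthetic-data generator does and does not emulate, and where
the design was genuinely open.

## Clinical stratification

Subjects are stratified independently on five variables:

* **ADOS-2 calibrated severity score (CSS)**, a 1–10 metric of core
  autism symptom severity, split into *mild/moderate* versus *severe*.
  The severe cutoff is not standardized across clinical sites; the
  default is CSS ≥ 8, consistent with published CSS banding and with a
  cohort whose mean CSS sits near 7 while roughly 40% of subjects are
  severe. It is exposed in `strat_config()`.
* **CBCL t-scores** (Internalizing, Externalizing, Total Problems),
  using the instrument's own bands: t < 60 no clinical symptoms,
  60 ≤ t ≤ 63 at risk, t ≥ 64 clinical symptoms. Both boundaries are
  inclusive on the at-risk side (60 and 63 are both *at risk*).
* **IQ/DQ**, split at 70 into cognitive impairment / developmental
  delay (CI/DD) versus no CI/DD. The 70 cutoff is the conventional
  psychometric boundary but is an assumption here, and configurable.

Missing scores are never imputed: a subject with a missing CSS simply
drops out of the CSS stratification (and its denominator) while
remaining in every other analysis. Reported percentages use the scored
count as denominator and integer rounding half away from zero.

## Feature-table preprocessing

The pipeline consumes a ready-made ASV-by-sample count table (sequence
processing — denoising, chimera removal, taxonomic assignment — is out
of scope). Two filters are applied, and a feature is kept only if it
passes both, which makes the filter order-insensitive:

1. **Prevalence**: non-zero in at least 25% of samples, implemented as
   `ceiling(0.25 * n_samples)` with an inclusive boundary (1 of 4
   samples passes).
2. **Relative abundance** > 0.01. The rule is ambiguous in common
   usage — per-sample or averaged, fraction or percent. The default
   reads it as a fraction (1%) satisfied in *at least one* sample,
   the least destructive reading; a mean-across-samples variant is
   available in `filter_features()`.

Downstream, two normalizations serve two branches. **Rarefaction**
(without-replacement subsampling to the minimum retained depth, after a
1000-read QC floor) feeds alpha and beta diversity, where even sampling
effort matters more than efficiency. **Cumulative sum scaling (CSS)**
feeds the differential-abundance models: each sample is divided by the
sum of its counts at or below the median of its non-zero counts (times
1000), which is robust to a handful of dominant taxa soaking up
sequencing effort. The original method's adaptive percentile selection
is deliberately not implemented; the percentile is fixed at 0.5 and
exposed as an argument. CSS output is invariant to multiplying a sample
by a positive constant.

Rank aggregation sums counts over features sharing a lineage label at
the requested rank; unassigned labels pool into one explicit
`"unassigned"` taxon so per-sample totals are conserved.

## Diversity

Alpha diversity uses Chao1 (bias-corrected,
$S_{obs} + F_1(F_1-1)/(2(F_2+1))$, requiring integer counts), Shannon
entropy in nats (base configurable), and Gini–Simpson $1 - \sum p_i^2$.
Group differences use an omnibus Kruskal–Wallis test (tie-corrected,
asymptotic chi-square p) with two-sided Mann–Whitney post-hoc pairs. No
multiple-testing correction is applied to post-hoc pairs by default —
the reporting convention this pipeline mirrors uses raw thresholds — but
Benjamini–Hochberg adjustment is a flag away. At very small group sizes
the chi-square approximation and an exact-enumeration Mann–Whitney can
disagree right at the significance boundary; the tests acknowledge that
by checking decisions away from the boundary.

Beta diversity is Bray–Curtis,
$d(x,y) = 1 - 2\sum_i \min(x_i,y_i)/(\sum x + \sum y)$, tested by
PERMANOVA with $p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})$ (999
permutations and an explicit seed by default), and ordinated by
principal coordinates. PCoA reports the full eigenvalue spectrum,
including negative eigenvalues from non-Euclidean dissimilarities,
rather than silently truncating it; explained-variance fractions are
relative to the positive part.

## The Microbial Dysbiosis Index

The MDI scores a subject's composition against a control reference by
the quadratic dissimilarity

$$Z = \sqrt{\tfrac{1}{2} \sum_t (f_{case,t} - f_{controls,t})^2} \times 100,$$

ranging from 0 (identical profiles) to 100, the maximum being attained
when each profile concentrates all mass on a taxon absent from the
other. Three design points were genuinely open:

* **The case profile.** A "median of the patient's taxa distribution"
  is ill-defined for a single composition; a per-subject MDI (needed
  for cohort means and subgroup comparisons) uses the subject's own
  relative-abundance vector at the rank. A group mode (median profile
  of a case subgroup) is available through `build_reference()` on the
  subgroup.
* **The control reference.** Coordinate-wise medians of compositions
  need not sum to one, and the $[0,100]$ bound is only guaranteed on
  the simplex, so the median vector is renormalized by default
  (disable with `renormalize = FALSE`, which also relaxes the bound
  check in `mdi_score()`).
* **Combining ranks.** Z is computed at phylum, family and genus rank;
  the composite is their unweighted mean, and the per-rank values are
  always retained since no combination rule is canonical.

Z is symmetric and bounded (property-tested on random compositions) but
is not claimed to be a metric; no triangle inequality is asserted, and
no monotonicity across rank refinement is assumed.

For testing, `perturb_for_mdi()` constructs a composition at an exact
requested Z from any base: draining a fraction $s$ of every coordinate
into the largest one makes $Z(s)$ linear in $s$, so the drain fraction
solves exactly. The attainable maximum is reached at $s = 1$.

## Dual-method biomarker discovery

Discriminatory taxa must be supported by two arms simultaneously:

1. **Effect-size arm**: a Kruskal–Wallis screen at $\alpha = 0.05$
   followed by a bootstrapped linear-discriminant effect size. On each
   of 30 bootstrap iterations, two-thirds of every class is subsampled
   and a one-dimensional per-feature discriminant evaluated; with a
   single feature the unit-norm discriminant axis is trivial, so the
   effect reduces to the signed difference between the feature's most-
   and least-enriched classes (fixed from the full data, one-vs-all
   style). Effects are averaged *signed* across bootstraps — a feature
   whose class distributions coincide cancels toward zero — and
   reported as $\log_{10}(1 + |\bar e|)$. Scores are covariant with the
   input scale; the pipeline feeds per-million-rescaled abundances so
   that the conventional "LDA > 2" cutoff corresponds to roughly 100
   parts per million of mean separation. The original algorithm's
   subclass (within-class Wilcoxon) stage is omitted: this design has
   no subclasses.
2. **Model arm**: per feature,
   $\log(x + \epsilon) \sim group + age + gender$ on CSS-normalized
   abundances, with the group p-value from a nested-model F comparison
   (covariate-only versus full) so that three-class variables get an
   omnibus test. The pseudocount $\epsilon$ is half the smallest
   non-zero value of the table and is recorded on the result. Whether
   the linear models should run on log-transformed or raw normalized
   abundances was open; log is the default because the abundance noise
   is multiplicative.

A feature is a **consensus biomarker** iff the screen passes, the LDA
score exceeds 2, and the adjusted-model group p is below 0.05. Features
supported by one arm only are kept in the report marked
`single-method`; BH-adjusted q-value columns are always emitted
alongside the raw p-values.

`pathway_differential()` applies the same machinery to a functional
(KO/pathway) table; its model arm can optionally use limma-voom
mean–variance precision weights, with the unweighted log-linear model
as the reference arm.

The age/gender confounder check bins age into two classes (default at 6
years — the binning is not canonical and is configurable) and flags a
factor as a confounder when its Bray–Curtis PERMANOVA p falls below
0.05, feeding the linear models' covariate list.

## The synthetic cohort generator

`generate_cohort()` emulates the structure of the target study design:
70 cases and 70 matched controls; gender allocated exactly at 80/20
male/female; ages from a normal with location 6.91 and scale 3.17
truncated to 3–17 years (truncation shrinks the realized SD to about
2.2 — the stated location/scale are used as given, and tests compare
against the truncated distribution's own moments); CSS from a
discretized truncated normal (7.0 ± 1.5) on 1–10; CBCL t-scores from
per-scale normals whose defaults (INT 65 ± 8, EXT 59 ± 8, TOT 64 ± 9)
populate all three bands in roughly the proportions such cohorts show;
IQ/DQ normal 63 ± 20; and missing-score counts mirroring a real cohort
(5/70 CSS, 9/70 CBCL, 1/70 IQ). Subgroup labels are *derived* from the
simulated scores through the cohort module, so labels and scores are
consistent by construction.

Compositions come from a Dirichlet (precision 50) around a log-normal
ranked base composition — realistic dominance structure with heavy
per-taxon overdispersion — with counts drawn multinomially at negative-
binomial depths (mean 20000, size 10) floored at 1000 reads. The
taxonomy is a random 7-rank hierarchy with Greengenes2-style suffixed
names (e.g. `GenXX_A`) to exercise name handling.

Planted group effects multiply chosen taxa by $e^{logfold}$ in the
expected composition of subjects in the chosen subgroup, followed by
renormalization. `default_planted_effects()` draws planted taxa from
the mid-abundance band (0.5–3% relative abundance): below the
pipeline's own 1% abundance filter a planted effect is removed before
any test sees it, while planting on the dominant taxa moves so much
mass that renormalization induces visible shifts on every other
feature. Even in the mid band, **compositional spillover is real**: a
planted mass fraction $m$ at fold $e^{1.5}$ compresses all other taxa
by $1/(1 + m(e^{1.5}-1))$ in the affected subgroup. CSS normalization
absorbs most of this (the scaling factor compresses by the same
amount), but rank-based tests can still sense the residual change in
dispersion of rare taxa.

What the generator does **not** emulate: phylogenetic correlation
between taxa (the Dirichlet is exchangeable given the base), zero
inflation beyond what the Dirichlet-multinomial induces, batch or
sequencing-run effects, age- or gender-dependent composition (unless
planted explicitly), and any real taxon identities. Passing recovery
tests on these cohorts therefore demonstrates that the machinery
detects planted location shifts under realistic overdispersion — not
that it would behave identically on real stool microbiomes.

## Validation scale and known limitations

The test suite runs null-calibration and recovery experiments at sizes
chosen to finish in minutes on one core: PERMANOVA calibration on 300
null tables of 40 samples × 100 features (199 permutations each),
model-arm calibration on 400 single-feature null fits, and biomarker
recovery on 50 seeded cohorts of 50 cases with 5 planted taxa at
log-fold 1.5. Both calibrations hold their nominal 0.05 level within
±0.02, and planted-taxon sensitivity is 1.0.

Two limitations are worth stating plainly:

* **Raw-threshold consensus does not control the family-wise error.**
  With ~150 features surviving the filter, the two consensus arms are
  highly correlated (they test the same group contrast on the same
  normalized table), so requiring both at raw 0.05 leaves an expected
  handful of null features called per run; the intersection shrinks
  error relative to either single arm but not to ≤ 1 call. Users who
  need stricter error control should gate on the emitted BH q-value
  columns instead of the raw defaults.
* **Per-sample scaling spreads single-feature spikes.** Under
  totals-based scaling (the per-million rescale of the LDA arm, or any
  relative-abundance view), a large planted shift in one feature
  induces opposite shifts in all others; this is a property of
  compositional data, not an artifact of the implementation, and is
  why the model arm runs on CSS-normalized values.
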