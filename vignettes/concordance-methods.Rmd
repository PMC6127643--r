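---
title: "Methods: scoring fecal collection methods against a gold standard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring fecal collection methods against a gold standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Epidemiological microbiome studies rarely get immediately frozen stool.
Field collection uses preservative kits (OMNIgene GUT, 95% ethanol,
RNAlater) or dried formats (FTA cards), and the question every such study
must answer first is: *do measurements from the field method agree with the
measurements we would have gotten from the gold standard, immediate
freezing?* The natural design is paired — each subject contributes one
sample per method from a single stool — and the natural agreement statistic
is the intraclass correlation coefficient (ICC), the fraction of total
variance attributable to subjects rather than to the method/measurement
layer.

`fecalconcord` implements that evaluation end to end for three assay
families: 16S-style taxon count tables, untargeted metabolite intensity
tables (with detection-limit missingness), and a targeted short-chain fatty
acid (SCFA) panel, plus a genus-by-SCFA correlation screen. A synthetic
paired-design generator with known variance components makes every stage
testable without any external data.

## Agreement models

### Scalar ICC

For a scalar variable (an alpha-diversity index, a phylum relative
abundance, a metabolite level) measured on the gold sample $g_i$ and the
alternate-method sample $m_i$ of subjects $i = 1, \dots, n$, we fit the
one-way random-effects model
$$x_{ij} = \mu + u_i + \varepsilon_{ij}, \qquad
  u_i \sim N(0, \sigma_b^2),\ \varepsilon_{ij} \sim N(0, \sigma_w^2),$$
with $k = 2$ replicates per subject, and report the ANOVA estimator
$$\widehat{\mathrm{ICC}} = \frac{MSB - MSW}{MSB + (k-1)\,MSW},$$
the classical ICC(1). Choices worth stating:

* **One-way, not two-way.** The two replicates are not interchangeable
  raters with their own fixed effects we wish to remove; a systematic shift
  introduced by a collection method is a disagreement and should count
  against concordance. (The underlying study's software choice is not
  documented beyond "an ICC package", so this is our design decision, not a
  claim about theirs.)
* **Negative estimates are reported as-is.** Truncation at zero would hide
  exactly the failures the comparison exists to find; published
  concordances in this area go as low as 0.01.
* **All values identical** means both variance components are zero and the
  ratio is undefined; this is an explicit error, not a silent 1 or NaN.

Confidence intervals are nonparametric percentile bootstrap over
*subjects* (pairs resampled intact), default $B = 1000$. Resamples with
undefined ICC (all resampled values identical) are redrawn and counted.
The same CI machinery serves scalars and the distance-based ICC so that a
report mixes only one interval type.

### Distance-based ICC for beta-diversity

Beta-diversity lives in a dissimilarity matrix, not a scalar, so the ICC is
re-expressed in squared distances. With $d(\cdot,\cdot)$ the Bray-Curtis
distance, within-subject variance is estimated from each subject's own
gold/method pair,
$$\hat\sigma_w^2 = \frac{1}{2n}\sum_i d(g_i, m_i)^2,$$
and total variance as the mean of $d^2/2$ over all pairs of samples from
*different* subjects (four sample pairs per subject pair). The ICC is
$(\hat\sigma_t^2 - \hat\sigma_w^2)/\hat\sigma_t^2$: at most 1 by
construction, negative when paired samples sit farther apart than strangers.

The correctness anchor is a reduction: if samples are points on the real
line and $d$ is Euclidean distance, $d^2$ recovers squared differences and
the formula collapses to the moment version of the scalar ICC. The test
suite verifies agreement with `icc_oneway()` within ±0.05 at $n = 200$ on
exactly that embedding (in the balanced two-replicate case the two
estimators are algebraically near-identical; observed agreement is to
machine precision).

The subject bootstrap for this ICC resamples subjects with replacement and
rebuilds the statistic on the induced submatrix; duplicated subjects enter
as distinct copies, so zero distances between copies of the same physical
sample legitimately appear in the between-subject average.

## Diversity, ordination and group tests

* **Shannon** uses natural logarithm (the vegan convention), **Simpson** is
  the Gini-Simpson form $1 - \sum p_i^2$ (bounded in $[0,1]$, matching how
  such values are plotted in this literature), and **Chao1** is the
  bias-corrected form $S_{obs} + F_1(F_1-1)/(2(F_2+1))$, which is defined
  when no doubletons exist and requires raw integer counts. All three are
  computed on the unrarefied count table: the motivating analysis nowhere
  mentions rarefaction, and whether diversity was computed at even depth is
  deliberately left as a user choice rather than guessed.
* **Bray-Curtis** distances default to the table as supplied (vegan
  convention), with an option to convert to relative abundances first; the
  matrix itself is delegated to `vegan::vegdist` while the scalar
  definition is kept in-package as the elementwise oracle for testing.
* **PCoA** is classical scaling via `stats::cmdscale`; negative eigenvalues
  (expected for Bray-Curtis) are reported unmodified and excluded from the
  proportion-explained denominator. No Lingoes/Cailliez correction.
* **Kruskal-Wallis** across methods wraps `stats::kruskal.test`, with the
  all-tied degenerate case mapped to $H = 0$, $p = 1$.
* **PERMANOVA** is authored in-package from the squared-distance partition
  (Anderson's pseudo-F, one factor, free permutation of labels, no
  strata), with $p = (1 + \#\{F^* \ge F\})/(B + 1)$ so permutation p-values
  are never zero and never below $1/(B+1)$. Default 999 permutations; the
  seed is a required argument because a reproducible report beats a
  convenient default. The F statistic is checked against `vegan::adonis2`
  in the tests.
* Sample-level QC drops samples under 1000 reads by default, the standard
  failed-library exclusion.

## Metabolomics preprocessing

Detectability of a metabolite within a method is the fraction of
participants whose sample has a non-missing value; it is always computed on
raw, pre-imputation data. The overlap table counts, at levels all / ≥50% /
≥75% / 100%, each method's detected features and the subset shared with the
gold standard, as counts and as percentages of the gold set (one decimal,
half-away-from-zero — the table-formatting convention of the motivating
study). The ≥75% level with $n = 8$ participants corresponds to ≥6
detected, via the ceiling rule.

The concordance preprocessing chain is, per method:

1. **half-minimum imputation** — each missing cell gets half the minimum
   detected value of that metabolite within that method;
2. **quantile normalization** (Bolstad-style; each sample's order
   statistics are replaced by across-sample means of order statistics, ties
   receiving the mean of the reference values they span — identical to
   `limma::normalizeQuantiles(ties = TRUE)`, which the tests use as the
   oracle);
3. **log10**.

The source description lists normalization before imputation in the same
paragraph without fixing an order; we impute first because quantile
normalization is only well-defined on complete columns. This is a
divergence-risk decision: a pipeline that normalized the incomplete matrix
by some other convention would produce slightly different per-feature ICCs.
Note the exact "same multiset in every sample" property of quantile
normalization holds verbatim only for tie-free data; with ties the averaged
reference values break it by design.

Per-metabolite ICCs are then computed on the shared ≥75%-detectability set
(intersection of gold and method sets — the restriction "between the gold
standard and each method" is read as the intersection) and summarized by
median and interquartile range per method.

## Correlation screen

Genus-level relative abundances are square-root transformed (the
variance-stabilizing convention for taxonomic proportions used throughout)
and screened against the SCFA panel by Spearman correlation within each
method. For $n \le 9$ the two-sided p-value is computed by full enumeration
of all $n!$ orderings — exact, and valid under ties where the classical
S-statistic tables are not; above that, the usual t-approximation. The
published p-values this reproduces (e.g. $\rho = 0.83$, $p = 0.010$ at
$n = 8$) match the *t-approximation* convention; the exact p for the same
rho is 0.0154. Both paths are exposed (`exact_max_n`), the exact one being
the default at small n.

Bonferroni control defaults to the number of tests actually performed. The
published critical value of 0.002 implies a family of 25 tests, which is
not derivable from any stated count, so the family size is overridable.

## The synthetic world

`generate_paired_scalars()` is the pure variance-components model: subject
effect $N(0, \rho\sigma^2)$ plus replicate noise $N(0, (1-\rho)\sigma^2)$,
so the true ICC is exactly the requested $\rho$.

`generate_community()` emulates the study shape — 8 subjects × 5 methods =
40 samples — with a log-normal composition model: a common base profile
(SD 2 across taxa), subject offsets (`subject_sd`, default 1), per-sample
method noise (`method_sd`, default 0.3), softmax to proportions, and
multinomial counts at Poisson depths around `depth_mean` (default 18,000,
the study's average coverage). The default subject/method SD ratio puts the
simulation in the regime the study reports: inter-individual differences
dominate Bray-Curtis space, and distance ICCs land above 0.88. The model
makes no claim to real stool ecology — no phylogeny, no batch structure, no
zero-inflation beyond multinomial sampling — so a green test establishes
that the *estimators* behave, not that the generator is biologically
faithful.

`generate_metabolome()` draws a per-feature true ICC uniformly in
`icc_range` (default 0.2–0.9, spanning the low-concordance regime the
untargeted comparison actually found), builds latent log-intensities with
unit total variance, exponentiates, and censors values below the feature's
marginal `censor_quantile` (default 0.25), with optional per-method
threshold shifts so methods can differ in detectability the way collection
chemistry makes them differ. The recorded truth object carries every
parameter needed to recompute expected estimates; there are no hidden
knobs. Because the truth lives on the log scale, recovery checks on raw
intensities must log-transform first — exponentiation is a nonlinear map
and attenuates the ICC.

## Numerical and degenerate-input choices

* Percentile intervals use `stats::quantile` type 7; measured coverage of
  the 95% interval at $n = 50$, true ICC 0.8, $B = 1000$ is ≈0.925 —
  the usual modest small-sample undercoverage of the percentile method.
* Permutation and bootstrap seeds are mandatory arguments; all generators
  and the pipeline are bit-reproducible given their seeds, and library code
  restores the caller's RNG state.
* Zero-variance inputs (identical values everywhere) raise errors in every
  estimator rather than returning a conventional value; all-zero abundance
  vectors are rejected by the diversity indices; zero-total samples are
  rejected by `relative_abundance()`.
* Aggregation keeps unannotated taxa under a `<Deepest>_UCG`-style
  placeholder (e.g. `Rikenellaceae_UCG` for an unclassified genus in a
  known family) because downstream correlation tables legitimately feature
  unclassified genera; dropping them would break column-total conservation.

## Known limitations

* Chao1 concordance saturates below the other indices even when the
  generator's method noise is exactly zero: the singleton/doubleton
  correction keeps order-one noise under multinomial resampling while
  between-subject richness variance is bounded, so simulated chao1 ICCs sit
  around 0.8–0.98 where Shannon/Simpson reach 0.9999. This is a property of
  the estimator, not a bug — and it is consistent with chao1 showing the
  lowest concordance of the three indices in real comparisons.
* The distance-based ICC formula is reconstructed from its published
  description (the original delegates to an external algorithm); the 1-D
  Euclidean equivalence with the scalar ICC is the correctness anchor, and
  no claim is made that it reproduces any specific prior implementation's
  edge-case behaviour.
* The exact estimator behind the published alpha-diversity ICCs, their CI
  construction, and the handling of the one excluded low-read sample in the
  published beta-diversity ICC are all unstated in the source; the choices
  here are documented defaults, not reverse-engineered facts.
* No rarefaction, no UniFrac (no tree is consumed), no FDR control other
  than Bonferroni, no compositional (CLR) association methods.
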