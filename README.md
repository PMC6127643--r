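# fecalconcord

Concordance evaluation of fecal collection methods for integrated
microbiome + metabolomics studies.

## What problem this solves

Large epidemiological studies cannot ship immediately frozen stool; they
collect with preservative kits (OMNIgene GUT, 95% ethanol, RNAlater) or
dried formats (FTA cards). Before fielding a protocol you need to know how
well each method's measurements agree with the gold standard of immediate
freezing, across everything you plan to measure: alpha-diversity,
beta-diversity, taxon abundances, untargeted metabolites, and targeted
short-chain fatty acids (SCFAs). This package implements that paired-design
evaluation as a tested, reusable pipeline, for microbiome/metabolomics
methodologists and analysts.

## The statistics at its core

With each of n subjects contributing a gold-standard sample and an
alternate-method sample, agreement for a scalar variable is the one-way
random-effects intraclass correlation, estimated by ANOVA with k = 2
replicates:

    ICC = (MSB − MSW) / (MSB + (k − 1)·MSW),

with subject-level percentile-bootstrap 95% CIs (B = 1000). Beta-diversity
agreement uses a distance-based ICC on the Bray-Curtis matrix:

    σ̂w² = (1/2n) Σᵢ d(gᵢ, mᵢ)²,   σ̂t² = mean over between-subject pairs of d²/2,
    ICC = (σ̂t² − σ̂w²) / σ̂t²,

which reduces to the scalar ICC on 1-D Euclidean data (the package's
correctness anchor). Around these sit: Shannon/Gini-Simpson/bias-corrected
Chao1 indices, PCoA, Kruskal-Wallis and permutation PERMANOVA,
detectability/overlap accounting for metabolites, half-minimum imputation →
quantile normalization → log10 preprocessing, per-metabolite ICC profiles
(median, IQR), and genus×SCFA Spearman screens with exact small-n p-values
and Bonferroni control. A synthetic paired-design generator with known
variance components (hence known true ICCs) backs the test suite. See
`vignettes/concordance-methods.Rmd` for the full methods account.

## Worked example

Simulate the study design (8 subjects × 5 collection methods, ~18k reads
per sample), QC, and score one method against immediate freezing:

```r
library(fecalconcord)

sim <- generate_community(n_subjects = 8, n_taxa = 200, seed = 2018)
qc  <- filter_low_depth(sim$table, min_reads = 1000)   # drop failed libraries
a   <- alpha_diversity(qc$table)
head(a, 3)
#>               sample_id  shannon   simpson    chao1
#> 1 S1.immediate_freezing 2.515228 0.8110625 173.0000
#> 2       S1.omnigene_gut 2.795392 0.8388438 167.2857
#> 3         S1.ethanol_95 2.455817 0.7737826 191.1000

sh <- setNames(a$shannon, a$sample_id)
pr <- pair_by_subject(sh, sim$design, "fta_card", variable = "shannon")
icc_oneway(pr, n_bootstrap = 1000, seed = 1)
#> <icc_estimate> anova_oneway: 0.643 [-0.137, 0.826] (n = 8 subjects)

D <- distance_matrix(qc$table)                         # Bray-Curtis
bootstrap_distance_icc(D, sim$design, "fta_card", B = 1000, seed = 2)
#> <icc_estimate> distance_based: 0.891 [0.810, 0.919] (n = 8 subjects)

grp <- sim$design$samples$method[match(colnames(qc$table$values),
                                       sim$design$samples$sample_id)]
permanova(D, grp, n_permutations = 999, seed = 3)
#> <group_test> permanova: statistic = 0.0662, p = 1 (5 groups, 40 samples)
```

Reading the numbers: the Shannon ICC of 0.64 says subject identity explains
about two-thirds of the variance in Shannon diversity between the paired
FTA-card and frozen samples (at n = 8 the CI is wide and dips negative).
The distance-based ICC of 0.89 says subjects, not collection method, drive
Bray-Curtis structure — the regime real comparisons report. PERMANOVA
grouping samples *by method* finds nothing (p = 1), as it should when
method effects are small relative to inter-individual differences.

The full study — detectability/overlap tables, per-metabolite ICC
distributions, SCFA panel, correlation screen — runs from one YAML config:

```r
run_all(system.file("extdata", "synthetic_config.yaml",
                    package = "fecalconcord"),
        out_dir = "concordance_out")   # report.json + TSV tables + run.log
```

or from the command line via
`Rscript inst/cli/fecalconcord.R report --config cfg.yaml --out-dir out/`
(subcommands: simulate, diversity, concordance, metabolome, targeted,
correlate, report).

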