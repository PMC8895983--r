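---
title: "Methods: joint-linkage and resampling-GWAS dissection of NAM traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint-linkage and resampling-GWAS dissection of NAM traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(namqtl)
```

# Scope

`namqtl` implements the quantitative-genetics workflow used to dissect
correlated grain traits (carotenoid concentrations and visually scored
kernel color) in multi-family nested association mapping (NAM) panels of
maize recombinant inbred lines (RILs): per-line BLUE estimation from
multi-environment field trials, multi-family joint-linkage (JL) QTL
mapping, resampling-based GWAS on projected dense variants, pleiotropy
quantification, merged-interval candidate-gene resolution, and
prediction of a target trait from component traits. Because the real
panel's genotypes and its ~27M-variant projection are far beyond desk
scale, the package ships a synthetic NAM generator with the statistical
structure the analysis assumes, and every stage is validated against it.

# The synthetic NAM generator

## RIL genomes

Each family descends from a cross of a common parent with one alternate
parent. RIL genomes are produced *generatively*: explicit meioses with
Poisson crossovers on the cM scale (Haldane, no interference) through
`n_gen = 10` generations of selfing from the F1, after which residual
heterozygosity (<0.1% of loci) is forced to fixation. We chose the
generative route over a marker-to-marker Markov chain because the
two-locus RIL recombination fraction R = 2r/(1+2r) is then reproduced
automatically at every distance; a Markov kernel with that marginal
composes to a measurably wrong two-locus value at 10 cM (0.165 instead
of 0.155). The construction also yields the classical two-fold RIL map
expansion (about 2 breakpoints per Morgan per RIL), which the test
suite checks. RILs are fully inbred (0/1 codes), matching the
downstream parental-origin coding; NAM RILs are at least S5 in
practice, so residual heterozygosity is a negligible feature of the
real data that the generator does not carry.

Defaults mirror the study conditions: 10 families sharing a common
parent, ~170 RILs per family (~1,700 lines), and an evenly spaced
genetic map (consensus NAM maps imputed at 0.1 cM resolution run to
~15,000 markers; simulation studies in the tests use 1 cM grids, which
is the resolution that matters for the assertions made on them).
Physical positions default to 1 Mb/cM.

Segregation distortion is implemented as viability selection: an
oversized cohort is simulated and RILs are drawn from the allele
classes at the distorted marker to hit a target frequency, so linked
markers show the expected decaying distortion rather than an isolated
spike.

## Phenotypes

Plot values are built additively: family-nested QTL effects (the
`effect` is the difference between genotype-class means on the 0/1
coding), a family intercept, random draws for year, field-in-year,
set, incomplete block and assay plate, an optional family-by-year
stratum, and a spatial plot error that is separable AR1 x AR1 over row
and range coordinates within each field (defaults rho = 0.4 in both
directions, a moderate level typical of field trials). The design
emulates an augmented sets layout over two years and three fields (two
in year one, one in year two), one plot per line per year.

Design-stratum variances are specified as fractions of the realized
within-family genetic variance so that the generator adapts to any
architecture. The residual variance is calibrated against the target
line-mean heritability h2 via
sigma2_e = p_bar (sigma2_g (1 - h2)/h2 - sigma2_ge / e_bar), with
e_bar and p_bar the (harmonic mean) numbers of environments and plots
per line. Cross-trait pleiotropy at a shared QTL is parameterized as a
correlation of the per-family effect vectors (`pleiotropic_qtl()`).

What passing tests on this generator do *not* show: robustness to
non-additive gene action, genotype-calling error, residual
heterozygosity, non-Gaussian error, or the LD structure of real
founder haplotypes (simulated founder alleles are exchangeable across
loci). Conclusions about those features require real data.

# BLUE estimation

The plot-level mixed model is fitted by REML with a hand-written
engine because the residual structure — a separable AR1 x AR1
covariance over plot coordinates, per field-in-year, under arbitrary
crossed random terms — is not available in the installed mixed-model
packages. The engine profiles the REML log-likelihood with variance
parameters on the log scale and AR1 correlations through atanh, so the
optimization is smooth and unconstrained (Nelder-Mead search followed
by a BFGS polish). The AR1 x AR1 block is evaluated as
C_ij = sigma2_b rho_row^|dr| rho_range^|dc|, which requires no complete
grid; the identity direction of a single-AR1 structure is the
same-coordinate indicator. A floor of 1e-9 x var(y) on residual
variances keeps the covariance positive definite when a variance
collapses (e.g. duplicated plots). On balanced one-way layouts the
REML estimates agree with the closed-form ANOVA estimators to three
decimals, which the tests assert.

Structure selection is two-stage by BIC (`-2 logLik + k log(n)` with k
the number of variance parameters and n the number of non-missing
observations; several conventions exist for REML-BIC, so the one used
is documented here): first the
random structure with an identity residual, then the residual
structure conditional on it; ties break toward fewer parameters, and
the choice is invariant to candidate order.

Outliers are screened by DFFITS on the whitened (GLS-decorrelated)
fixed-line projection; flagged plots are set missing for that trait
only. The default cutoff in the pipeline configuration is 3 — i.e.
conservative, flagging only gross errors; the conventional
2 sqrt(p/n) rule is available but with one line fixed effect per ~2
plots it flags >10% of clean simulated data, which is not the intent
of an outlier screen in this design. BLUEs are then the fixed-line GLS
estimates at the REML variance parameters of the all-random fit
(re-estimating components under the sparse-fixed-line model changes
estimates negligibly and costs another optimization; we plug in).

Box-Cox transformation uses the "convenient lambda": the profile
likelihood (with Jacobian) evaluated on the grid -2(0.5)2 and the best
grid value taken; when non-positive values occur the series is shifted
by -min(y) + 0.001 range(y) first. Line-mean heritability is
h2 = s2_g / (s2_g + s2_ge/e_bar + s2_e/p_bar), with a first-order
delta-method SE from the numerically inverted observed information of
the variance components.

# Joint-linkage mapping

The JL scan regresses transformed BLUEs on map markers with the family
term forced in first and marker effects nested within family (one
slope per family in which the marker segregates; the partial-F
numerator degrees of freedom equal the number of segregating
families). The computational core exploits the disjoint row support of
one marker's family-nested block: its raw Gram matrix is diagonal, so
the partial SS of a candidate given the current model is a small
F x F solve after one sparse cross-product, and a whole-genome scan is
a few matrix products.

Entry thresholds come from permutations of the phenotype *within
family* — the family term is forced into every model, so the null must
preserve between-family structure; published protocols rarely state
the scheme, and this is the only one consistent with a forced family
term. The threshold at level alpha is the
floor(alpha x n_perm)-th smallest of the per-permutation minimum
p-values; exit thresholds are exactly twice the entry threshold.
Forward steps add the best marker at or below the entry threshold
(ties break to the lower chromosome, then lower cM); backward steps
drop any included marker above the exit threshold.

After selection: multicollinearity pruning removes, from any pair of
included markers with |r| of genotype codes strictly above 0.8, the
member with the lower sum of squares; peaks are then re-scanned within
their support intervals, substituting any in-interval marker with a
larger model SS until each peak is a local SS maximum (plateau ties
keep the lowest-cM marker; a revisited model state raises an
oscillation error). The alpha = 0.01 support interval is
operationalized as the contiguous marker run around the peak whose
members, substituted for the peak, stay at or below the alpha = 0.01
permutation threshold. Support intervals are usually reported only by
their level; the substitution mapping above is this package's
construction, documented here.

PVE uses observed within-family allele frequencies (hence robust to
segregation distortion): var_q = sum_f w_f p_f (1-p_f) s_f^2, with
w_f = n_f/N and s_f the family-nested class-difference effect; this is
identical to the p(1-p)(2a)^2 form with a = s/2 the allelic
substitution effect. The denominator is the variance of the
transformed BLUEs. Distortion-aware PVE formulas vary in detail across
the NAM literature; this implementation is validated by parameter
recovery (a planted 15%-PVE QTL is estimated at 15.8% on average over
seeds, inside the +-4 point band).

# Resampling GWAS

Dense founder variants are projected onto RILs by linear interpolation
(in cM) of the parental-origin codes at the flanking map markers,
mapped through the two founders' alleles; a variant colinear with a map
marker reproduces that marker's codes exactly. Single-variant tests
are family-nested dosage slopes, partial F against the family model,
matching the JL conventions.

Each trait is scanned per chromosome against the residuals of its JL
model with the focal chromosome's peaks *removed* (all other peaks and
the family term retained) — the chromosome-specific residual scheme of
the NAM-GWAS lineage, adopted here as an explicit assumption. The
significance threshold at FDR 0.05 is empirical-null: full scans of
within-family permuted residuals are retained and the threshold is the
largest observed p at which
(mean permutation count <= t) / (observed count <= t) stays at or
below the target — one of several defensible constructions, chosen
because it satisfies the natural boundary (FDR 1 passes everything)
and monotonicity requirements, and exposed in the configuration. The
resampling scan then runs 100 iterations, each drawing 80% of the RILs
*with replacement* (a bootstrap, taken literally; without-replacement
subsampling is a switch), with forward selection per chromosome at the
threshold;
RMIP is the inclusion count out of 100, reported at RMIP >= 5.
Forward-selection ties break on the variant identifier so results are
invariant to column order.

# Pleiotropy, loci, prediction

Pleiotropy between traits A and B is the Pearson correlation of
family-nested allelic effects: A's final JL model is re-fit with B's
phenotype (identical terms, swapped response) and effects are paired
by (peak, family), per common interval and genome-wide, both
directions reported separately. Effects are standardized by the trait
SD of transformed BLUEs before correlating (a no-op for r itself but
it keeps exported effect tables comparable across Box-Cox scales; the
option is exposed). Monomorphic-family
effects drop pairwise; fewer than 3 pairs or a zero-variance vector
marks the test untestable rather than erroring. Significance is
Benjamini-Hochberg across the whole batch at q <= 0.05.

Interval merging is the sweep-line union of physically overlapping
(>= 1 shared bp, 1-based closed coordinates; BED input is converted on
read) intervals per chromosome, via GenomicRanges. Candidate genes
must satisfy all three criteria: within +-250 kb of a reported
association, overlapping (full containment is a config switch;
overlap is the weaker and therefore safer default reading)
an individual-trait JL interval *of the same trait*, and presence on
the a priori list. LD profiles compare r^2 of dosages within 250 kb of
reported variants against a random-variant null.

Trait prediction compares OLS specifications (family as a categorical
factor) by R^2/AIC/BIC with a 1,000-tree random forest (`ranger`,
impurity importances, single-threaded for reproducibility) on repeated
70/30 splits; per split the forest and an OLS model fit identical
training rows, and metrics average over 30 seeds. Percent Accuracy is
computed per test observation as 100 - 100 |pred - obs| / obs and then
averaged — the conventional definition taken literally even though it
is ill-behaved near obs = 0; observations with |obs| < 1e-6 are excluded
and counted. The family term is one-hot (first-level reference) for
OLS and integer-coded for the forest.

# Problem sizes and numerical choices

The test-suite and acceptance-script simulations use deliberately
modest sizes chosen to make their statistical assertions sharp rather
than to mimic the full panel: null-calibration runs use 5 families x
100 RILs with ~200 markers; the QTL-recovery study uses the full
10 x 170 line count on one 150 cM chromosome at 1 cM spacing; the
heritability study uses 2 x 60 lines over two years. The pipeline
scales to larger inputs linearly in markers and quadratically in plot
count (dense REML); a full ~15,000-marker consensus map is within reach of the
scan machinery, while the mixed-model stage is the practical
bottleneck for very large plot tables.

Key numerical choices, collected: REML parameters on log/atanh scales
with a BFGS polish; residual variance floor 1e-9 var(y); BIC ties to
fewer parameters; stepwise ties to lower chromosome/cM; re-scan
plateau ties to lowest cM; segregating family means within-family
genotype variance > 1e-10; monomorphic-in-panel variants dropped at
projection; p-value ties in the resampling scan broken by variant id.

# Known limitations

The REML engine is dense (O(n^3) per likelihood evaluation) and meant
for plot tables up to a few thousand rows, not for, say, multi-site
series with tens of thousands of plots. The empirical-null FDR
threshold and the support-interval construction are reasonable
operationalizations of under-specified steps and are exposed in the
configuration; alternative constructions would shift thresholds
somewhat. The generator's founder alleles are exchangeable across
loci, so LD-based conclusions transfer to real panels only
qualitatively. Genome-assembly uplift is out of scope: all coordinates
must arrive harmonized to one assembly.
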