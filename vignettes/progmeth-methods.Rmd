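---
title: "Methods: differential methylation analysis of progeroid fibroblasts"
author: "progmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation analysis of progeroid fibroblasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the contrast

Cockayne syndrome (CS) fibroblasts show a premature-ageing phenotype; UV-sensitive
syndrome (UVSS) fibroblasts carry mutations in the same DNA-repair pathway but do
not. Contrasting "Progeroid" (CS) against "NonProgeroid" (wild-type + UVSS)
separates methylation changes linked to precocious ageing from changes caused by
the repair deficiency itself, because any repair-linked change should also appear
in UVSS. The phenotype factor is therefore fully derived from the condition:
CS → Progeroid, WT and UVSS → NonProgeroid (`as_sample_sheet()`).

The cohort design the package emulates is 12 fibroblast lines — 3 WT, 2 UVSS and
7 CS across four clinical subtypes (CS-I mutated in *CSA* or *CSB*, CS-II,
CS-III) — measured on the Infinium 450k and/or EPIC arrays, with seven samples
assayed on both platforms.

## Preprocessing

The pipeline starts from beta matrices (methylated fraction per probe, in
[0, 1]); raw IDAT processing and within-array normalisation are out of scope.
The fixed order is:

1. **Platform intersection** (`intersect_platforms()`): both matrices are cut to
   the probes shared by the two manifests.
2. **Batch adjustment** (`combat_adjust()`): the platform is a batch. The
   adjustment is the parametric empirical-Bayes location/scale model (ComBat, via
   the sva package): per-probe standardisation, per-batch per-probe location and
   scale estimates shrunk toward normal / inverse-gamma priors, adjust and
   restore. The biological grouping is passed as a protected covariate — the
   design confounds platform and phenotype only partially (replicated samples
   bridge the batches), and protecting the contrast is standard practice.
   Output is clipped back to [0, 1]. A single batch level is a no-op; batches
   of size one are refused; zero-variance probes pass through with a warning.
3. **Sex-probe removal** (`drop_sex_probes()`): probes on X/Y, plus an optional
   user-supplied list of sex-associated autosomal probes. Run after batch
   adjustment and before testing, because the CS-I *CSA*/*CSB* subtypes are
   sex-confounded.
4. **Replicate averaging** (`merge_replicates()`): per-sample arithmetic mean of
   the two platform measurements, after batch adjustment (the adjusted scale is
   the comparable one); a value missing on one platform falls back to the other.

PCA (`pca_overview()`) operates on samples as rows with per-probe mean centering
and no scaling — beta values share a common scale, so variance weighting would
distort probe contributions. Hierarchical clustering (`hierarchical_cluster()`)
uses Euclidean distance with complete linkage, cut at two clusters.

**A note on empirical-Bayes idempotency.** Because EB shrinkage deliberately
leaves a residual fraction of the estimated batch offsets, applying the
adjustment twice is not bit-identical to applying it once; the second pass is a
strong contraction (it changes values by far less than the original batch
effect) but not a fixed point. The test suite asserts the contraction, not exact
idempotency.

## Differential methylation

**DMPs** (`call_dmps()`): per-probe one-way ANOVA of beta on the two-level
phenotype — with two groups the F statistic equals the squared pooled-variance
t — followed by Benjamini–Hochberg correction across all tested probes. A probe
is a DMP when BH-adjusted p < 0.05 **and** the absolute group difference in mean
beta exceeds 0.10 (a 10% methylation difference). The delta filter matters with
n = 12: at this size, statistically stable but biologically trivial differences
are otherwise reportable. "Hypomethylated" always means lower in the progeroid
group (delta = Progeroid − NonProgeroid < 0). Probes with missing values use
available samples, with at least two usable samples per group; otherwise the
probe is excluded from the multiplicity count.

**DMRs** (`call_dmrs()`): probes sharing an island identifier — the CpG island
plus its annotated shores and shelves — form a block; only gene-annotated blocks
are scanned and Open Sea probes are excluded, restricting regions to
regulatory, gene-associated territory. Every window of three chromosomally
adjacent probes (step 1) is tested by one-way MANOVA of the three-dimensional
beta vector on phenotype. The statistic is the Pillai trace
V = tr(H(H+E)⁻¹) from the between/within SSCP matrices; with two groups the
exact-F conversion is F = V/(1−V) · (n−p−1)/p on (p, n−p−1) degrees of freedom.
Pillai was chosen over Wilks for robustness to covariance heterogeneity between
groups; with s = 1 (two groups) the two are monotone transforms of each other,
so the choice affects nothing here beyond presentation. Singular total SSCP
matrices fall back to a ridge (1e−6 on the diagonal) with a warning; the ridge
can be disabled, in which case a one-dimensional window reproduces the
univariate ANOVA p exactly.

BH correction runs across all windows; significant windows overlapping within a
block are merged into one region (probe union, minimum raw and adjusted p,
Pillai trace of the best window). Merging is a design choice — region-level
counts imply consolidated windows, but the merging rule itself was open; union
with minimum p is the most conservative consolidation that keeps every
significant probe. Region direction follows the **lead probe**: the member probe
with the smallest BH-adjusted per-probe ANOVA p, ties broken by larger |delta|,
then lexicographic probe id. A region can contain probes moving in both
directions; the lead-probe rule is an explicit, reproducible tie-break for an
acknowledged ambiguity.

**StringentDMRs** (`stringent_filter()`): for each significant region, the
per-sample mean beta across the region's probes must separate the groups with
*disjoint ranges* — max of one group + `gap_min` ≤ min of the other. This is
the operationalisation of "unambiguous separation": a region where UVSS samples
sit between WT and CS fails it, which is exactly the class of repair-linked
(rather than ageing-linked) changes the filter exists to remove. `gap_min` is a
beta-scale margin (default 0); 0.1 demands a visible gap and empirically drives
recovery of the planted UVSS-intermediate regions to zero.

**Region enrichment** (`region_enrichment()`): for each island-relation
category × direction, a two-sided Fisher exact test of category membership
against DMP status over all tested probes. The comparison column is DMPs of the
given direction versus non-DMPs; DMPs of the opposite direction are excluded
(the "DMP vs non-DMP" framing is ambiguous once split by direction; mixing
opposite-direction DMPs into the background would dilute both tests). Odds
ratios are the plain cross-product; a 0.5 continuity correction is applied, and
flagged, only when a zero cell occurs.

## Epigenetic clocks

A clock is a linear combination of probe betas plus an intercept with a
piecewise log-linear age calibration: F(a) = log(a+1) − log(A+1) for a < A,
(a−A)/(A+1) otherwise, with adult age A = 20 by default. The calibration
compresses pediatric ages, where methylation change per year is fastest.
Coefficient sets are pluggable CSVs (`probe_id,weight` with an `(Intercept)`
row) — published clocks are externally licensed data and are user-supplied
inputs; the repository ships only a synthetic fixture clock (generated, not
trained; see `inst/extdata/synthetic_clock.csv`).

Age acceleration is the residual of DNAm age regressed on chronological age,
pooled over **all** samples (a single regression line; the alternative —
fitting on non-progeroid samples only — was considered and not taken, since a
pooled line is what a single regression fit over the cohort produces). Group
comparison is a Welch t-test on residuals, optionally with a sex-adjusted p
from residual ~ phenotype + sex. Two caveats the package surfaces explicitly:

* Samples whose chronological age is censored (recorded at last report/death,
  not at biopsy) are included by default with a warning — their age is likely
  overestimated, which *underestimates* acceleration.
* A group shift in DNAm age is partially absorbed by the pooled regression
  whenever age distributions differ between groups (OLS attenuation). Tests and
  the acceptance script therefore compare the estimated gap against the oracle
  regression run on the generating model, not against the nominal planted
  shift.

## Cross-dataset comparison and expression

Methylation changes of external datasets enter as per-probe delta tables (case
mean − control mean) with that dataset's own significance calls. Pairwise
Pearson correlations of delta vectors are computed on the probes shared by each
pair (`delta_correlation_matrix()`); list overlaps use Fisher exact tests on a
universe of items assayed in both datasets, with direction concordance counted
on the common items (`overlap_test()`). DMR matching across datasets is by
island-id string; gene matching by upper-cased symbol. Methylation–expression
coupling uses Pearson r of the per-sample regional mean beta against
expression, R² = r², p from the exact t transform, with the strength bands
strong (0.4 ≤ R² ≤ 0.9), moderate (0.2 ≤ R² < 0.4), weak otherwise.

## Gene-set testing with probe-count adjustment

Genes tile the array unevenly (1 to dozens of probes); scoring a gene by its
best probe without correction inflates large genes. `aggregate_gene_p()` uses
the Šidák best-of-n correction, p_gene = 1 − (1 − min p)ⁿ, which is exactly
uniform under independence and conservative under the positive correlation of
probes within a gene. Šidák best-probe was preferred over Fisher's combination
precisely because within-gene probes are correlated: Fisher's product statistic
is anticonservative there, best-probe is not. `geneset_test()` then regresses
set membership on −log10(p_gene) with log(probe count) as a covariate
(logistic model, one-sided Wald p for a positive coefficient); complete
separation falls back to a seeded membership permutation test on the difference
of mean −log10(p_gene). Direction (hypo/hyper) is reported descriptively, not
scored separately.

## The synthetic cohort generator

`simulate_annotation()` lays out island blocks — shelf, shore, island probes,
shore, shelf at increasing positions — plus isolated Open Sea probes, over
chromosomes 1–22 with a configurable fraction on X/Y (default 0.023, the
sex-probe share of the shared 450k/EPIC manifest: 10,585 of 452,567). Most
blocks carry a gene label (default 80%), since DMR calling is restricted to
gene-associated blocks.

`simulate_cohort()` draws per-probe baselines from the bimodal mixture
0.5·Beta(2,8) + 0.5·Beta(8,2) — the characteristic two-mode marginal of array
methylomes — adds i.i.d. Gaussian noise on the beta scale (default sd 0.05),
applies a per-probe platform offset (sd 0.05) to the EPIC matrix, and clips to
[0, 1]. Noise on the beta scale with clipping was chosen over a logit-normal
model for transparency; it is adequate for the effect sizes of interest
(≥ 0.1), and baselines of planted probes are drawn so that mean ± effect stays
inside (0.05, 0.95), keeping truncation from attenuating planted effects.
Planted effects (default magnitude 0.30, the region-scale effect the power
analyses use) are added to CS samples on isolated positions and on runs of
three adjacent block probes; "UVSS-intermediate" regions additionally give UVSS
samples half the effect. Planted signs are hypo-biased 3:1, matching the
predominance of hypomethylation in the progeroid group. Subtype labels are
carried but effects are planted at the CS-vs-rest level; subtype-specific
effects are a configuration extension, off by default.

What the generator does **not** emulate: co-methylation decay along
chromosomes (effects are block-constant), probe-type chemistry differences,
cell-composition heterogeneity, and realistic missingness patterns. Passing
tests therefore demonstrate correctness of the statistical machinery under the
stated model, not performance on real arrays.

`simulate_expression()` couples a configurable fraction (default 0.6) of
planted genes to their regional mean beta with a negative-slope linear model
plus noise; remaining genes are independent.

## Numerical and design details

* BH adjustment delegates to `stats::p.adjust`; Fisher p-values to
  `stats::fisher.test`. The per-probe F and the window Pillai trace are
  computed directly (vectorised / SSCP form) and are cross-checked in the test
  suite against `anova(lm(...))`, `summary(manova(...))` and brute-force
  sum-of-squares/eigenvalue oracles to 1e−8 or better.
* Determinism: every stochastic step is seed-parameterised; identical seeds
  give bit-identical output end-to-end (asserted at ~20k probes × 12 samples).
* Calibration: on pure-null cohorts with homoscedastic noise the raw ANOVA
  p-values are uniform (KS). Two realistic deviations are known and
  documented rather than hidden: partial replicate averaging makes per-sample
  variances unequal (7 of 12 samples averaged over two platforms), and EB batch
  adjustment slightly perturbs the null distribution. Both shift per-seed KS
  p-values low without inflating the false DMP rate (the BH + 10% delta rule
  flags essentially nothing on null data in either design).
* Problem sizes in tests and the acceptance script — 5,000-probe null cohorts
  over 20 seeds, 16 cohorts for region recovery, ~20k probes for the
  determinism run — were chosen as the smallest sizes at which the Monte-Carlo
  standard errors are decisively smaller than the margins being tested.

## Limitations

The headline counts of the motivating study (tens of thousands of DMPs from
~442k probes, region counts, a 15.5-year acceleration gap) depend on the
deposited cohort and externally licensed clock coefficients; they are not
recomputable from synthetic data and the package does not claim them. The
stringent filter's range-disjointness rule is this package's operationalisation
of "unambiguous separation" and is not guaranteed to reproduce any particular
published region count. MANOVA windows assume within-group multivariate
normality on the beta scale; with three probes and twelve samples this is an
approximation, mitigated by the exact-F small-sample conversion.
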