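---
title: "Models and methods behind the sadewas pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the sadewas pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

sadewas implements the statistical core of a blood DNA-methylation
case/control study of mixed connective tissue disease (MCTD) and its
neighbouring systemic autoimmune diseases (SLE, Sjögren's syndrome,
rheumatoid arthritis, systemic sclerosis). This vignette explains the
models, the synthetic cohort generator that the test suite scores the
pipeline against, the tunable parameters, and the numerical choices — in
the spirit of a methods section, not a tutorial.

## The differential methylation model

Methylation at a CpG is summarised per sample as a beta value, the
fraction of methylated molecules, in [0, 1]. For each probe the package
fits ordinary least squares on the beta scale:

```
beta ~ diagnosis + age + sex + batch + 5 cell proportions
```

The diagnosis coefficient is therefore directly the covariate-adjusted
case–control difference in mean beta (Δβ), the effect size that study
tables print; we deliberately do not model M-values, which would make the
coefficient a log-odds-scale quantity. The p-value is the two-sided t-test
on that coefficient. Differentially methylated sites (DMS) are declared by
a Bonferroni threshold α/m, where m counts the probes actually tested —
zero-variance and n-deficient probes are skipped, reported, and never
called.

Collinearity is handled once, at design construction: batch is one-hot
encoded with the first level dropped, and one cell type (neutrophils, the
largest compartment) is dropped so the proportions do not sum to the
intercept. A rank check names any remaining aliased column and refuses to
fit.

Two caveats of this classical design are worth stating. First, OLS pools
residual variance across groups; at probes whose case variance is many
times the control variance (see below) the t-test for the diagnosis term
is anticonservative, so a variance-inflated probe with no mean shift can
occasionally clear even a Bonferroni threshold. This is a property of the
method being implemented, not a defect of the implementation, and it is
one reason variability scans and mean scans call heavily overlapping
sets. Second, betas near 0 or 1 compress effects; the simulator's truth
is defined on the beta scale precisely so this compression is part of
what recovery tests measure.

## Differential variability

Variable methylated sites (VMS) are found in two steps: methylation is
first residualised on all covariates (without the diagnosis term), then
case and control residuals are compared with a Brown–Forsythe test —
Levene's test with group-median centring, which keeps residual mean
differences from masquerading as variance differences. The statistic is
the one-way ANOVA F on absolute deviations from the group median with
F(1, N−2) degrees of freedom for two groups. Degenerate probes (all
deviations zero) are skipped with a warning; a probe where the deviations
are constant but equal across groups returns W = 0, p = 1 (equal spread),
a convention that matters only for pathological inputs. A mean-centred
classical Levene variant is available through `levene_bf()` by
pre-centring, but the median-centred form is the default everywhere.

## Replication logic

A discovery call is testable in the replication cohort when its probe is
present on the legacy platform and was not skipped; it replicates when the
replication effect has the same direction and p < 0.05. For variability
calls "direction" means the case/control variance contrast lies on the
same side. The summary percentage is replicated/testable × 100, rounded
to an integer, matching how such studies report replication.

## Cell-type deconvolution

Leukocyte proportions are estimated by constrained projection of each
sample's reference-probe betas onto cell-type reference profiles:
minimise ‖b − Rw‖² subject to w ≥ 0 and Σw = 1. The solver is an
active-set non-negative least squares with the equality constraint kept in
the KKT system, so solutions sit on the simplex exactly (to 1e-9) with no
post-hoc renormalisation. The classical unconstrained-then-truncate
variant is available via `method = "truncate"` for comparison. Because
the equality constraint absorbs any shared offset, the argmin is
invariant when reference and sample are transformed by the same affine
map — a property the tests verify. A rank-deficient reference (e.g. two
indistinguishable cell types) is refused with advice to supply more
discriminating probes.

## Genetic integration

cis-meQTL pairs are all (SNP, CpG) combinations on the same chromosome
within 1 Mb, boundary inclusive — "closer than 1 Mb" is ambiguous and we
chose inclusivity, configurable via `window`. Per pair, OLS of beta on
additive dosage adjusts for sex, age, batch, cell proportions, disease
status and the first genetic principal component (computed from
standardised dosages, sign anchored at the first variant). The
Benjamini–Hochberg adjustment runs jointly across all tested pairs, not
per probe, matching the single-FDR convention of standard eQTL software.
MAF is computed on the analysis samples after complete-case reduction;
sub-MAF and monomorphic SNPs are skipped with counts.

Case/control association fits per-SNP logistic regressions under the
additive model (IRLS, tolerance 1e-8, at most 100 iterations); complete
separation is flagged and no odds ratio reported. A genomic-control
lambda of the per-SNP score-test chi-squares is reported for the scan but
never applied as a correction.

The mediation triangle intersects three scans: significant meQTL pairs
whose CpG is a called DMS and whose SNP shows suggestive disease
association (p < 0.05). The `direction_consistent` flag records whether
the risk allele moves methylation toward the case profile
(sign(meQTL effect) × sign(log OR) = sign(EWAS effect)); it is reported,
not filtered on, because the underlying studies report such tables
without a formal mediation test. Formal causal mediation and Mendelian
randomization are out of scope.

## Cross-disease comparison and biomarkers

Each other disease is contrasted against the same healthy pool with the
identical covariate model, restricted to the MCTD DMS set; Pearson
correlation of the per-disease effect vectors with the MCTD vector
summarises sharing, and the heat-map subset keeps DMS with |MCTD effect|
> 0.15 (the rule applies to MCTD effects only). Case-vs-case scans swap
the control group for the second disease and use a Bonferroni level of
0.05/|DMS|.

AUC is computed by the Mann–Whitney identity (ties count 1/2), which
equals the trapezoidal area under the empirical ROC and is invariant
under monotone transforms of the score. Panel evaluation fits a logistic
regression of case status on the panel betas — covariate-adjusted by
default, since the study's description of its logistic models points to
the same covariates as the linear ones; `adjust_covariates = FALSE` gives
the unadjusted mode. AUCs are in-sample, matching standard pROC usage in
this literature; no cross-validation is performed by default. Under
complete separation the linear score still orders samples, so the AUC is
computed from it and flagged.

Gene-set over-representation uses the one-sided hypergeometric tail with
BH adjustment across sets, with the background defaulting to the genes on
the filtered array rather than the genome.

## The synthetic cohort generator

No individual-level data from such consortium studies are publicly
deposited, so the package ships a generator that emulates their
statistical structure, and all cohort-level testing is parameter
recovery against its ground-truth ledger. Per probe j and sample i the
latent logit methylation is

```
a_j + r_j'(w_i − E[w]) + batch_(j,b(i)) + s_j (age_i − 50) + x_j male_i
    + D_j(i) + γ*_j g_ij + e_ij
```

mapped through the logistic function and clipped to (1e-6, 1 − 1e-6).
Here w_i are Dirichlet cell proportions (blood-like prior), r_j, batch,
age and sex loadings are probe-specific Gaussian draws, g is additive
dosage, and e is Gaussian noise.

Three calibrations keep the ledger on the beta scale, where the study's
effect sizes live:

* **Disease shifts.** The truth for an affected probe is a beta-scale
  difference d_j (drawn in [−0.5, −0.07], 6% hypermethylated). The
  logit-scale shift is solved numerically (fixed 201-point Gauss grid +
  `uniroot`) so the expected beta difference between the shifted and
  reference groups equals d_j, accounting for the probe's total latent
  spread. Treated cases carry d_j(1 − attenuation); other diseases carry
  the full d_j at a random subset of probes (below).
* **Variance inflation.** VMS probes multiply the case residual sd on the
  logit scale, but a naive constant multiplier collapses on the beta
  scale wherever the case mean sits in a flat tail of the logistic. The
  generator therefore solves per probe for the logit multiplier whose
  realized beta-scale case/control variance ratio equals
  `var_inflation` (default 8, the magnitude of printed variance
  contrasts), capped at 15 where the bounded scale makes the target
  unattainable. Because inflation alone also drags the beta-scale mean
  toward 0.5, a compensating shift is solved jointly so variance-only
  probes keep a zero mean difference.
* **meQTL effects.** Per-allele beta-scale effects are linearised through
  the expected logistic derivative at the probe's baseline; the single
  designated mediated locus draws its effect from the top of the range
  (|γ| ≥ 0.10) and opposes methylation, as the exemplar loci in this
  literature do, so the triangle has one reliably recoverable solution.

**Cross-disease sharing.** The sharing map gives, per disease, the
probability that an affected probe carries the full MCTD effect in that
disease (SLE 1.0, SjS 1.0, RA 0.15, SSc 0.2). We chose probability-of-
sharing rather than scaling the whole effect vector because Pearson
correlation is scale-invariant: a scaled vector would correlate perfectly
with the MCTD effects and could reproduce neither the observed
correlation ordering across diseases nor the printed percentages of
shared sites. Bernoulli sharing reproduces both.

**Treatments.** Steroid, antimalarial and immunosuppressant flags are
assigned to exact case counts (12/13/9 of 31 by default, scaled for the
replication cohort). Attenuation (default 0.15 of the effect, applied to
the union of treated flags) was chosen to match the qualitative published
pattern — stratified effect correlations near 0.94, all DMS surviving
treatment adjustment, and only a mild untreated>treated tendency. Strong
probe-specific attenuation, the pattern behind replicated
treatment-specific calls, is exercised through
`per_treatment_attenuation` and `atten_frac`.

**Genetics.** Dosages are Hardy–Weinberg draws at U(0.05, 0.5) allele
frequencies; risk SNPs shift the case frequency by +0.10 (+0.15 at the
mediated locus, enough for reliable p < 0.05 association at the
genotyped sample sizes). SNPs are otherwise independent: no linkage
disequilibrium is simulated, so haplotype-block phenomena are out of
scope. meQTL target probes are drawn from the unaffected probes except
the mediated locus, so the triangle's truth is a single pair.

**Cohort layout.** Discovery holds 31 MCTD cases and 255 controls plus
234/206/217/177 SLE/SjS/RA/SSc cases; replication holds 21 cases and 103
controls and sees ~55% of probes (the legacy-platform mask). Genotypes
cover 29 + 230 discovery and 20 + 96 replication samples plus 60 + 320
genotype-only individuals for association, approximating the published
overlap sizes. Where the source material printed two replication control
counts, we use the results-section figure (103).

What the generator does **not** emulate: realistic probe-level genomic
annotation (genes are synthetic labels over position-sorted probes), LD
structure, array batch chemistry, longitudinal treatment dynamics, and
any environmental exposure model. Passing recovery tests therefore shows
the scans estimate what the generator encodes under realistic noise — it
does not certify performance on real arrays.

## Problem sizes and numerical choices

The default generator uses 1,000 probes with 50 affected; study-scale
runs in the analysis scripts and acceptance checks use 2,000 probes with
200 affected so the discovery call set lands near the study's (~180
calls), at which point quantities like the hypomethylated fraction are
stable. Calibration runs use a 2,000-probe null cohort; recovery
experiments average 20–50 independent seeds of reduced cohorts. All
sub-streams derive from a single seed, and the same seed reproduces every
matrix bit for bit.

Display rounding follows the tables of this literature — effects to 2
decimals, thresholds to 2 significant digits, replication percentages to
integers — and applies only at the reporting layer; all computation is
at full double precision. The Bonferroni threshold is always α/m with m
the tests actually run. Coordinates are 1-based fully closed; BED input
is converted at the reader boundary. Missing betas are handled
complete-case per probe; missing dosages complete-case per pair.

## Known limitations

* The OLS t-test anticonservativity under strong case-variance inflation
  (discussed above) is inherited from the plain-linear-model design.
* The detection-p filtering rule is interpreted as *keep* probes with
  detection p ≤ 0.01 in ≥ 95% of samples; the literal printed phrasing
  ("p > 0.01 in > 95%") would discard almost nothing. Both the threshold
  and the fraction are configurable.
* Probe-level SNP-overlap and multi-mapping exclusions are delegated to
  user-supplied lists; no genome lookup is performed.
* In-sample AUCs are optimistic by construction; they are the quantity
  this literature reports, not an estimate of out-of-sample performance.
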