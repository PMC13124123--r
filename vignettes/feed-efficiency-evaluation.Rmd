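---
title: "Feed-efficiency genetic evaluation: models, generator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feed-efficiency genetic evaluation: models, generator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`feedeval` evaluates six ways of scoring the feed-utilization
efficiency of lactating dairy cows from weekly feed-intake records, and
compares them by forward validation. This vignette is the package's own
account of the science it implements: the models and their assumptions,
the tunable parameters and why their defaults are what they are, what
the synthetic herd generator does and does not emulate, and the
numerical decisions a maintainer would want spelled out.

## Phenotype engineering

Every model starts from derived weekly traits (`derive_metrics()`):

* **ECM** (kg/d): milk standardized to a fixed energy content,
  `milk (38.30 fat + 24.20 protein + 16.54 lactose + 20.7) / 3140`,
  with milk contents in **g/kg**. This is the one unit convention in
  the package that matters most: with percentages the formula is off by
  a factor of ten, and only g/kg makes ECM land near milk yield.
  Ingestion from percentage data must multiply by 10 first.
* **MBW** (kg^0.75): metabolic body weight `BW^0.75`; a 590 kg cow has
  MBW 119.7.
* **BWL/BWG** (kg/d): daily body-weight change split by sign,
  `BWL = max(0, −ΔBW)`, `BWG = max(0, ΔBW)`. At most one of the two is
  nonzero for any record; their difference reconstructs ΔBW exactly.
* **eDMI_RDC** (kg/d): requirement-based expected intake
  `0.456 ECM + 0.0508 MBW − 3.25 BWL + 3.25 BWG`, the Nordic Red
  energy-requirement system.
* **eDMI_NRC2021** (kg/d): the NRC (2021) first-parity intake equation.
  Its printed form is typographically ambiguous about what the
  lactation-stage term `1 − 0.212 e^(−0.053 DIM)` multiplies; the
  package applies it to the whole bracket
  `(3.7 + 0.305 MilkE + 0.022 BW − 0.689 BCS)`, which is the published
  NRC equation 2-1 form. Milk energy is taken as 0.752 Mcal NEL per kg
  ECM when not measured.
* **ECE** (kg/MJ): ECM divided by metabolizable energy intake — the
  model-free benchmark trait.
* **Lactation period class**: weeks 1–4, 5–9, 10–13, 14–35, 36–44
  (approximating lactation months 1, 2, 3, 4–8, 9–11), used for
  heterogeneous residual variances. The breaks are configurable in
  `period_class()`.

`nrc_to_sink_scale()` converts the NRC milk-energy and body-weight
coefficients to the ECM and MBW scales (0.229 and 0.108 at the herd
mean MBW of 119.7), which is how the requirement systems are compared
on one table. `min_energy_content()` documents the feasibility
argument for ECM coefficients: a coefficient of 0.30 kg DM per kg ECM
with 4,765 kJ of ME per kg ECM implies a diet of at least 15,883 kJ/kg
DM before lactation efficiency exceeds 100%.

## The six evaluation models

All models are univariate or multi-trait linear mixed models on weekly
records, solved by Henderson's mixed-model equations with residual
variances heterogeneous over the five period classes.

**ReFI (two variants).** DMI is regressed on expected intake with
*every* term a regression on eDMI: a fixed slope per
herd × production-year (HPY) class, a random slope per
herd × trial × test-month (HTM) class, a random permanent-environment
slope per cow, and a random additive-genetic slope per animal with
covariance `A σ²` (pedigree kernel) or `H σ²` (single-step kernel).
There is deliberately **no general intercept and no lactation-curve
fixed effect**: the HPY slopes absorb level differences, and the
multiplicative structure lets one efficiency factor scale the whole
requirement. This is unusual for an animal model and is preserved
exactly. The two variants differ only in which eDMI column they
regress on.

**One-step RFI.** DMI on the four sink covariates (coefficients
estimated in the model) plus fixed HPY classes and random HTM,
permanent-environment and additive intercepts.

**ECE.** As RFI with the sink covariates replaced by fixed
lactation-week classes.

**Multi-trait.** DMI, ECM, MBW, BWL, BWG jointly, with a fixed
fourth-order Legendre regression on lactation week nested in herd
(plain Legendre polynomials on the week standardized to [−1, 1] over
weeks 1–44 by default) and 5×5 covariance matrices for HTM,
permanent environment, additive (Kronecker with A or H) and period
residuals. BWL and BWG records are structural zeros when the cow is
not losing (gaining); they are treated as observed zeros, consistent
with the sign-split definition. The RFI index and RZFE are then linear
combinations of the five estimated breeding values, computed **after**
fitting (two-step), never folded into the equations.

**Breeding-value scales.** For the ReFI models the additive solution is
a slope per unit eDMI; `ebv()` rescales it by the data mean of the
eDMI covariate so that breeding values and reported genetic variances
are on the intake scale (`0.00303 × 20² = 1.21 kg²` is the arithmetic
this matches). Correlations and rankings are invariant to this choice;
only variance reporting depends on it.

## Variance components

`em_reml()` is an expectation–maximization REML with **exact** trace
terms. Each round factorizes the coefficient matrix with a sparse
LDL' (CHOLMOD) factorization and obtains every needed entry of its
inverse from a Takahashi selected inverse implemented in C++
(`src/takahashi.cpp`): the recursion yields the inverse on the filled
factor pattern, which covers the mixed-model-equation pattern, at a
small fraction of the cost of a dense inverse (about 0.1 s at ~3,800
equations against ~2 s dense). The Monte-Carlo trace approximation
used by large national evaluations is unnecessary at package scale, so
exact traces are the only path.

Updates are the standard EM forms — `(û'K⁻¹û + tr(K⁻¹ C^uu)) / q` for
each random term and `(ê_p'ê_p + Σ_{i∈p} w_i'C⁻¹w_i) / n_p` per period
residual — with the per-period trace evaluated as a sparse dot product
against the constant cross-product pattern. The restricted
log-likelihood is tracked and tested to be non-decreasing.
Convergence is declared when the maximum relative parameter change
drops below `tol` (default 1e-6, 500-iteration cap); variances are
floored at `1e-10` times the phenotypic variance with the usual EM
caveat that a truly null variance is approached slowly from above, so
boundary cases report a small positive estimate rather than zero.
Multi-trait EM-REML uses the same updates in matrix form and is
guarded to reduced scale (≤ 12,000 equations): no published component
values exist to recover, so it is exercised on small syntheses only.

`heritability()` computes `h² = VarG / (VarPE + VarG + VarR)` and
`r = (VarPE + VarG) / (VarPE + VarG + VarR)` with VarR the
record-count-weighted average of the period residuals. The HTM
variance is treated as a contemporary-group component and excluded
from the phenotypic denominator — this convention, together with the
mean-eDMI² rescaling of the slope-scale ReFI components (whose
residuals are already on the intake scale), is what reproduces the
published ratio arithmetic from the published components.
Standard errors use the first-order delta method with a
finite-difference gradient; the estimate covariance it needs must come
from replicate studies or a bootstrap, since EM supplies none.

## Relationship kernels

The pedigree kernel builds Wright's numerator relationships by the
vectorized tabular method and the sparse inverse directly by
Henderson's rules, **always with inbreeding** (Mendelian-sampling
variances from parental inbreeding coefficients): nucleus-herd
pedigrees are inbred and the cost is negligible. Unknown-parent groups
are optional and off by default; the grouping rule is equal-width
birth-year bins within origin, boundary years to the earlier bin — a
package convention, since only "birth year and origin" is specified in
the practice it mirrors. Animals are canonically ordered parents-first
by birth year then id, and every matrix is indexed in that order.

The genomic kernel is VanRaden method 1, `G* = ZZ'/(2Σp(1−p))`, with
allele frequencies computed from the observed genotyped animals
(base-population frequencies are unavailable in practice), blended as
`G = 0.9 G* + 0.1 A₂₂` with no further compatibility tuning — exactly
the stated blend, nothing more. `H⁻¹` adds the dense
`G⁻¹ − A₂₂⁻¹` correction on the genotyped block of the sparse `A⁻¹`;
dense inversion of G is acceptable because realistic genotyped sets
here are O(10³). A property test inverts `H⁻¹` on a small pedigree and
checks it against the textbook conditional-distribution form of H.

## The synthetic herd generator

The generator (`simulate_study()`) emulates the recording scheme of a
nucleus research-herd feed-efficiency database: by default ~791
primiparous cows with 28 weekly records each (≤ 305 days in milk)
across 4 herds and ~24 production years, a multi-generation pedigree
(~1,800 animals) with strong paternal half-sib structure from a small
active-sire pool, and a genotyped subset (~27% of the pedigree)
prioritizing the youngest record cows and their parents — the
structure forward validation needs.

Energy sinks follow a latent four-trait system (ECM, MBW, ΔBW, BCS)
with lactation-stage mean curves plus HTM, permanent-environment,
additive and residual components; BWL/BWG are the sign split of latent
ΔBW. A literal five-trait Gaussian over (DMI, ECM, MBW, BWL, BWG)
cannot reproduce the structural zero `BWL × BWG = 0`, which is why the
latent parameterization is used; the 4×4 covariance defaults (and the
5×5 defaults used for *fitting* the multi-trait model,
`default_multitrait_vc()`) are package choices scaled to typical
first-parity phenotypic variances — **no published values exist for
them**, and no acceptance-level test depends on them.

DMI is generated under one of two structures. `"refi"` (default)
builds `DMI = eDMI_RDC × (α_h + β_m + γ_i + δ_i) + e` — the ReFI
structural assumption holds by construction, and with all efficiency
variances zero DMI equals eDMI exactly (a tested limit). `"rfi"`
builds `DMI = eDMI_RDC + HPY + HTM + pe + u + e` with the
repeatability-model components (pe 1.127, genetic 1.043, residual
pattern averaging 2.37 under the 28-week design) so that one-step RFI
is the correctly specified model and EM-REML should recover h² ≈ 0.23
— the package's central parameter-recovery check. The per-period
residual patterns were chosen once so their record-count-weighted
averages under the default design match the repeatability-model values
(≈ 2.50 for the ReFI scale, ≈ 2.37 for the intake scale).

**Genetic architecture.** True breeding values are built by default
from additive marker effects on the gene-dropped genotypes
(`marker_breeding_values()`): per-locus effects drawn with covariance
`Va / (2Σpq)` at the founder frequencies, summed over centered allele
counts. This makes the genomic relationship matrix genuinely
informative about Mendelian sampling, which is the premise of
single-step evaluation; with the alternative
`genetic_architecture = "pedigree"` (breeding values from the pedigree
multivariate normal, parent average plus Mendelian sampling with
`Va/2`, optionally inbreeding-adjusted) the genotypes carry no
within-family information and ssGBLUP cannot outperform pedigree BLUP
— useful as a null configuration, not as the default. The loci are
unlinked, so a given number of simulated SNPs corresponds to that many
independent segments; a few hundred to a few thousand loci emulate the
effective-segment count that a 50k chip on real linkage disequilibrium
provides, which is why test configurations use 300–2,000 SNPs rather
than chip-scale counts.

**What the generator does not emulate**, and hence what passing tests
do not show about real data: linkage and LD structure (no map),
selection and assortative mating within the nucleus, lactation-curve
shapes beyond what the fixed regressions absorb, measurement-error
structure in BW smoothing (daily BW and ΔBW are emitted directly), and
genotype-by-environment interaction. Pasture-season record gaps exist
behind a flag (`pasture_gaps`), off by default.

## Forward validation

`split_forward()` truncates by birth year: the validation group is the
genotyped cows with records born at or after the cutoff, excluding any
whose daughters keep records in the reduced data; the reduced dataset
drops the group's and their daughters' records. Granddaughters are not
excluded (the definition speaks of daughters). `lr_validation()` is
ordinary least squares of whole-data on partial-data breeding values —
not errors-in-variables, per the method's definition — and reports
bias `b0` (also as `|b0|` in genetic standard deviations when the
genetic variance is supplied), dispersion `b1` and the prediction
accuracy (Pearson correlation). Standard errors come from the ordinary
nonparametric bootstrap over validation animals (default 1,000
replicates, fixed seed, degenerate resamples skipped and counted);
animal-level resampling is the assumed unit. `adjusted_ece()` removes
every estimated ECE-model effect except the additive one from each
record and averages per cow — an ECE yield deviation — for correlating
realized efficiency with the metrics' breeding values.

Calibration properties are asserted as means over replicates at
reduced scale (30 replicates of ~170-cow herds for `b1 ∈ [0.8, 1.2]`
and `b0 ≈ 0`; 20 replicates of ~140-cow herds for the
genomic-accuracy inequality): single-replicate LR estimates on
validation groups of a few dozen animals are noisy, and the
ratio form of `b1` is biased upward when the group contains few
distinct parent-average families, so group sizes below ~30 are not
meaningful for dispersion.

## Numerical choices and degenerate inputs

* Mixed-model equations are solved by sparse Cholesky up to 60,000
  equations, otherwise by Jacobi-preconditioned conjugate gradients
  (relative residual 1e-10); the two paths are cross-checked on a
  shared fixture. Solutions are permutation-invariant in the records.
* Rank-deficient fixed blocks (e.g. lactation-week classes together
  with HPY classes in the ECE model) are resolved by constraining the
  QR-pivoted-out columns to zero; the dropped levels are reported in
  the fit object.
* In the one-step RFI model the level split between the no-intercept
  sink regression and the HPY classes is weakly identified — MBW
  varies only ~7%, so the sink block nearly contains a constant. The
  sink *coefficients* are recovered accurately, but the mean of the
  fitted sink part (`eDMI_FIT`) can drift a few percent relative to
  mean DMI; tests bound that drift at 5% rather than asserting
  equality.
* Ties and orderings are all made deterministic: canonical animal
  order, sorted factor levels, fixed bootstrap seeds, and a master
  simulation seed fanned out to per-stage child seeds so each stage is
  independently reproducible.
* Covariance matrices are validated symmetric PSD (eigenvalue floor
  −1e-8); matrix square roots use the symmetric eigendecomposition so
  semidefinite inputs (including exact zeros) are handled.

## Problem sizes

The shipped tests run the full default herd (791 cows × 28 weeks,
~22,100 records, ~3,800 mixed-model equations) once for EM-REML
parameter recovery, and reduced herds (70–200 cows, 10–12 weeks,
300–800 loci) for replicate-based properties; the complete suite is a
few minutes on one CPU, with the selected-inverse EM-REML taking
~0.15 s per iteration at full scale. These sizes are the package's
choices for keeping replicate counts high enough to test distributional
claims; all of them are configurable upward through `sim_config()`.

## Known limitations

Reliabilities from the inverse of the coefficient matrix are not
computed (bootstrap SEs cover the validation statistics); genomic-
kernel REML is not provided (components are estimated under the
pedigree kernel, matching the evaluation design the package mirrors);
no significance test is attached to accuracy differences — only
standard errors; and the unknown-parent-group path is exposed both for
`A⁻¹` alone and inside `H⁻¹`, with no claim about which a given
national evaluation uses.
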