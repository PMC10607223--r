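---
title: "Methods: simulation, NCA and the association cascade in pkpgx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, NCA and the association cascade in pkpgx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pkpgx implements a complete candidate-gene pharmacokinetic (PK) analysis for
single-dose crossover trials of valsartan, olmesartan and
hydrochlorothiazide: non-compartmental analysis (NCA) of concentration-time
profiles, star-allele genotype-to-phenotype translation, and a
univariate-to-multivariate association cascade with exact safety-incidence
tests. Because the underlying clinical-trial data are sponsor-held, the
package ships a synthetic-cohort generator whose defaults emulate the
pooled 64-volunteer cohort; every downstream stage is tested end to end
against that generator and against independent closed-form oracles.

## The synthetic cohort

**Structure.** Seven trials are simulated with sizes 6/4/8/8/12/10/16 and
drug/dose sets (valsartan 160 or 320 mg; olmesartan 40 mg;
hydrochlorothiazide 12.5 or 25 mg). Valsartan uses a replicated four-period
crossover (T, R, T, R), the other drugs a two-period T/R design. The
default cohort has 27 women and 37 men and a 43:21 European:Other split of
self-reported biogeographic origin.

**Demographics.** Age, height and weight are drawn per sex from normal
distributions truncated at the trial inclusion bounds (age 18-55 years,
BMI 18.5-30 kg/m^2; the BMI bound makes the admissible weight range
subject-specific given height). The configured moments describe the
*post-inclusion* cohort (e.g. women 60.56 kg, SD 7.57), so the sampler
solves for pre-truncation parameters whose truncated moments reproduce the
targets, using closed-form truncated-normal moments averaged over a fixed
height grid. The mean is matched essentially exactly; an SD can saturate at
the support-limited maximum (this happens for the female age SD of 10.69
years on [18, 55], where the sampler delivers about 9.9 — the closest a
truncated normal can get).

**Genotypes.** The ten transporter variants are drawn independently per
locus under Hardy-Weinberg equilibrium from European allele frequencies.
The star-allele genes (CYP2D6, CYP2C9, CYP2C19, CYP2B6, CYP2C8, CYP2A6,
CYP3A4, CYP3A5, SLCO1B1, UGT1A1) are drawn at the *haplotype* level — two
star alleles per subject — and then expanded into the variant calls their
definitions imply. Sampling variants independently would destroy haplotype
structure (CYP2D6\*4 needs both of its defining variants in cis) and make
diplotype recovery untestable. Loci are simulated without linkage
disequilibrium; the real ABCB1 variants are partially linked, which the
default generator does not reproduce (each variant therefore needs its own
injected effect to be detectable). CYP2D6 copy number defaults to 2;
configuring the distribution exercises the deletion (\*5) and duplication
paths.

**Pharmacokinetics.** Each subject-drug pair gets one-compartment
first-order parameters: apparent clearance `CL/F`, volume `V/F` and
absorption rate `ka`, log-normally distributed around the drug's base
values (CV 25%, 20% and 30%) with a 0.6 correlation between `CL` and `V`
so that the half-life CV stays near the observed ~20%. Concentrations
follow

$$C(t) = \frac{1000\,D}{V/F}\,\frac{k_a}{k_a-k_e}\left(e^{-k_e t} - e^{-k_a t}\right)$$

in ng/mL for dose in mg, multiplied by mean-one lognormal proportional
error (default CV 15%; no assay error model is published, and 15% is a
typical validated LC-MS/MS figure). Sampling uses a fixed 17-point 0-48 h
schedule (0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 6, 8, 10, 12, 24, 36,
48 h) covering the 1-5 h tmax range with at least three terminal points.
Values under the drug's lower limit of quantification (20.02 / 2.51 /
1.01 ng/mL for valsartan / olmesartan / hydrochlorothiazide) are flagged
below-quantification. A between-period variability component on relative
bioavailability is exposed in the configuration and defaults to 0 (no
within-subject between-period variance is reported for these trials).

Base parameters are calibrated so that noise-free NCA of the simulated
profiles lands within +-25% of the published group means for AUC~inf~,
tmax and t~1/2~ at every dose (e.g. valsartan 160 mg AUC~inf~ near
27,000 ng·h/mL, hydrochlorothiazide t~1/2~ near 9.5 h). A one-compartment
model cannot simultaneously match those three quantities *and* the
published Cmax: real profiles are multi-phasic, and matching the terminal
half-life forces a large apparent volume that caps the peak. Simulated
Cmax therefore runs at roughly half the printed values, with all relative
(between-group) Cmax structure preserved. We chose to privilege AUC, tmax
and t~1/2~ because they carry the cohort's association findings.

**Injected effects.** Covariate effects are multiplicative on `CL`, `V`,
`ka` or `ke` (a `ke` multiplier rescales `V` at fixed `CL`, changing
half-life without touching exposure). The defaults encode the association
structure the analysis is meant to detect: ABCB1 rs1045642 T/T halves
valsartan `ka` (slower absorption, later tmax); SLC22A1 rs34059508
A-carriers have 0.76x hydrochlorothiazide clearance (higher exposure);
CYP2D6 poor metabolisers have 0.63x valsartan `ke` (longer half-life,
unchanged AUC); women have 0.77x clearance of hydrochlorothiazide and
olmesartan (higher dose-corrected exposure, tracking body size) and a
smaller hydrochlorothiazide volume (shorter half-life). The lower female
valsartan AUC~inf~/DW needs no explicit effect: it emerges from body
weight alone. `null_effects()` switches every multiplier to 1 and every
ADR slope to 0, which is the configuration used for type-I calibration.

**Safety.** Each ADR term (headache, dizziness, postural dizziness,
nausea) is a Bernoulli draw with logit = intercept + slope x standardised
log AUC~inf~; intercepts are calibrated to the published incidences and
the slope links ADR risk to exposure. Blood pressure falls at 3 h and 6 h
(the 6 h systolic fall is larger in women), heart rate rises at 6 h more
in olmesartan trials, and QTc lengthens ~12.5 ms at 6 h.

## Non-compartmental analysis

`nca()` is the estimator core: it returns a classed object with
`print()`, `coef()`, `summary()`, `plot()` and `residuals()` methods.

* **BLOQ policy** (`preprocess_bloq()`): below-quantification samples
  before the first quantifiable one become zeros (the pre-dose sample
  contributes a leading zero trapezoid); embedded BLOQ samples are
  excluded; of a trailing BLOQ run only the first sample is kept, excluded
  from both AUC and slope fitting. All-BLOQ profiles are flagged
  non-evaluable and excluded listwise with a logged reason, never raised
  as errors.
* **Cmax/tmax** are read directly off the observed curve; ties go to the
  earliest time, and profiles are re-sorted canonically so the tie-break
  is order-stable.
* **AUC~t~** uses the plain linear trapezoid up to the last quantifiable
  sample at or before 48 h (a log-linear-down variant exists but is off by
  default, since only "the trapezoidal rule" is specified for these
  analyses). The anchor is the last quantifiable sample rather than a
  forced 48 h reading.
* **Terminal slope**: ordinary least squares of log C on time over a tail
  of quantifiable points strictly after tmax. Tail selection maximises
  adjusted R^2 over all tails of >= 3 points, with ties (within 1e-4)
  going to the longer tail — the convention of the commercial NCA tools
  this replaces; a fixed last-3 rule is available. `Ke` is the negative
  slope and must be positive, else the profile is non-evaluable;
  `t1/2 = ln 2 / Ke`.
* **Extrapolation**: `AUCinf = AUCt + C_last/Ke`, with the extrapolated
  percentage reported and flagged above 20%.
* **Normalisation**: `X/D = X/dose` and `X/DW = X · weight/dose`
  (ng·h·kg/mL·mg for AUC).
* **Crossover aggregation**: valsartan and hydrochlorothiazide T and R
  periods are averaged arithmetically per subject (all their test
  formulations were bioequivalent); olmesartan keeps reference periods
  only. Because parameters are averaged individually, an aggregated row
  need not satisfy `t1/2 = ln2/Ke` exactly — that identity holds per
  period.

On noise-free profiles the engine recovers the analytic one-compartment
values: trapezoidal AUC within 1% of the closed-form integral on a dense
schedule, AUC~inf~ within 2% of `D/CL`, t~1/2~ within 5% of `ln2·V/CL`
even on the sparse clinical schedule. These oracle comparisons are frozen
in the test suite.

## Genotype-to-phenotype translation

Star-allele definitions, per-variant reference/alternate alleles and
per-allele function assignments are bundled as versioned text fixtures
(CPIC/DPWG-style conventions, PharmVar-style definitions; the CYP2C8
assignments are provisional, and UGT1A1 rs887829 stands in for \*28).
`call_diplotype()` enumerates every unordered pair of defined alleles
(plus the implicit reference \*1) and keeps the pairs whose summed
variant-allele counts reproduce the observed genotype. Phase being
unknown, several pairs can be consistent; the nesting rule prefers the
pair containing the allele defined by the most variants (so rs4149056 C +
rs2306283 G heterozygotes call \*1/\*15 rather than \*5/\*37), and
alternatives are reported with an ambiguity flag rather than silently
dropped. CYP2D6 copy number enters both the call (one copy calls the
retained haplotype against \*5; zero copies is \*5/\*5) and the activity
score (a duplication counts the higher-activity allele once per extra
copy). Activity-score cut-offs: 0 poor, (0, 1] intermediate, (1, 2.25]
normal, > 2.25 ultrarapid metaboliser; \*1/\*41 scores 1.25 and is NM
under these bins. Other genes combine the two alleles' function classes
(two deficient alleles PM/PF, one IM/DF, increased-function alleles
shifting toward RM/UM). In round-trip tests over the bundled allele
universe the caller recovers every unambiguous simulated diplotype and
never changes the phenotype on the ambiguous ones.

## The association cascade

For each outcome the **normality gate** applies Shapiro-Wilk at
alpha = 0.05 to the raw values, then to their natural logs (the log base
is a package convention), and otherwise routes nonparametric; values <= 0
forbid the transform. Univariate screens then use the pooled-variance
t-test or one-way ANOVA with Bonferroni pairwise post hoc on the gated
scale, or Mann-Whitney / Kruskal-Wallis with Bonferroni-adjusted pairwise
Mann-Whitney on the nonparametric route (Bonferroni for the rank post hoc
is a package choice; only the ANOVA post hoc is specified upstream).
Bonferroni correction is applied only within one post-hoc family — there
is no across-variant correction, mirroring the exploratory candidate-gene
design; this is a deliberate, documented caveat. Predictors with
univariate p < 0.05 enter one ordinary least-squares model on the gate's
chosen scale (the regression always uses the gated scale, including after
a log route); collinear predictors are dropped with a warning and the
model refitted. The pooled t-test default makes the single-binary-
predictor regression exactly equivalent to the univariate test (checked
to 1e-10); Welch is available by flag. Paired pre/post tests report mean
(SD) changes; zero-variance differences return flagged sentinels (p = 1
for no change, the machine floor for a constant shift) instead of
raising. Incidence tables use Pearson chi-squared without continuity
correction when all expected counts are >= 5 and the two-sided Fisher
exact test otherwise; the Fisher route is verified against brute-force
hypergeometric enumeration for tables up to N = 200.

## Calibration studies and their problem sizes

`sign_recovery_study()` simulates single-drug cohorts of n = 200 (200
replicates) per injected effect and checks that the cascade's estimated
effect carries the injected sign; at the valsartan trial's own size
(n = 26) the rs1045642 absorption effect is detected (univariate
p < 0.05) in well over half the replicates. `null_calibration_study()`
runs 500 replicates of a trial-sized null cohort (n = 58,
`null_effects()`) and pools two quasi-independent screens per replicate;
the type-I rate must sit within the 3-SE binomial band around 5%. Note
that under the null configuration, dose/weight-corrected exposure still
differs by sex through body weight itself — that contrast is mechanical,
not a type-I error, so the null study screens half-life against sex and
exposure against genotype. These problem sizes (200 x 200, 500 x 58) were
chosen as the smallest designs that pin the binomial bands meaningfully.

## Numerical and degenerate-input conventions

Sampling is fully deterministic given the master seed: each generator
stage (and each drug within a stage) draws from a derived substream seed,
so stages can be re-run independently and identical configurations give
byte-identical tables. Lognormal parameter variability is median-centred;
residual error is mean-one. `ka = ke` profiles are excluded by
construction (a degenerate equal-rate model has a removable singularity we
do not special-case). Identical-group comparisons return p = 1; constant
outcomes route nonparametric because Shapiro-Wilk is undefined. Written
tables use fixed 10-significant-digit formatting so equal seeds give
byte-identical files across platforms.

## Limitations

The generator is one-compartmental (no distribution phase, hence the low
simulated Cmax; no enterohepatic recirculation), simulates loci without
linkage disequilibrium, carries ADR causality labels directly rather than
deriving them from an adjudication algorithm, and does not model the
olmesartan-hydrochlorothiazide absorption interaction or amlodipine.
Passing tests demonstrate that the analysis machinery is correct and
calibrated under these assumptions — not that real profiles are
one-compartmental, nor that the published cohort's group means are
recoverable (they derive from sponsor-held raw data and serve only as
plausibility bands here). Bioequivalence TOST/90% CI analysis and
compartmental fitting are out of scope.
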