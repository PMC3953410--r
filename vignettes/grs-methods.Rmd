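---
title: "Genetic risk scores for adiposity traits: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic risk scores for adiposity traits: models, simulation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grsobesity)
```

## The scientific problem

Genome-wide association studies have identified dozens of loci whose common
variants shift body-mass index (BMI) by small per-allele amounts, mostly in
European-ancestry populations. Two questions follow for any other
population: do those variants, individually and in aggregate, carry over,
and is the aggregate genetic effect modified by lifestyle — here, physical
activity (PA)? This package implements the full analysis chain for those
questions around an *unweighted genetic risk score* (GRS): the count of
BMI-increasing alleles an individual carries across a SNP panel.

The packaged panel (`default_panel()`) holds 28 BMI-associated loci with
their effect-allele frequencies (EAF) in a Han Chinese cohort, split into a
24-SNP European-ancestry (EA) subset and an 11-SNP East-Asian-ancestry
(EAA) subset sharing 7 loci. Three fields of the fixture are documented
assumptions rather than published facts: the effect/other allele letters
(well-established ones such as FTO rs9939609 A/T are used where known,
conventional placeholders elsewhere), the identity of the 7 shared EAA loci
(taken to be the EA loci replicated at genome-wide significance in East
Asians: FTO, SEC16B, MC4R, GIPR, RBJ, BDNF, MAP2K5), and the imputed flags
(all `FALSE`). None of these affect frequency-based computations — allele
letters matter only to VCF alignment plumbing, membership only to which
rsIDs enter a subset score.

## Score construction

Genotypes are effect-allele dosages in {0, 1, 2}. The overall GRS is the
row sum over the panel; EA/EAA scores restrict the columns. Two rules
surround the sum:

* **Missing genotypes** are replaced by the SNP's mean non-missing dosage
  in the analysis sample ("average allele count"). A panel-frequency
  fallback (`2*EAF`, `impute = "panel"`) exists for single-individual
  scoring, where a sample mean is undefined.
* **Missingness cap**: individuals with more than `max_missing` (default
  3) missing genotypes in the subset are excluded and reported, not
  imputed. The default mirrors the observation that no analysed individual
  exceeded three missing genotypes; we treat it as a conservative cap
  rather than a certainty about new data.

Scores are unweighted counts. Effect-size weighting is deliberately absent:
the method under study is the plain allele count, and a weighted variant
would change every downstream interpretation (units, explained variance).

Under Hardy-Weinberg equilibrium and independent loci the overall score has
mean $2\sum_j f_j$ and variance $\sum_j 2 f_j (1-f_j)$; for the packaged
EAFs this gives 23.30 and SD 3.19, which is what `scripts/acceptance.R`
re-measures by simulation.

## Quality control

Per SNP we report call rate, genotype counts, and the **exact
Hardy-Weinberg test**: conditional on the allele totals, the heterozygote
count $n_1$ has probability proportional to
$\frac{n!}{n_0!\,n_1!\,n_2!} 2^{n_1}$, and the two-sided p-value sums the
probabilities of all heterozygote counts no more likely than the observed
one. We chose the exact conditional test over the chi-squared
approximation because panel minor-allele counts can be small and because
the exact test is verifiable against independent enumeration (the test
suite checks every attainable table up to $n = 200$ against a
recurrence-based oracle). Defaults follow the conventional thresholds:
call rate $\ge 0.95$, HWE $p \ge 0.01$. Monomorphic SNPs fail QC with
their own reason code — an extension beyond the usual two rules, since a
monomorphic locus contributes nothing to a count score but would otherwise
pass both checks silently. QC annotates and reports; it never filters
silently. Downstream stages receive an explicit kept-SNP list.

Cross-population genotype-distribution comparison uses a likelihood-ratio
G-test on the 2x3 genotype table (expected counts from pooled
proportions), with an allele-level 2x2 collapse available via
`level = "allele"`; genotype-level is the default because it is the
stronger null. Categories empty in both populations reduce the degrees of
freedom and are noted in the result.

## Association models

Quantitative traits are analysed by ordinary least squares with an
intercept, assuming additivity in allele count. Two covariate presets
mirror standard adiposity practice: `bmi-set` (age, age\^2, sex, region,
first two principal components) for BMI, weight classes and interaction
models; `dxa-set` (age, age\^2, sex) for the DXA fat-percentage traits.
Age\^2 is always built internally from the age column so the quadratic
term can never be supplied on a different scale; sex and region enter as
0/1 indicators with reference levels male and Beijing recorded in the
design's metadata. Complete cases are determined per model, because DXA
traits exist only for a subset of individuals and each model's n must
float accordingly; dropped rows are counted in the result.

The **inverse-normal transform** maps a trait to
$\Phi^{-1}((r - 3/8)/(n + 1/4))$ with average ranks for ties (Blom
offset, configurable). Only the target moments (mean 0, SD 1) are fixed
by convention; the Blom offset is our choice and is documented as such.
Effects on the transformed trait are per-SD and invariant to monotone
rescaling of the raw trait, which is what makes effect sizes comparable
across traits.

Weight classes follow the Chinese adult cut-offs with left-closed,
right-open intervals: normal < 24, 24 $\le$ overweight < 28, obese
$\ge$ 28 kg/m^2. Obesity and overweight are each contrasted against
normal by maximum-likelihood logistic regression (IRLS, coefficient
tolerance 1e-10, 50 iterations), reporting the per-allele odds ratio with
Wald 95% CI — Wald rather than likelihood-ratio because the OR (CI)
presentation is the reporting convention being matched. Non-convergence
and separation (|beta| > 15 or SE > 100) are hard errors in the
user-facing function; the pipeline catches them per predictor, emits an
NA row and lists the failure in the run manifest, so one rare allele
cannot abort a whole report.

Two small conversions round out the reporting: explained variance of a
locus, $2 f (1-f) \beta^2$ with $\beta$ per-allele on the standardized
trait (symmetric in $f \leftrightarrow 1-f$, so effect-allele frequencies
above 0.5 are handled by `min(f, 1-f)` without changing the value), and
the gram equivalent of a BMI effect, $\beta \cdot h^2 \cdot 1000$ g at
height $h$. The Bonferroni threshold is plain $\alpha/m$ with $m$ always
an explicit argument — the package never hard-codes a test count.

## Interaction, stratification, attenuation

The score-by-PA model is one joint OLS fit of
`trait ~ score + pa + score:pa + covariates` with PA ordinal (0/1/2 for
low/moderate/high): the interaction coefficient is the change in
per-allele effect per PA-category step. Stratum-specific effects come
from separate per-stratum fits with the same covariates — we use separate
fits (rather than slopes implied by the joint model) because they carry
their own SEs, matching how stratified results are conventionally
tabulated; PA is ordinal in the joint model and categorical for
stratification. Attenuation is $100 (\beta_{low} - \beta_{high}) /
\beta_{low}$, negative when the high-activity effect is larger.

**Directional consistency** across a SNP set is tested with the exact
one-sided binomial tail $\sum_{k \ge n_c} \binom{n}{k} 2^{-n}$. One-sided
is the deliberate convention for replication testing — the alternative of
interest is "more consistent than coin flips", and only the upper tail
reproduces the standard worked values (26 of 28 consistent gives
1.52e-6). Zero betas count as inconsistent and are flagged. For
$n \le 50$ the tail is computed in exact integer arithmetic
(binomial coefficients and their sum stay below $2^{53}$), above that in
log space.

**Cross-ancestry heterogeneity** per SNP is fixed-effect Cochran's Q on
two estimates with inverse-variance weights, df = 1. $I^2 = \max(0,
(Q-1)/Q)$ is attached as a supplementary descriptive (labelled an
extension; with two studies it is a monotone transform of Q).

## The synthetic cohort generator

The generator is first-class, tested code: it runs the analysis model
forward so that every downstream stage has a ground truth.

* Genotypes: independent Hardy-Weinberg draws at the panel EAFs
  ($P(2) = f^2$ etc.), no linkage disequilibrium.
* Covariates: age uniform integer 50–70; sex and region Bernoulli(0.5);
  PC1/PC2 standard normal; PA categorical with default probabilities
  219/1226/1449 out of 2894 (the low/moderate/high mix of the emulated
  cohort), coded 0/1/2.
* Trait: $BMI = \mu + \beta_{GRS} \cdot S + \text{covariates} + \delta
  (S - \bar S)(PA - \overline{PA}) + \varepsilon$.

The interaction acts on the **centered score and centered PA code**. This
is a deliberate parameterization: it keeps the marginal per-allele effect
equal to `grs_beta` while making the per-stratum effect
$\beta + \delta (PA - \overline{PA})$. At the defaults
($\beta = 0.11$, $\delta = -0.06$ kg/m^2, the 219/1226/1449 PA mix) the
implied stratum effects are about 0.20 / 0.13 / 0.08 kg/m^2 per allele —
i.e. one parameter pair generates, simultaneously, the marginal
association and the stratified-presentation pattern that the analysis
stage is meant to detect. Centering only the score (with a raw PA code)
would instead make the marginal effect $\beta + \delta\,E[PA] \approx
0.02$, leaving the generator internally inconsistent with its own
marginal target; we consider the double-centered form the correct
encoding of the intended study conditions.

Defaults the emulated study does not publish are calibrations, chosen
once: residual SD 3.6 kg/m^2 (set so the simulated score explains about
0.9% of BMI variance at $\beta = 0.11$ — with score variance
$\approx 10$, $R^2 = 0.11^2 \cdot 10 / (0.11^2 \cdot 10 + 3.6^2 +
\text{covariate variance}) \approx 0.009$), trait mean 23.7 kg/m^2,
small covariate effects (age 0.02 per year, sex 0.5, region 0.3, PCs 0.2
kg/m^2), fat-percentage traits with mean 28%, SD 5, +8 for women,
generated only for the Shanghai half to mirror a single-city DXA
sub-study. Genotype missingness is applied after the trait is computed —
missingness masks the emitted matrix, never the biology.

What the generator does **not** emulate, and hence what green tests do
not establish about real data: linkage disequilibrium between loci,
population stratification beyond two synthetic PCs, genotyping error and
imputation uncertainty, informative (non-MCAR) missingness, non-normal
trait residuals, and any correlation between PA and covariates. Recovery
tests therefore target the generating values, not any published SE.

`simulated_power()` estimates power by direct simulation (fraction of
replicates rejecting at $\alpha$, with an exact binomial CI) for either
the main effect or the interaction — simulation rather than a closed
form, so the power target is exactly the test actually run.

## Numerical choices and degenerate inputs

* HWE p-values: probability-mass ordering uses a relative tie guard of
  1e-12 (`prob <= p_obs * (1 + 1e-12)`), and the allele count is
  canonicalized to the rarer allele so that allele relabeling is exactly
  neutral (without this, floating-point ties can flip the inclusion of a
  tied heterozygote count between orientations). Monomorphic tables have
  a single attainable configuration and return p = 1.
* Binomial tails: exact integer arithmetic up to n = 50, log-space sums
  beyond.
* OLS rank deficiency is an error naming the collinear columns, never a
  silent drop. A constant trait cannot be inverse-normal transformed.
* `classify_weight` rejects non-positive and non-finite BMI; NA passes
  through.
* Palindromic (A/T, C/G) panel records are flagged strand-ambiguous
  during allele alignment and never auto-flipped by frequency; silent
  strand inference is a known error source at desk scale.
* VCF sites are matched to the panel by the ID column only (the panel
  carries no coordinates); missing-ID sites are skipped with a warning,
  multiallelic sites and allele-set mismatches are errors.
* All pipeline randomness flows from one seed in the config; rerunning a
  manifest reproduces every output byte for byte.

## Problem sizes in the test suite

The suite's simulation scales were chosen as the smallest that make each
statistical check meaningful: 100,000 individuals for the score-moment
checks (Monte-Carlo SE on the mean $\approx 0.01$ alleles), 200 seeds at
n = 2894 for coefficient recovery, 2000 replicates at n = 300 with a
6-SNP panel for type-I-error calibration of the main-effect and
interaction tests, exhaustive HWE-oracle comparison for all tables with
$n \le 60$ plus distribution-level comparison and sampled direct calls up
to $n = 200$. Coverage-style checks (e.g. "within 2 SE in $\ge$ 95% of
seeds") are themselves binomial measurements whose truth sits near the
threshold (nominal coverage of a 2-SE interval is 95.45%), so individual
fixed-seed runs of such checks carry irreducible assertion noise of a few
percentage points; the seeds are fixed a priori and not selected on
outcomes.

## Known limitations

* Loci are simulated and analysed as independent; no LD, no haplotypes.
* The EA/EAA subset membership and allele letters in the packaged panel
  are documented assumptions (see above); subset-score summaries
  therefore need not match any particular published cohort.
* No sample-level QC (relatedness, heterozygosity) beyond the
  missing-genotype cap; no genotype calling or reference-panel
  imputation; no liftover.
* Interaction testing is on the quantitative trait only; no
  multiplicative-scale (logistic) interaction.
* Heterogeneity is two-study fixed-effect only; no random-effects
  meta-analysis.
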