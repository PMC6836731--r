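---
title: "Absolute mtDNA quantitation from droplet counts: models and methods"
author: "ddmdm package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute mtDNA quantitation from droplet counts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddmdm)
```

## The measurement problem

Mitochondrial DNA copy number varies over orders of magnitude between cell
types and changes during activation, transformation and aging, which makes
it an attractive biomarker — but the standard qPCR read-out is relative
(mtDNA normalised to a nuclear gene) and inherits the compounded noise of
two exponential amplifications.  Droplet digital PCR sidesteps both
problems: the reaction is emulsified into thousands of nanolitre droplets,
each an independent endpoint PCR, and quantitation reduces to *counting*
fluorescent droplets.  When the sample is a measured number of **cell
equivalents** of crude lysate (the fraction of one cell's lysate delivered
to the reaction, tracked through the dilution chain), the result is an
absolute number of mtDNA molecules per cell — no DNA purification, no
reference gene.

This package implements that computational chain, its duplexed extension
for the 4977-bp common deletion, the validation statistics used to
characterise such an assay, and a generative simulator of the whole
measurement process so that every estimator can be exercised against known
ground truth.

## The occupancy estimator

With $k$ of $n$ analyzed droplets fluorescent, the maximum-likelihood mean
occupancy (template molecules per droplet) is the Poisson correction for
co-encapsulation:

$$\hat\lambda = -\ln\!\left(1 - \frac{k}{n}\right).$$

Conversions (`toCopies()`):

* concentration $= \hat\lambda / V_d$ copies/µL, with $V_d$ the droplet
  volume;
* copies per reaction $= \hat\lambda \, V_{rxn} / V_d$ (**volumetric**
  mode, default — the convention of instrument software, which reports a
  concentration and multiplies by the 20 µL pre-emulsion volume), or
  $\hat\lambda\, n$ (**counted** mode, the template actually emulsified);
* copies per cell equivalent $=$ copies per reaction / cell equivalents.

The two conversion modes genuinely differ by the fraction of the reaction
the reader analyzed ($nV_d/V_{rxn}$, roughly 0.65–0.85 at 15,000–20,000
droplets of 0.85 nL in 20 µL).  The "800–1000 copies per reaction
$\approx$ 5 % positive droplets" working point is a counted-mode
statement; volumetric copies are correspondingly larger.  We keep both
modes and document the discrepancy rather than resolving it silently.

Confidence intervals are Wilson score intervals on $p = k/n$, mapped
through the monotone transform $-\ln(1-p)$ and then through the linear
volume conversions.  Wilson was chosen over Wald or bootstrap because it
behaves at $k = 0$ (the interval collapses to an honest one-sided upper
bound, reported with a `zero` flag) and is asymmetric at small $k$ without
simulation cost.  $k = n$ is an error, not a value: occupancy is undefined
at saturation and the sample must be diluted.  A `high_occupancy` flag is
raised above $k/n = 0.85$, where precision degrades; the assay is designed
to sit near 5 %.

## Droplet classification

Positive/negative calling is deliberately simple and deterministic:

* `two_cluster` (default): one-dimensional 2-means with centres initialised
  at the amplitude extremes; threshold midway between the cluster centres.
  The clustering used by instrument software is proprietary, so this is an
  explicit, reproducible stand-in.
* `negative_control`: threshold at the cell-free control's mean amplitude
  plus five control standard deviations.
* `manual`: a user threshold, for replicating a hand-confirmed analysis.

Ties sit below the threshold (strictly-above counts as positive), the
conservative choice.  Two-means run on a *unimodal* amplitude cloud (a
template-free well) splits the Gaussian at its mean and reports centres
about 2.7 pooled within-cluster SDs apart; genuinely bimodal wells sit tens
of SDs apart.  The degeneracy guard therefore fires when the centres are
closer than **3** pooled SDs, falling back to the negative control when one
is available and warning otherwise.  A 2-SD guard would never trigger on
exactly the wells it is meant to catch.

## Duplexed common-deletion estimation

The 4977-bp common deletion removes *MT-ND4* but no known large deletion
spans the *D-Loop*, so a duplex of the two targets in one well estimates
the deletion burden as

$$\hat f = 1 - \frac{\hat\lambda_{ND4}}{\hat\lambda_{DLoop}}.$$

The ratio is taken on occupancies, not raw positive counts: at high
occupancy, co-encapsulation saturates counts nonlinearly and a raw-count
ratio is biased (the test suite demonstrates this at $\lambda = 0.5$).
The 95 % interval is a parametric bootstrap (2,000 draws, binomial
resampling of $k \mid n$ per channel), which respects $k = 0$ in the ND4
channel where a delta-method interval would not.  Negative $\hat f$ from
sampling noise is reported as-is with a flag — clamping at zero would bias
group means upward exactly in the young, low-burden donors one wants to
compare.

## Validation statistics

* `dilutionLinearity()` — OLS of $\log_{10}$ mean measured copies on
  $\log_{10}$ expected input; slope 1 and $R^2 \to 1$ indicate accurate
  absolute quantitation down to the limit of detection.  Nonpositive means
  are excluded with a warning rather than pseudocounted, because a zero at
  the bottom of a dilution series is information about the detection
  limit, not a measurement to be patched.
* `replicateCv()` — intra-assay CV within replicate groups, inter-assay CV
  across group means, in percent.
* `sigmaEst()` — the standard error of the estimate: residual SD about the
  measured-versus-prepared OLS fit, as a percentage of the mean measured
  value.  Residuals are taken about the regression (not about group means);
  the alternative exists in the literature but the regression form is the
  conventional reading of the term.
* `minDetectableDifference()` — smallest prepared increment
  distinguishable from baseline by an unpaired two-tailed t-test, and the
  smallest pairwise increment difference significant under one-way ANOVA
  with Tukey HSD (studentized-range quantiles via `ptukey`).  Welch is the
  default t-test — printed group SDs are rarely equal — with a
  pooled-variance option for exact replication of classical analyses.
  One caveat found during development: the *global* minima are not
  guaranteed to order as "Tukey ≥ t-test".  Tukey pools the within-group
  variance across all groups and gains degrees of freedom, so with small
  $n$ per group it can out-power a per-pair Welch test.  What is
  guaranteed, and what the test suite asserts, is the per-contrast form:
  the Tukey-adjusted p-value of a contrast is never smaller than the
  unadjusted p-value of the same studentized contrast.
* `methodComparison()` — simulates the amplicon-mixing sensitivity design
  under three measurement models (qPCR target/reference ratio with Ct
  noise; two-reaction droplet ratio; single-channel per-cell-equivalent
  measurement) and scores each with the statistics above.  Under the
  default noise settings the single-channel model approaches its
  shot-noise floor (≈ 3.4 % CV at 900 copies in 17,500 droplets) while the
  ratio designs compound two channels' noise, reproducing the published
  sensitivity ordering.

Group comparisons (`compareGroups()`) accept either raw values or printed
summary statistics $(n, \bar x, s)$ per group, so published cohort tables
can be re-tested without raw data; the two modes agree to numerical
precision when summaries come from the raw values, and both are
cross-checked in the tests against `t.test()` and `TukeyHSD()`.

## The generative simulator

`SimModel()` parameterises the chain lysate → dilution → reaction →
droplets → amplitudes.  One simulated well is drawn as:

1. analyzed droplets $n \sim$ Uniform[15,000, 20,000] — modelling the
   reader's output directly rather than emulsion dead volume, because the
   estimator is invariant to droplet subsampling (a property the tests
   check);
2. reaction molecules $m \sim$ Poisson(copies/cell × cell equivalents ×
   pipetting factor), the pipetting factor being one multiplicative
   log-normal draw per well (CV `pipettingCv`), a single-parameter model of
   loading/dilution handling noise;
3. binomial thinning of $m$ to the analyzed droplets with probability
   $n V_d / V_{rxn}$ — the analyzed droplets physically cover only part of
   the reaction volume, and without this step the volumetric conversion
   would overestimate by $V_{rxn}/(nV_d)$ (~1.3×);
4. multinomial partition of the thinned molecules over the $n$ droplets
   (`partitionMolecules()`, which always conserves the molecule count);
5. amplitudes: empty droplets from the negative cluster, template-positive
   droplets from the positive cluster, except a `rainFraction` drawn
   uniformly from the inter-cluster band; amplitude-level
   misclassification (`misclassFp`, `misclassFn`) applied last.

Key defaults, with units and reasons:

| parameter | default | why |
|---|---|---|
| `dropletVolumeNl` | 0.85 nL | platform-typical droplet volume; required for any copies-per-µL conversion, exposed because instruments differ |
| `dropletCountRange` | [15000, 20000] | typical analyzed-droplet yield per well |
| `reactionVolumeUl` | 20 µL | standard reaction volume |
| `copiesPerCellMean`, `copiesPerCellCv` | 500, 0.5 | hundreds of copies per cell; log-normal cell-to-cell heterogeneity (strictly positive, right-skewed, matching the wide single-cell spread; CV 0.5 for heterogeneous lines, 0.15 emulates a clone) |
| `pipettingCv` | 0.05 | per-well loading CV of a multi-step manual dilution |
| amplitude clusters | 2000 ± 200 / 10000 ± 400 | well-separated clusters in arbitrary fluorescence units |
| `rainFraction` | 0.02 | rain is real but unquantified in endpoint assays; a small value that makes threshold placement matter |
| `misclassFp`, `misclassFn` | 10⁻⁴ | rare stray calls; ~1–2 droplets per well |

The rain and misclassification defaults are conventions, not measured
values; both are zero-able, and every exact-recovery test uses the clean
setting.

The matched qPCR model (`QpcrModel()`) draws
$C_t = c_0 - \ln(\text{copies})/\ln(1+E) + \mathcal N(0, \sigma_{C_t})$,
deterministic at $\sigma_{C_t} = 0$, with the textbook −3.32 cycles per
decade at $E = 1$; fitting the simulator's own standard curve recovers $E$
to machine precision, which the tests assert.

Dilution chains are symbolic: `cellEquivalents()` propagates a starting
cell count through take/add steps and the final aliquot with no sampling,
so the protocol arithmetic (a bulk chain delivering exactly 5 cell
equivalents per reaction; a single-cell chain delivering exactly 0.3) is
checked exactly.  Which cell type a dilution series emulates is a free
parameter (`copiesPerCellMean`); the package takes no position on it.

Cohort simulation (`simulateCohort()`) generates per-subject stimulation
time courses: a resting day-0 draw (Normal(422, 44) truncated at zero), a
day-1 dip at ×0.70 of day 0 (the scale of the published resting-to-day-1
drop; configurable) reflecting activation-induced cell death, a rise to a
subject-specific peak (truncated Normal with the group's published mean and
SD) on a day drawn from days 3–6, and a slow exponential decline (rate
0.05/day) afterwards.  Series are capped at the subject's peak so the
maximum equals the drawn peak whenever the peak day is on the grid.  The
four default groups use the published sizes, ages, day grids and peak
summaries; the frail-centenarian peak distribution is not published, so a
synthetic 650 ± 300 (below the old group) is used and labelled as such.
Peaks are extracted on each subject's own day grid with no interpolation,
ties broken by the earliest day.

Sub-streams: every top-level simulation call draws child seeds for its
units (wells, cells, subjects) up front, so enlarging a panel never
perturbs the units already generated, and identical seeds give
bit-identical output.

### What the simulator does not emulate

No thermocycling kinetics or within-droplet amplification efficiency
(endpoint fluorescence is assumed saturated), no PCR inhibitors, no
droplet-volume variation, no spatial or temporal drift in the reader, no
between-run batch effects, and no cell-cycle structure beyond what the
per-cell log-normal absorbs.  Passing the recovery and calibration tests
therefore shows the *estimators* are correct for the stated noise model;
it does not certify performance on instruments whose rain or baseline
behaviour departs strongly from these assumptions.

## Numerical choices and degenerate inputs

* Positives are amplitudes strictly above the threshold; ties negative.
* $k=0$ yields a 0 point estimate plus an upper bound (not a censored
  missing value), matching how cell-free controls are reported.
* Replicate pooling sums droplets ($\sum k$, $\sum n$) rather than
  averaging per-well estimates; per-well estimates are retained for CV
  reporting.
* Log-log fits refuse to run with fewer than 3 positive points; constant
  expected loadings and constant ages are errors, not NaNs.
* The bootstrap deletion interval is widened, if necessary, to bracket the
  point estimate (relevant only for extremely sparse channels).
* All file output writes numerics with 17 significant digits so round
  trips are exact.

## Problem sizes used by the checks

The packaged checks run, on one CPU, with: 52,000 count-level wells for
estimator bias across $\lambda \in [0.001, 1]$ and 4,000 wells for CI
coverage at $\lambda = 0.05$; 5,000 full partition chains for the
shot-noise floor; a 4-point × 6-well limit-of-detection series at 5 →
0.01 cell equivalents; 200 duplex wells (2,000 bootstrap draws each) for
deletion recovery; 73 simulated single cells in triplicate against six
pooled bulk wells; and 30-cell clone versus heterogeneous panels.  These
sizes put Monte-Carlo error comfortably below each tolerance while keeping
the whole suite in seconds.

## Limitations

The two-cluster threshold is a stand-in for proprietary instrument
clustering and is per-well (optionally per-plate-control); no global
multi-well threshold optimisation is attempted, mirroring practice where
thresholds are confirmed manually.  Whether published replicate CVs were
computed on duplicate means or pooled droplets is not generally stated, so
empirical CV values are treated as order-of-magnitude consistency checks,
not exact targets.  The duplex model assumes channel independence given
loading (one well, one pipetting event) and a one-well duplex design.
Cohort analyses on real data require subject-level values, which published
tables rarely include; the simulator is the bridge.
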