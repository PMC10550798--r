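---
title: "Post-analytical methods for microfluidic RT-qPCR miRNA arrays"
author: "cqpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-analytical methods for microfluidic RT-qPCR miRNA arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cqpipe)
library(dplyr)
```

# Scope

`cqpipe` implements the post-analytical stages that sit between a microfluidic
RT-qPCR (low-density array) run and a biological conclusion: quantification
cycle (Cq) determination under three threshold algorithms, amplification-curve
quality control, call-rate and median-Cq filtering, reference-miRNA stability
ranking, normalization-factor construction, and `2^-ddCq` relative expression
with the associated comparison statistics. Every stage operates on plain
tibbles and returns tibbles, so the pipeline composes with ordinary
dplyr verbs.

The package deliberately does not touch anything upstream of the fluorescence
table: probe chemistry, passive-reference dyes, instrument file formats and
melt-curve analysis are out of scope, as are efficiency-corrected
quantification models and multiple-testing-corrected discovery claims.

# The simulated experiment

Real microfluidic-card data sets are rarely redistributable, so the package
ships a seeded simulator whose ground truth drives every test.

## Amplification curves

A simulated well follows a four-parameter logistic on a linear baseline:

$$Rn(c) = \beta_0 + \beta_1 c + \frac{A}{1 + e^{-(c - m)/b}} + \varepsilon_c,
\qquad \varepsilon_c \sim N(0, \sigma^2) \text{ i.i.d.}$$

This is the minimal model exhibiting the four phases of a real amplification
plot (baseline, exponential, linear, plateau). Richards-type asymmetry is
omitted: no operation in the package depends on plateau asymmetry, so the
extra parameter would only dilute the ground truth. `amplitude = 0` encodes a
non-amplifying well.

Parameter conventions and defaults:

* **steepness** `b` is tied to amplification efficiency: a reaction of
  efficiency $E$ multiplies template by $1+E$ per cycle, so the exponential
  phase has log-slope $\ln(1+E)$ and $b = 1/\ln(1+E)$. Efficiencies of
  0.8--1.1 (the range a validated assay is expected to reach) give
  $b \in [1.35, 1.70]$; the default $b = 1.44$ is perfect doubling ($E = 1$).
* **midpoint_cycle** defaults span 22--32 in the simulated data sets, matching
  the observed Cq range of arrays whose barely-expressed targets are filtered
  at a median Cq of 32.
* **noise_sd** is i.i.d. Gaussian per cycle. Real instrument noise has mild
  autocorrelation and a heavier tail; i.i.d. noise is sufficient to calibrate
  a pass/fail QC gate and keeps the analytic ground truth exact.
* The ground-truth Cq of a simulated curve is the closed-form crossing of its
  noise-free, baseline-subtracted logistic
  ($c = m + b\,\ln(t/(A-t))$, `analytic_crossing()`), which every threshold
  algorithm is tested against.

The simulated card layout (`card_layout()`) reproduces the control complement
of the real two-card set: four wells of U6 snRNA-001973, one RNU44-001094 and
one RNU48-001006 per card, plus the non-human negative control ath-miR-159,
leaving 377 miRNA assays per card (754 across cards A + B).

## Cq data sets

`simulate_cq_dataset()` draws Cq tables under an additive model: per-target
base level, per-group effect, per-sample global abundance shift, and
per-target Gaussian noise, with missingness completely at random. Its
defaults encode the rank-recovery design used throughout the validation: one
designated stable target (technical SD 0.05 Cq) among 20 targets with SDs of
0.5--1.5 Cq, half of the unstable targets carrying a group shift of 0.5--2 Cq
with random sign, 25 + 25 samples, a per-sample shift SD of 0.5 Cq, and 5%
missingness (set to 0 where completeness is required). What the simulator
does **not** emulate — amplification-efficiency differences between targets,
plate-position effects, correlated dropout at high Cq — bounds what passing
tests show: they validate the post-analytical arithmetic and decision rules,
not robustness to every failure mode of real cards.

# Cq calling

## Baseline subtraction

The baseline is estimated in two passes. A provisional line is fitted to
cycles 3--10; the emergence of amplification is the first cycle whose
smoothed provisional-corrected signal exceeds
$\max(0.2\% \text{ of the rise}, 3 \times \text{residual SD})$; the final
line is refitted on cycles 3 up to six cycles before emergence, clamped to
[5, 15] so at least three cycles remain. Keeping the window well clear of
emergence matters: the exponential tail decays like $e^{-(m - c)/b}$, and a
window ending too close to emergence biases the fitted slope enough to move
the called Cq by ~0.1 cycles for early amplifiers. With this rule the
maximum recovery error over random noise-free logistics
(amplitude 0.6--2.5, midpoint 22--32, steepness 1.35--1.70) is below
0.01 cycles. Curves with no detectable pre-amplification phase (flat wells,
very early amplifiers) fall back to the minimal window and are flagged with a
summarising warning.

Every decision in the pass uses ratios of signal magnitudes, so the corrected
trace transforms exactly linearly under $Rn \mapsto a\,Rn + b$ — the property
the relative threshold method inherits.

The per-curve noise estimate is the larger of the two windows' residual SDs:
the final window can hold only three cycles (one residual degree of freedom),
where its own residual SD is an unusable estimate.

## Threshold crossing

The fractional crossing cycle is located on the integer grid and refined with
a monotone cubic Hermite interpolant (`stats::splinefun`, `monoH.FC`) of
log-signal through the neighbouring positive cycles, degrading to log-linear
and then linear interpolation when too few positive points surround the
crossing. Log-linear interpolation alone was considered and rejected: its
worst-case error on an integer-cycle grid is approximately
$(t/A)/(8b)$ cycles, which exceeds the package's 0.02-cycle recovery target
for steep curves at the default threshold-to-amplitude ratio, while the
monotone cubic is two orders of magnitude more accurate at identical cost.

## The three threshold algorithms

* **Fixed** (default 0.2): one user-set fluorescence level for every curve,
  the convention for small target panels. Not scale-invariant by design —
  that is precisely the behaviour the cross-method comparison quantifies.
* **Automatic**: one threshold per target, shared by all of that target's
  curves: 20% of the geometric-mean estimated plateau rise over the target's
  amplified curves, the plateau rise being twice the corrected signal at the
  detected exponential-phase midpoint (the inflection, found as the maximum
  smoothed first difference). The 20% factor places the threshold in the
  exponential region and makes the automatic call coincide with the fixed
  0.2 call for unit-rise curves, which anchors the two methods' comparability.
* **Relative**: a per-curve, threshold-free call. The smoothed corrected
  signal is min--max rescaled to [0, 1]; the per-cycle efficiency
  $e(c) = z(c+1)/z(c) - 1$ is computed on the positive part and smoothed; the
  reference level is 50% of the peak smoothed efficiency; the fractional
  cycle where the efficiency model falls to that level past its peak is
  mapped to a fluorescence level, and the call is the crossing of that level.
  Every step commutes with positive affine maps of the raw signal, so the
  call is exactly invariant under rescaling and offsets (verified to 1e-12).
  The 50%-of-peak rule is this package's open choice of reference efficiency
  level; instrument vendors use an unpublished predetermined value, and no
  claim of numerical agreement with any instrument is made. Curves whose
  dynamic range is below five times the noise estimate return no call: a
  relative scale on noise is meaningless.

Commercial implementations of the automatic and relative algorithms are
proprietary; the versions here honour the documented *contracts* (per-target
shared threshold; per-curve, threshold-free, affine-invariant relative call)
and are validated against the simulator's analytic ground truth instead of
against any instrument.

# Curve quality control

Two scores gate every call, with the conventional ranges and cutoffs:
an amplification score in [0, 2] (pass > 1) and a Cq confidence in [0, 1]
(pass > 0.8; above 0.95 is very confident). The pass rule is
`amp_score > 1 AND cq_conf > 0.8`; the categorical status adds `NO_AMP`
(score < 0.5 with no crossing) and `INCONCLUSIVE` for everything between.
`INCONCLUSIVE` is never auto-promoted — the gate treats it as a failure.
Unlike instrument software, the status here is deliberately per-curve and
does not depend on how many curves share the run.

The amplification score is a logistic map of (curve nonlinearity in noise
units) × (log-linear fit $R^2$ of the exponential region). Nonlinearity is
the largest smoothed residual from a straight line fitted to the whole
corrected curve: a genuine sigmoid leaves residuals of the order of the
plateau rise, while pure noise — including the smooth ramp that a small
baseline-slope estimation error produces under extrapolation — is globally
linear and leaves residuals of the order of the noise. That ramp artifact is
why a naive rise/noise ratio is not used: extrapolating a slope error of
$\epsilon$ per cycle across 30 cycles manufactures an apparent rise of
$30\epsilon$ with a high log-linear $R^2$. On the calibration benchmark
(1,000 amplified curves at amplitude/noise ≥ 50 against 1,000 non-amplified
noise traces) the two classes sit above ~8 and below ~4.5 respectively, and
the logistic is centred at 6, the geometric middle of that gap. All inputs
are ratios of corrected-signal magnitudes, so the score is invariant to
positive rescaling of the fluorescence axis.

The Cq confidence multiplies a saturating function of the local rise at the
crossing (per cycle, in noise units) by the exponential-region $R^2$ raised
to the 0.25 power; it is 0 whenever no Cq was called, and non-increasing in
the noise level for fixed signal parameters. All calibration constants are
frozen in code; the separation benchmark (≥ 99% accuracy of the pass rule)
runs as an acceptance test, and the frozen constants achieve 99.7--99.9%
with no false positives across independent benchmark draws.

# Filtering

Filters apply in a fixed order — QC gating, then call rate, then median Cq —
because each one's denominator is defined by the previous stage. A cell
counts as a *reliable call* only when a Cq is present and the QC gate passed.
The call rate of a target is the percentage of samples with a reliable call,
with all samples loaded on the target's card as the denominator. The
non-human negative control never enters call-rate accounting; endogenous
control assays are retained and flagged. The conventional retention rule is
call rate ≥ 90%, and the cumulative call-rate table reports the
100/98/96/94/92/90% categories against the QC-passing total.

The median-Cq filter drops barely expressed targets: in fixed mode at the
conventional cutoff of 32 cycles, or in adaptive mode at the median of the
per-target medians — the adaptive cutoff exists because a fixed cycle cutoff
risks discarding low-expressed targets of genuine biological relevance.
Medians are computed over observed reliable Cq only; undetermined Cq is
always represented as missing, never as a sentinel value such as 40, because
sentinels corrupt every median and SD downstream.

# Reference stability

Candidates must be expressed in **all** samples (call rate 100%); violating
input is an error rather than a silent subset. Cq is already a log2-scale
quantity, so pairwise expression ratios are plain Cq differences. Cards are
independent experiments (separate retrotranscription, pre-amplification and
runs), so each card is ranked separately.

* **BestKeeper**: sample SD (n−1 denominator) and CV of each candidate's raw
  Cq. This follows the descriptive definition in common use; the original
  Excel tool's geometric-mean/MAD variant is deliberately not reproduced.
* **geNorm**: $M_j$ = mean over partners $k$ of the SD across samples of
  $Cq_j - Cq_k$. The classical stepwise-exclusion ranking (drop the worst,
  recompute, final pair tied) is available via `stepwise = TRUE`, but the
  raw-M ranking is what enters the comprehensive rank: the stepwise variant
  re-ranks under a shrinking candidate set, which makes ranks across methods
  incommensurable.
* **Comparative delta-Ct**: the same pairwise SDs, averaged without
  exclusion.
* **NormFinder**: model-based decomposition after centring each sample by its
  mean over candidates. Intragroup variances are estimated with the bias
  correction induced by the shared centring; the intergroup component is a
  candidate's deviation of group means. Because the deviations sum to zero
  across candidates by construction, regulation of *other* candidates leaks
  into every candidate's deviation; the package therefore re-centres the
  per-group deviations on a **precision-weighted median** of the candidates
  (weights inversely proportional to intragroup variance), anchoring the zero
  point to the most stable candidates while the median keeps a few genuinely
  regulated candidates from dragging the anchor. The stability value averages
  |intergroup deviation| + intragroup standard error over groups, and reduces
  to the intragroup-only variant with a single group. Group-aware mode is the
  default whenever group labels exist. The anchor has one knowable failure
  mode — a candidate with tiny variance *and* a genuine group effect could
  attract it — which is the usual price of anchoring and is why the
  group-stability check on the normalization factor exists as a companion
  diagnostic.
* **Comprehensive rank**: the geometric mean of the four 1-based per-method
  ranks (ties within a method get average ranks), final order ascending with
  ties broken lexicographically by target id.

On the simulated rank-recovery design each individual method and the
comprehensive rank place the designated stable target first in ≥ 99% of
replicates.

## Normalization factors

Two interchangeable normalizations are built: the top-ranked reference
target's raw Cq, or the per-sample geometric mean of all 100%-call-rate
targets on the card. The geometric mean controls extreme values and abundance
differences better than the arithmetic mean, and is undefined when any value
is zero or negative — such input is an error, never silently dropped. A
normalization factor should not differ between study groups; a two-sided
Wilcoxon rank-sum test per card flags it as unstable at p < 0.05 (fully tied
data carry no rank evidence and report p = 1). The Pearson correlation
between the top reference's raw Cq and the geometric-mean factor measures how
interchangeable the two strategies are; under a dominant per-sample global
abundance shift it exceeds 0.95.

# Relative expression

Per-sample $\Delta Cq$ subtracts the normalization value; samples with a
missing target Cq are excluded listwise, never imputed.
$\Delta\Delta Cq$ is the difference of group **means** of $\Delta Cq$ (the
conventional estimator; group medians are reported alongside for the
nonparametric reader, but means drive the fold change).
$RQ = 2^{-\Delta\Delta Cq}$, reported as $RQ$ when $RQ \ge 1$ and as the
negative inverse $-1/RQ$ otherwise, so a fold change never lies in (−1, 1)
and swapping case and control maps $x \mapsto -x$ for $|x| > 1$. Group
comparison uses the two-sided Wilcoxon rank-sum test, exact for small
tie-free samples and normal-approximated with tie correction otherwise; the
implementation is validated against full enumeration of the rank-sum null
for all group sizes up to 5 + 5.

## Comparing threshold algorithms

The three-method comparison is a fan-out, not a special mode: the pipeline
runs once per threshold method and the per-target Cq distributions are
compared with a Kruskal-Wallis rank-sum test followed by Dunn's post hoc
pairwise z statistics with tie correction. Holm is the default multiplicity
adjustment — the conventional reporting names the test but not the
correction, and Holm controls the family-wise error without independence
assumptions; it is configurable. Targets are flagged at Kruskal-Wallis
p < 0.01. Method agreement on the final results is summarised by Pearson
correlation matrices of the fold-change and p-value vectors over shared
targets. Supply the comparison with targets passing the quality filters
under every method (call rate ≥ 90%, median Cq ≤ 32): the wording of filter
cutoffs varies across reports, and this package consistently *retains*
call rate ≥ 90 and *excludes* median Cq > 32.

# Numerical and engineering choices

* Ties in `write_report()` row ordering break by identifier after rank, so
  two runs on identical input are byte-identical.
* Run manifests contain no timestamps; identical config + input + seed gives
  byte-identical outputs and manifests (asserted by test).
* Seeds are explicit arguments everywhere, RNG state is saved and restored
  around every draw, and no function depends on the global random state.
* Degenerate inputs fail loudly with the offending identifier in the
  message: zero samples, incomplete candidates in stability input, groups
  below minimum sizes, non-positive Cq in geometric means, thresholds ≤ 0.
* Percentages are on the 0--100 scale throughout.

# Problem sizes used by the validation suite

The shipped tests exercise the full stated designs: 1,000 noise-free random
logistics for Cq recovery; 100 curves × 6 affine maps for relative-threshold
invariance; 500 + 500 curves for QC separation; 50 random 8 × 20 matrices
against brute-force stability oracles; 100 replicates of the 20-target,
25 + 25-sample rank-recovery design; full rank-sum enumeration to 5 + 5; and
100 replicates of the 30-sample threshold-shift detection design. The whole
suite runs in well under a minute on a single core.

# Known limitations

* The automatic and relative Cq algorithms are open analogues; numerical
  agreement with any vendor's proprietary implementation is not claimed and
  not tested.
* QC calibration is performed on the i.i.d.-noise simulator; instrument
  noise with strong autocorrelation may shift the score distributions, and
  the cutoffs (1.0, 0.8) should be treated as conventions, not universal
  constants.
* The geometric-mean normalization is only defined on 100%-call-rate
  targets; cards with heavy missingness may leave no qualifying target, which
  is reported as an error rather than silently falling back.
* `2^-ddCq` assumes equal amplification efficiencies between target and
  reference; efficiency-corrected models are out of scope.
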