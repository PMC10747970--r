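---
title: "Method-comparison statistics for two-system gait measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Method-comparison statistics for two-system gait measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitagree)
library(dplyr)
```

## The problem

Wearable inertial systems are increasingly used to measure spatiotemporal
gait parameters — cadence (steps/min), gait-cycle duration (s), walking
speed (m/s), stance and swing phase (% of the gait cycle) and stride length
(m) — in populations where a trip to a motion-analysis laboratory is a
burden, such as people with progressive supranuclear palsy. Before a
wearable can replace the optoelectronic laboratory system it must be shown
to *agree* with it: not merely correlate, but return interchangeable
numbers. gaitagree implements the statistical pipeline used for such
validations: per-subject trial averaging, a normality-gated paired
comparison, Passing–Bablok regression, Bland–Altman analysis, and a
deterministic classification of systematic measurement error.

Throughout, the difference convention is fixed as
$d_i = \mathrm{reference}_i - \mathrm{test}_i$. The sign matters: a wearable
that *over*-reads produces a *negative* bias under this convention.

## Data model and averaging

Input is a long table of raw records: one row per
(subject, parameter, trial, side, system, value). Subjects typically walk
several trials and values exist for left and right sides; following common
practice all trials and sides are collapsed to one value per
(subject, parameter, system) by the arithmetic mean
(`average_trials()`). Unequal trial counts between the two systems are
accepted, since the two systems are often recorded in separate sessions.
Subjects observed under only one system are dropped for that parameter
(listwise deletion) with a warning; nothing is imputed. Averaging is
idempotent and invariant to trial order, and the pipeline needs at least
three complete pairs per parameter.

## Paired comparison with a normality gate

The first question is whether the systems differ *on average*. For each
parameter the differences $d_i$ are tested with the Shapiro–Wilk test; when
its p-value is at least $\alpha$ a two-tailed paired t-test is used,
otherwise a two-tailed Wilcoxon signed-rank test. Both delegate to the
standard R routines: Wilcoxon drops zero differences and uses the exact
null distribution for small tie-free samples, switching to the
continuity-corrected normal approximation otherwise, which reproduces the
behaviour of mainstream statistical packages at $n = 15$.

Normality is assessed on the *differences*, not on each arm separately,
because the paired tests' assumptions concern $d$. The gate is itself a
level-$\alpha$ test, so on Gaussian data the t-branch is chosen in about
$95\%$ of samples. When the two systems return literally identical values
the procedure degenerates; the result is flagged with the no-difference
convention (statistic 0, p-value 1).

No multiple-testing correction is applied across parameters: each
parameter's verdict is reported marginally, as is conventional in
method-comparison studies.

## Passing–Bablok regression

The structural relationship between the systems is estimated by
Passing–Bablok regression (Procedure I), which assumes only a linear
relationship and tolerates measurement error in *both* variables — the
reference system is not error-free. All pairwise slopes

$$S_{ij} = \frac{y_j - y_i}{x_j - x_i}, \qquad i < j$$

are computed; pairs with identical coordinates are skipped, ties in $x$
alone contribute signed infinities that participate in ordering but never
in averaging, and slopes exactly $-1$ are discarded. With $N$ retained
slopes and $K$ of them below $-1$, the slope estimate is the $K$-shifted
median of the sorted slopes — the shift is what makes the estimator
invariant when the axes are swapped ($m \mapsto 1/m$). The $1-\alpha$
confidence interval is rank-based: with
$C = z_{1-\alpha/2}\sqrt{n(n-1)(2n+5)/18}$,
$M_1 = \operatorname{round}\!\big((N - C)/2\big)$ (half away from zero) and
$M_2 = N - M_1 + 1$, the bounds are the $(M_1+K)$-th and $(M_2+K)$-th order
statistics. The intercept is $q = \operatorname{median}(y_i - m x_i)$, with
bounds obtained by plugging the opposite slope bounds in. Rounding $M_1$
half away from zero and using the normal (not small-sample) quantile are
deliberate choices matching mainstream method-comparison software, and are
documented here so results are bit-reproducible.

Three degenerate regimes are handled explicitly: fewer than three finite
slopes, an infinite central order statistic (both raise a degenerate-fit
error), and samples too small for the requested level, which raise a
CI-undefined error that still carries the point estimates.

### Linearity check

Passing–Bablok is only meaningful if the relationship is linear, so every
fit attaches a cusum check: residual signs are walked in order of
increasing reference value (ties broken by test value) and
$H = \max_j |{\textstyle\sum_{i \le j}} s_i| / \sqrt{L}$ is compared with
the Kolmogorov–Smirnov critical value ($1.36$ at $\alpha = 0.05$). Ordering
by the reference value is one of several conventions in circulation; it is
fixed here and stated so that results are reproducible. Residuals within
floating-point noise of zero ($10^{-8}$ relative) carry no sign, so exact
lines give $H = 0$. The check has limited power at small $n$: for convex
data the sign runs grow like $n/4$ while the critical value grows like
$\sqrt{n}$, so for example $y = x^2$ on $x = 1..20$ yields $H = 1.12$
(not flagged) but on $x = 1..40$ yields $H = 1.58$ (flagged). At $n = 15$
the check should be read as a coarse screen, not a powerful test.

## Bland–Altman analysis

Agreement in absolute terms is summarised by the Bland–Altman quantities:
bias $= \bar d$, the sample SD of the differences ($n-1$ denominator), the
limits of agreement $\bar d \pm 1.96\, s_d$ (the multiplier is
configurable), and a t-based bias confidence interval
$\bar d \pm t_{1-\alpha/2,\,n-1}\, s_d/\sqrt n$. Two structural identities
hold by construction and are enforced by tests: the limits are centred on
the bias, and the bias equals the difference of the per-system means.

The shape of the difference-vs-mean cloud is summarised by two diagnostics:
an ordinary-least-squares regression of $d$ on the pair means (a
significant slope indicates a proportional error visible as a linear trend)
and a Spearman rank correlation of $|d - \bar d|$ with the pair means (a
significant correlation indicates heteroscedasticity, the fan shape). Both
are reported as context; they do not enter the headline classification,
which relies on confidence intervals only.

The bias CI formula is a deliberate design choice: published validation
tables do not always state how their bias bounds were computed, and at
small $n$ different conventions differ visibly. For classification of
*published* tables the classifier therefore consumes whatever bias CI the
table prints (`classify_intervals()`), rather than recomputing one.

## Classifying systematic error

The verdict per parameter is a deterministic function of three intervals:

* **proportional systematic error** — the PB slope CI excludes 1;
* **constant systematic error** — the PB intercept CI excludes 0 **or**
  the BA bias CI excludes 0;
* **level** — `agreement` if no error fires; `very_close_agreement` if
  only a constant error fires (it could be removed by re-zeroing the test
  system); `no_agreement` whenever a proportional error fires.

The disjunctive constant-error rule is the unique simple rule consistent
with published validation tables in which, for different parameters, the
constant error is carried sometimes only by the intercept interval and
sometimes only by the bias interval. Endpoints exactly at 1 or 0 count as
containing, so boundary cases never fire, and interval *width* alone never
fires a flag — a wide but 0-covering intercept interval is reported as
context, not as an error. The paired-test p-value never affects the level:
a parameter can pass the mean-difference test yet disagree structurally,
and vice versa.

```{r verdicts}
classify_intervals(psp_gait_intervals()) |> select(parameter, level)
```

## The synthetic generator

Real validation data are rarely public, so the package ships a generator
whose defaults emulate a published PSP validation cohort: $n = 15$
subjects, four trials, per-parameter truth moments equal to the published
reference-system column of `psp_gait_moments()`. Per subject $s$ and
parameter $p$ the latent truth is
$T_{sp} \sim \mathcal N(\mu_p, \sigma_p^2)$ truncated to the tighter of
$\mu_p \pm 6\sigma_p$ and the physical range (positive values; phases in
$(0,100)$), and per trial

$$x = T_{sp} + \varepsilon_r, \qquad y = q_p + m_p T_{sp} + \varepsilon_t,$$

with Gaussian noise. The generative $m$ and $q$ are exactly the quantities
the Passing–Bablok stage estimates, so error injection is directly
testable: noiseless data give exact recovery, and a constant offset $q$
shifts the downstream bias by $-q$.

Choices worth stating:

* **Noise default 2% of the truth mean.** Small relative to the
  between-subject SDs, so PB recovers generative parameters tightly at
  $n = 15$; chosen once as a realistic instrument-noise scale.
* **Independence between parameters is the default.** The published
  reference moments are internally inconsistent with the kinematic
  identities (speed × cycle duration far exceeds the printed stride
  length, which likely follows a different definition), so the defaults
  take each parameter's moments verbatim rather than forcing consistency.
  An optional `consistent_kinematics` mode enforces, on the truth layer,
  swing $= 100 -$ stance, cycle $= 120/$cadence (two steps per stride) and
  speed $=$ stride/cycle, for users who want coherent profiles.
* **Heteroscedastic mode** scales noise SD linearly with the truth,
  producing the fan shape the BA diagnostics are meant to detect.

What the generator does *not* emulate: gait dynamics, within-session
learning or fatigue, side asymmetries, non-Gaussian outliers, or
device-specific event-detection artefacts. Passing the calibration checks
therefore demonstrates that the *statistics* are correct, not that any
particular instrument is valid.

## Calibration checks

Three simulation studies, run by `simulate_*()` and re-run from scratch by
`scripts/acceptance.R`, calibrate the pipeline:

* **Slope recovery** — 1000 replicates of $n = 15$ pairs with truth
  $\mathcal N(0.41, 0.10^2)$, noise SD $0.02$ on both axes and generative
  line $y = -0.06 + 2.10\,x$ (a stride-length-like strong proportional
  error): the mean PB slope estimate recovers 2.10.
* **Type-I error** — 5000 null replicates ($n = 15$, both systems the same
  truth plus independent noise): the gated paired-test stage rejects at
  the nominal 5%.
* **CI coverage** — 1000 replicates of $n = 50$ pairs, truth
  $\mathcal N(10, 2^2)$, noise SD $0.3$ on both axes, slope 1: the PB
  slope CI covers the generative slope about 95% of the time.

Replicate counts were fixed once at sizes that give Monte-Carlo standard
errors well inside the quantities' tolerances (about 0.004 for the slope
mean, 0.003 for the rejection rate, 0.7 points for coverage) while keeping
each study in the minutes range on one CPU.

One calibration property sits exactly on its boundary: with no injected
error, the probability that *none* of the three roughly-95% intervals
fires is about 0.90–0.92 (the intervals are positively correlated, which
helps), so roughly one synthetic null study in ten reports a spurious
systematic error. That is an honest property of interval-based error
classification at $n = 15$, and a caution against over-reading single
small-sample validation studies.

## Known limitations

* Rank-based PB intervals are asymptotic; below about $n = 10$ they are
  unreliable and below a threshold undefined (an explicit error).
* The cusum linearity screen is weak at $n = 15$ (see above).
* No confidence intervals on the limits of agreement themselves, and no
  repeated-measures Bland–Altman; trial averaging is assumed adequate.
* No equivalence margins: "agreement" means "no systematic error
  detected", which at small $n$ is not proof of interchangeability.
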