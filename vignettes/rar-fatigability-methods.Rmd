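---
title: "Methods: rest-activity rhythm profiling and fatigability association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rest-activity rhythm profiling and fatigability association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rarfatigue)
```

This vignette is the package's own account of its science: the models and
procedures it implements, the defaults it chose where the design was open,
and what its synthetic-data tests do and do not establish. It states no
empirical result that the test suite or the acceptance script does not
itself compute.

## 1. The measurement problem

Wrist accelerometry in older-adult cohorts yields minute-epoch activity
counts over roughly a week. Perceived physical fatigability — how tired a
person expects standardized tasks to make them — is measured with a 10-item
0–5 scale whose Physical score runs 0–50, with 15 the established cut point
for greater fatigability. The scientific question is which features of the
24-h rest–activity rhythm (RAR) — magnitude, shape, timing, variability,
singly or jointly — are associated with higher fatigability scores. This
package implements that analysis end to end, on real epoch data or on
synthetic cohorts with known ground truth.

## 2. Epoch data and cleaning

**Time semantics.** Timestamps are naive local clock time, stored as UTC
`POSIXct` so no daylight-saving arithmetic is ever applied; series with
repeated timestamps are refused, and gaps are errors rather than silently
resampled. The epoch width is carried as a field (`epoch_seconds`, default
60) and every downstream computation converts through it, so tests can run
on coarser epochs without touching any logic.

**Midnight truncation.** Recordings are cut to the half-open window from the
first local midnight to the midnight `truncate_days` later (default 5,
the literal first-to-sixth-midnight reading of the week protocol; the value
is configurable because protocols with more complete days exist). Shorter
series truncate to what is available with a warning.

**Non-wear.** An epoch is non-wear when it lies in a qualifying interval: at
least `window_min` = 90 minutes, zeros except interruptions totalling at
most `allowance_min` = 2 minutes, every interruption flanked by at least
`stream_min` = 30 minutes of consecutive zeros. Two readings required a
decision here:

* the allowance is *per candidate interval*, not per burst;
* qualifying intervals start and end on zero epochs, so interruptions are
  whole bursts strictly interior to the interval. Without this, an interval
  could co-opt the trailing two minutes of a genuine activity bout, and a
  plain 89-minute zero run flanked by activity would be (wrongly) flaggable.

Zero runs touching a series boundary satisfy the flanking requirement,
because device start/stop commonly truncates sleep-time zeros. The detector
is validated against a brute-force oracle that enumerates qualifying
intervals directly from the definition (1000 seeded random vectors).

**Validity.** A valid day has ≥ `valid_day_minutes` = 600 minutes (10 h) of
wear, boundary inclusive; participants need ≥ `min_valid_days` = 3 valid
days. Day validity gates *participants*; the cosine fit then uses all wear
epochs of eligible participants, while localized metrics drop invalid days
entirely. (The alternative — excluding invalid days from the fit too — is
defensible; we follow the participant-level reading of the eligibility
rule.) Non-wear epochs are excluded, never imputed: the model describes
observed activity only, and zero-filling would conflate non-wear with rest.

## 3. The antilogistic extended cosine model

On the `log(counts + 1)` scale (computed once and cached so all stages see
bit-identical inputs),

$$f(t;\theta) = m + \mathrm{amp}\cdot
\mathrm{expit}\!\left(\beta\left[\cos\!\big((t-\phi)\tfrac{2\pi}{24}\big)-\alpha\right]\right)$$

with minimum level $m$, amplitude $\mathrm{amp}\ge 0$, width
$\alpha\in(-1,1)$ (larger = narrower active period), steepness $\beta>0$
(large = square-wave), acrophase $\phi$ (hours, mod 24). The curve crosses
its mesor $m+\mathrm{amp}/2$ exactly where the cosine equals $\alpha$,
giving the rise time (up mesor) $\phi - \tfrac{24}{2\pi}\arccos\alpha$ and
settling time (down mesor) $\phi + \tfrac{24}{2\pi}\arccos\alpha$. Rhythm
robustness is summarized by the pseudo-F statistic
$\big((\mathrm{RSS}_0-\mathrm{RSS})/(p-1)\big)\big/\big(\mathrm{RSS}/(n-p)\big)$,
$p = 5$.

**Fitting.** Bounded L-BFGS-B on the residual sum of squares with analytic
gradients, at epoch midpoints, wear epochs only. Numerical choices:

* $\alpha \in [-0.999, 0.999]$; $\mathrm{amp} \ge 0$; $\phi$ unbounded then
  reduced mod 24.
* $\beta$ is optimized as $\log\beta$ with upper bound 1000: its sampling
  distribution is heavily right-tailed (cohort SDs exceeding the mean), and
  the log scale stabilizes the search. $\beta$ is weakly identified once the
  curve saturates, which is why recovery tolerances for $\beta$ are stated
  on the log scale.
* Warm start from the standard cosinor (linear cos/sin least squares), with
  $\alpha_0 = 0$, $\beta_0 = 2$; if the first start fails to converge,
  $\phi_0 \pm 3$ h restarts are tried and the best RSS kept. Every fit ends
  with one restart from its own optimum (fresh Hessian approximation),
  which takes noiseless recovery from ~1e-4 to ~1e-8.
* Fits require at least one full day (1440 minutes) of wear, converted
  through `epoch_seconds`.

**Scale ambiguity.** Published per-cohort summaries report the mesor in an
exponentiated form that is hard to reconcile with a log-scale amplitude
near 6; both `mesor_log` and `mesor_exp` are therefore emitted, and all
downstream stages (clustering included) use the log-scale value
consistently.

## 4. Localized metrics

Within half-open clock-time bins (default 4 h, epoch membership by
midpoint), the per-day mean of log activity over wear epochs is computed for
valid days; bins with no wear epochs are missing, not zero. Across days,
each bin reports the mean of the daily means and their sample SD
(n−1) — the time-specific variability of daily mean-level activity — with
pairwise deletion of missing (day, bin) cells and SD undefined for a single
contributing day. An optional sensitivity variant re-indexes each
participant's clock to "person time" ($t' = (t - \mathrm{up\ mesor})
\bmod 24$) before binning, which adjusts localized comparisons for
between-person rise-time differences; it refuses participants whose fit did
not converge. Note rise-aligned bin means are only comparable across
participants over whole aligned days; partial edge days introduce edge
effects (the test suite cuts them).

## 5. RAR profiles

The eight per-participant features — $\alpha$, $\beta$, acrophase,
amplitude, mesor (log scale), up mesor, down mesor, pseudo-F — are
z-scored (sample SD, zero-variance columns are an error) and clustered with
k-means: Lloyd iterations from k-means++-style seeded starts, 100 restarts,
best within-SS kept, empty clusters re-seeded from the farthest point,
deterministic given the seed. $\beta$ enters on its raw scale to match how
it is conventionally reported (a `log_beta` switch exists). `k = 4` is the
default; diagnostics (within-SS elbow curve, PCA eigenvalues and cumulative
variance, Ward-linkage merge heights, first-two-PC coordinates) are always
emitted so the choice stays inspectable.

The four profile names are assigned by a deterministic centroid-signature
rule (the original labels were assigned by inspection, so a reproducible
rule had to be chosen): "Later RAR" has the largest mean z of the timing
features (up mesor, acrophase, down mesor); among the rest,
"More Active/Robust" has the largest and "Less Active/Robust" the smallest
mean z of the magnitude/robustness features (amplitude, mesor, pseudo-F);
the remainder is "Earlier Risers". Ties break by cluster id. With
`k != 4`, labels are left empty with a warning.

## 6. Fatigability scoring and association

**PFS scoring.** Complete items are summed (0–50). The cited imputation
method for incomplete scales is not described in detail in the source
material, so the package implements the standard person-mean rule: with 1–3
missing items each is imputed with the mean of the respondent's completed
items and the rounded sum is returned; more missing yields a missing score
(`pfs.max_missing` configurable). Fatigability is `score >= 15`, boundary
inclusive.

**Median regression.** Conditional quantiles are estimated by exact
check-loss minimization: a Hunter–Lange majorize-minimize scheme
(iteratively reweighted least squares with a smoothing parameter annealed
from 1e-2 to 1e-8) followed by a vertex polish that interpolates the p
smallest-|residual| observations and keeps the interpolant if it lowers the
loss. On small instances this matches exhaustive vertex enumeration
exactly; an LP solver is deliberately not required. Inference is seeded
nonparametric case-resampling bootstrap (percentile CIs,
normal-approximation p-values): robust at modest n and fully reproducible.
Complete cases only, with the dropped count reported.

**Nested-model ("likelihood ratio") test.** For quantile models the LR-type
statistic is the scaled check-loss difference
$2(\hat V_{\mathrm{reduced}} - \hat V_{\mathrm{full}})\big/\big(\tau(1-\tau)s\big)$
referred to $\chi^2_q$, with sparsity $s = 1/f(F^{-1}(\tau))$ estimated by a
difference quotient of sample quantiles of the full-model residuals at the
Hall–Sheather bandwidth (level 0.05), after dropping the p numerically-zero
vertex residuals. Simulated size at n = 200 with integer-valued outcomes
falls inside [0.03, 0.08] at nominal 0.05 (acceptance criterion 8).

**Rank tests and odds.** Kruskal–Wallis (tie-corrected) across profiles and
all pairwise Wilcoxon rank-sum tests (normal approximation), unadjusted by
default to mirror conventional reporting, with a Holm switch. Logistic
regression (IRLS) gives the odds ratio of fatigability per unit of a
predictor with Wald CIs; complete separation is flagged and suppressed.
Cohen's d uses the (n−1)-weighted pooled SD.

## 7. The synthetic cohort generator

The generator is a stated world, fixed before testing:

* **Population parameters** per participant are independent truncated
  normals centered on the published cohort means: acrophase 14.8 ± 1.3 h,
  $\alpha$ −0.3 ± 0.3 (truncated to (−0.999, 0.999)), amplitude 5.9 ± 1.5
  (≥ 0.1), $m$ 0.5 ± 0.3, $\log\beta$ 3.1 ± 0.6 (so $\beta$ centers near 22
  with a heavy right tail). The amplitude SD is tightened from the
  published 2.8 (which mixes cohort heterogeneity the generator models
  elsewhere) to keep trough counts positive; this is a realism choice, not
  a tuning knob.
* **Counts**: latent log activity is $f(t;\theta)$ plus Gaussian noise
  (σ = 0.5 by default, optionally AR(1)); counts are
  $\max(0, \mathrm{round}(e^y - 1))$. σ = 0.5 is the canonical noise level
  used throughout the recovery criteria; real wrist data are noisier and
  less stationary, so green recovery tests establish correctness of the
  estimator, not field-performance guarantees.
* **Non-wear**: Poisson blocks per day, uniform 90–180 min lengths (long
  enough to be detectable by design), uniform placement; ground-truth masks
  are returned for detector scoring.
* **Outcomes**: the conditional median of PFS is linear in the *true* rise
  time (1.38 points/hour, echoing the published association), log mesor and
  a pseudo-F proxy (amp/σ), plus Gaussian noise, clipped to [0, 50] and
  rounded, then decomposed into 10 items (evenly, remainder on the first
  items — only the sum matters downstream). The outcome noise SD defaults
  to 1.5 points: a design-precision choice so that the stated
  ±0.25-at-n=200 recovery band has adequate power (asymptotic slope SE
  ≈ 0.10); observed cohort residual variability is several times larger,
  and with it the recovery band would be unattainable at n = 200 for any
  correct estimator.
* **Archetypes**: four parameter-mean vectors encode the qualitative
  profile signatures (dampened/steep/earlier-settling; average with early
  rise; high amplitude/mesor/robustness; late-shifted), with small
  within-archetype SDs so between-archetype separation exceeds 1.5 SD.
* **Covariates** use the cohort's reported marginals (age 71.3 ± 6.7, 79%
  female, 74% white, BMI 32.3 ± 6.0, CES-D 6.9 ± 5.9). They are drawn
  independently of the RAR parameters, so adjusted and unadjusted synthetic
  associations coincide in expectation — a limitation relative to real
  cohorts, where confounding is the point of adjustment.

Everything is reproducible bit-for-bit from one master seed, fanned out to
stages through a fixed affine map, so stages can be re-run in isolation.

## 8. Pipeline and artifacts

Stages run in the order truncate → log-transform → non-wear → validity →
cosine fits → localized metrics → clustering → association; each writes a
flat CSV/JSON artifact, the attrition log records participant counts at
every filter, and a manifest stores MD5 checksums. Reruns with the same
configuration and seed are byte-identical (numeric CSV columns are written
at 12 significant digits; the output directory path is excluded from the
serialized configuration so location does not break determinism). The
resolved configuration is serialized as JSON rather than YAML: no YAML
parser is available in the supported dependency set, and JSON is equally
diffable.

## 9. Known limitations

* Daylight-saving transitions are out of scope; the package works in naive
  clock time and refuses ambiguous series.
* The pseudo-F summarizes global rhythm robustness but not *when*
  variability occurs; residual spectral methods are future work.
* Beta is weakly identified at high values; interpret it jointly with the
  other parameters (its association tests are reported per raw unit, where
  effects are numerically tiny).
* The profile-label rule is a reproducible stand-in for by-eye labelling;
  with unusual centroid configurations the names may be assigned to
  clusters a human would label differently, though the assignment is always
  deterministic and inspectable.
* Synthetic cohorts draw covariates independently of rhythm parameters and
  do not model weekday/weekend structure, sleep architecture, or device
  noise physics.
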