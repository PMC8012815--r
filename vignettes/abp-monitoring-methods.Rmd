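---
title: "Methods: adaptive passport limits, CO-rebreathing volumes and training-load confounding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive passport limits, CO-rebreathing volumes and training-load confounding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abpmonitor)
```

`abpmonitor` studies a confounding problem at the heart of hematological
anti-doping monitoring: hemoglobin *concentration* — a primary passport
marker — is the ratio of a slow quantity (total hemoglobin mass, Hbmass)
to a fast one (blood volume, dominated by plasma volume, PV). Training
load moves PV within days, so an athlete's passport can drift toward its
individual limits for entirely physiological reasons. This vignette
documents the models, the tunable parameters, the synthetic-data
generator, and the numerical and design choices, in that order.

## The adaptive model for individual limits

For each marker we assume a two-level normal model in transformed units:
athlete level $\theta \sim N(\mu_0, \tau^2)$ between subjects, and
observations $x_i \mid \theta \sim N(\theta, \sigma^2)$ within. Both
variance components are treated as known configuration values. The
posterior after $n$ values with sum $S$ has precision
$p = 1/\tau^2 + n/\sigma^2$ and mean
$m = (\mu_0/\tau^2 + S/\sigma^2)/p$, and the *predictive* distribution
of the next value is $N(m, \sigma^2 + 1/p)$. The individual limits are
the central interval of this predictive distribution at the single-value
specificity (99% by default, $z = 2.576$); for $n = 0$ they reduce to
the population band $\mu_0 \pm z\sqrt{\tau^2+\sigma^2}$, and as
$n \to \infty$ they tighten monotonically to $m \pm z\sigma$. Each new
value is judged against the limits computed *before* it is incorporated,
and a tie (value exactly on a limit) is resolved in the athlete's
favor — only strict exceedance flags.

This conjugate recursion is a deliberate, documented approximation of
operational passport software, which we treat as out of scope: the
operational model's exact sequence statistic and its level-dependent
within-subject variance are not public. Here $\sigma$ is constant per
marker, (Hb) and OFF-score use the identity transform, and Ret% — a
right-skewed, strictly positive marker — uses the log transform, which
also guarantees positive limits in natural units.

Because the predictive interval is exact under the model, the
single-value rule is *calibrated by construction*: simulating athletes
from the same two-level model yields a per-sample flag rate of
$1 -$ specificity. The test suite verifies ~1% empirically over 1,000
athletes × 12 samples, and `scripts/acceptance.R` recomputes it at any
seed.

**The sequence rule is not calibrated.** The 2–5-sample sequence finding
multiplies the per-sample one-sided predictive tail probabilities on the
common most-extreme side and fires when the product falls below
$10^{-3}$. Sequential predictive tail probabilities are independent
uniforms under the model, and a product of $k$ uniforms falls below
$a$ with probability $a\sum_{j<k}(\ln 1/a)^j/j!$ — about 18% for
$k = 5$ at $a = 10^{-3}$. The rule therefore flags clean sequences far
more often than $0.1\%$; it is kept in this form as a simple,
transparent joint-deviation screen, all calibration claims in this
package attach to the single-value rule only, and the summary tables
report the two flag types separately. A calibrated alternative
(thresholding at the null quantile of the product) would change the
advertised contract and is left as future work.

Default priors (`default_marker_params()`: male (Hb) μ₀ = 14.6 g/dL,
τ = 0.9, σ = 0.45; OFF-score 90/12/8; log-Ret% log(1.1)/0.25/0.15) are
plausible for a male endurance cohort but carry no ground-truth claim:
every calibration and recovery property holds for any valid parameter
set, and `estimate_marker_params()` fits moment-based priors to a
cohort when population values are not available.

## CO-rebreathing mass and volumes

The mole balance is exact arithmetic: absorbed CO volume (administered
bolus minus the unabsorbed remainder, measured in the circuit) is
converted to moles by the ideal gas law at ambient pressure and
temperature, divided by the four CO binding sites per hemoglobin
molecule, scaled by $100/\Delta HbCO$ (dilution principle, with
$\Delta HbCO$ the rise of the triplicate-mean carboxyhemoglobin
percentage), and multiplied by the hemoglobin molar mass
$6.44\times10^4$ g/mol. The inverse map is used by the generator, and a
round-trip test demands $10^{-9}$ relative recovery. $\Delta HbCO$
below 2 percentage points triggers a precision warning rather than an
error. The volume partition uses the hemoglobin-dilution identity with
a configurable body/venous hematocrit factor `f_cell` (default 0.91 for
real venous data); the stated instrument errors (0.1 mL on the CO
meter, HbCO% analyzer noise) feed a first-order uncertainty report and
never correct the point estimate.

## Training load

Normalized power uses the standard 30-s trailing-average fourth-power
algorithm at 1 Hz (recording gaps are zero-filled before calling —
coasting convention); TSS is duration × squared relative intensity,
100 per hour at threshold; FTP is 95% of a 20-min maximal effort and is
held fixed per athlete for the whole analysis. Load windows are
half-open calendar windows ending the day *before* the blood sample:
exercise is barred in the hours before a collection, and a partial
sampling day would bias the load; sessions belong to windows by start
date only. ATL and CTL are reported both cumulated and as daily means;
the covariate analyses default to the cumulated form. High/low periods
slide an 84-day window day by day with earliest-start tie-breaking;
only complete windows count. Hypoxic dose is mean altitude (km) ×
exposure hours, additive over any partition of the exposure blocks;
progressive protocols contribute their midpoint altitude (linear ramp).

## The synthetic cohort generator

The generator emulates the structure of a one-year elite-cyclist
monitoring study: 10 athletes, 12 samples at 32 ± 12-day intervals
(floor 14), athlete baselines Hbmass ~ N(1030 g, 87²) and
PV ~ N(4300 mL, 350²), cellular MCHC 34 g/dL, analyzer noise 0.1 g/dL
(Hb) and 0.05 (Ret%), CO-rebreathing measurements over the trailing 8
occasions, and hypoxic-exposure presets reproducing two canonical
cases (27 d × 24 h at 2,750 m, dose 1,782 km·h; 36 × 9 h at
2,500→3,500 m, dose 972 km·h) with a lagged Ret% response and a slow,
delayed Hbmass gain (3 × 10⁻⁵ fractional gain per km·h).

Hemoglobin concentration is never simulated directly. At every sampling
date the generator enforces the physiological closure
$$PV + RCV = BV, \qquad RCV = \frac{Hbmass}{MCHC}\cdot 100, \qquad
[Hb] = \frac{Hbmass}{BV/100},$$
with $PV(t) = PV_0 + b\,(ATL(t) - \overline{ATL}) + season(t) +
\varepsilon$, $b = 2.2$ mL per a.u., a 150-mL seasonal wave peaking in
mid-summer, and 150 mL of day-to-day biological noise (~3%). The
negative association between acute load and (Hb) is thus an *emergent*
consequence of the PV response; its implied value is the average
marginal effect $\mathrm{mean}(-[Hb]\cdot b/BV_{mL}) \approx -0.004$
g/dL per a.u. (`closure_slope()`), which the mixed model recovers
(95% CI covering the truth in ≥ 90% of 100 seeded 50-athlete
replicates — the problem size all recovery tests use). The PV response
acts on the *deviation* of ATL from the athlete's habitual load so that
$PV_0$ retains its meaning as the athlete's characteristic volume.

The training schedule alternates 6-week high/low blocks
(athlete-specific random phase) with gamma daily TSS (means 95/72 a.u.,
shape 16, 12% rest days) and a per-athlete volume factor (SD 0.3) that
spreads habitual load and annual totals across the cohort. The
schedule is deliberately *steadier* than a literal reading of published
per-athlete load dispersions: published within-athlete 5-day-load
spreads, combined with the 2.2 mL/a.u. PV response, would imply PV and
(Hb) swings larger than the same sources' own within-athlete SDs — the
printed moments are mutually inconsistent — so the generator
prioritizes the effect sizes (the two slopes and the PV%-vs-Hb%
correlation) and lets the load dispersion absorb the tension. The
CO-rebreathing visit is scheduled 0–5 days after the blood sample
(monthly-monitoring logistics), and PV is re-evaluated at the visit
date: this partial decoupling, not a tuned correlation parameter, is
what brings the consecutive-percent-variation correlation between
measured PV and (Hb) to the study scale (≈ −0.3 to −0.65 across seeds,
mean near −0.46).

What passing tests on this generator do *not* show: real passports face
level-dependent analytical variance, pre-analytic drift, illness and
iron status, menstrual-cycle variation, true erythropoietic doping
kinetics, and operational ABP software whose sequence statistic and
variance model differ from the ones here. The generator's role is to
make every pipeline stage testable against a known truth, not to claim
physiological completeness.

## Statistical engine and numerical choices

Mixed models are fitted by REML with `nlme::lme` (random athlete
intercept); F tests use residual denominator degrees of freedom by
default, with a Satterthwaite option through `lmerTest`. Degenerate
inputs with zero residual variance (all values identical; noise-free
occasion shifts; exactly linear covariate relations) are not fittable
by REML, so the functions fall back to a fixed-effects
`lm(value ~ athlete + x)` F test — identical for the tested effect
under balance — and fully constant data report F = 0, p = 1. Percent
variations use the previous sample as baseline by default (the
athlete's first sample is available as an option); the direction
convention for summary-table changes is summer→winter and
high→low-load, rounded to one decimal in rendered tables only.
Bonferroni adjustment and the Pearson correlation delegate to
`stats::p.adjust` and `stats::cor.test`. Replicate-agreement and limit
comparisons use a 10⁻⁹ epsilon so that decimal analyzer readings on a
tolerance boundary pass.

## Known limitations

The sequence-ATPF statistic is anticonservative (see above). Constant
within-subject variance understates flagging uncertainty for markers
whose analytical error grows with level. The volume partition assumes a
single `f_cell`; the generator does not simulate the body/venous
hematocrit distinction (`f_cell = 1` there) and its emitted
concentrations therefore close exactly, which real venous samples do
not. FTP is static by design; long studies with true fitness drift
would misattribute load. None of the numerical results in this
document are asserted here: every number is computed by the test suite
or by `scripts/acceptance.R` at run time.
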