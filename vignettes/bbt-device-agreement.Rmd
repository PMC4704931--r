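---
title: "Methods: simulating and comparing basal-temperature measurement devices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and comparing basal-temperature measurement devices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbtagree)
```

## The problem

Basal body temperature (BBT) — the waking temperature before any activity —
rises by roughly 0.2–0.5 °C shortly after ovulation and stays elevated until
the next menses. A BBT chart is therefore *biphasic* in an ovulatory cycle:
a cooler follicular plateau, often a one-day *nadir*, then a sustained
luteal elevation. Classifying charts as ovulatory, anovulatory or
inconclusive is a long-standing clinical and research practice, done either
visually or quantitatively against the cycle mean.

A skin-temperature armband worn overnight promises the same information
without a morning measurement ritual. But skin temperature is systematically
cooler than core, more variable, affected by bedding and room temperature,
and the sensor needs time to equilibrate after going on-body. This package
provides (i) a generator for realistic synthetic cohorts with known ground
truth, (ii) the reduction from minute streams to daily pre-waking basal
values, (iii) both chart classifications, and (iv) the agreement statistics
that quantify whether the two measurement routes are interchangeable.
Because the original study cohort was never deposited, the synthetic cohort
is the package's test bed: every empirical claim below is recomputed by the
test suite or the acceptance script, not quoted.

## The synthetic cohort

`generate_cycle()` builds the daily oral series from `cycle_params()`:

* **Geometry.** An ovulatory cycle of length $L$ with luteal length $\ell$
  ovulates on day $L - \ell$; that day dips `nadir_depth` below the
  follicular baseline and days $L-\ell+1, \dots, L$ sit `shift_magnitude`
  above it. An anovulatory cycle (including the OCP-user controls) is flat.
  Noise-free cycles realise this geometry *exactly*, which the unit tests
  exploit as constructed oracles.
* **Nuisance processes.** Gaussian daily measurement noise (default SD
  0.2 °C — large enough that visual chart reading is genuinely hard, as it
  is in practice); per-day missingness (default 0.1, mirroring imperfect
  compliance); fever days elevated by 0.8 °C and flagged as illness (the
  magnitude is a package choice; illness was recorded but not quantified in
  the motivating study).
* **Defaults as study conditions.** Cohorts default to 15 participants, a
  fifth of them anovulatory controls, ovulation probability 0.8 among the
  rest, cycle lengths 26–32 d, luteal lengths 12–16 d, shifts uniform on
  0.2–0.5 °C. The follicular baseline (36.29 °C, between-participant SD
  0.12) is set *analytically* so that the expected cycle-wide oral mean is
  36.4 °C under this mix — the oral-device summary the comparison is
  calibrated to.

`generate_overnight_stream()` turns a night's true temperature $T$ into a
minute stream via `device_model()`:

$$\text{level} = T + b - s\,(T - T_{\mathrm{ref}}) + u_{\text{night}} + u_{\text{participant}}$$

* **Affine device bias.** $b = -1.8$ °C at the reference $T_{\mathrm{ref}} =
  36.4$ °C; the proportional-bias slope $s$ is the change in the
  oral-minus-armband difference per °C of true temperature. Its default,
  $-0.15$, makes the difference *larger on cooler nights*, the pattern a
  downward-sloping Bland–Altman cloud shows.
* **Night-level variance.** $u_{\text{night}} \sim N(0, 1.1^2)$ is shared by
  every minute of a night. This component is essential: minute noise (SD
  0.15) averages away in a 60-minute pre-waking mean, so only a night-level
  term can give armband daily values their observed dispersion (SD ≈ 1.2 °C)
  — physically it stands for room temperature, bedding and wear position.
  A per-participant placement offset (SD 0.2) adds the rest.
* **Stabilization.** The first 30 minutes ramp linearly from 2 °C below the
  level — a sensor warming against skin takes well over 20 minutes to
  stabilise, which is why pre-waking windows at the *end* of an 8-hour wear
  episode are the right reduction. The ramp shape is a package choice; only
  its insufficiency at 20 minutes is documented behaviour.
* **Clipping.** Readings are clipped to the device's recording limits
  (29.7–36.7 °C by default).
* **Wear behaviour.** Wake time is 07:00 jittered uniformly ±60 minutes
  (irregular wakening is documented, its distribution is not; uniform is the
  least-informative bounded choice). Whether the band is worn each night is
  sampled with the same probability as oral missingness, independently. A
  forgotten night is off-body throughout and yields no basal value.

**What the generator does *not* emulate** — and hence what passing tests do
not demonstrate about real data: circadian temperature structure beyond the
onset ramp (minute noise is iid, so the five pre-waking interval means are
almost perfectly correlated with each other, noticeably higher than the
0.76–0.97 a real device shows); environmental confounders as *covariates*
(they are folded into one Gaussian night effect); physiological OCP
temperature profiles (controls are simply flat); and any dependence between
compliance and cycle phase.

## Reducing streams to basal values

The waking time of a night is the timestamp of the last on-body minute —
under the protocol the band comes off immediately on waking. An explicit
`wake_time` field is honoured when supplied, since vendor software may
estimate waking differently; multiple wear episodes in one night resolve to
the final episode with a warning. `prewaking_mean()` averages on-body
minutes over the half-open window $[\mathrm{wake} - k, \mathrm{wake})$ for
$k \in \{10, 30, 60, 90, 120\}$ — half-open because the waking minute itself
is no longer basal. A window under 50 % on-body coverage returns `NA`
rather than an average of thin data (the handling of partial wear is a
package choice).

## Classification rules

`classify_visual()` applies, in order:

1. **Completeness.** Fewer than 17 observed temperatures, or more than 20 %
   of days missing, is inconclusive — too little chart to read. (The
   17-day floor mirrors the minimal protocol completion that made a
   participant analyzable.)
2. **Anchor.** The expected ovulation day is `cycle_length − 13`, the day
   leaving exactly 14 days to the cycle end; without an observed next
   menses the search window cannot be anchored and the call is
   inconclusive. The search window is ±4 days around the anchor (the width
   is a package choice).
3. **Biphasic shift.** The first window day $d$ whose temperatures on $d$,
   $d{+}1$, $d{+}2$ all exceed the six-day coverline by more than 0.2 °C
   (strict; an exact 0.2 °C shift does not qualify). The coverline is the
   *mean* of the six preceding observed temperatures. The mean was chosen
   over the maximum deliberately: a coverline pegged to the maximum is
   dragged upward by a single noisy follicular spike, and under it the
   package's own recovery requirement — ≥95 % of ovulatory cycles recovered
   at noise SD ≤ 0.05 °C and shift ≥ 0.3 °C — is unattainable (measured
   ≈ 46 % at the boundary), whereas the mean coverline satisfies it with
   margin. Fever days are excluded from all criterion arithmetic. If *no*
   candidate day has six observed predecessors and a complete three-day
   plateau, the criterion is undetermined (inconclusive), never silently
   negative.
4. **Thermal-shift adequacy.** Sustained ≥ 11 days through the cycle end;
   plateau begins within 2 days of the last observed pre-shift day; no
   luteal temperature at or below the pre-shift *maximum* of the six
   reference days (a "deep fall" — here the maximum is the right reference,
   because a luteal value below even the warmest pre-shift day genuinely
   breaks the biphasic reading). More than two missing luteal days leave it
   undetermined.
5. The **nadir** (coolest of the three days before the shift, strictly
   below the six-day reference mean) is recorded as supportive evidence
   only; it can never force an anovulatory call.

`classify_mtm()` is the quantitative counterpart: the cycle mean $\bar m$ of
all observed non-fever temperatures is the threshold; ovulatory iff some day
$d$ starts three consecutive days above $\bar m$ with at least 11 days from
$d$ to the cycle end above $\bar m$ and none more than 0.1 °C below it. The
0.1 °C tolerance absorbs single-day noise dips in an otherwise elevated
luteal phase; the historical mean-temperature method is cited in the
literature more often than it is specified, so this concrete rule is the
package's documented stand-in.

`adjudicate_majority()` reproduces the observer protocol: two concordant
raters decide; two discordant raters escalate to a third; three raters
decide by mode, a three-way tie resolving to inconclusive.

## Agreement statistics

Spearman's rank correlation (average ranks for ties, two-sided asymptotic
p, listwise deletion) comes from `stats::cor.test`. Bland–Altman analysis
uses differences against pair means, 1.96·SD limits of agreement, and a
least-squares slope of difference on mean for proportional bias. Cohen's
kappa is unweighted — the three categories are nominal — and per-category
agreement is defined as that category's concordant count over *all* pairs,
the convention under which the three per-category percentages sum exactly
to the overall percentage. When both raters assign a single identical
category throughout, expected agreement is 1 and kappa is undefined; this
is signalled as `NA`, deliberately distinct from κ = 0 (which means
"agreement at chance", not "agreement unmeasurable").

## Numerical choices

* Strict temperature comparisons carry a 10⁻⁶ °C guard so that constructed
  boundary cases (a shift of exactly 0.2 °C; a flat series at its own mean)
  behave identically in floating point and on paper.
* Tie-breaks: the *first* qualifying day is the shift day, for both
  classifiers; the nadir takes the minimum over its three-day window.
* Temperatures are stored at full precision; CSV round-trips are lossless
  to numeric tolerance, and regenerating a cohort from the same seed is
  byte-identical on disk.
* All randomness flows from a single integer seed per cohort; individual
  generators also accept their own seed for isolated use.

## Problem sizes

The shipped analyses and checks run at the scale the design calls for: the
pipeline and calibration checks use the default 15-participant cohort
(~450 participant-days, ~190 000 stream minutes); parameter-recovery
properties use 500 ovulatory plus 500 flat cycles in the low-noise regime
(noise SD 0.05, shift uniform on 0.3–0.5 °C, the generator's shift range
restricted to the regime's floor); oracle-equivalence sweeps use 1 000
random contingency tables and 200 random cycles. Ground-truth-only cohort
properties (e.g. binomial behaviour of the ovulatory fraction) run at 1 000
participants with stream generation disabled.

## Known limitations

* The armband's inter-interval correlations are near 1 by construction (no
  within-night autocorrelated drift), overstating the internal consistency
  a real device would show across the five windows.
* The visual classifier is a single deterministic reader; it emulates the
  *criteria* human observers apply, not inter-observer variability, so
  rater-adjudication paths are exercised only with externally supplied
  calls.
* The mean-temperature rule is a documented reconstruction, and results
  that depend on its exact tolerance should be read as such.
* Exclusion uses only the observed-day count; a real study may exclude for
  protocol violations the generator does not model.
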