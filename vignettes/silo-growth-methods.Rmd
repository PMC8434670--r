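---
title: "Methods: from silo level readings to pig growth distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from silo level readings to pig growth distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silogrowth)
```

## The measurement problem

A fattening batch (500–900 pigs, 17–20 weeks) eats from a silo monitored by
a one-point time-of-flight level sensor that reports, every two hours, the
fraction of the usable silo volume still occupied. Three physical facts
shape everything downstream:

* the sensor measures **volume**, but feed is bought, declared and consumed
  by **weight**, and density differs between truckloads (we default to
  640 kg/m³, with per-load values typically 600–680 kg/m³);
* feed discharge leaves an uneven surface, so consecutive readings
  fluctuate instead of decreasing monotonically;
* refills appear as large upward jumps that must never be smoothed over or
  counted as negative consumption.

The pipeline therefore works on *segments* — maximal spans between refills
— and treats the refills themselves as calibration events: when the farmer
declares the weight of a load, the observed volume jump yields that load's
density.

## Models

**Accumulated feed intake (AFI).** The theoretical cumulative intake of an
animal of age $a$ weeks is logistic,

$$\mathrm{AFI}(a) = \frac{A_f}{1 + e^{-b_f a}},$$

with $A_f$ the asymptotic lifetime intake (kg) and $b_f$ (1/weeks) a fitted
rate. For a subgroup entering at age $a_0$, the on-farm cumulative intake
at the end of week $t$ is $\mathrm{AFI}(a_0 + t + 1) - \mathrm{AFI}(a_0)$,
which starts at zero at entry and is directly comparable with what the
sensor measures. Note a structural property of this curve: its inflection
sits at age zero, so over the fattening range the *weekly* theoretical
intake declines slowly; the parameters are farm- and breed-specific fits
over exactly that range, not a mechanistic feeding model. A conventional
linear cross-check $\mathrm{ADG} \times \mathrm{FCR} \times 7t$ (average
daily gain times feed conversion rate) is reported alongside.

**Growth.** Average body weight follows a Gompertz curve in cumulative
intake, not in time:

$$\mathrm{AW} = A\,e^{-e^{\,b - k\,\mathrm{AFI}}},$$

with $A$ the asymptotic adult weight (kg), $b$ a dimensionless offset that
sets the entry weight ($\mathrm{AW}(0) = A e^{-e^b}$), and $k$ (1/kg) a
rate per kilogram of feed. Driving growth by intake is what lets a feeding
anomaly propagate into a visible weight deviation.

**Spread.** Weight variation between pigs grows as they grow; we model the
subgroup variance (kg²) as a cubic polynomial in weeks since that
subgroup's entry, validated positive over the whole horizon at
configuration load. Week-since-entry is used as the polynomial's argument
because it is the same monotone clock used everywhere else; coefficients
are user-supplied with no defaults. Each entry subgroup contributes a
normal component $N(\mathrm{AW}_i, \sigma_i^2)$ weighted by its head count;
the batch distribution is the mixture, binned into half-open 5-kg ranges
whose expected counts use the normal CDF directly. Bins cover every mean
±4 standard deviations of the widest component, so the unbinned tail is
below $10^{-4}$ of the head count. Components are not truncated at 0 kg;
the (negligible) sub-zero tail mass is reported in the summary rather than
redistributed.

## Pipeline numerics

**Refill detection.** The spec-level detector is exact and simple: every
maximal run of consecutive increases of occupied volume whose cumulative
gain reaches the threshold (default 1 m³) is one refill, stamped at the
run's first reading. Raw-threshold detection is, however, fragile under
realistic reading noise (1% of capacity ≈ 0.2 m³ per reading), which fakes
short increase runs. The orchestrator therefore runs the detector on a
centered-moving-average copy of the volume series (same window as the
cleaner, default 13 readings ≈ one day), where spurious runs are
statistically impossible while a 6,000-kg load still towers over the
threshold, and then locates the raw jump step inside each detected run.

**Jump refinement.** The volume just before and just after a refill sets
both the load's density and the segment's consumption bookkeeping, so the
two raw readings bracketing the jump are replaced by local least-squares
fits over up to three days on each side. Within a day the series is linear
(consumption is steady over hours); day-to-day the drain rate drifts.
The local model is therefore piecewise linear with knots at UTC midnights,
*model-selected* against a plain line by an F-test at the 1% level: on
noise-free data the kinks are identified exactly (the fit interpolates),
while under noise the kink coefficients are indistinguishable from noise
and the plain line — with roughly half the prediction variance — is used.
Both sides are evaluated at the jump-interval midpoint; their difference is
the refined volume delta.

**Density bookkeeping.** A declared load weight divided by the refined
delta gives the load density; without a declaration the default density is
used. The post-refill segment density is the blended contents' mass over
the observed post-refill volume — operationally the mass-weighted blend of
the remaining contents and the load, expressed through the observed
volumes, which makes the chain self-consistent: on a noise-free trace the
entire density chain, and hence the weight series, is recovered exactly.
Re-running the pipeline recomputes the whole series with the current
density chain, so late declarations simply take effect on the next run.

**Cleaning.** Within each segment, independently: short gaps (≤ 6 missing
readings, i.e. 12 h) are linearly interpolated on time; a centered moving
average of width 13 is applied with the window truncated symmetrically at
segment edges; monotonicity is enforced by antitonic pool-adjacent
violators (via `stats::isoreg` on the negated series). PAV is preferred to
clipping because it is the least-squares projection onto the monotone cone
and preserves segment totals' interpretation. The two readings adjacent to
each refill jump, and the first and last readings of the series, are
anchored at the local regression fits: the edge-truncated moving average
barely smooths an endpoint, yet endpoints determine every segment's
consumption total — the anchors average noise over the whole fit window
and equal the raw readings on noise-free data. Segments with fewer than
two readings pass through untouched with a warning.

**Consumption and attribution.** Within a segment, consumption between
consecutive readings is the weight decrease; across a refill boundary it is
$\max(0,\; \mathrm{pre} - (\mathrm{post} - \mathrm{load}))$, floored at
zero with a warning when sensor error exceeds true consumption. Each
interval's consumption is prorated uniformly over the time it spans when
aggregating into calendar days (exact when intake is steady within a day);
an interval longer than the interpolation gap limit is assigned to the day
the gap ends. Weeks are 0-based half-open blocks $[7t, 7t+7)$ of days since
the batch start (the earliest entry date); entries and departures take
effect at the start of their day. Timestamps are UTC throughout — a
2-hourly series must not wobble with daylight-saving time.

**Deviation and alerts.** The deviation series compares weekly *increments*
of sensor-based and theoretical per-animal intake,
$(s_t - \theta_t)/\theta_t$ (0/0 defined as 0); an underfeeding episode
then registers at its true magnitude within a week, whereas the cumulative
ratio would dilute a 20% intake drop at week 8 of 18 to under 10% forever.
The cumulative comparison remains available (`cumulative = TRUE`).
A growth alert fires at the first week of every run of at least 2
consecutive weeks (configurable) with $|$deviation$| > \tau$ (default
0.10); if any refill inside the deviating span lacks its declared weight,
the alert is *replaced* by a data-verification alert — data accuracy is
checked before the animals are blamed, and suppression (rather than
emitting both) keeps one actionable message per span. A missing-data alert
fires for any week with more than 25% of readings missing. Alert
evaluation is pure and idempotent; delivery goes through an injected
notifier (default: structured log), with per-alert failure reporting.

**Subgroup attribution.** One silo cannot attribute intake to entry
subgroups, so the sensor-based subgroup AFI is the per-animal batch intake
accumulated since the subgroup's entry week; the theoretical variant uses
each subgroup's own age offset. Departures are attributed to subgroups in
proportion to their current size (the records do not say which entry a
removed truckload belonged to), which leaves fractional expected head
counts — appropriate, since the distribution is itself an expectation.

## The simulator

`simulate_scenario()` is the package's digital twin and the source of all
test fixtures. Defaults are the study conditions: 600 pigs entering at 10
weeks of age and 30 kg, 18 weeks on farm, a 20 m³ (12,800 kg) linear silo
starting 90% full, 6,000-kg truckloads ordered at 20% fill with densities
drawn uniformly from 600–680 kg/m³, readings every 2 h with Gaussian level
noise (sd 1% of capacity) and 5% missing readings, departures of 100
animals per week once the average weight crosses 110 kg. Growth parameters
($A_f = 1100$, $b_f = 0.065$, $A = 230$, $b = 0.7115$, $k = 0.00481$,
variance $9 + 2t + 0.35t^2$) were chosen once to give a realistic
fattening trajectory — 30 → 115 kg on ~224 kg of feed, 1.3–2.3 kg/day —
and are exposed, not hard-coded. Mass balance is exact by construction
before noise; intake is uniform within each day; trucks deliver at
reading-interval midpoints during working hours (09:00–17:00), as real
deliveries do. A single seeded RNG stream draws, in order: per-load
densities during the silo pass, then the noise vector, then the missingness
vector — identical seeds give bit-identical scenarios.

What the twin does *not* emulate: feed bridging or rat-holing in the cone,
laser-spot geometry, surface unevenness beyond white noise (real
fluctuations are autocorrelated), diurnal feeding rhythms, weighing errors
in declared loads, and intake attribution differences between subgroups
sharing a feeder. Passing recovery tests on the twin therefore shows the
pipeline inverts its own observation model under realistic noise levels —
not that every farm series will behave.

## Verified accuracy at the default conditions

The acceptance suite (also re-runnable via `scripts/acceptance.R`)
establishes, at the default scenario sizes (1,513 readings, 18 weeks, ~21
refills; Monte-Carlo sweeps over 20 seeds):

* noise-free traces invert exactly: total consumption to < 10⁻⁶ kg, weekly
  AFI and subgroup AW to ≤ 0.1% at every week;
* with 1%-of-capacity noise: total consumption within 0.5% per seed,
  per-load density to ~1% mean absolute error, weekly AFI within 2%
  (Monte-Carlo mean per week; typical ~0.6%);
* bin counts conserve the living head count to 10⁻⁴ relative every week;
* a 20% underfeeding injected at week 8 yields exactly one growth alert at
  week 8; the anomaly-free twin yields none; withholding one declared
  refill weight in the span converts the alert to data verification;
* byte-identical outputs for identical seeds.

## Limitations

* The logistic AFI form cannot represent intake that accelerates with age;
  parameters are only valid over the fitted fattening window.
* Gompertz and variance parameters are taken as given; the package does not
  fit them from historical batches.
* Per-load density is identifiable only when the load weight is declared;
  an undeclared load silently inherits the default density, biasing that
  segment's weights by up to the true density's deviation from the default
  (the data-verification alert exists precisely for this case).
* Alert thresholds are heuristics (τ = 0.10 over 2 weeks by default);
  "significance" here is operational, not statistical.
* Batch processing only: the pipeline recomputes the full series per run
  and is not a streaming estimator.
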