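---
title: "Quantifying nicotine avoidance in two-bottle choice experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nicotine avoidance in two-bottle choice experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bottlechoice)
```

## The measurement problem

In a continuous-access two-bottle choice test a single-housed mouse
chooses freely between a vehicle bottle (2% saccharine) and a nicotine
bottle whose concentration is stepped up every 4 days (10, 50, 100,
200 µg/ml), with the bottles swapped every other day to control for side
preference. An automated system logs the cumulative volume drunk from
each bottle every minute. Two quantities summarise a day:

- **intake** in mg of nicotine per kg body weight per day,
  `vol_drug_ml * conc / weight_g`;
- **percent nicotine consumption**, the drug-bottle volume as a share of
  total fluid.

Group averages hide the interesting structure: individual mice either
keep increasing their intake with concentration (or titrate to a
plateau), or they durably stop drinking nicotine at some
animal-specific concentration. This package operationalises that
distinction and the representations used to analyse it.

## Design choices in the data layer

**Cumulative volumes on disk.** The acquisition system measures
cumulative consumption; missing minutes then simply mean "no drinking
recorded" and the day increment is unaffected. A day is minutes
`[1440 (d-1), 1440 d)` from experiment start; `day_offset_minutes`
shifts the boundary if the recording did not start at a day boundary
(whether daily volumes should follow calendar days or swap periods is
not determinable from the design — calendar days are the default).
A day with no observation at all is flagged missing rather than scored
as zero: an absent record is not evidence of abstinence. Likewise a day
with zero total fluid has undefined percent consumption — no preference
can be read off non-drinking — and condition means simply skip flagged
days (coverage is reported, nothing is imputed).

**Weights.** Mice are weighed every other day; weights are stable over
that horizon, so the day's weight is the last recorded one
(step carry-forward; carry-backward before the first record). Linear
interpolation would change intakes by well under 1% while adding an
assumption.

## The pseudo-ternary representation

Side-wise percents `%c1` (left) and `%c2` (right) distinguish *active*
choice (following or fleeing the nicotine bottle across swaps) from
*passive* side bias. Folding them into `a = min`, `b = max` and mapping
to `x = (a+b)/2` (consumption index) and `y = b - a` (side-bias index)
puts every animal inside a triangle whose apices are complete avoidance
(0, 0), complete tracking (100, 0) and pure side bias (50, 100). Before
computing Euclidean apex distances the `y` axis is scaled by `sqrt(3)/2`
so the apices form an equilateral triangle and the three distances are
mutually comparable; the scale is exposed (`side_scale`, alternative 1)
because the published construction does not pin it down. Habituation
(water vs water) points use the *virtual* drug side — the task's
alternation pattern continued backwards — so trajectories can start from
the habituation condition.

The map `(a, b) -> (x, y)` is invertible on the triangle, and any two
apex distances reconstruct the point (the test suite checks this
trilateration to numerical tolerance), so no information is lost.

## Phenotype classification

The published definitions are narrative; four numeric parameters make
them reproducible (all exposed in `phenotype_params()`):

| parameter | default | role |
|---|---|---|
| `low_intake_ceiling` | 2 mg/kg/day | constitutive avoider: intake never exceeds it |
| `noise_band` | 0.5 mg/kg/day | smallest day-to-day change treated as real |
| `quit_level` | 0.2 | post-drop intake must stay below this fraction of the pre-drop condition mean |
| `avoid_pct` | 20% | consumption level below which a condition counts as avoided |

The ceiling is stated by the phenotype definition itself; the other
three were fixed once at values a practitioner would defend (half a
mg/kg/day is below the day-to-day variability of any consuming mouse;
20% mirrors the side-bias exclusion bound) and are not tuned per
dataset. Rule precedence is `low_intake` first, then `abrupt_drop` —
how a mouse that both stays low *and* drops should be labeled is not
determinable from the published description, so the choice is flagged
as operational. "Abrupt" is anchored to concentration steps (the drop
must begin at or within one day of an increase) and cessation must be
durable (intake below `quit_level` for the remainder of the task):
transient dips that recover do not classify. Habituation side preference
outside (20, 80)% excludes the animal, with strict inequalities — the
boundary is kept.

The per-mouse aversion threshold is the lowest concentration whose
condition-mean percent consumption falls below `avoid_pct` and stays
there for all later conditions; it is reported only for avoiders.

## Evoked-response quantification

**Puff-evoked currents.** Baseline is the median over the pre-puff
second (median, not mean, for robustness to brief artifacts); the
response is the largest inward deflection within 3 s of the puff,
reported as a positive magnitude in the inward "−pA" convention. The
trace is boxcar-smoothed over 20 ms first: the raw minimum of thousands
of noisy samples is biased by the noise floor, while 20 ms is short
against the transient's 50 ms rise and 500 ms decay, so the peak itself
is essentially unattenuated. Deflections within 4 baseline standard
deviations (or purely outward ones) count as no response.

**Firing-rate changes.** Baseline rate is the spike count over the 5-min
pre-injection span. The post-injection excursion is read from 10-s bins
over 180 s; the response is the bin deviating most from baseline,
directional when it exceeds 3 standard deviations of the binned
baseline rates. The 3-s.d. band is deliberately conservative because the
excursion is the most extreme of 18 scanned bins. When nothing crosses
the band the reported change uses the *mean* post-injection rate — the
extremum of a flat rate is pure selection bias, and homogeneous trains
must average to zero change (a property the tests verify over 200
replicates). Note the extremum read-out modestly overshoots the
magnitude of true square excursions (by ~25% at these rates and bin
widths); it is a peak estimator, not an unbiased mean-effect estimator,
which is the standard trade-off for transient responses of unknown
timing. Windows and bins (3 s current window; 10 s bins, 180 s post
window) are not documented for the original recordings and were chosen
from the figures' visible kinetics; all are parameters.

**Dose–current regression.** Ordinary least squares of per-*mouse* mean
current on log10 of the dose consumed over the last 24 h. Averaging to
mouse level first is enforced by `per_mouse_means()`: per-neuron
regression would pseudo-replicate. The reported
`F(1,12) = 12.45` at `n = 14` is consistent with the printed
`R^2 = 0.47` only as an *adjusted* R² (raw `R² = F/(F+12) = 0.509`);
`covariate_regression()` therefore reports both, and
`r_squared_from_f()` makes the identity checkable.

## Statistics

All tests are two-sided. `mann_whitney()` uses the exact rank-sum
distribution (dynamic-programming enumeration) for untied samples with
`n1*n2 <= 400`, else a tie-corrected normal approximation without
continuity correction; the "paired Mann-Whitney" of the experimental
literature is implemented as the Wilcoxon signed-rank test with zero
differences dropped and exact enumeration up to n = 50. The Friedman
statistic carries the standard tie correction. Holm-Bonferroni is the
step-down adjustment with monotonicity enforcement, applied within
declared families (one per figure panel) by `family_report()`. The Yates
chi-squared floors `|O - E| - 0.5` at zero so near-balanced tables are
not over-corrected. Each procedure is cross-checked in the tests against
an independent implementation on random inputs.

One analytic note: the avoider-proportion table (17/35 vs 0/13) gives
χ² = 7.77, p ≈ 0.005 under the standard Yates formula, not the p = 0.04
printed alongside it in the source experiments; the package reports its
own computed value rather than silently matching.

## The synthetic cohort generator

The generator exists to close the loop: archetypes with known labels go
in, the pipeline must recover them. Drinking is simulated at *bout*
level — each bottle gets a Poisson number of gamma-volume bouts per day,
scaled to a day target with lognormal day-to-day variability (CV 0.12) —
because the analysis only consumes minute-resolution volumes and bouts
are the minimal structure producing realistic within- and between-day
variability. Weights follow a slow random walk around 25 g, recorded
every other day.

The reference cohort (35 mice, default seed 101) mixes 6 trackers,
5 side-biased drinkers and 7 titrating plateau trackers (18
non-avoiders) with 12 abrupt avoiders at the 100→200 µg/ml step, one
each at 100, 50 and 10 µg/ml, and 2 constitutive low-intake avoiders
(17 avoiders). Archetype volume parameters were set by moment matching —
solving `intake = vol * conc / weight` forward for the published group
means (≈2.6 mg/kg/day for avoiders and ≈16.9 for non-avoiders at
200 µg/ml; population intake ≈10) — since the underlying per-mouse
distributions are not available. Abrupt avoiders drink normally on
their first day above threshold (they must sample the new concentration
to react to it) and collapse to a near-zero residual (0.003–0.008
ml/day) from the next day; the residual is small enough that residual
*intake* stays below the quit level even at 200 µg/ml, which is what
durable cessation means. Habituation drinking is balanced (42–58% per
side) so no synthetic mouse trips the side-bias exclusion.

Minipump-pretreatment cohorts for the single-step 100 µg/ml protocol
follow per-day percent-consumption paths: saline-pretreated mice drop
abruptly (40, 18, 17, 17 → condition mean 23%), nicotine-pretreated mice
decline gradually (50, 44, 37, 34 → mean ≈41%), with per-mouse
multiplicative jitter.

Ephys ensembles draw per-neuron amplitudes from a lognormal with CV 0.4
around the group mean — a typical within-group spread for evoked
currents that keeps a group mean of ~25-60 neurons estimable to a few
percent — on a noisy −20 pA holding baseline, with double-exponential
transients (50 ms rise, 500 ms decay). Spike trains are inhomogeneous
Poisson with a ramp-hold-decay excursion, generated by thinning.

### What passing tests do and do not show

The generator reproduces the *structure* the pipeline assumes:
bout-paced cumulative logs, condition-level intake trajectories,
archetype-specific choice geometry, transient currents and rate
excursions. It deliberately omits circadian structure, lick-level
microstructure, day-level autocorrelated drift within conditions (real
non-avoiders ramp smoothly day by day, so their minimum day-to-day
difference is positive; synthetic trackers step between conditions and
fluctuate within them), pharmacokinetics, and any learning dynamics
beyond the threshold-triggered collapse. Recovery of the calibration
targets therefore validates the pipeline's correctness on data with
known truth — it does not certify classifier performance on real mice,
whose noise structure is richer.

## Problem sizes and determinism

All randomness flows from a single seeded generator per cohort; the same
seed yields byte-identical output. The test suite simulates 25-cohort
batches for label-recovery statistics and 200-replicate ensembles for
the rate-change null; the analysis scripts run the 35-mouse reference
cohort end to end. These sizes keep every computation deterministic,
well-margined and fast while leaving the estimators in the regime where
their biases and tolerances are documented above.

## Known limitations

- The avoider rule set is one defensible operationalisation; mice
  engineered to sit exactly on a parameter boundary can flip label with
  the parameters, which is why every threshold is exposed and echoed.
- The aversion threshold is resolution-limited by the schedule: a mouse
  whose true threshold lies between tested concentrations is assigned
  the first tested concentration it avoids.
- Percent consumption is undefined on zero-fluid days; sustained
  non-drinking (illness) is not distinguished from avoidance and should
  be screened upstream.
- The extremum-based firing-rate change overshoots true step amplitudes
  (documented above); comparisons *between* groups analysed identically
  are unaffected.
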