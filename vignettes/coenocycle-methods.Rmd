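---
title: "Models and methods behind coenocycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind coenocycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its models, the choices we
made where the design was genuinely open, and the limits of what the
synthetic data can show. It states no number that the test suite or
`scripts/acceptance.R` does not itself compute.

## The timer model of coenocytic nuclear division

A coenocyte's nuclei divide synchronously, so the cell's DNA content is a
single power-of-two value that doubles at each division. We model the
interval between divisions as an independent draw from
Normal(μ, cv·μ), with mean μ (default 11 h) and coefficient of variation
cv (default 0.10). The assumptions baked in:

* **Independence.** Each interval is independent of the previous one,
  within and across cells. No mother–daughter correlation is modelled:
  the simulation window of interest precedes burst.
* **Starvation-release phase.** Every cell starts a *fresh* interval at
  t = 0. Starved populations consist of arrested 1C/2C/4C cells that
  re-enter the cycle on dilution into fresh medium, so a synchronized
  start is the realistic convention — and it is what produces the
  experimentally observed staircase of DNA content. The alternative
  (stationary random phase) would erase population synchrony entirely.
* **Positivity.** A normal interval can be non-positive in principle; we
  redraw until positive. At cv ≤ 0.15 the probability of a non-positive
  draw is Φ(−1/cv) < 10⁻¹⁰, so the redraw is unbiased in practice.
* **Closed-right counting.** The ploidy at time t counts divisions with
  time ≤ t; a division falling exactly on a sampling time has happened.

Initial ploidies are apportioned deterministically from the configured
fractions by largest-remainder rounding, so the realized composition is
exact and contributes no extra noise; multinomial sampling is available
behind `init_method = "multinomial"` for users who want that noise
source.

### Random numbers

All stochastic functions take a single integer seed. Substream seeds for
replicates (and for each table of the data generator) are derived by a
deterministic 31-bit mixing of the root seed with the replicate index,
so replicate r is reproducible in isolation. Within a replicate the
interval matrix is filled cell-major: growing `n_cells` appends new
cells' draws without reshuffling existing ones.

## Flow-cytometry DNA-content statistics

For a ploidy histogram with fraction $f_i$ in bin $x_i$:

$$\log_2(\mathrm{geommean}) = \sum_i f_i \log_2 x_i, \qquad
\log_2(\mathrm{GSD}) = \sqrt{\sum_i f_i\,(\log_2 x_i - \log_2 \mathrm{geommean})^2}.$$

The unrooted sum is a variance; we apply the square root by default so
the quantity is a standard deviation on the log2 axis, identical to the
per-event population SD of log2 ploidy (the test suite verifies this
equivalence to 10⁻¹²). A `"literal"` mode returns the unrooted sum for
users replicating legacy scripts that skipped the root. No conclusion in
the package depends on the choice, because asynchrony is only ever
compared against envelopes computed in the same mode.

### Calibration and binning

Ploidy peaks sit at 2-fold intensity spacings, i.e. unit spacing on a
log2 axis. The 1C-equivalent reference is the mode of the lowest
significant peak of a kernel-density estimate of log2 intensity, where a
peak qualifies if its prominence is at least 5% of the global density
maximum. The bandwidth is Silverman's rule *capped at 0.25 log2 units*
(a quarter of the known unit spacing): the whole-sample Silverman value
on a wide mixture (eight unit-spaced components) is ≈ 0.38 and smears the
edge peak inward by ~4%, while the cap keeps the recovered reference
within ~1% of truth. The cap is a structural prior — we know the peak
spacing — not a tuning constant.

Events are then assigned to bin $2^k$, $k = \mathrm{round}(\log_2(I/\mathrm{ref}))$.
The bin half-width (tolerance 0.5 log2 units) tiles the axis exactly
because adjacent peaks are one unit apart; events beyond the tolerance or
below the 1C bin are *flagged* debris, never silently dropped, and the
retained/flagged counts are always reported.

### Doubling time, and why it is not exactly μ

The nuclear doubling time is 1/slope of the OLS fit of log2 geometric
mean on time, restricted to a window (default 0–36 h, before any burst).
The slope's standard error is reported as-is; the doubling-time SE is the
delta-method transform SE/slope².

A subtlety worth understanding: with *phase-synchronized* cells the
expected log2 geometric mean is a smoothed staircase (the renewal
function of the interval distribution), not a straight line. Over a
window a few periods long, OLS on a staircase recovers a slope that
deviates from 1/μ by an amount that depends on the grid's alignment with
the period. At μ = 11 h, cv = 0.1, sampled every 3 h over 0–36 h, the
estimator's expectation is ≈ 11.7 h, not 11.0 (the acceptance script
computes this; the sparser 12 h grid of the synthetic experiment gives
≈ 12.1). This is a property of the estimator under synchronized start,
not an implementation artifact — and it is consistent with an observed
"approximately 11–12 h" read-out for an 11 h timer. Users comparing
conditions should compare fitted values with matched grids and windows,
which cancels the alignment effect.

### Asynchrony envelopes and the CV upper bound

Per replicate we simulate a population, compute log2(GSD) on its exact
histogram at each grid time, and subtract the replicate's own t = 0
value; the envelope is the mean ± SD of this increase across replicates
(default 100). The increase of asynchrony grows with cv, so envelopes on
a cv grid let an observed series bound the cell-to-cell variability.

`cv_upper_bound()` returns the smallest grid cv whose envelope is
*compatible* with the observation. Compatibility is one-sided by
default: the observation must not exceed the envelope's mean + SD at any
shared time point. The rationale: the quantity is an upper bound, so
only *excess* asynchrony is evidence against a cv; requiring the
observation to also stay above the lower edge (available via
`sides = "both"`) makes the test reject its own matched cv most of the
time, because a single realization sits inside its own ±1 SD band only
~68% per time point.

One degeneracy deserves a warning. At sampling times that are exact
multiples of μ (e.g. 33 h for an 11 h timer), every cell is mid-step with
a 50/50 split *regardless of cv*, so envelopes of adjacent cv values
coincide there and no containment rule can separate them. Avoid grids
aligned with the suspected period when bounding cv, or start the
comparison (`start_time`) past the degenerate points.

## The synthetic experiment

`generate_experiment()` produces event tables, microscopy tables and
time-lapse series with known ground truth. What it emulates, and how:

* **Shared timer across media.** One cohort of cells with one set of
  division schedules serves all media levels — the decoupling of nuclear
  timing from growth is built in *by construction*, which is exactly what
  makes the generator a ground-truth oracle for the decoupling analysis.
* **Nutrient-dependent growth.** Volume grows exponentially at a
  media-specific rate (defaults 0.044, 0.033, 0.024, 0.012 h⁻¹ for 1×,
  1/2×, 1/4×, 1/16×). The exponential form and the rates are invented
  ordinal stand-ins — no quantitative growth law is available — chosen so
  that rich-media cells roughly double their projected area by ~24 h.
  Only orderings across media are ever asserted on these volumes.
* **Burst.** Each cell draws a cellularization threshold log-uniformly
  from {64C, 128C}; if the division reaching it falls inside the burst
  window (48–72 h) the cell bursts into threshold/newborn-ploidy
  newborns (2C with weight 0.8, 4C with 0.2), which partition the mother
  volume and restart the timer. Cells reaching their threshold early
  hold at the cap without bursting. Nuclei are conserved at burst.
* **Instrument noise.** DAPI intensity is reference × ploidy × a
  log-normal factor with mean 1 (CV 0.07); SSC is a volume power law
  (exponent 2/3, surface-like scattering) with noise; ~2% of events are
  replaced by log-uniform sub-1C debris, exercising the debris-flag
  path. The SSC and debris models are invented; only ordinal SSC
  properties are asserted.

What it deliberately does **not** emulate: outlier cells that escape
synchrony, early dividers that contaminate late GSD measurements (the
experimental reality that makes observed asynchrony an overestimate),
nutrient depletion at high inoculum, temperature effects, and any
spatial structure inside the coenocyte. Consequently, passing tests show
that the *analysis* recovers the truth of this generative model; they do
not show that real data are this clean. In particular real asynchrony
series carry outlier sensitivity that the optional `trim_floor` of
`summarize_ploidy()` exists to probe.

## Statistical comparisons

Two-sample comparisons use the Wilcoxon rank-sum test with mid-rank tie
handling. For group sizes up to 20 the two-sided p-value is exact,
computed by a subset-sum dynamic programme over the (doubled) mid-ranks —
equivalent to full enumeration of all $\binom{n+m}{n}$ assignments, which
the tests verify against brute force for all sizes ≤ 8, ties included.
Larger groups use the normal approximation with continuity correction
and tie-corrected variance. Quartile summaries use linear interpolation
(Tukey boxplot convention).

## Problem sizes and tolerances used in the tests

The test suite exercises the study-scale configuration where the claim
depends on it — 5000-cell populations, 100-replicate envelopes, the full
four-media synthetic experiment — and smaller populations (hundreds of
cells) where only structural properties are checked. Closed-form
identities are asserted to 10⁻¹² or exactly; Monte-Carlo quantities get
tolerances of a few standard errors at the simulated size. The
end-to-end decoupling check estimates its Monte-Carlo SD from five
generator seeds.

## Known limitations

* The doubling-time estimator carries the grid-alignment bias described
  above; it is shared by any analysis that regresses a synchronized
  staircase, and cancels in within-study comparisons but not against the
  generating μ.
* CV bounding cannot separate adjacent cv values at sampling times equal
  to exact multiples of the period, and a mean ± 1 SD band is a
  *descriptive* envelope, not a calibrated hypothesis test.
* The generator's volume model is ordinal; absolute sizes, growth-rate
  values and SSC scalings should not be interpreted quantitatively.
* Newborn re-entry into the cycle after burst reuses the same timer with
  no maturation delay; late-time (> 60 h) DNA-content profiles are
  therefore stylized.
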