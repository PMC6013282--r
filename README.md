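# coenocycle

Quantitative analysis of coenocytic cell cycles, modelled on the growth of
the ichthyosporean *Sphaeroforma arctica*. In this organism a small newborn
cell grows into a large multinucleate coenocyte through rounds of
*synchronous* nuclear divisions — DNA content walks up the power-of-two
ladder 1C → 2C → … → 128C — before the cytoplasm cellularizes and bursts
into newborn daughter cells. The striking feature of this cycle is its
*decoupling*: the nuclear division clock runs at a fixed period
(a "timer", ~11 h) regardless of nutrient concentration, while the growth
of cell volume is strongly nutrient-dependent.

The package is written for people analysing flow-cytometry DNA-content
time courses and cell-size measurements of such systems, and for people
who want to simulate them. Everything is data-frame in, tibble out, and
composes with the pipe.

## What it computes

**Timer simulation.** Each cell's division intervals are i.i.d. draws from
Normal(μ, cv·μ) (non-positive draws redrawn), with every cell starting a
fresh interval at t = 0 (starvation release). A population of cells yields
a ploidy trajectory set; repeated simulation yields an asynchrony envelope.

**DNA-content statistics.** For a histogram with fraction *f&#8336;* of events
in ploidy bin *x&#8336;* (powers of two):

- log2 geometric mean: `log2(geommean) = Σᵢ fᵢ · log2(xᵢ)`
- asynchrony (geometric SD, log2 scale):
  `log2(GSD) = sqrt( Σᵢ fᵢ · (log2(xᵢ) − log2(geommean))² )`
  (a `"literal"` mode returns the unrooted sum)
- nuclear doubling time: OLS of log2(geommean) on time over a window
  (default 0–36 h); the doubling time is 1/slope, with the slope's
  standard error reported and propagated by the delta method
- increase of asynchrony: `Δlog2(GSD)(t) = log2(GSD)(t) − log2(GSD)(0)`,
  compared against simulated envelopes over a CV grid to bound the
  cell-to-cell variability of the timer

Raw events are calibrated from the lowest peak of a mixed-stage sample
(KDE on log2 intensity) and assigned to bin `2^k`,
`k = round(log2(I / reference))`, with off-ladder and sub-1C events
flagged as debris.

**Size statistics.** Spherical volumes `V = (4/3)πr³`, nuclei-to-volume
ratios, relative areas of time-lapse series normalized to t = 0, SSC
summaries per ploidy bin, and exact mid-rank Wilcoxon rank-sum
comparisons between conditions.

**Synthetic data.** `generate_experiment()` emulates the whole study —
timer-driven coenocytes shared across media levels, nutrient-dependent
exponential volume growth, cellularization thresholds of 64–128C with
burst between 48 and 72 h into 2C/4C newborns, log-normal instrument
noise and a debris channel — with full ground truth, so every analysis
stage can be exercised and tested without any external data.

## Worked example

```r
library(coenocycle)
library(dplyr)

cfg        <- experiment_config(events_per_timepoint = 2000)
experiment <- generate_experiment(cfg, seed = 7)
mixed      <- generate_mixed_calibration_sample(cfg, n_events = 3000, seed = 7)

cal <- calibrate_reference(mixed)
cal
#> <ploidy_calibration> reference intensity: 100.18 | bin tolerance: 0.5 log2 units | 8 peak(s)

binned    <- assign_ploidy(experiment$events, cal)
#> assign_ploidy: 54880 events retained, 1120 flagged as debris.
summaries <- summarize_ploidy(binned)

summaries |> filter(condition == "1x") |> fit_doubling_time()
#> <doubling_time_fit> doubling time 12.09 h (slope 0.0827 +/- 0.0027 log2C/h, 4 points in [0, 36] h)
```

The calibration recovered the generator's true 1C intensity (100) from
the lowest KDE peak; 2% of events were flagged as debris, matching the
configured debris fraction. The fitted doubling time is close to the 11 h
timer driving the simulation — the excess (~1 h here) is the expected
finite-window bias of regressing a phase-synchronized division staircase
on a sparse 12 h grid; see the methods vignette.

Cell size, in contrast, tracks nutrients at fixed nuclear content:

```r
cells16 <- nuclei_volume_ratio(experiment$cells) |> filter(n_nuclei == 16)
cells16 |> group_by(condition) |> summarise(median_volume = median(volume_um3))
#>   condition median_volume
#> 1 1/16x              673.
#> 2 1/2x              1392.
#> 3 1/4x               985.
#> 4 1x                2183.

compare_groups(cells16$nuclei_per_um3[cells16$condition == "1/16x"],
               cells16$nuclei_per_um3[cells16$condition == "1x"])
#>     n_a   n_b statistic  p_value method direction
#> 1    59    57      3363 1.64e-20 normal a>b
```

Median volume of 16-nuclei cells is ordered by media concentration
(2183 > 1392 > 985 > 673 µm³), and the nuclei-to-volume ratio is
significantly higher in 1/16× media: cells grown poor are more compact,
while their division clock (above) is unchanged.

`run_pipeline()` chains all stages (generate → calibrate/bin → doubling
times → envelopes and CV bounds → size comparisons) into one seeded,
manifest-tracked output directory; `inst/scripts/coenocycle.R` is a thin
command-line wrapper around it.

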