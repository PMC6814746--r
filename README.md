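# nucspike

Detection and quantification of nuclear calcium spikes in fluorescence
recordings of growing plant root meristems.

Root meristem cells of *Arabidopsis* fire brief, cell-autonomous Ca²⁺
transients that start in the nucleus and spread to the cytosol, and the
statistics of those transients — kinetics, frequency, spatial
distribution — track primary-root growth and its genetic modulation
(e.g. through the nuclear-envelope channel DMI1). Recordings from
dual-targeted GECO sensors arrive as per-cell fluorescence time series
sampled every 2–3 s for about 1.5 h, with slow baseline drift and
substantial noise. `nucspike` turns such traces into spike calls and
cohort statistics, and ships a seeded simulator with exact ground truth
for benchmarking every stage.

## The method

Per trace, with `F₀` the mean of the first 20 frames:

1. ΔF/F = (F − F₀)/F₀;
2. detrending by subtraction of an order-3 least-squares polynomial in
   time (two-pass: detected pulses are excluded from the final fit);
3. candidate peaks = local maxima reaching 5 robust noise scales
   (1.4826 × MAD) on a 5-frame running mean;
4. pulse boundaries = the first frames before and after the peak where
   the detrended signal falls below θ_s = 0.5 σ̂ **and** the absolute
   gradient falls below θ_g = 2 σ̂_g, refined to sub-frame precision by
   crossing interpolation and a least-squares piecewise-linear pulse
   fit;
5. rise = t_peak − t_on, fall = t_off − t_peak, duration = rise + fall,
   amplitude = detrended ΔF/F at the peak; boundaries that hit the
   recording edge are censored.

On top of the per-trace calls: nuclear/cytosolic onset-lag origin
classification, per-plant responder flags and spike rates within a
200 µm reference span, meristem/elongation zone partitions, and an OLS
regression of root growth rate on spike frequency. The methods
vignette (`vignettes/spike-detection.Rmd`) derives the defaults and
records every invented constant.

## Worked example

```r
library(nucspike)

cfg  <- sim_config(seed = 42, n_plants = 12)   # wild-type study conditions
coh  <- simulate_cohort(cfg)

fits  <- detect_spikes(coh$collection)
fits
#> <spike_fit_set> 101 trace(s), 65 call(s)

calls <- spike_calls(fits)
str(shape_means(calls))
#> List of 7
#>  $ n              : int 65
#>  $ mean_rise_s    : num 15.3
#>  $ sd_rise_s      : num 6.98
#>  $ mean_fall_s    : num 22.3
#>  $ sd_fall_s      : num 10.4
#>  $ mean_duration_s: num 37.5
#>  $ sd_duration_s  : num 9.9

summ <- summarize_plants(calls, coh$plants, coh$positions)
responder_fraction(summ)
#> [1] 58.33333
partition_by_zone(calls, coh$positions,
                  coh$plants[, c("plant_id", "boundary_um")])$meristem_pct
#> [1] 76.92308
correlate_growth_spiking(growth_records(coh$plants), summ)$slope
#> [1] 0.03975575
```

The 65 detected calls recover the generating kinetics (mean rise
15.3 s against a generating mean of 15.4 s, fall 22.3 s against
24.1 s at this small cohort size), 58% of plants respond (generating
probability 0.7), 77% of spikes fall in the meristematic zone
(generating share 0.8), and the growth regression recovers a positive
slope. A single fitted trace behaves like a classic model object:
`coef()`, `fitted()`, `residuals()`, `summary()` and `plot()` all work
on a `spike_fit`.

A thin command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "nucspike.R", package = "nucspike"))')" \
    simulate --out-dir sim --seed 7 --plants 6
Rscript .../nucspike.R detect --in sim/traces.csv --out sim/spikes.csv
Rscript .../nucspike.R origin --spikes sim/spikes.csv --out sim/origin.csv
Rscript .../nucspike.R summarize --spikes sim/spikes.csv \
    --meta sim/plants.csv --traces sim/traces.csv --out sim/summary.csv
```

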