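# tcbloom

Diagnostics for attributing a lagged phytoplankton bloom to the passage of
a tropical cyclone and the cyclonic eddies it spins up.

When a storm crosses a stratified tropical ocean it cools the surface and —
through wind-stress-curl (Ekman) upwelling and intensified cyclonic eddies —
lifts nutrients into the sunlit layer. Satellite chlorophyll-a then blooms
with a lag of several days. `tcbloom` implements the standard diagnostic
chain for this attribution, for oceanographers who want the computation
reusable and testable rather than re-scripted per case study:

* **track** — best-track parsing, great-circle translation speeds
  (haversine, R = 6371 km, reported at the arrival fix), and intensity
  classification by maximum sustained wind with total, monotone, half-open
  bands (tropical depression [10.8, 17.2) m s⁻¹ … super-severe typhoon
  [52, ∞)).
* **wind forcing** — bulk wind stress τ = ρₐC_d|U|(u, v); spherical
  wind-stress curl ∇×τ = [∂τ_y/∂λ − ∂(τ_x cos φ)/∂φ]/(R cos φ); Ekman
  pumping w_E = ∇×τ/(ρf) with the equatorial band masked.
* **ocean diagnostics** — relative vorticity of current fields with the
  full spherical metric (reducing locally to ∂v/∂x − ∂u/∂y) and
  box-averaged positive-vorticity depth–time sections.
* **hydro profiles** — density (linear EOS by default, TEOS-10 via `gsw`
  when installed), buoyancy frequency N² = (g/ρ₀)dρ/dz at layer midpoints,
  thermocline depth (argmax N), mixed-layer depth (0.2 °C from 10 m).
* **box time series** — cos-latitude-weighted box means, gap-aware pooled
  two-day composites, and bloom-lag / fold-increase / SST-cooling metrics.
* **synthetic data** — generators for every input (translating Rankine
  cyclone winds, Gaussian cyclonic eddies with analytic geostrophic
  currents, tanh-thermocline profiles, cloud-masked lagged chlorophyll,
  step-cooled SST) with known ground truth, so the whole pipeline is
  validated end to end without downloads.

All gridded I/O uses a plain-text CF-like dialect (long CSV with metadata
headers); profiles are 3-column text. See the methods vignette
(`vignettes/tcbloom-methods.Rmd`) for the models, assumptions, parameter
defaults and design decisions.

## Worked example

A bundled 6-hourly best track (27 fixes, Arabian Sea, Nov–Dec 2017) drives
everything:

```r
library(tcbloom)
tr <- example_track()
data.frame(time = format(tr$time, "%m/%d %HZ"), lat = tr$lat, lon = tr$lon,
           msw = tr$msw, ts = round(tr$ts, 1), category = tr$category)[c(9, 13, 20), ]
#>         time  lat  lon  msw  ts              category
#> 9  12/01 06Z  8.8 73.3 32.5 4.6 severe_tropical_storm
#> 13 12/02 06Z  9.8 71.0 42.5 3.6        severe_typhoon
#> 20 12/04 00Z 14.5 68.5 35.0 5.1               typhoon
```

The speed column is the great-circle distance from the previous fix over
the elapsed 6 h; at 12/01 06Z and 12/04 00Z it reproduces the printed
best-track values (4.6 and 5.1 m s⁻¹) to one decimal.

A full synthetic scenario — 30% cloud cover, chlorophyll rising 0.26 →
4.68 mg m⁻³ four days after local storm passage, a 2 °C / 10-day SST step —
is generated, box-averaged over 11–14°N, 67–70°E, and analysed:

```r
sc <- bloom_scenario(baseline_chl = 0.26, peak_chl = 4.68, lag_days = 4,
                     cloud_fraction = 0.3, seed = 42)
res <- run_bloom_scenario(sc, sst_drop = 2, sst_duration_days = 10)
res$passage_time
#> [1] "2017-12-03"
res$bloom
#> <bloom_metrics> baseline 0.26, peak 4.27 (x16.4) 4 days after passage
res$cooling
#> <cooling_metrics> baseline 29.00 degC, max drop 2.00 degC, persistence 11 days
```

The recovered lag (4 days) and cooling magnitude (2.00 °C) match the
injected ground truth; the box-mean peak (4.27 of 4.68) is slightly smeared
because pixels peak on two adjacent days as the storm crosses the box —
the recovered fold increase (16.4 of the injected 18.0) stays within the
10% recovery tolerance, and persistence lands within a day of the injected
10 (the 0.5 °C recovery margin credits one partially cooled shoulder day).

Stratification diagnostics on a synthetic float profile (1-m sampling,
thermocline prescribed at 46.2 m):

```r
p <- gen_profile(stratification_params(), seq(0, 200, 1))
stratification_summary(p)
#> <stratification_summary> thermocline 46.5 m, N_max 0.03698 s-1, MLD 24.3 m
```

The argmax-N midpoint (46.5 m) recovers the prescribed depth within the
grid spacing.

## Command line

A CLI covering simulation, track reporting, EPV, vorticity sections,
profile summaries, box series and the end-to-end report ships in
`inst/cli/tcbloom-cli.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "tcbloom-cli.R", package = "tcbloom"))')
Rscript $CLI simulate --config cfg.txt --out simout --seed 3
Rscript $CLI epv --wind simout/wind10m.txt --out epv.txt
Rscript $CLI report --seed 3
```

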