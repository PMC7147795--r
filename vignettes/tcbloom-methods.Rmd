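---
title: "Diagnosing cyclone-driven blooms: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing cyclone-driven blooms: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcbloom)
```

## The scientific problem

When a tropical cyclone crosses a stratified tropical ocean it cools the
surface, deepens the mixed layer, and — where its wind-stress curl or
pre-existing cyclonic eddies drive upwelling — lifts nutrient-rich water
into the euphotic zone. Satellite chlorophyll-a then often shows a bloom
that *lags* the storm by several days and persists long after the wind has
gone. Attributing such a lagged bloom requires a chain of small, standard
diagnostics: Ekman pumping from the wind field, relative vorticity of the
surface currents, stratification from float profiles, and cloud-gap-aware
box-averaged time series of chlorophyll, SST, rainfall and light.

`tcbloom` packages that chain, together with a synthetic-data module that
generates every input with known ground truth, so that the whole pipeline
is testable end to end without any satellite, reanalysis or float download.

## Models and formulas

**Ekman pumping.** The upwelling velocity at the base of the Ekman layer is

$$ w_E = \frac{\nabla \times \tau}{\rho f}, \qquad
   \nabla \times \tau = \frac{1}{R\cos\varphi}\left[
     \frac{\partial \tau_y}{\partial \lambda}
     - \frac{\partial}{\partial \varphi}(\tau_x \cos\varphi)\right], $$

with $\rho = 1024$ kg m$^{-3}$, $f = 2\Omega\sin\varphi$, and
$(\varphi, \lambda)$ latitude/longitude in radians on a sphere of radius
$R = 6371$ km. The $\varphi$-derivative is applied to the *product*
$\tau_x\cos\varphi$, exactly as the curl is written, not expanded. Note a
consequence that surprises at first sight: a spatially constant
$\tau_x$ is **not** curl-free on the sphere — its curl is the metric term
$\tau_x\tan\varphi/R$ (about $3\times10^{-9}$ N m$^{-3}$ for 0.1 N m$^{-2}$
at 13°N). The test suite asserts this analytically rather than pretending
the term is zero.

**Wind to stress.** No bulk formula is canonical at cyclone wind speeds, so
the package defaults to the simplest defensible choice: $\tau = \rho_a
C_d |U| (u, v)$ with $\rho_a = 1.2$ kg m$^{-3}$ and a constant
$C_d = 1.3\times10^{-3}$, which keeps every oracle analytic. A
piecewise-linear scheme (1.2e-3 below 11 m s$^{-1}$, $(0.49 + 0.065U)
\times 10^{-3}$ up to a 25 m s$^{-1}$ cap) is selectable as
`cd_scheme = "largepond"`. EPV magnitudes therefore depend on this choice
and are treated as structural (sign and pattern), never as absolute targets.

**Relative vorticity.** The vertical curl of the horizontal current is
implemented in full spherical form,
$\zeta = \frac{1}{R\cos\varphi}\frac{\partial v}{\partial\lambda}
 - \frac{1}{R}\frac{\partial u}{\partial\varphi}
 + \frac{u\tan\varphi}{R}$,
which reduces locally to the planar $\partial v/\partial x - \partial
u/\partial y$; the metric term is small but nonzero at 11–14°N, and keeping
it makes the current curl grid-consistent with the wind-stress curl.
Cyclonic-eddy intensity in a box is summarised as the cos-latitude-weighted
mean of *positive* vorticity. "Positive vorticity average" is ambiguous, so
two statistics are offered: the default `pos_conditional_mean` (mean over
cells with $\zeta > 0$; tracks eddy-core intensity and is 0 when nothing is
cyclonic) and `rectified_mean` (mean of $\max(\zeta, 0)$ over all cells).

**Stratification.** Density defaults to a linear equation of state,
$\rho = \rho_0[1 - \alpha(T - T_0) + \beta(S - S_0)]$ with $\rho_0 = 1024$
kg m$^{-3}$, $\alpha = 2.0\times10^{-4}$ °C$^{-1}$, $\beta = 7.6\times
10^{-4}$ psu$^{-1}$ — every buoyancy-frequency test then has a closed form.
TEOS-10 is delegated to the `gsw` package when installed. $N^2 = (g/\rho_0)
\,d\rho/dz$ (depth positive down) is evaluated by first differences at
layer midpoints with no smoothing by default (a 3-point running-mean flag
exists because real float data need it; synthetic profiles do not).
Unstable layers are reported as $N = 0$ with a flag, never as NaN, so the
thermocline argmax stays well defined; ties break to the shallowest
midpoint. The mixed-layer depth uses the de-facto community criterion —
temperature 0.2 °C below the value at 10 m, linearly interpolated — since
the field of study names the mixed layer without defining one.

**Box series and bloom metrics.** Box averages are cos-latitude-weighted
means over unmasked pixels whose centres fall inside the (inclusive) box.
Two-day composites pool *pixel-days* across the window rather than
averaging daily means: a fully clouded day is then rescued by its clear
neighbour, which is the whole point of compositing; windows tile the record
by default (a daily-sliding option exists). The bloom metrics take the
baseline as the mean over a 6-day window ending at the passage time, the
peak as the post-passage maximum (ties to the earliest), the fold increase
as peak/baseline and the lag as peak time minus passage time. Cooling
metrics report baseline minus post-passage minimum, and the longest
contiguous run of samples colder than baseline minus a 0.5 °C recovery
margin.

## The synthetic world

The generator states one concrete world and keeps it:

* **Cyclone winds** — a Rankine vortex: $v(r) = v_{max} r/r_{max}$ inside
  the radius of maximum wind, $v_{max}(r_{max}/r)^{0.5}$ outside (decay
  exponent configurable), rotated counterclockwise about a centre
  interpolated great-circle-linearly between 6-hourly best-track fixes.
  Simpler than a Holland profile and analytically invertible; any smooth
  cyclonic vortex exercises the same curl/EPV code.
* **Eddies** — Gaussian SSH anomalies $A e^{-d^2/2r^2}$ with analytic
  geostrophic currents, so superposition is exact to machine precision and
  a negative anomaly provably yields a cyclonic, positive-vorticity core.
* **Profiles** — tanh thermoclines normalised so $T(0)$ equals the surface
  temperature exactly; the maximum gradient (hence maximum $N$) sits at the
  prescribed thermocline depth by construction.
* **Chlorophyll** — each pixel rises linearly from baseline to peak over
  `lag_days` days after the storm's closest approach to that pixel, then
  relaxes exponentially with a 3-day e-folding (the observed record shows
  rise-then-drop without a stated functional form; defaults 0.26 →
  4.68 mg m$^{-3}$, lag 4 days match the studied case). Clouds are i.i.d.
  Bernoulli per pixel-day (probability 0.3 by default) — deliberately the
  simplest model that exercises gap-aware compositing; spatially correlated
  cloud systems are a stated non-goal.
* **SST** — a step cooling of known magnitude and duration beginning one
  day after local closest approach. The one-day onset reflects that
  storm-induced cooling develops over the hours to a day after passage, and
  it keeps the passage day itself clean for baseline estimation.

Closest-approach times are evaluated on the daily grid of the requested
series, so injected lags are exact in whole days — this is what makes
"argmax minus closest approach equals the lag exactly" a meaningful
invariant on daily data.

**What a green test does and does not establish.** Ground-truth recovery on
this world validates the plumbing and the numerics: curls, weights, masks,
windows, argmaxes. It does not validate the biology (bloom amplitude is a
free parameter — the nutrient supply that would set it is not modelled),
nor robustness to correlated cloud fields, track errors, or real equations
of state.

## Randomised-scenario ranges

The end-to-end recovery tests draw 20 scenarios with lag 4–6 days,
baseline chlorophyll 0.15–0.4 and peak 2.5–6 mg m$^{-3}$, SST drop
1.5–3 °C, cooling duration 8–18 days, cloud fraction 0.3 — ranges bracketing
the studied case (lag ≈ 4 days, 0.26 → 4.68 mg m$^{-3}$, ~2–3 °C cooling
persisting ~18 days). Lags below 4 days are not drawn: with daily sampling
and a 3°-wide box the storm needs ~2 days to cross, pixels therefore peak
on two adjacent days, and for very short rises the box-mean peak is
discretisation-biased low by an amount approaching the 10% recovery
tolerance. That is a documented limitation of box-mean fold estimation at
short lags, not a property of the generator.

## Numerical choices

* Finite differences: centred 2nd-order at interior points, 1st-order
  one-sided at edges, degrees converted to radians before differencing.
  Convergence order is verified on a sinusoidal stress field; a linear
  field is differenced exactly and cannot exhibit an order.
* Masked data poison their stencils (no gap filling) — conservative;
  compositing handles gaps downstream.
* $f \to 0$: rows within 2° of the equator are masked in Ekman pumping and
  grids touching that band are rejected for geostrophic currents; study
  boxes start at 5°N so nothing is lost.
* Intensity bands: the printed wind-speed bands leave (41, 42) and (51, 52)
  m s$^{-1}$ unassigned; the classifier closes each gap upward with
  half-open intervals ([32.7, 42), [42, 52), [52, ∞)) so it is total and
  monotone. A 42.5 m s$^{-1}$ fix is therefore a *severe* typhoon under the
  printed bands even where prose might call it a typhoon.
* Translation speeds: haversine on a 6371-km sphere, reported at the
  arrival fix (the first fix has none). Only about a third of typical
  printed best-track speed columns are reproducible from adjacent fixes by
  any plain distance/time rule; the tests assert exactly those rows.
* Peak and tie-breaks: bloom peaks tie to the earliest time; thermocline
  ties to the shallowest midpoint.

## File formats

Gridded series are exchanged as long-format CSV with `# key: value`
metadata headers (variable, units, fill = NA, latitude order, longitude
convention, Earth radius) — the same information a CF-style NetCDF header
would carry, chosen so the package needs no binary I/O dependency.
Profiles use 3-column `depth_m temp_C sal_psu` text; best tracks use
`lat,lon,MM/DD/HH,msw` CSV with the year supplied by the caller.

## Known limitations

* EPV magnitudes inherit the drag-coefficient choice; only signs and
  spatial structure are asserted.
* Reported eddy "vorticity" magnitudes in the motivating observational
  record are several orders above $f$ and are treated as descriptive;
  the package asserts signs, orderings and oracle equivalences only.
* The bloom generator's amplitude is free: no nutrient budget links
  vorticity or EPV to chlorophyll.
* Two-day windows tile from the first time stamp; a different anchor
  shifts composite values by up to one day.
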