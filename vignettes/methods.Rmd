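---
title: "Methods: partitioning, flow assistance and migration phenology from weather-radar profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioning, flow assistance and migration phenology from weather-radar profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aeromig)
```

# Overview

`aeromig` analyses vertical profile time series (VPTS) from weather
surveillance radars in regions where nocturnal bird migration shares the
airspace with large numbers of wind-drifting insects. The pipeline runs

1. **pair** — attach pressure-level atmospheric variables to every altitude
   bin by linear interpolation in time, then altitude;
2. **partition** — split each bin's linear reflectivity into bird and insect
   components from the observed reflectivity-weighted velocity and the local
   wind;
3. **screen** — keep nocturnal, in-season scans and bins moving with the
   seasonal migration direction;
4. **integrate** — convert bird reflectivity into vertically integrated
   density (VID, birds km^-2^) and migration traffic rate (MTR,
   birds km^-1^ h^-1^);
5. **phenology** — aggregate nights and quantify how steady or episodic the
   season was;
6. **acoustics** — pair nightly flight-call rates with radar bird density.

A synthetic-data generator produces all three input streams (VPTS,
atmosphere, call logs) from known ground truth, so each stage is testable by
parameter recovery rather than against an archive.

# The airspeed-mixture partition model

A radar bin's reflectivity-weighted mean ground velocity
$\mathbf{V}_{obs}$ mixes two target classes. Insects drift with the wind
$\mathbf{V}_w$ plus a small self-propulsion $a_i$ oriented downwind
($\hat{w}$); birds are self-propelled at a fixed airspeed $a_b$ along an
unknown heading $\hat{h}$. With bird reflectivity fraction $f$,

$$\mathbf{V}_{obs} = f(\mathbf{V}_w + a_b \hat{h}) +
  (1-f)(\mathbf{V}_w + a_i \hat{w}).$$

Writing $\mathbf{A} = \mathbf{V}_{obs} - \mathbf{V}_w$ and eliminating the
unit vector $\hat{h}$ gives the scalar constraint
$\lVert \mathbf{A} - (1-f)a_i\hat{w} \rVert = f a_b$, i.e. the quadratic

$$f^2(a_i^2 - a_b^2) + 2 f a_i(\mathbf{A}\cdot\hat{w} - a_i) +
  \lVert \mathbf{A} - a_i\hat{w} \rVert^2 = 0 .$$

Because $a_i < a_b$ the parabola opens downward, is non-negative at $f = 0$
and equals $\lVert\mathbf{A}\rVert^2 - a_b^2$ at $f = 1$; whenever the
mixture airspeed $\lVert\mathbf{A}\rVert < a_b$ there is exactly one root in
$[0,1]$ — the larger quadratic root, which `partition_bin()` takes in closed
form. $\lVert\mathbf{A}\rVert \ge a_b$ clamps $f = 1$ and records the misfit
in `residual`. The bird air velocity is then
$\hat{h} = (\mathbf{A} - (1-f)a_i\hat{w})/(f a_b)$, bird reflectivity
$\eta_{bird} = f\,\eta$, heading the compass bearing of $\hat{h}$, and track
the bearing of $\hat{h}a_b + \mathbf{V}_w$.

Numerical and convention choices:

* **Airspeeds** default to $a_b = 8$ m s^-1^ and $a_i = 1$ m s^-1^,
  representative of sustained passerine and insect flight; both are
  arguments of `partition_params()` and the invariants ($f \in [0,1]$,
  reflectivity conservation) hold across $a_i \in [0.5, 3]$,
  $a_b \in [8, 12]$.
* **Calm wind** (speed `< calm_wind_eps`, default 0.5 m s^-1^) leaves the
  downwind direction undefined, so the insect self-propulsion term is
  dropped and the model reduces to $f = \lVert\mathbf{A}\rVert/a_b$.
* **Compass convention** is 0° = north, 90° = east for heading and track,
  computed as $\mathrm{atan2}(u, v)$ in degrees mod 360. A commonly printed
  variant, $90 - (180/\pi)\,\mathrm{atan2}(u, v)$, evaluates to 0° for due
  *east* motion under the conventional argument order; we pin the compass
  convention and note the discrepancy rather than follow the formula
  literally.
* For $\lVert\mathbf{A}\rVert < a_i$ the model legitimately fits a small
  bird fraction with an *upwind* heading; $f$ is therefore monotone in the
  downwind mixture airspeed only from $a_i$ upwards.
* A scalar diagnostic, `partition_scalar()`, interpolates the observed
  airspeed between $a_i$ and $a_b$; it agrees with the vector model in the
  collinear case and is not used by the pipeline.
* `partition_grid_oracle()` is a deliberately brute-force $(f, \theta)$ grid
  scan (Rcpp) used only to validate the closed form; the test suite checks
  $|\Delta f| \le 2\times10^{-3}$ against it wherever the oracle residual is
  below $10^{-3}$ m s^-1^.

# Atmospheric pairing and flow assistance

`pair_weather()` interpolates each grid variable linearly in time between
the bracketing 3-hourly instants at each of 15 pressure levels
(1000–600 hPa), then linearly in altitude using the level geopotential
heights as the vertical coordinate, evaluated at bin centres
(`height + 50` m — bin centres are used for every height-indexed operation,
a symmetric within-bin assumption). Outside the level height span, values
**clamp** to the nearest level rather than extrapolate; inventing lapse
rates below the lowest level risks larger errors than the clamp. The
procedure is exact for fields jointly linear in time and height, which the
tests verify to 1e-9.

Flow assistance follows the fixed-airspeed full-compensation model: with
tailwind component $t$ and crosswind component $c$ of the wind along the
preferred migratory direction,

$$\mathrm{assistance} = t + \sqrt{a^2 - c^2} - a,$$

the ground-speed gain of a bird at airspeed $a$ (default 8 m s^-1^) that
rotates its heading to cancel the crosswind. When $|c| > a$ compensation is
infeasible and the value is **missing** (not floored); downstream covariate
rows with missing tailwind are dropped. The preferred direction itself is
the bird-reflectivity-weighted circular mean track per station and season
(`preferred_direction()`).

The ground-level value of a paired variable (e.g. surface temperature)
comes from the bin whose centre is nearest the station's antenna height,
ties resolving to the lower bin. The collinearity screen drops the
lower-priority member of any covariate pair with $|r| > 0.7$; the default
priority keeps specific humidity over air temperature and vertical motion
(omega) over turbulent kinetic energy, matching the retention outcome the
screen is meant to reproduce. `wind_mad()` gives the mean absolute
wind-speed difference used to validate a modelled wind product against
balloon soundings.

# Screening

* **Season windows** default to Feb 20 – Jun 1 (boreal spring) and
  Aug 1 – Nov 25 (fall), both ends inclusive; a one-day boundary choice is
  negligible for season statistics. Windows are overridable for other
  flyways.
* **Night** means solar elevation below −0.833° (the refraction-corrected
  horizon). Solar geometry uses the standard NOAA low-accuracy algorithm,
  good to ±1–2 min at study latitudes; sunset/sunrise anchor each night key
  (the local calendar date of the most recent sunset).
* **Direction filter**: spring removes bins with track strictly inside
  (90°, 270°); fall removes track strictly below 90° or strictly above
  270°; 90° and 270° are retained in both. The filter is applied to *track*
  in both seasons — the cleaning intent is ground direction — even though
  one conventional phrasing says "headings" for fall; bins with missing
  track pass through flagged.
* **Thinning** selects the scan closest to sunset + 3 h (near the typical
  nightly density peak, safely past dusk bat emergence), ties to the
  earlier scan.
* **Completeness**: nightly mean/CV statistics require more than two weeks
  of continuous data; season traffic totals require a ≥75%-complete night
  series, with >3000 radar volumes flagged near-complete.

# Phenology statistics

Nightly migration traffic is the time integral of MTR with
midpoint-to-midpoint weights clipped to [sunset, sunrise]; MTR is declared
missing for any scan in which an occupied bin lacks velocity, and a night
is gap-flagged when any stretch without usable MTR (edges included) exceeds
`max_gap_h` (default 1 h). Gap-flagged nights still contribute to totals —
gaps are surfaced, not imputed, and no interpolation bridges multi-night
outages.

Season-level statistics:

* **CV** of nightly mean MTR uses the sample (n−1) standard deviation.
* **Bootstrap** mean/CV intervals resample nights with replacement
  (default 10 000 replicates, 95% percentile interval), deterministic given
  a seed.
* **Percent of nights** to capture 50/75/90% of seasonal passage sorts
  nights by traffic *descending* (the "top nights" convention) and reports
  the minimal count as a percent of nights with data. The chronological
  variant is deliberately separate: **core spans** (20–80%, 10–90%) and the
  **peak date** (50% crossing) are date-crossing statistics on the
  cumulative curve. Crossing comparisons carry a 1e-9 relative tolerance so
  exact-fraction ties resolve deterministically.
* The denominator for percent-of-nights is nights *with usable data* inside
  the season window; the completeness rules gate which seasons should be
  reported at all.

# Acoustics

Nightly call rate is total calls divided by recording hours, pooled across
a night's recordings (so splitting a night into files changes nothing);
the fourth-root transform stabilizes variance before modelling. Radar and
acoustic nights pair by inner join on the night key. The radar-acoustic
correlation is reported both for the fourth-root rate (default, matching
the modelling transform) and the raw rate, since either pairing against
bird density is defensible.

# The synthetic generator

`truth_params()` fixes a full scenario; `scenario_preset()` packages three:

* **tropical** (default parameters): weak base wind (2 m s^-1^), a stable
  nocturnal low-level jet toward 225° at 8 m s^-1^ centred at 1750 m
  (Gaussian in altitude, width 500 m) with mild nightly AR(1) variation,
  and a small night-effect sd (`night_sigma = 0.4`) — steady passage. The
  jet and base-wind direction reflect the south-westward low-level jet
  regime of the study region; fall birds (preferred heading 165°) receive
  partial support from it.
* **temperate**: strong, variable winds and `night_sigma = 1.2` — episodic
  passage concentrated in few nights.
* **noisefree**: the tropical scenario with zero velocity noise and no
  heading scatter, for exact forward–inverse checks.

Per night, true passage is a Gaussian seasonal curve (peak day, sd 15 d)
times mean-corrected lognormal night effects
$\mathrm{LogNormal}(-\sigma^2/2, \sigma)$, normalized so the season total
equals `total_passage` exactly — the mean correction keeps expected totals
$\sigma$-invariant, isolating `night_sigma` as the episodicity knob. Bird
density is allocated over altitude as
$\exp(-h/\mathrm{scale})\exp(\kappa_w\,\mathrm{tailwind}(h))$ and scaled so
each night's time-integrated bird MTR equals its true passage exactly;
bird air velocity is the fixed airspeed along a (von Mises-scattered)
preferred heading; insect reflectivity is an exponentially height-decaying
background with a within-night modulation, drifting downwind at 1 m s^-1^;
the observed bin velocity is the exact reflectivity-weighted mixture plus
isotropic Gaussian noise (per-component sd `noise_v`). Default totals
(50 000 birds km^-1^ per season against an insect background of
5 cm^2^ km^-3^) put bird and insect signals at comparable magnitude near
peak passage with insect dominance off-peak, the balance described for
tropical radar data. Call counts are Poisson with rate proportional to
bird density weighted by $\exp(-h/h_{det})$, so lower flight means more
calls; whole recorder-nights drop out at a configured probability.

What the generator does **not** emulate: radar beam geometry and
range-dependent sampling, clutter and anomalous propagation, rain,
signal-strength-dependent velocity availability (real profiles lose
velocity when signal is weak; synthetic bins always carry it unless
withheld), bats, and within-night departure/landing waves. Passing
recovery tests therefore demonstrates the correctness of the estimators
under the model's own assumptions, not robustness to radar artefacts.

# Problem sizes and determinism

The packaged scenarios span one 117-night fall season at one station, 30
altitude bins, 30-min scans (~84 000 bins) — small enough that the full
pipeline, the grid-oracle comparison at its native resolution
(1001 × 3600 grid on 1000 draws), and a 200 × 2000 bootstrap calibration
all run comfortably on one CPU. All randomness flows from a single integer
seed: generation, bootstrap and pipeline runs are bit-reproducible, and the
season JSON embeds the seed and a config hash.

# Known limitations

* The partition is ill-conditioned where the bird fraction is near zero:
  velocity noise maps one-sidedly into small positive $f$, so
  insect-dominated bins carry a positive bias of order
  $\lVert\varepsilon\rVert / (a_b - a_i)$.
* MTR uses the ground speed of the partitioned bird component; where wind
  data are clamped (below the lowest pressure level) the bird air velocity
  inherits the clamp.
* Night keying trusts the configured civil UTC offset; stations spanning
  unusual time zones need an explicit `utc_offset`.
* The collinearity screen is greedy and priority-ordered — deterministic,
  but not the globally minimal drop set.
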