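# aeromig

Radar aeroecology of nocturnal bird migration for airspaces where insects
dominate the biological radar signal.

Weather surveillance radars see everything that flies. At temperate
latitudes most nocturnal biological echo in migration season is birds; in
the tropics, wind-drifting insects frequently match or exceed the bird
signal, so bird quantities cannot be read off a vertical profile directly.
`aeromig` is an analysis pipeline for vertical profile time series
(VPTS: 100 m altitude bins of linear reflectivity `eta` and
reflectivity-weighted mean velocity) that

- pairs every altitude bin with pressure-level atmospheric data (wind,
  temperature, humidity, vertical motion, TKE) by linear interpolation in
  time then altitude;
- **partitions each bin's echo into bird and insect components by
  airspeed**: insects move with the wind plus a fixed 1 m s⁻¹ downwind
  self-propulsion, birds are self-propelled at a fixed 8 m s⁻¹ along an
  unknown heading. With `A = V_obs − V_wind` the bird fraction `f` solves

  ```
  f²(a_i² − a_b²) + 2 f a_i (A·ŵ − a_i) + |A − a_i ŵ|² = 0 ,
  ```

  taken in closed form (unique root in [0, 1] whenever `|A| < a_b`), giving
  bird reflectivity `η_bird = f·η`, heading, and track;
- computes flow assistance along the seasonally preferred migratory
  direction at fixed airspeed with full crosswind compensation
  (`t + sqrt(a² − c²) − a`, missing when `|c| > a`);
- screens scans to night (solar elevation < −0.833°), migration season
  (Feb 20 – Jun 1, Aug 1 – Nov 25) and season-consistent movement
  directions, and thins to a reference scan at sunset + 3 h;
- integrates bird reflectivity (radar cross section 11 cm²) into vertically
  integrated density (**VID**, birds km⁻²) and migration traffic rate
  (**MTR**, birds km⁻¹ h⁻¹), and accumulates nightly migration traffic
  (**MT**, birds km⁻¹);
- quantifies seasonal **episodicity**: CV of nightly MTR with 10 000-replicate
  bootstrap CIs, the percent of nights capturing 50/75/90% of seasonal
  passage, core-season 20–80% and 10–90% spans, and the 50%-passage peak
  date;
- pairs radar nights with nocturnal **flight-call** recording logs (calls
  per hour, fourth-root transformed) and reports their correlation with
  bird density.

A synthetic-data generator (`scenario_preset()`, `gen_*()`) produces VPTS,
atmosphere and call-log inputs from known ground truth — a Gaussian
seasonal passage curve with a tunable lognormal night effect, a nocturnal
south-westward low-level jet centred near 1750 m, exact bird/insect
velocity mixtures and height-dependent call detectability — so every stage
of the pipeline is verified by parameter recovery. See the methods
vignette (`vignettes/methods.Rmd`) for the model details and design
choices.

## Worked example

```r
library(aeromig)
st  <- station_config("BAR", 6.9325, -73.7625, 80)     # Magdalena Valley
cfg <- pipeline_config(st, "demo", preset = "tropical", seed = 42)
cmd_simulate(cfg)   # writes vpts.csv, atmosphere.csv, calls.csv + truth manifest
cmd_run(cfg)        # pair -> partition -> screen -> integrate -> phenology
cmd_report("demo")  # renders demo/report.md
```

The report for this seed reads:

```
## 2019 fall

- nights with data: 117
- total migration traffic: 50822 birds/km
- mean nightly MTR: 36.3 [28.6, 44.7] birds/km/h
- CV of nightly MTR: 1.21 [1.04, 1.38]
- % of nights for 50/75/90% of passage: 15.4 / 28.2 / 41.9
- core spans 20-80% / 10-90%: 25 / 38 days
- peak (50%-passage) date: 2019-10-05
- preferred direction: 183 deg

## Acoustics
- paired nights: 104
- Pearson r (fourth-root rate vs VID): 0.819
```

Reading it: the season carried ~50 800 birds across each km of transect;
half of that passage fell on 15% of nights (a fairly steady, tropical-style
season — an episodic temperate-style season concentrates half its passage
on well under 10% of nights); the middle 60% of passage took 25 days; and
nightly flight-call rates track radar bird density across the 104 nights
when both sensors ran. Bracketed ranges are 95% bootstrap CIs over nights.

The same stages are callable individually (`read_vpts()`,
`pair_weather()`, `partition_series()`, `integrate_profile()`,
`nightly_summaries()`, `season_phenology()`, …) on your own VPTS-CSV
(`radar,datetime,height,eta,u,v`) and atmosphere tables
(`time,level_hPa,gph_m,u,v,temp_K,shum,omega,tke`).

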