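# cosmoskit

Simulation and kinetic analysis of colocalization single-molecule
spectroscopy (CoSMoS) binding data in R.

In a CoSMoS experiment, RNA molecules are tethered to a microscope slide and
dye-labeled protein complexes — here spliceosomal subcomplexes (U1, U2, U5)
binding pre-mRNA splice sites — are watched arriving at and departing from
individual molecules under alternating-excitation TIRF imaging. The raw
outcome per surface location is a binary binding/absence time series; the
science lives in the statistics computed from those series. `cosmoskit` is
for experimentalists and method developers who need those statistics with
defensible uncertainties, and a fully synthetic test bed to validate them.

## What it computes

For an interval table (location, start, end, censoring flags):

* **Cumulative dwell-time distributions** — mean events per location with
  dwell ≥ *t* (`cumulative_dwell_distribution()`),
* **RNA-specific binding frequencies** *f* = *f*(RNA) − *f*(no-RNA), total
  and split at a dwell threshold (50 s by default), with bootstrap standard
  errors over locations (`specific_binding_frequency()`,
  `frequency_by_duration_class()`),
* **Background-corrected specific occupancy**
  (*f*<sub>m</sub> − *f*<sub>c</sub>) / (1 − *f*<sub>c</sub>), where
  *f*<sub>m</sub> and *f*<sub>c</sub> are the fractions of observed time a
  spot is present at RNA and control locations
  (`specific_occupancy()`, `occupancy_from_table()`),
* **First-binding kinetics** — maximum-likelihood fit of the
  background-corrected single-exponential model
  *P*(*t*) = *A*<sub>f</sub>(1 − e^−(k_f + k_bg)t) +
  (1 − *A*<sub>f</sub>)(1 − e^−k_bg·t), censoring-aware
  (`fit_first_binding()`),
* **Rastergrams** and percent-bound (`build_rastergram()`),
* **Intron-retention curves** for two-color single-molecule splicing assays
  (`intron_retention_curve()`),
* **The 5′SS synergy ratio** *R* = *f*<sub>both</sub> /
  (*f*<sub>up</sub> + *f*<sub>down</sub>), the test of whether two flanking
  5′ splice sites recruit U2 additively (*R* = 1) or synergistically
  (*R* > 1), with a joint bootstrap confidence interval
  (`synergy_ratio()`).

The synthetic-data generator (`simulate_panel()` and friends) emulates the
experimental design end to end: several RNA constructs plus no-RNA controls
co-deposited on one surface, alternating-renewal binding with
exponential-mixture dwells, nonspecific surface binding everywhere, partial
dye labeling, photobleaching clocked on green-excitation exposure, and a
frame schedule of 100 × 1 s green frames alternating with one red frame
over 2,400 s. Ground truth is retained so every estimator can be checked by
parameter recovery. An optional image-level layer
(`render_image_stack()`, `detect_spots()`, `estimate_drift()`,
`fit_channel_mapping()`, `colocalize_locations()`) renders synthetic TIRF
movies and recovers binding through spot detection, fiducial-based drift
correction, and channel registration.

## Worked example

Simulate the four-construct double-5′SS panel (both flanking 5′ splice
sites functional, upstream only, downstream only, neither) probed with
labeled U2, and recover the synergy:

```r
library(cosmoskit)

sched  <- acquisition_schedule()          # 2,400 s, 100 green + 1 red frames
params <- kinetic_params("U2")            # defaults: synergy factor 3, 60% labeled
layout <- build_slide_layout(panel_double_5ss(), counts = rep(100, 4),
                             n_controls = 100, seed = 7)
panel  <- simulate_panel(layout, params, sched, seed = 7)
tab    <- panel_intervals(panel)

d_rna  <- cumulative_dwell_distribution(tab, "5i3e5")
d_ctrl <- cumulative_dwell_distribution(tab, "no_RNA")
specific_binding_frequency(d_rna, d_ctrl, B = 2000, seed = 7)
occupancy_from_table(tab, "5i3e5", B = 2000, seed = 7)
build_rastergram(tab, "5i3e5")
synergy_ratio(tab, B = 2000, seed = 7)
```

```
<frequency_result> 5i3e5 (all): 3.13 ± 0.24 events/location (RNA 3.28 - ctrl 0.15; N=100)
<occupancy_result> 5i3e5: 0.02566 ± 0.0029 (f_m=0.02584, f_c=0.0001893, N=100)
<rastergram> 5i3e5: 100 molecules, 82.0% ± 3.8% bound
<synergy_result> R = 2.98 ± 0.45 (CI 2.3-4.01); f = [5i3e5: 3.13, 5i3eX: 0.54, Xi3e5: 0.51] events/location
```

Reading the output: each RNA with both 5′SS collected 3.13 ± 0.24 U2
binding events above background over the 2,400 s experiment and was
occupied by labeled U2 2.6% of the observed time; 82% of molecules bound at
least once. The specific frequency with both sites is ~3× the *sum* of the
two single-site frequencies (R = 2.98, CI 2.3–4.0), recovering the
simulated synergy factor of 3 and excluding additivity (R = 1).

`run_simulated_experiment()` wraps the whole chain behind a YAML config
(see `inst/extdata/example-config.yaml`) and writes tidy CSVs plus a JSON
summary; `analyze_intervals()` applies the same statistics to interval
tables read from disk — the package's documented CSV dialect
(`write_intervals()` / `read_intervals()`, schema in
`inst/extdata/intervals-schema.yaml`) or MAT-format interval containers via
the best-effort `read_imscroll_intervals()`. A thin command-line wrapper
lives at `inst/cli/cosmoskit.R` (`simulate`, `analyze`, `report`
subcommands).

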