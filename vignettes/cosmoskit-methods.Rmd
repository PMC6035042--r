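---
title: "Models and methods behind cosmoskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cosmoskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cosmoskit` analyzes colocalization single-molecule spectroscopy (CoSMoS)
experiments: dye-labeled spliceosomal subcomplexes binding to individual
surface-tethered pre-mRNA molecules under alternating-excitation TIRF
imaging. This vignette is the package's account of the models it
implements, the choices made where the design was genuinely open, and what
its synthetic tests do and do not establish about real data.

## The observation model

An experiment is a frame schedule (`acquisition_schedule()`): by default
one-second frames, 100 green-excitation frames alternating with a single
red frame, 2,400 s total. The green channel reports binding of the labeled
subcomplex; red frames exist to re-locate the tethered RNAs and carry no
binding information. Red frames are therefore treated as *missing data*,
never as absence: a binding run interrupted only by a red frame is bridged
into one interval, and occupancy denominators count only observed green
time. This missing-not-absent rule is a deliberate design decision — the
alternative (treating the gap as absence) would split roughly one event in
twenty purely by the schedule.

Intervals are closed on the left and open on the right, in frame units
converted to seconds, so `dwell = end - start` with no off-by-one
ambiguity. An interval touching the start or end of the observation is
flagged left-/right-censored; its true dwell exceeds the observed span.
Censored dwells enter occupancy fully, and enter dwell distributions at
their observed value only (they are never extrapolated). How censored
dwells should enter cumulative dwell distributions is not settled by
convention; this minimal treatment is unbiased for the survival values it
does report and is configurable (`include_censored`).

## The kinetic model of the simulator

Binding at one location is the superposition of two independent
alternating-renewal processes:

* **specific binding**: exponential waiting times at rate $k_a$ between a
  departure and the next arrival (memoryless association; the site is
  blocked while occupied), dwells drawn from an exponential mixture with a
  short-lived class (seconds) and a long-lived class (around a minute);
* **nonspecific surface binding**: the same construction at every location
  — including no-RNA controls — with a small rate and short exponential
  dwells.

Each event is dye-labeled independently with probability
`labeling_fraction`; only labeled events are visible. A labeled fluorophore
photobleaches after an exponential amount of *cumulative green-excitation
exposure* (not wall time), truncating the visible dwell without ending the
underlying binding event. Bleaching accrues only during green frames,
matching the alternating-excitation design. A fraction `frac_active` of RNA
locations is competent for specific binding at all; the rest show only
nonspecific events, which is what the amplitude of the first-binding model
estimates.

The memoryless alternating-renewal scheme is deliberately *not* a
multi-state spliceosome assembly model. The kinetic scheme linking U1
occupancy to U2 arrival (strictly ordered vs dynamically gated) is not
identified by the statistics this package computes, so the simulator makes
the weakest assumption sufficient to generate every statistic the analysis
layer estimates. No claim about splicing chemistry is encoded.

**Splice-site logic.** Constructs are abstract flag sets (functional
upstream 5'SS, functional downstream 5'SS, intact branch-site/3'SS block,
spliceable). U1 associates at `k_assoc_specific` per functional 5'SS. U2
(and U5) require the intact 3'SS block plus at least one functional 5'SS;
each functional site contributes `k_assoc_specific`, and when both flanking
sites are present the summed rate is multiplied by `synergy_factor`. Under
this encoding, with equal single-site rates, the frequency ratio
$R = f_\mathrm{both} / (f_\mathrm{up} + f_\mathrm{down})$ recovers
`synergy_factor` exactly in the low-occupancy limit; multiplying the
*summed* rate (rather than the per-site rate) is what makes $R = 1$ the
additivity null.

**Discretization.** A frame is marked present iff a labeled, unbleached
event overlaps at least 50% of that frame. The half-frame rule is a
concrete, testable choice; events shorter than half a frame are invisible,
and an event of duration $d < 1$ frame is visible with probability $\max(0,
\min(d, 1))$-ish depending on phase. This is the main reason recovery tests
compare estimators against the simulator's *realized* visible ground truth
rather than against closed-form event counts; the renewal-theory
expectation is asserted separately at the event level, before
discretization.

## Estimators

All estimators operate on an `intervals_table`; every location appears in
its metadata even with zero events, which keeps per-location frequencies
unbiased.

* **Cumulative dwell distribution** $V(t) = \#\{\text{dwell} \ge t\}/N$,
  evaluated on a log-spaced grid.
* **Specific frequency** $f = V_\mathrm{RNA}(0) - V_\mathrm{ctrl}(0)$,
  optionally per second of observed time. Reporting both per-experiment and
  per-second units is intentional: figures of merit in this field are
  usually per-molecule totals over the experiment, while ratios of
  frequency to occupancy only have dimension 1/time in per-second units.
  Both conventions are computed and labeled.
* **Specific occupancy** $(f_m - f_c)/(1 - f_c)$, $f$ being the fraction of
  observed green time a spot is present, averaged over locations. The value
  is reported unclamped (it may be slightly negative by sampling noise) and
  underestimates true occupancy by roughly the labeling fraction.
* **First-binding model** $P(t) = A_f(1 - e^{-(k_f + k_{bg})t}) +
  (1 - A_f)(1 - e^{-k_{bg} t})$. $k_{bg}$ is estimated from control
  locations by the censored-exponential MLE (events ÷ total waiting time)
  and held fixed; $A_f$ and $k_f$ are then fit by maximum likelihood with
  never-bound locations contributing survival terms $1 - P(t)$. Treating
  censored locations this way (rather than discarding them) is required
  for $A_f$ to estimate the active fraction. Parameters are optimized on
  logit/log scales; standard errors come from the observed information,
  with a per-parameter fallback when the joint Hessian degenerates (which
  happens when $A_f$ saturates at 1).
* **Synergy ratio** $R$ with a joint bootstrap: locations of all three RNA
  groups and of the controls are resampled together, $R$ recomputed per
  resample, and a percentile interval reported. Resamples with
  non-positive denominators are dropped (with a warning if they exceed half
  the draws).
* **Bootstrap errors** always resample *surface locations*, never
  individual events — locations are the independent experimental unit;
  events within a location are autocorrelated through blocking and
  molecule-specific heterogeneity. The default is 2,000 resamples.
* **Intron retention** conditions on molecules retaining exon-dye
  fluorescence through the full experiment — removing RNAs lost to
  surface detachment or degradation from the denominator entirely — then
  reports the fraction of that subset retaining intron dye over time, with
  binomial errors.
* **Rastergrams** sort molecules by first-binding time, latest to earliest,
  never-bound molecules above all bound ones; every sort in the package
  breaks ties by `location_id`, so outputs are invariant to input order.

## Default parameters

Chosen once as the package's study conditions and not revisited:

| parameter | default | why |
|---|---|---|
| schedule | 1 s frames, 100 green + 1 red, 2,400 s | standard alternating-excitation design |
| labeling fraction | U1 0.30, U2 0.60, U5 0.50 | measured dye-carrying fractions of the tagged pools |
| U2 `k_assoc_specific` | 5e-4 /s per site | a few specific events per RNA per experiment, in the low-occupancy regime ($k\bar\tau \approx 0.01$) where the synergy ratio is an unbiased estimate of the synergy factor |
| U2 dwell mixture | 0.7 @ 5 s + 0.3 @ 60 s | short/long classes straddling the 50 s split |
| nonspecific | 2e-4 /s, mean 2.5 s | sparse, short-lived control-location events |
| bleach rate | 2e-4 per green-second | mild truncation of minute-scale dwells |
| `frac_active` | 0.75 | typical fraction of competent surface molecules |
| `synergy_factor` | 3 | the effect size the synergy analysis must resolve |
| intron loss | lag 600 s + 1.1e-4 /s; intron bleach 4.6e-6 /s; exon loss 5e-5 /s | emulates ≈18% ATP-dependent loss vs ≈1% bleaching-only loss in 2,400 s |

Problem sizes used by the test suite and acceptance script — 100 locations
per construct, 50 replicates for coverage checks, a 10 µm / 301 s scene for
the image-level round trip — are the package's chosen benchmark sizes;
estimates stabilize well below them.

## The image-level layer

The forward model renders every visible fluorophore as a symmetric 2-D
Gaussian integrated over pixels (so summed signal equals amplitude), on a
constant background with Poisson shot noise and Gaussian read noise, plus
bright persistent fiducial beads and an optional stage-drift trajectory.
Coordinates are 0-based, pixel-center, x along columns — stated once and
used everywhere.

Detection is matched filtering with a unit-L2-norm Gaussian kernel (white
noise keeps its SD through the filter, so the threshold is in honest noise
SDs), local maxima, and centroid refinement; frames are averaged in a
5-frame sliding window first. Drift is the mean per-frame fiducial
displacement, interpolated across gaps; channel registration is a
least-squares affine fit. Colocalization binds a location when a detected
spot lies within 1.5–2 PSF sigmas after drift correction, nearest location
winning contested spots. Detection thresholds and the colocalization radius
are calibrated on synthetic data only; no claim is made that these defaults
transfer to real movies.

One practical constraint surfaced by testing: locations within the centroid
refinement window of a 6×-brighter fiducial bead get their positions
dragged toward the bead and are lost to colocalization. Real slide layouts
avoid this by construction; the synthetic scenes therefore keep tethered
molecules in an inner box away from the border beads.

## What the tests show — and what they cannot

Every statistic is validated by parameter recovery against retained ground
truth: coverage of bootstrap intervals across 50 replicate panels,
zero-bias at the null (RNA locations parameterized identically to
controls), closed-form checks (renewal event counts, exponential survival,
bootstrap vs $\sigma/\sqrt{n}$), and an end-to-end image-to-statistics
round trip. The synthetic generator, however, emulates *idealized* data:
stationary rates, exponential mixtures, perfect spot registration, constant
background, no RNA conformational heterogeneity, no dye blinking, no
spot-detection dropouts beyond noise. Passing tests establish that the
estimators are correct for the model class they assume — not that the model
class captures any particular real extract. The first-binding metric is the
most robust of the set on real data (it is insensitive to dropout), which
is why it is fit with full censoring support.

## Known limitations

* No hidden-Markov or multi-state dwell modeling; dwell mixtures are
  estimated only through survival curves and duration classes.
* The MAT-container reader is best-effort for foreign files: field layouts
  it does not recognize raise an unsupported-format error rather than
  guessing silently, and heuristically mapped files are flagged with
  warnings.
* `fit_first_binding` fixes the background rate at its control-set MLE
  rather than fitting jointly; with very few control events this
  understates the uncertainty in $k_f$ slightly.
* The frequency/occupancy ratio inherits the units ambiguity discussed
  above; both conventions are emitted, and consumers must pick one and say
  so.
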