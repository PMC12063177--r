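---
title: "Models and methods behind poreCage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind poreCage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreCage)
```

poreCage analyzes single-channel current recordings from
peptide-functionalized nanopores that capture and *cage* a multivalent
target protein, and it ships a synthetic trace generator that reproduces
the statistical structure those analyses assume. This vignette is the
package's own account of the models, the parameters that matter, the
numerical choices, and what the passing test suite does and does not
demonstrate.

## The signal model

A pore of conductance $G$ (nS) under applied potential $V$ (mV) passes an
open-pore current $I_O = G\,V$ (pA). A protein entering the pore blocks a
protein-specific fraction of that current; we work throughout with the
*excluded current*

$$ I_{EX} = \frac{I_O - I_B}{I_O} \times 100\,\%, $$

which is invariant to the absolute current scale and therefore comparable
across pores and voltages. Traces are stored signed, exactly as recorded
(negative at negative potential); `normalizePolarity()` flips each
protocol segment by the sign of its own voltage before any statistics are
taken, so downstream code sees positive magnitudes.

Two recording modes are modelled. *Gap-free*: one voltage throughout.
*Sweeps*: a cyclic program — by default +100 mV for 200 ms followed by
−75 mV for 2 s — whose brief positive pulse ejects long-dwelling,
non-caged proteins; a 10 min recording holds 272 full 2.2 s sweeps plus a
remainder shorter than one period, which is excluded from analysis.
Only measuring-voltage ("analysis") segments contribute samples to
baselines, histograms and event detection.

## Multivalent caging as a birth–death chain

A target with $n$ binding pockets (4 for tetrameric streptavidin) trapped
over a pore displaying $T$ tags (10 for a didecamer, one per subunit)
occupies states $m = 0 \dots n$ bound tags. `OccupancyModel` uses
mass-action propensities

$$ m \to m+1:\; k_b (n-m)(T-m), \qquad
   m \to m-1:\; k_u \, c \, m, $$

with $c \ge 1$ a *trans*-side competitor factor (a competing ligand such
as biotin raises the per-bond off-rate), and escape from the pore allowed
only from the fully unbound state $m = 0$ at rate $k_{esc}$ — trapped
proteins are observed to leave from the deepest current level. Each state
has its own excluded-current level, maximal at $m=0$ (the unbound analyte
sits deepest) and non-increasing in $m$; with only the two extremes known
experimentally, the default ladder is linear between `depthMaxPct` and
`depthMinPct`. Hence a tetravalent target shows $n+1 = 5$ discrete
levels and a monovalent one shows 2 (`predictedLevelCount()`), and the
*blockade bandwidth* $\Delta I_{EX} = I_{EX,max} - I_{EX,min}$ is the
reproducible fingerprint even when intermediate levels vary.

The stationary law of the chain (escape ignored) is the closed-form
birth–death product implemented in `stationaryOccupancy()` and
cross-checked in the tests against long-run chain simulation.

**Defaults.** The in-pore bond rates are not experimentally determined;
the defaults are illustrative and chosen once: $k_u = 1\,s^{-1}$ and
$k_b/k_u = 0.12$, the ratio at which the stationary distribution puts
equal mass ($\approx 5\%$) on both extreme states of the $4 \times 10$
ladder — emulating recordings in which all five peaks, including the
outer ones used for the bandwidth fit, are resolvable. The default
$k_{esc} = 0.01\,s^{-1}$ yields minutes-scale caging
(effective escape rate $k_{esc}\,\pi_0 \approx 5\times10^{-4}\,s^{-1}$);
a competitor raises it into the regime where repeated events are
observed within one recording. Default level extremes 48.0 % and 32.6 %
($\Delta I_{EX} = 15.4$) correspond to the long-linker (70-residue)
construct regime.

## The synthetic generator

`simulateTrace()` renders, per `SimulationConfig`:

- a signed conductance baseline per protocol segment plus i.i.d. Gaussian
  noise (default sd 2 pA). $1/f$ and gating noise are out of scope: all
  downstream statistics use mean levels, not noise spectra;
- captures as a Poisson process at
  $\lambda = k_{on} \cdot [\mathrm{POI}]$ per species (with
  $k_{on}$ in µM⁻¹s⁻¹ and concentration in nM), restricted to
  measuring-voltage time and *thinned to single occupancy* — while one
  analyte resides in the pore no new capture can start, implemented
  exactly by pausing the exponential arrival clock (memorylessness makes
  this equivalent to thinning);
- the *entropic gate* as a per-species multiplicative attenuation of
  $\lambda$ in $(0, 1]$;
- non-caged species as square blockades at a configured depth (per-event
  Gaussian jitter) with exponential dwell, ejected instantly by voltage
  flips (such events are flagged truncated in the ground truth);
- caged species as occupancy-model blockades that persist across voltage
  flips and end only by escape from $m=0$, with the full occupancy path
  recorded.

All randomness flows from the single seed in the config; simulation is
bit-reproducible. The ground-truth event table uses the same schema as
the detector output, so detector/truth agreement can be scored by
interval overlap.

What the generator deliberately does **not** emulate: amplifier and
Bessel-filter dynamics, capacitive transients at voltage steps, $1/f$ and
conformational gating noise, baseline drift, and correlated noise within
blockades. Passing tests therefore demonstrate correctness of the
analysis chain under the stated statistical model — they do not certify
performance on recordings whose noise violates it.

## Preprocessing

`gaussianLowpass()` implements the standard software Gaussian filter with
the −3 dB convention: $|H(f)| = e^{-2\pi^2\sigma_t^2 f^2}$ equals
$1/\sqrt 2$ at the cutoff, giving $\sigma_t = 0.1325/f_c$. The kernel is
truncated at $\pm 4\sigma$ (amplitude error $<10^{-4}$), normalized to
unit DC gain, and applied zero-phase by reflect-padded FFT convolution;
the FFT length is zero-padded to the next 2–3–5–smooth integer, since
mixed-radix transforms degrade badly on lengths with large prime factors.
Typical cutoffs are 500 Hz (caged-level analysis) and 2000 Hz (fast
events).

## Event detection

`estimateBaseline()` fits a Gaussian to the *highest-current mode* of the
all-point histogram (bin 0.5 pA) of the measuring-voltage samples — not
the global mean, which a half-blocked trace would corrupt. When the pore
is caged nearly continuously the open-pore mode can vanish entirely; the
correct procedure then, as in practice, is to take $I_O$ from the blank
recorded before analyte addition and pass it to `detectEvents()`
directly.

Idealization uses two thresholds with hysteresis: an event opens when the
current falls below `openFraction` (default 0.90) of $I_O$ and closes
when it recovers above `closeFraction` (default 0.95). The 5 % band
prevents noise from splitting one blockade; the 10 % opening depth keeps
even shallow linker blockades ($I_{EX} < 10\%$) detectable after 2 kHz
filtering while sitting several noise standard deviations away from
a typical baseline. Events shorter than `minDwellS` (default 5 samples)
are discarded. Per event the detector reports mean blocked current,
dwell, interevent gap, excluded current, and a truncation flag for events
abutting a segment boundary or recording edge.

For sweep protocols, detection runs per measuring segment, and blockades
that touch the end of one segment and the start of the next are merged
into a single wall-clock event (`mergeAcrossSweeps`): this reconstructs
caged blockades that survive the voltage flip, including the number of
sweeps spanned. A blockade whose escape happens to fall inside a flip
segment is flagged truncated; because exponential dwells are memoryless,
the phase of the endpoint within the sweep cycle is asymptotically
independent of the dwell length, so excluding these censored dwells from
dwell fits does not bias the estimate.

The classification gate (`gateEvents()`) selects events inside
$\mu \pm 2\sigma$ windows on $I_{EX}$ *and* on log dwell. Dwell
distributions are exponential-tailed, so a two-sided window is taken on
the log scale, where the acceptance probability for an on-target
population with independent Gaussian margins is $0.954^2 \approx 91\%$
(verified by Monte Carlo in the tests).

## Caged-level profiling

`allpointProfile()` histograms a window — canonically exactly 60 s — at
0.1 pA resolution and converts bins to the $I_{EX}$ axis using the blank
$I_O$; for sweep traces, only measuring-voltage samples enter, since flip
segments sit on a different baseline. Long caged blockades are tiled
into 60 s windows and per-window $\Delta I_{EX}$ values averaged, which
mirrors replicate reporting across pores.

Peak handling has two deliberately different prominence thresholds on the
smoothed histogram (Gaussian smoothing, sd 3 bins), both relative to the
tallest non-baseline mode and both excluding the open-pore mode (any mode
within 3 of its own standard deviations of $I_{EX}=0$):

- `countLevels()` — the discrete level census — requires 5 %
  topographic prominence, a conservative census that resists noise bumps;
- `fitOuterPeaks()` — the bandwidth measurement — uses 2 %, because the
  extreme occupancy states are systematically the least-populated rungs
  of the ladder; requiring census-level prominence would intermittently
  drop a real outer level and bias $\Delta I_{EX}$ low.

Gaussians are then fitted locally (Levenberg–Marquardt, with weighted
moments as fallback) to the raw histogram around the outermost modes;
their means are $I_{EX,min}$ and $I_{EX,max}$. Degenerate cases are
explicit: one blocked mode gives $\Delta I_{EX} = 0$ with a degeneracy
flag; a profile with only the open-pore mode is an error.

## Kinetics

Dwell and interevent constants come from the cumulative-histogram
exponential fit classic to single-channel work
(`fitExponentialCumulative()`: least squares of
$N(t) = N_{tot}(1-e^{-t/\tau})$ over a 0–500 ms window, requiring at
least 150 events). For fewer events the pipeline uses the arithmetic
mean of uncensored dwells, which is the exponential maximum-likelihood
estimator. The geometric mean (`logMeanDwell()`) is also provided as a
robust descriptive statistic for small skewed samples, but it is *not*
used for rate estimation: for exponential dwells
$\exp(\mathbb E[\ln X]) = \tau e^{-\gamma} \approx 0.561\,\tau$
(Euler–Mascheroni $\gamma$), so $1/\text{geometric mean}$ would
overestimate $k_{off}$ by a factor of 1.78.

Capture frequency normalizes event counts by *target-free* recording
time. Two estimators are implemented:

- `captureFrequencyGapfree()` — the exact form,
  $n / (\text{analyzed time} - \text{target-occupied time})$; for sweep
  protocols the pipeline applies it to measuring-segment time with the
  occupied time computed from event/segment overlaps
  (`sweepOccupancy()`);
- `captureFrequencySweeps()` — the sweep-counting discretization,
  $n / (2\,\mathrm s \times \#\text{sweeps without target})$, with
  multi-sweep events counted once and every sweep they touch excluded
  from the denominator.

The sweep-counting form discards the target-free remainder of partially
occupied sweeps from its denominator while keeping events from those
sweeps in its numerator, so it overestimates the rate once occupancy is
appreciable — at $\lambda\tau \approx 1$ (25 nM at the default rates) by
roughly 50 %. Both forms agree in the low-occupancy limit; the pipeline
and the titration analysis use the exact form.

`analyzeTitration()` aggregates per-run capture frequencies and pooled
uncensored dwells per concentration, then fits
$f_C = k_{on} [\mathrm{POI}]$ by *unweighted* least squares through the
origin (`fitKon()`; inverse-variance weighting is available but
discouraged when the per-point standard deviations rest on a handful of
replicate pores, where a degenerate replicate sd can dominate the fit)
and $k_{off}$ as the inverse-variance weighted mean of per-concentration
release frequencies (`fitKoff()` — the "slope constrained to zero"
regression). `bindingConstant()` composes
$K_D = k_{off}/k_{on}$, reported in nM; the uncertainty uses first-order
propagation,
$(\sigma_K/K)^2 = (\sigma_{k_{off}}/k_{off})^2 +
(\sigma_{k_{on}}/k_{on})^2$.

## Selectivity and fingerprint classification

`fitMixturePeaks()` fits a sum of Gaussians to the per-event $I_{EX}$
histogram (component means seeded at expected depths when known) and
integrates each fitted curve to an area in event counts,
$A\,\sigma\sqrt{2\pi}/\text{binwidth}$. The default bin width follows
the Freedman–Diaconis rule bounded to $[0.5, 5]$ %: sparse gated
recordings (tens of events) need wider bins for a stable area, where a
fixed 1 % binning makes the fitted area essentially unconstrained.
`foldReduction()` then ratios the areas of the same protein between a
reference and a gated pore over equal analysis durations (enforce by
truncating to the shorter recording), and `backgroundFraction()` reports
the target-like event frequency without analyte as a fraction of the
frequency with analyte.

`classifyFingerprints()` codifies the manual identification of a caged
target among background blockades. An event is a target when **all**
criteria hold: maximum depth and bandwidth inside calibration windows
(defaults from the long-linker statistics: $48 \pm 7\%$ and
$15 \pm 6\ \Delta\%$, i.e. $\mu \pm 2\sigma$-style windows), duration of
at least 10 s, and at least 3 discrete levels. The per-event inputs come
from `eventLevelMetrics()`, which profiles each event's own window (up to
60 s). On a simulated serum-like background (four fast square-blockade
species behind the gate plus a caged target) the classifier achieves
≥ 90 % sensitivity on qualifying target events and ≥ 95 % specificity
in the seeded suite — an internal benchmark under the generator's
assumptions, not a claim about any particular real sample.

## Numerical and edge-case conventions

- Time in seconds, current in pA, voltage in mV, rates in s⁻¹
  ($k_{on}$ in µM⁻¹s⁻¹, $K_D$ in nM); sample indices 0-based,
  ranges half-open.
- Segment boundaries snap to `round(t · rate)`; a recording may run on
  for less than one sweep period past the last full repeat, and that
  remainder is excluded from segmentation and analysis.
- Histogram fits fall back to weighted moments when the nonlinear
  optimizer fails; peak half-windows extend to half the distance to the
  nearest neighbouring peak.
- Event tables are validated containers: time-ordered, non-overlapping,
  positive dwells; files round-trip through TSV with 10 significant
  digits, traces through CSV with 17 (exact for doubles).
- Degenerate inputs raise errors or flags rather than silent numbers:
  constant traces (baseline), all-equal durations (exponential fit),
  single blocked mode ($\Delta I_{EX} = 0$ + flag), zero gated AUC
  (infinite fold with warning).

## Problem sizes in the shipped tests

The suite runs the full chain at reduced but statistically meaningful
sizes, chosen so that every claim is still a property of the method
rather than of a lucky draw: titration recovery uses the four-point
1–25 nM design, 10 min sweep recordings at 5 kHz sampling, three seeds
per point (k_on and k_off recovered within 15 %, $K_D$ within 20 %);
detector/ground-truth agreement uses 600 s gap-free at 5 kHz
(≥ 99 % recovery, ≤ 1 % spurious at amplitude ≥ 5 noise sd and dwell ≥ 10
samples); bandwidth recovery uses 60 s windows (within 0.5 Δ%). The
5 kHz generator sampling (vs 50 kHz acquisition hardware) leaves all
relevant dwells hundreds of samples long while keeping the suite's
runtime around two minutes.

## Known limitations

- The occupancy model's in-pore bond rates are not calibrated to
  experiment; only the level extremes and the qualitative structure
  (level count, caging persistence, competitor response) are anchored.
- Intermediate level depths are a linear ladder by default; real linker
  geometries need not be equally spaced, and level *assignment* to
  specific tag combinations is out of scope.
- The detector is threshold-based; it does not attempt HMM idealization
  and will blur sub-threshold or sub-millisecond structure.
- ABF and HDF5 containers are recognised but not read by this build;
  CSV/TSV are the interchange formats.
- The classifier's criteria windows are a codification of a manual
  procedure, validated against the generator only.
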