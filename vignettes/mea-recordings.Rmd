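---
title: "Storing and analysing MEA spike-train recordings"
author: "mearec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Storing and analysing MEA spike-train recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mearec)
```

## Scope and model of the data

During early development, retinal ganglion cells fire spontaneously in
waves that sweep across the retina; multielectrode arrays (MEAs) record
these as dozens to thousands of parallel spike trains. After spike
detection and sorting, a recording reduces to a set of event times per
"unit" (a putative neuron), each unit with an (x, y) position on the
array. `mearec` treats that reduced representation as the unit of
storage and analysis: no voltage traces, no spike sorting, no
lab-specific source formats.

A recording is stored in a single HDF5 file. The root holds `epos`
(N × 2 positions in µm), `sCount` (per-unit spike counts), `spikes`
(all spike times in seconds, trains concatenated in unit order, each
train sorted), `array` (a layout label such as `MCS_8x8_100um`) and
optionally `names`. Metadata live under `/meta`: a study `key`, the
`species`, the postnatal `age` in days (negative = embryonic, 0 = day
of birth, 500 = adult sentinel), the `genotype` (default `"wt"`) and
the recording condition `cond` (default `"ctl"`). A `/summary` group
caches what can be recomputed from the spikes — `N`, the `duration` in
whole seconds (the latest spike time rounded **up** to the nearest
second), the per-unit firing rates `frate = sCount / duration`, and
`totalspikes` — so that repository-wide inventories can be built by
reading a few scalars per file.

Concatenation is indexed by the closed 1-based range returned by
`unit_slice()`: unit *j* occupies elements
*a* = 1 + Σ~i<j~ sCount[i] through *b* = *a* + sCount[j] − 1; a silent
unit gives *b* < *a*, the empty range.

```{r slices}
unit_slice(c(2, 3, 1), j = 2)
```

## Reading, writing and validation

`write_mea_h5()` refuses to serialise anything that fails
`validate_mea()`; `read_mea_h5()` is deliberately more tolerant than the
writer. Decisions worth stating explicitly:

* **Matrix orientation.** HDF5 bindings disagree about dimension order,
  so files written from row-major environments can present `epos` as
  2 × N. The reader transposes any (2, N) position matrix with N ≠ 2;
  an ambiguous 2 × 2 is taken as-is. The writer always produces N × 2
  as seen from R.
* **On-disk types.** Spike times and rates are 64-bit IEEE floats
  (round trips are bit-exact); counts, ages and durations are 64-bit
  integers; strings are variable-length UTF-8.
* **Defaults.** Absent `genotype`/`cond` materialise as `"wt"`/`"ctl"`
  on read; an absent `/summary` is recomputed.
* **Degenerate recordings.** Empty spike trains are legal (their rate
  is 0), but a recording with no spikes at all — or whose only spike is
  at t = 0 — has an undefined duration; `compute_summary()` raises an
  error unless an explicit duration override is supplied, rather than
  silently writing 0 and breaking every rate downstream.
* **Vocabulary.** The `array`/`species` label sets are open;
  `validate_mea()` reports unseen labels as warnings, never errors,
  since real repositories carry free-text conditions and lab-specific
  array names. Violation records carry stable codes
  (`SPIKES_LEN_MISMATCH`, `TRAIN_UNSORTED`,
  `SUMMARY_DURATION_WRONG`, ...) so scripts can filter on them.

```{r validate}
rec <- simulate_waves(wave_sim_params(duration = 120, seed = 1))
f <- tempfile(fileext = ".h5")
write_mea_h5(rec, f)
validate_mea(f)
```

## The correlation index

The spatial structure of correlated firing is summarised by the classic
coincidence-within-a-window ratio. For trains *a* and *b* over a
recording of duration *T*,

$$\mathrm{CI}(a, b) = \frac{N_{ab}(\pm\Delta t)\; T}
                           {N_a\, N_b\, 2\Delta t},$$

where $N_{ab}(\pm\Delta t)$ counts ordered spike pairs within
$\Delta t$ of each other (window closed at both ends). The denominator
is the expected pair count for independent homogeneous trains, so
independence gives CI ≈ 1, and the statistic is symmetric and invariant
to a common time shift. Parameters and conventions:

* $\Delta t$ defaults to 0.05 s, the conventional 50 ms window for
  retinal waves; it is a half-width, and enlarging it can only increase
  the coincidence count.
* *T* is taken from the `/summary` duration (the ceiling), not the raw
  last spike time, so one source of truth defines rates and indices.
* Pairs involving a silent train get `NaN`, **not** 0 — a zero would
  fake anti-correlation and bias binned means downward. Binning skips
  `NaN`s.
* Pairs of units sharing one array position (distance 0) are kept.

The pair counting is a two-pointer sweep over the two sorted trains
(compiled, O(|a| + |b| + pairs)); the test suite checks it against an
O(n²) brute-force enumeration on a thousand random train pairs, and
checks the calibration E[CI] = 1 by Monte Carlo on independent Poisson
trains (200 pairs at 1 Hz, T = 1000 s, tolerance ±0.1 on the mean).

`ci_map()` evaluates all N(N−1)/2 pairs with Euclidean distances in the
electrode plane; `bin_ci_by_distance()` averages into left-closed
100 µm bins, omitting empty bins. Note a geometric consequence on a
100 µm lattice: the minimum inter-unit distance is exactly 100 µm, so
the [0, 100) bin is empty unless units share a position, and binned
curves start at [100, 200).

## Burst detection

The repository literature delegates burst detection to per-lab methods
that are rarely restated; `mearec` therefore implements one transparent,
parameterised definition rather than guessing at any particular lab's:
a burst is a maximal run of consecutive spikes whose inter-spike
intervals are all ≤ `max_isi`, kept if it has ≥ `min_spikes` spikes;
accepted runs closer than `merge_interval` (offset to next onset) are
merged, and a merged burst spans every spike between its first and last
member. Burst duration is last minus first spike time.

Defaults — `max_isi` 0.3 s, `min_spikes` 3, `merge_interval` 0.5 s —
are set so that the dense volleys a passing wave evokes (tens of Hz for
around a second, against a background of well under 1 Hz) are recovered
as single bursts. All three parameters are exposed so other
ISI-threshold definitions can be emulated; exact reproduction of any
specific published burst count is explicitly not a goal, because those
algorithms and parameters are not recoverable. The planted-burst tests
pin the behaviour exactly: for trains with inter-burst gaps larger than
both `max_isi` and `merge_interval`, detected counts, spike counts and
durations equal the planted values, and isolated spikes far from any
burst never change the output.

`duration_cdf()` turns per-group burst tables into empirical CDFs
(k/n at the k-th smallest duration) for step plots and CSV export.

## The synthetic-data generator

`simulate_waves()` is an event-level generative model, not a biophysical
one. Waves initiate as a Poisson process in time (rate `wave_rate`),
uniformly over the array bounding box; each wavefront is a circle
expanding at constant `speed` with unbounded extent and no wave–wave
interaction. When a front reaches a unit, the unit emits a Poisson
burst (`burst_rate` Hz for `burst_duration` s) unless it responded to a
wave within the last `refractory` s; independent background firing at
`bg_rate` Hz runs throughout. Spikes are truncated to [0, T) and sorted
per unit; ties are kept. The generator owns its RNG: the seed is
mandatory, runs are byte-identical under the same seed, and the
caller's `.Random.seed` is untouched.

Defaults: `MCS_8x8_100um` layout, T = 1800 s, `wave_rate` 0.02 waves/s
(a wave roughly every 50 s, matching the periodic rate elevations
separated by long silences that characterise these recordings),
`speed` 200 µm/s, `burst_rate` 30 Hz, `burst_duration` 1 s,
`bg_rate` 0.05 Hz, `refractory` 5 s. With a ~1 s burst and 200 µm/s
propagation, units within ~200 µm have strongly overlapping volleys and
units across the array do not, which yields the distance-decaying
correlation structure; at these defaults the binned mean CI falls
monotonically from the [100, 200) bin out to [500, 600), and the peak
1-s population rate exceeds five times the median bin.

What the simulator emulates: episodic array-wide rate elevations,
distance-decaying pairwise correlation, per-unit burst/silence
structure, background firing, and every schema invariant (all outputs
pass `validate_mea()`). What it does **not** emulate: wave boundaries
and refractory wave domains, direction biases, developmental and
genotype-dependent changes, multi-unit contamination, electrode noise,
or realistic firing-rate heterogeneity. Passing tests on simulated data
therefore demonstrate that the machinery (format, statistics, detection,
plots) is correct, not that any scientific conclusion about real retinas
follows.

`simulate_poisson()` is the matched null: independent homogeneous
trains at one rate on the same layouts, used to calibrate CI ≈ 1. With
`rate = 0` no spikes exist and the summary duration is undefined, so
construction fails with the documented error.

`make_layout()` provides the standard geometries: the two 60-electrode
8 × 8 lattices with missing corners (100/200 µm pitch), the 4096-site
64 × 64 high-density grid (42 µm), and 60 µm triangular ("hex")
lattices trimmed to 61 sites (rings 0–4) or to the 512 sites closest to
the patch centre, with deterministic tie-breaking.

## Figures

`fourplot()` renders the one-page QC overview: (A) unit positions
labelled by index, so duplicated positions show as overlapping labels;
(B) population rate in 1 s bins averaged across the array; (C) the
raster with unit 1 at the bottom; (D) CI versus distance on a log y
axis, annotated as unavailable when fewer than two units exist.
`ci_family_plot()` overlays binned CI curves, one line per recording,
coloured by group (e.g. genotype), as used to compare the spatial range
of correlations across genotypes.

Figures are tested through their data, not their pixels: every figure
has a companion export (`fourplot_data()`, `ci_family_data()`, the JSON
and CSV exports) containing exactly the plotted numbers. Zero CI values
cannot sit on a log axis; they are drawn at half the smallest positive
value and flagged `floored` in the export rather than dropped silently.

## Problem sizes and numerical choices

The shipped tests and the reproduction script run entirely on generated
data at desk scale: round trips use recordings of up to 8 units and a
few hundred spikes; oracle comparisons use trains of up to 200 spikes;
CI calibration uses 200 Poisson pairs at 1 Hz over 1000 s; the
distance-decay check runs the simulator at its full defaults (60 units,
1800 s) over five seeds. These sizes were chosen as the smallest that
make the stochastic checks stable, and the whole suite runs in about a
minute.

Other numerical conventions: the coincidence window is closed
(|s − t| ≤ Δt); distance bins are left-closed; burst merging compares
the gap strictly against `merge_interval`; summary comparisons in the
validator use a 1e-9 relative tolerance for `frate` (the only derived
float) and exact equality for integers; catalogue age columns sort
ascending so the adult sentinel 500 lands last.

## Limitations

* The container stores spike times only; anything upstream of sorting
  is out of scope, and sorting provenance is free text at best.
* One transparent burst definition is provided; published burst counts
  from unpublished algorithms cannot be reproduced exactly.
* The correlation index is the only pair statistic implemented; it is
  biased for strongly non-stationary trains, which is precisely why it
  is informative for waves, but modern alternatives (e.g. tiling-based
  coefficients) are not included.
* The wave model is phenomenological; its parameters are in plausible
  ranges for developing retina but are not fitted to any dataset.
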