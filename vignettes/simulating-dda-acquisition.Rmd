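---
title: "Simulating data-dependent LC-MS/MS acquisition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating data-dependent LC-MS/MS acquisition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(acquisim)
```

## Motivation

Developing and comparing fragmentation strategies for data-dependent
acquisition (DDA) on a real LC-MS/MS instrument is slow and expensive:
every candidate parameter set costs instrument time and sample material,
and the ground truth (which chemicals were really present, and when) is
never fully known. `acquisim` replaces the instrument with a virtual one.
Chemical objects with known chromatographic profiles and fragment spectra
are rendered scan by scan under a controllable clock, so acquisition
strategies can be scored against exact ground truth, re-run under
different parameters, and compared across replicate samples — entirely
in silico.

The package covers the full loop:

1. **Feature database** (`build_feature_db`, `make_fixture_db`): empirical
   or parametric pools of MS1 features, MS2 peaks, per-scan fragment
   counts, scan durations, and chromatogram templates.
2. **Chemicals** (`sample_known_chemicals`, `chemicals_from_rois`,
   `replicate_samples`): sample objects drawn from those pools, either
   formula-based (adducts and isotopes) or taken directly from extracted
   regions of interest.
3. **Virtual mass spectrometer** (`virtual_ms`, `generate_scan`,
   `run_acquisition`): renders MS1 and MS2 scans at the current clock
   time and advances the clock by empirically sampled scan durations.
4. **Controllers** (`top_n_controller`, `dsda_run`): acquisition
   strategies deciding, scan by scan, what to do next.
5. **Evaluation** (`pick_peaks`, `confusion_counts`, `grid_evaluate`,
   `coverage_count`): scoring against a full-scan reference or known
   truth.
6. **mzML I/O** (`read_mzml`, `write_mzml`): interchange with real
   instrument software and peak pickers.

## The simulation model

### Chemicals and traces

A chemical is defined by a start RT, a maximum intensity, a normalized
chromatogram template (RT offsets, relative intensities, m/z drift), a
fragment spectrum, and its MS1 trace definition. A *known* chemical has a
molecular formula; its traces are the adduct × isotope grid, with
intensity split by the product of the adduct proportion and the
truncated (M, M+1, M+2) natural-abundance isotope proportions. An
*unknown* chemical — typically created from an extracted ROI of a real
file — emits a single trace at its observed m/z.

At any time `t` the intensity of a trace is the linear interpolation of
the chromatogram template between its stored knots, scaled by the
chemical's maximum intensity and the trace proportion; outside the
template span the signal is exactly zero.

### The clock and scan durations

Real instruments take different times for MS1 and MS2 scans, and the
gap also depends on the preceding scan type. The feature database
therefore stores empirical duration pools keyed by the level transition
(`"1->1"`, `"1->2"`, `"2->1"`, `"2->2"`), measured from real files as the
RT gap between consecutive scans. During simulation each completed scan
advances the clock by a draw from the matching pool (with a pooled
fallback for unobserved transitions), or by a user-supplied
`duration_fn` when a fixed timing grid is wanted.

### Precursor intensity is measured at execution time

A design decision worth stating explicitly: a Top-N controller selects
precursors using their survey-scan intensities, but the precursor
intensity recorded in the resulting MS2 scan is the one the virtual
instrument measures when that scan actually executes. With a large N the
last fragmentation of a duty cycle can run a second or more after the
survey scan, by which time a chemical on the tail of its elution profile
may have decayed below the selection threshold. This is the mechanism
that makes very large N counterproductive (see the grid evaluation
below): more fragmentation events, but an increasing share of them below
the intensity needed to count, and fewer MS1 scans left for
peak-picking. Evaluations that threshold on precursor intensity use the
executed value.

## Controllers

### Top-N with dynamic exclusion

`top_n_controller` implements the standard duty cycle: after each survey
scan it queues MS2 scans on the `N` most intense eligible precursors.
Eligibility requires intensity at or above `min_ms1_intensity`
(default 1.75e5), no match (±`mz_tol`, default 0.01 Th) against an
active dynamic-exclusion record, and spacing of more than `mz_tol` from
precursors already chosen in the same cycle. Fragmenting a precursor
excludes its m/z for `dew` seconds (default 15 s) from the moment the
MS2 scan executes. These three properties — cycle size, exclusion
window, and threshold — are tested as invariants of entire simulated
runs.

### DsDA-style multi-sample prioritization

`dsda_run` acquires an ordered series of related samples. The first
sample runs plain Top-N; after each sample, MS1 features are picked and
merged into a cross-sample registry (m/z centers within 10 ppm and
overlapping RT ranges), and each feature's best MS2 quality so far is
recorded. The next sample is then planned by walking the acquisition
clock over a fixed timing grid (scan durations are the database medians,
so planned and executed times coincide exactly): each cycle opens with
an MS1 scan and fragments up to `N` features of highest weight

```
weight = intensity × (1 − quality)
```

currently near their apex, one slot per feature per sample; when no
eligible feature remains, the cycle returns early to MS1. Eligibility
requires the clock to be within the ±1σ core of the feature's RT extent
— fragmenting at the elution edges would produce spectra too weak to
count. Quality updates are likewise gated on the *measured* precursor
intensity reaching the picking threshold, so a feature fragmented
uselessly on its tail remains schedulable in later samples.

The original strategy scores MS2 spectral quality with an external
model; this package deliberately uses a documented surrogate —
`quality = min(1, n_fragment_peaks_above_floor / k_ref)` with
`k_ref = 10` — because the scheduling behaviour being studied depends
only on quality being 0 for unfragmented features and increasing with
spectrum richness. The surrogate keeps the package self-contained and
deterministic under a seed.

### Replicate samples

`replicate_samples` models biological/technical replication: each sample
keeps each chemical independently with probability `1 − dropout`, and
retained chemicals get Gaussian noise (SD in counts) added to their
maximum intensity, floored at 1. Two replicates at dropout `d` share a
chemical with probability `(1 − d)²` — a closed form used as a
correctness check of the generator at `n = 10,000` chemicals.

## Evaluation

`confusion_counts` scores a DDA file against a full-scan file of the
same sample. Features picked from the two files are matched (10 ppm,
overlapping RT); features present in both form the ground truth, and
"fragmented" means at least one fragmentation event inside the feature
box with (executed) precursor intensity at or above the threshold.
Counts are:

* **TP** — ground-truth features fragmented;
* **FP** — fragmentation-file-only features fragmented;
* **TN** — fragmentation-file-only features not fragmented;
* **FN** — full-scan-only features not fragmented, **plus** ground-truth
  features not fragmented.

The second FN group is an extension of the classical four-way split:
without it, recall would ignore exactly the features a strategy failed
to fragment, which is the quantity of interest. Full-scan-only features
that *were* fragmented above threshold fall outside all four classes and
are left uncounted. All interval comparisons are closed.

## Study conditions and scaling

The full-scale experiments this simulator is designed around use
thousands of chemicals over a ~15-minute gradient. The package's bundled
study conditions scale this down so that every experiment runs on a
laptop in minutes while preserving the quantity that makes the problem
hard — the chemical arrival rate (features eluting per second), which is
what makes MS2 capacity the binding resource:

* 500 chemicals with apexes uniform over a 70 s elution window
  (≈ 7.2 chemicals/s, matching 6,500 chemicals over 900 s);
* acquisition window 0–125 s;
* fixed scan durations of 0.6 s (MS1) and 0.2 s (MS2), the medians of
  the parametric duration pools.

Under these conditions `grid_evaluate` over N ∈ {1, 2, 5, 10, 20, 50}
reproduces the qualitative behaviour of real Top-N optimization: F1
rises from N = 1 to an interior maximum and falls again at N = 50, while
the number of MS1 features recoverable from the fragmentation file is
non-increasing in N.

## Fragment spectra: truncated Chinese Restaurant Process

Fragment spectra are drawn from the database's MS2 peak pool either
independently (`method = "random"`) or through a shared Chinese
Restaurant Process (`method = "crp"`), which makes fragment peaks recur
across chemicals the way real fragment ions do. Each draw picks a
previously used peak with probability proportional to its accumulated
count, or a new one with probability proportional to the concentration
parameter; peaks already in the current spectrum are excluded, with
their probability mass redistributed proportionally, so no spectrum
contains the same peak twice. With counts {A: 3, B: 1} and
concentration 1, the next draw is A/B/new with probability
0.6/0.2/0.2.

## Numerical and design choices

* **MS1 feature sampling is joint**: RT and maximum intensity are drawn
  as whole rows of the feature pool, preserving any empirical
  correlation between them, and the chromatogram template is chosen by
  nearest log10 apex intensity.
* **ROI extraction** uses a running-mean m/z window (default 10 ppm),
  admits one point per ROI per scan with closest-point-wins assignment,
  and closes an ROI the first time a scan fails to extend it. A single
  missed scan therefore splits a trace; this matches the strict variant
  of the extraction rule and is the behaviour the brute-force test
  oracle encodes.
* **Fragment m/z values are unconstrained** by the precursor: the MS2
  pool is sampled as-is, so a fragment may exceed its precursor's m/z.
  Enforcing a constraint would bias the pool and is unnecessary for the
  acquisition questions studied here.
* **No instrument noise** is added to rendered intensities; noise enters
  only through `replicate_samples`. This keeps single-run comparisons
  exactly reproducible under a seed.
* **Persistence** of feature databases is versioned JSON written with
  full double precision (`digits = NA`), so a write/read cycle is exact.
* All randomness flows through R's global RNG; any workflow is
  reproducible with a single `set.seed()`.

## Limitations

The simulator renders centroids directly (no profile peaks, resolution
model, or detector saturation), models chromatography purely through
templates (no RT drift between replicates), and its bundled peak picker
is intentionally naive — external picked-peak lists can be imported with
`read_picked_peaks_csv` when realistic picking matters. The DsDA quality
surrogate is a stand-in for a learned spectral-quality model; absolute
coverage numbers will differ from an implementation with the original
scorer, although the direction of the comparisons (helped by clean
replicates, hurt by heavy dropout) is preserved.

## A minimal end-to-end example

```{r example, eval = FALSE}
set.seed(1)
db <- make_fixture_db()
chems <- sample_known_chemicals(db, 200, fragment_method = "crp",
                                crp = crp_state(1))
log <- run_acquisition(chems, top_n_controller(top_n_params(N = 10)),
                       db, start_rt = 0, end_rt = 300)
print(log)
write_mzml(log, "topn10.mzML")

full <- run_acquisition(chems, ms1_controller(), db, 0, 300)
confusion_counts(pick_peaks(full), pick_peaks(log),
                 fragmentation_events(log))
```
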