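---
title: "Quantifying transcriptional bursting from MS2-MCP movies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcriptional bursting from MS2-MCP movies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ms2burst)
```

## The measurement problem

In syncytial *Drosophila* embryos carrying an MS2 reporter, nascent
transcription at a single locus is visible as a diffraction-limited green dot
(MCP-GFP bound to MS2 stem-loops) inside each nucleus, while Nup-RFP marks
nuclear envelopes in the red channel. Movies taken through nuclear cycles
nc12-nc14 show *transcriptional bursting*: each promoter switches episodically
between an active (ON) and inactive (OFF) state, so dots appear, brighten,
dim and vanish. Comparing a wild-type enhancer against a binding-site mutant
requires turning these movies into numbers: when transcription starts after
each mitosis, how many nuclei engage, how big and bright the dots are, how
long bursts last and how often they recur, and whether case and control
differ significantly.

`ms2burst` implements that quantification end to end, plus a synthetic-movie
generator with complete ground truth so every stage of the pipeline is
testable without microscopy data.

## The generative model

`simulateTelegraph()` simulates each nucleus independently as a two-state
telegraph promoter: a continuous-time Markov chain switching OFF→ON at rate
$k_{on}$ and ON→OFF at rate $k_{off}$ (stationary ON probability
$k_{on}/(k_{on}+k_{off})$; mean ON run $1/k_{off}$; mean OFF gap $1/k_{on}$).
While ON, transcripts initiate as a Poisson process at `loadingRate`; each
nascent transcript contributes fluorescence for a deterministic dwell
`transcriptDwellS`, so the instantaneous transcript count is the number of
initiation events in the trailing dwell window. The chain is simulated
exactly in continuous time (exponential sojourns) and discretized by the
state at each frame midpoint, which avoids frame-rate bias in the switch
times at moderate rates — though promoter excursions shorter than one frame
interval are invisible at any cadence (see *Limitations*).

Dot-intensity kinetics are not observable directly, and several models are
defensible (full elongation kinetics, stochastic termination, deterministic
dwell). The deterministic dwell-window count is the simplest model that
produces the intensity rise, plateau and decay the pipeline must measure; it
is isolated behind `GroundTruth` so it can be swapped without touching the
renderer or the analysis.

`renderMovie()` is the forward model of acquisition: green channel = sum of
Gaussian dots (amplitude `ampPerTranscript` × transcript count × bleach
factor, PSF width `psfSigmaPx`), plus flat background and Gaussian read
noise, rounded and clipped to the bit depth; red channel = nuclear envelope
rings. Photobleaching scales dot signal by $2^{-t/\text{halflife}}$.
Optional defocused z-planes (`nZPlanes > 1`) widen and dim the PSF away from
the focal plane so that maximum projection recovers the in-focus image.
Mitosis is modeled as a hard reset at each stage boundary — all promoters
OFF, nascent transcripts cleared, nuclei re-jittered — with no lineage
tracking, because the analysis restarts tracking per stage anyway.

### Default parameters and why

| parameter | default | units | rationale |
|---|---|---|---|
| `frameIntervalS` | 1.77 | s | acquisition cadence of the super-resolution movies |
| `kOn` | 0.02 | 1/s | mean OFF gap 50 s, the order seen in single-nucleus traces |
| `kOff` | 0.05 | 1/s | mean ON run 20 s |
| `loadingRate` | 0.5 | transcripts/s | ~10-15 nascent transcripts at steady state |
| `transcriptDwellS` | 30 | s | residence of a nascent transcript (transit + release) for a kb-scale reporter |
| `psfSigmaPx` | 1.5 | px | diffraction-limited dot at the rendered pixel size |
| `ampPerTranscript` | 15 | 8-bit units | a single transcript is near-threshold; mature dots are bright |
| `backgroundLevel` / `noiseSd` | 20 / 4 | 8-bit units | dim autofluorescent background with mild read noise |
| `bleachHalflifeS` | 600 | s | gentle bleaching over a multi-stage movie |
| `dotDiffusionPx` | 1 | px | slow centroid wobble, well under the inter-nuclear pitch |

These defaults are the package's standard simulation conditions. Validation
fixtures override only what the property being tested requires (e.g.
noise-free, very bright dots for detection-exactness checks), never the
switching rates.

The generator emulates: telegraph switching, transcript accumulation and
decay, PSF blur, background, read noise, bleaching, mitotic resets, dot
wobble, saturation/clipping. It does **not** emulate: nuclear crowding and
movement, segmentation-relevant red-channel texture, spatial expression
gradients, Poisson shot noise (optional Gaussian-only by design), focal
drift, or enhancer-promoter spatial dynamics. Tests passing on synthetic
movies therefore certify the *algorithmic* correctness of the pipeline, not
its robustness to every artifact of real microscopy.

## Preprocessing

* **Flattening** — `maxProject()` takes the per-pixel maximum over z, the
  standard projection for point-like sources; it is idempotent.
* **Bleach correction** — `bleachCorrect()` offers `simple_ratio` (scale
  each frame so its mean equals the frame-0 mean; the lightest mode of the
  classic ImageJ plugin, and the default because it is robust on short
  per-stage movies) and `exponential_fit` (fit $a e^{-bt}+c$ to frame means,
  divide by the decay normalized to $t=0$; falls back to `simple_ratio` with
  a warning if the fit fails). Correction defaults to whole-movie; per-stage
  correction is available by running it on `splitStages()` output.
* **Stage splitting** — nuclear-cycle boundaries are user-supplied 0-based,
  half-open frame intervals (`stagePartition()`). Cycles are identified
  manually in practice (counting backward from nc14); automatic anaphase
  detection is out of scope.
* All quantitative processing is floating point; data are converted to the
  8-bit scale only at the detection boundary (`asEightBit()`), because the
  fixed detection threshold is defined on 8-bit data.

## Detection conventions

`detectDots()` thresholds the green channel at 55 (8-bit scale) and labels
connected components. Conventions chosen for bit-exact reproducibility:

* strict `>` at the threshold (a uniform frame exactly at 55 is empty);
* 8-connectivity by default (the contour convention of common CV libraries),
  4-connectivity available;
* `minAreaPx = 1` (no area filter) by default;
* per-dot brightness is the mean over the *filled* component, not a boundary
  polygon — "mean pixel value of a contour" is ambiguous, and the filled
  region matches the intensity semantics of a fluorescent focus;
* centroids are unweighted means of member pixel coordinates (0-based
  row/col).

Per-stage min-max normalization (`normalizeStage()`) maps each dot's mean
brightness to $[0,1]$ using the minimum and maximum over *all dots of the
stage, all frames pooled, within one movie* (whether the original analysis
pooled across movies of a condition is unknowable; per-movie is the safer,
documented default). The degenerate stage (max = min, e.g. a single dot)
maps to 0 rather than dividing by zero. Normalization is invariant to affine
rescaling of the stage's brightnesses.

Nuclear masking (Otsu threshold of the red channel + hole filling, dots kept
only if their centroid lies inside) is available but **off** by default: the
quantitative path described for tissue metrics is a pure green-channel
threshold, while the tracking description mentions dots "inside nuclei", so
the mask is offered as an option rather than imposed.

## Tracking

`linkFrames()` assigns persistent IDs frame by frame: each dot may link to
one active track whose last centroid lies within `maxLinkDistPx`
(default 15 px — roughly half the inter-nuclear pitch at nc13-14 on a
700-px field; the original threshold value is unpublished, so it is a logged
parameter, not a constant). Greedy ascending-distance matching is the
default, faithful to the simple described algorithm; `assignment =
"optimal"` solves the minimum-total-distance assignment with an $O(n^3)$
Hungarian solver for dense fields. Distance ties break toward the lower
(older) track ID for determinism. Unmatched dots found new tracks with
sequential per-stage IDs; no track crosses a stage boundary.

Because a bursting nucleus goes dark between bursts, tracks tolerate
`maxGapFrames` (default 10) of silence before closing; 0 restores strict
previous-frame linking. The default tolerance (~18 s) re-links blinks but
not long OFF gaps; per-nucleus burst *frequency* analyses should raise it
above the typical OFF-gap length, at the cost of mis-link risk in crowded
fields.

## Metrics

Per frame (`frameMetrics()`): dot count, mean and total dot area, mean raw
and normalized brightness (missing when a frame has no dots).

Per stage (`stageMetrics()`), with $t = (\text{frame} - \text{stage
start}) \times \Delta t$:

* `t_first_dot_s` — first frame with any dot;
* `t_first_peak_s` — first local maximum of the dot-count series after
  moving-average smoothing (window `smoothW = 3` frames, suppressing
  single-frame detection flicker);
* `t_all_dots_s` — first frame reaching the stage-maximum dot count;
* `avg_transcription_rate` — stage mean of per-frame mean dot area (dot
  size proxies nascent transcript number; a documented proxy, not a rate
  fit);
* `init_total_pixels`, `init_active_nuclei` — total dot pixels / distinct
  active tracks inside the *initiation window*, defined as the first
  `ceiling(initWindowFrac × stage length)` frames from first detection
  (`initWindowFrac = 0.25`; the window is not defined in the original
  description, so it is configurable);
* `intensity_peak_sd` — SD across tracks of each track's maximum mean
  brightness.

Per track (`trackFeatures()`): onset time, frames present, average size and
brightness, maximum brightness, and the burst structure. A **burst** is a
maximal ON run — consecutive frames with an observation; OFF gaps are the
complementary intervals inside the track span, so runs and gaps tile the
span exactly and `n_transitions = 2(n_bursts − 1)`. Intensity-peak burst
calling (local maxima above median + 1 SD of a trace) exists only as a
plotting annotation, not a headline metric, because presence/absence is the
reproducible definition. `dispersionStats()` reports sample SD
($n-1$ denominator) and SEM $= \mathrm{SD}/\sqrt{n}$.

`sojournEstimates()` recovers mean ON/OFF sojourns from ground-truth
trajectories as exposure time over completed transitions — the
censored-exponential MLE. Averaging only fully observed runs inside a stage
window would under-estimate long sojourns (length-biased truncation, ~20%
for 50-s gaps in a 120-frame window), so the estimator discards each
trajectory's initial partial run and counts the final censored run as
exposure without an event.

## Statistics

`compareConditions()` runs, per metric × stage:

* **Mann-Whitney U** (`mannWhitneyU()`): U from pooled midranks. For
  $n_1+n_2 \le 12$ the null is enumerated exactly over all
  $\binom{n_1+n_2}{n_1}$ label splits — enumeration handles ties correctly,
  which matters for small integer-valued metrics such as burst counts;
  larger samples use the normal approximation with tie and continuity
  corrections.
* **Permutation test** (`permutationTest()`): statistic = difference in
  means; exact enumeration when $\binom{n}{n_1} \le 20{,}000$, else 10,000
  seeded Monte-Carlo draws; the observed arrangement is always counted, so
  $p \ge 1/N$. The primary p-value follows the source procedure: the
  alternative's direction is chosen by the *sign of the observed
  difference*. That choice is anti-conservative (under the null it rejects
  at roughly twice the nominal level), so every result also carries the
  calibrated two-sided p (`pTwoSided`), and calibration properties are
  asserted on the two-sided value.
* **Variance-gated t-test** (`tTestAuto()`): pooled-variance Student t
  unless an F-test of variance equality is significant at α = 0.05, then
  Welch with Satterthwaite df; the chosen branch is recorded. The variance
  gate is an F-test because no specific test is named for the switch;
  Levene (Brown-Forsythe) is available in `varianceCompare()`.
* **Variance comparison** (`varianceCompare()`): F ratio
  (var(case)/var(control), two-sided) or Levene on absolute deviations from
  group medians.

The **movie (embryo) is the default statistical unit**, matching the
per-stage sample sizes of the original comparisons (n = 4-7 movies per
condition); track features are averaged within movie first. `unit =
"track"` pools tracks across movies for extra power but violates
independence (tracks share a movie), so its outputs are labeled exploratory.
A movie-level `total_bursts` (bursts summed over tracks) is also tested,
mirroring the "total bursts per movie" comparison. No multiple-testing
correction is applied, matching the source analysis; significance stars use
the ns > 0.05 convention.

## Orchestration

This is an analysis package, so the pipeline surface is a pair of functions
rather than a shell tool: `pipelineConfig()` + `runPipeline()` simulate (or
load fixtures via `readFixture()`), analyze every movie
(`analyzeMovie()`), pool per-condition tables, compare two conditions, and
optionally write all CSV/JSON outputs with a verbatim config echo and a
manifest, so a bundle is reproducible bit-for-bit from its config and seeds.
Per-movie failures are logged and skipped, not fatal. Movie $m$ of
condition $k$ is seeded `baseSeed + 1000(k−1) + m`; every stochastic step
(simulation, rendering noise, Monte-Carlo permutations) derives from
configured seeds.

## Numerical choices and degenerate inputs

* Thresholding is strict (`>`); conversion to 8-bit rounds half away from
  zero and clips.
* Degenerate normalization (max = min) → 0; empty frames → missing means;
  single-value dispersion → SD flagged missing.
* Zero observed difference in the permutation test → two-sided convention,
  p = 1, flagged degenerate. Constant pooled data in MWU → p = 1 with a
  warning.
* Exponential bleach fits that fail or return a negative decay rate fall
  back to `simple_ratio` with a warning; an all-zero reference frame is an
  error.
* Assignment cost ties and distance ties resolve deterministically (lower
  track ID); forbidden links are +∞ and can leave dots unmatched, which
  founds new tracks.

## Validation problem sizes

The shipped validation suite uses: 3×3-nucleus, 50-frame noise-free renders
for detection exactness; 200 random 32×32 binary images against an
independent flood-fill labeling oracle; 20 seeded fixtures for
track-to-nucleus bijection; 50 tracks × 120 frames for telegraph-rate
recovery; 1,000 small-sample enumeration checks and 2,000 null datasets for
test calibration; and 10 replicate 7-vs-7-movie studies for the
direction-of-effect power check. These sizes were chosen so that Monte-Carlo
error comfortably dominates known discretization biases (see below).

## Limitations

* **Frame-rate censoring of short bursts.** Discretizing at Δt = 1.77 s
  misses promoter excursions shorter than a frame: at $k_{off} = 0.2$/s,
  ~30% of ON runs are sub-frame. A consequence the package's own power
  analysis exposes: raising $k_{off}$ 4× *shortens* observed ON runs
  robustly (detected in 10/10 replicate studies) but leaves the *observable
  burst count* nearly flat — the ~27% increase in promoter cycling is
  cancelled by sub-frame censoring, and the transcript dwell merges adjacent
  cycles. A mutant that visibly bursts *both* more often and more briefly at
  this cadence therefore implies a change in $k_{on}$ as well, not
  $k_{off}$ alone. The `power_more_bursts` quantity reported by
  `scripts/acceptance.R` stays near 0 for exactly this reason, and the
  corresponding assertion in the validation suite documents it as a known
  failure under these generative conditions.
* Discretized sojourn estimates carry a small upward bias (~6% at the
  default rates) because sub-frame excursions are missed; validation
  tolerances are SE-based at sizes where this bias is well inside 2 SE.
* The detection-presence burst definition conflates promoter OFF with
  sub-threshold signal; very dim dots blink at the threshold.
* Greedy linking can mis-assign in fields denser than the link distance;
  use `assignment = "optimal"` there.
* The simulator's nuclei are static rings; real nc14 nuclei crowd, deform
  and drift, so nuclear-mask performance on real movies is untested here.
* JPEG frame export exists in the original workflow; this package operates
  on lossless arrays only, because JPEG artifacts corrupt area and
  brightness metrics.

## A worked micro-example

```{r example}
cfg <- simConfig(nNucleiSide = 2L, fieldSizePx = 64L, nFramesPerStage = 40L,
                 ampPerTranscript = 120, noiseSd = 2, seed = 4L)
truth <- simulateTelegraph(cfg)
movie <- renderMovie(truth)
bundle <- analyzeMovie(movie, simStagePartition(cfg))
bundle$stage_metrics
head(bundle$track_features)
```
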