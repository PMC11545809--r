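# ms2burst

Quantification of transcriptional bursting from MS2-MCP live-imaging movies
of syncytial *Drosophila* embryos — for researchers who film nascent
transcription as fluorescent nuclear dots (MCP-GFP on MS2 stem-loops, with
Nup-RFP nuclear envelopes) through nuclear cycles nc12–nc14 and need
reproducible numbers out of those movies: dot detection, identity tracking
through burst-driven disappearances, tissue- and nucleus-level burst
metrics, and a case-vs-control statistical battery. A telegraph-model
synthetic-movie generator with full ground truth makes the whole pipeline
testable without microscopy data.

## The model and the measurements

Each promoter is treated as a two-state **telegraph process**: it switches
OFF→ON at rate $k_{on}$ and ON→OFF at rate $k_{off}$, so the stationary
active fraction is $k_{on}/(k_{on}+k_{off})$, the mean burst (ON-run)
duration is $1/k_{off}$ and the mean OFF gap is $1/k_{on}$. While ON,
transcripts initiate at a loading rate and each contributes dot fluorescence
for a dwell time; the rendered dot is a Gaussian focus over background,
noise and exponential photobleaching ($2^{-t/t_{1/2}}$).

The analysis inverts that picture from pixels:

1. **Preprocess** — maximum-intensity z-projection, bleach correction
   (frame-mean ratio or exponential fit), nuclear-cycle stage splitting by
   user-supplied frame ranges.
2. **Detect** — green-channel threshold 55 (8-bit scale, strict `>`),
   connected-component labeling, per-dot area/centroid/mean brightness, and
   per-stage min–max brightness normalization.
3. **Track** — centroid-proximity linking with a distance threshold and a
   dark-gap tolerance, so a nucleus keeps its ID across OFF periods; greedy
   or optimal (Hungarian) assignment.
4. **Measure** — per-frame dot counts/sizes/brightness; per-stage timing
   metrics (first dot, first peak in active nuclei, time to all dots,
   initiation-window totals); per-track burst structure (ON runs, OFF gaps,
   burst counts, transitions).
5. **Compare** — Mann–Whitney U (exact enumeration for small samples),
   mean-difference permutation test (exact or seeded Monte-Carlo, with the
   sign-of-difference sidedness rule and a calibrated two-sided p alongside),
   variance-gated Student/Welch t-test, and F/Levene variance comparison,
   with the movie (embryo) as the statistical unit.

## Worked example

Simulate one small movie, render it, and run the full single-movie analysis:

```r
library(ms2burst)

cfg <- simConfig(nNucleiSide = 2L, fieldSizePx = 64L, nFramesPerStage = 40L,
                 ampPerTranscript = 120, noiseSd = 2, seed = 4L)
truth  <- simulateTelegraph(cfg)   # ground-truth states, counts, positions
movie  <- renderMovie(truth)       # T x Z x Y x X x C stack, 8-bit
bundle <- analyzeMovie(movie, simStagePartition(cfg))
#> stage nc14: 86 dots, 3 tracks, max n_dots 3

bundle$stage_metrics
#>   n_frames t_first_dot_s t_first_peak_s t_all_dots_s max_n_dots
#> 1       40          1.77           3.54        33.63          3
#>   avg_transcription_rate init_total_pixels init_active_nuclei intensity_peak_sd
#> 1                  41.29               424                  1             13.09
```

The first dot appears 1.77 s (one frame) into the stage; all 3 active nuclei
are engaged by 33.6 s; dots average 41.3 px, a size proxy for nascent
transcript number. Per-nucleus burst structure:

```r
head(bundle$track_features[, c("track_id", "start_time_s", "n_frames_present",
                               "avg_size_px", "max_brightness", "n_bursts",
                               "mean_on_run_s")])
#>   track_id start_time_s n_frames_present avg_size_px max_brightness n_bursts
#> 1        1         1.77               39       48.00          178.7        1
#> 2        2        24.78               26       35.04          158.9        1
#> 3        3        33.63               21       33.95          154.1        1
#>   mean_on_run_s
#> 1         69.03
#> 2         46.02
#> 3         37.17
```

Case-vs-control inference uses the same battery the figures rely on, e.g.

```r
permutationTest(c(3, 4), c(1, 2))
#> permutation: statistic = 2, p = 0.1667 (greater, exact)
#>   two-sided p = 0.3333
#>   n_case = 2, n_control = 2
```

(the observed mean difference +2 is beaten by none of the C(4,2) = 6 label
splits, so the one-sided exact p is 1/6). A full two-condition study —
simulate N movies per condition, analyze, and test every metric per stage —
is one call: `runPipeline(pipelineConfig(conditions = list(case = ...,
control = ...), nMovies = 7))`.

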