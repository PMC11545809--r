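test_that("frame metrics compute the stated aggregates", {
  d <- dotRows(c(0, 0), row = 1, col = 1, area = c(4L, 6L),
               bright = c(100, 200), norm = c(0.2, 0.8))
  fm <- frameMetrics(d, frames = 0:1)
  expect_equal(fm$n_dots, c(2L, 0L))
  expect_equal(fm$mean_size_px, c(5, NA))
  expect_equal(fm$total_size_px, c(10L, 0L))
  expect_equal(fm$mean_brightness, c(150, NA))
  expect_equal(fm$mean_norm_brightness, c(0.5, NA))
})

test_that("frame dot totals equal per-track frame totals (conservation)", {
  set.seed(44)
  d <- do.call(rbind, lapply(0:9, function(f)
    dotRows(rep(f, 4), row = runif(4, 0, 90), col = runif(4, 0, 90),
            area = sample(2:9, 4, TRUE))))
  d <- linkFrames(d, trackingParams(maxLinkDistPx = 10))
  fm <- frameMetrics(d, 0:9)
  tf <- trackFeatures(d, 1)
  expect_equal(sum(fm$n_dots), sum(tf$n_frames_present))
  expect_equal(sum(fm$total_size_px), sum(d$area_px))
})

test_that("stage metrics match the hand-evaluated example", {
  # n_dots series [0,1,3,2,3] at 1 s cadence, no smoothing
  d <- rbind(dotRows(1, 1, 1), dotRows(rep(2, 3), 1:3 * 10, 1),
             dotRows(rep(3, 2), 1:2 * 10, 1), dotRows(rep(4, 3), 1:3 * 10, 1))
  d$track_id <- 1L
  fm <- frameMetrics(d, 0:4)
  expect_equal(fm$n_dots, c(0L, 1L, 3L, 2L, 3L))
  sm <- stageMetrics(fm, d, frameIntervalS = 1, smoothW = 1L, stageStart = 0)
  expect_equal(sm$t_first_dot_s, 1)
  expect_equal(sm$t_first_peak_s, 2)
  expect_equal(sm$t_all_dots_s, 2)
  expect_equal(sm$max_n_dots, 3L)
})

test_that("monotone dot counts put the first peak at saturation", {
  d <- do.call(rbind, lapply(0:3, function(f)
    dotRows(rep(f, f + 1), row = seq_len(f + 1) * 10, col = 1)))
  d$track_id <- seq_len(nrow(d))
  fm <- frameMetrics(d, 0:3)
  sm <- stageMetrics(fm, d, frameIntervalS = 2, smoothW = 1L, stageStart = 0)
  expect_equal(sm$t_first_peak_s, sm$t_all_dots_s)
})

test_that("initiation window of 1 covers the whole stage", {
  set.seed(9)
  d <- do.call(rbind, lapply(2:9, function(f)
    dotRows(rep(f, 3), row = 1:3 * 10, col = 1, area = sample(1:9, 3))))
  d$track_id <- rep(1:3, 8)
  fm <- frameMetrics(d, 0:9)
  sm <- stageMetrics(fm, d, frameIntervalS = 1, initWindowFrac = 1,
                     stageStart = 0)
  expect_equal(sm$init_total_pixels, sum(d$area_px))
  expect_equal(sm$init_active_nuclei, 3)
})

test_that("a dotless stage yields missing times and zero max", {
  fm <- frameMetrics(ms2burst:::emptyDots(), 0:9)
  sm <- stageMetrics(fm, NULL, frameIntervalS = 1, stageStart = 0)
  expect_true(is.na(sm$t_first_dot_s))
  expect_true(is.na(sm$t_first_peak_s))
  expect_equal(sm$max_n_dots, 0L)
})

test_that("track features encode the burst run structure", {
  d <- dotRows(c(10:13, 16:20), row = 5, col = 5, id = 1L)
  tf <- trackFeatures(d, frameIntervalS = 1)
  expect_equal(tf$n_bursts, 2L)
  expect_equal(tf$n_transitions, 2L)
  runs <- trackRuns(d, 1)
  expect_equal(runs$duration_s[runs$kind == "on"], c(4, 5))
  expect_equal(runs$duration_s[runs$kind == "off"], 2)
  expect_equal(tf$start_time_s, 10)
  # always-on track
  d2 <- dotRows(0:7, row = 5, col = 5, id = 1L)
  tf2 <- trackFeatures(d2, frameIntervalS = 1.77)
  expect_equal(tf2$n_bursts, 1L)
  expect_equal(tf2$n_transitions, 0L)
  expect_equal(tf2$start_time_s, 0)
  expect_equal(tf2$mean_on_run_s, 8 * 1.77)
})

test_that("on-runs and off-gaps tile each track span exactly", {
  set.seed(66)
  for (i in 1:10) {
    frames <- sort(sample(0:40, sample(3:20, 1)))
    d <- dotRows(frames, row = 5, col = 5, id = 1L)
    runs <- trackRuns(d, 1)
    covered <- unlist(Map(seq, runs$start_frame, runs$end_frame))
    expect_equal(sort(covered), min(frames):max(frames))
    expect_false(any(duplicated(covered)))
    onFrames <- unlist(Map(seq, runs$start_frame[runs$kind == "on"],
                           runs$end_frame[runs$kind == "on"]))
    expect_setequal(onFrames, frames)
  }
})

test_that("dispersion stats follow the sample-SD and SEM formulas", {
  ds <- dispersionStats(c(2, 4, 6))
  expect_equal(ds$sd, 2)
  expect_equal(ds$sem, 2 / sqrt(3))
  expect_equal(ds$n, 3L)
  expect_equal(dispersionStats(rep(5, 4))$sd, 0)
  single <- dispersionStats(7)
  expect_true(is.na(single$sd))
  expect_true(single$degenerate)
  expect_error(dispersionStats(numeric(0)), "at least one")
})

test_that("recovered ON/OFF durations track the telegraph rates", {
  # parameter recovery through the ground-truth trajectory at moderate rates
  cfg <- simConfig(nNucleiSide = 8L, kOn = 0.02, kOff = 0.05,
                   frameIntervalS = 1.77, nFramesPerStage = 120L, seed = 31L)
  tr <- simulateTelegraph(cfg, nNuclei = 50L, initState = "stationary")
  est <- sojournEstimates(tr)
  on <- est[est$kind == "on", ]
  off <- est[est$kind == "off", ]
  expect_lt(abs(on$mean_s - 1 / 0.05), 2 * on$se_s)
  expect_lt(abs(off$mean_s - 1 / 0.02), 2 * off$se_s)
})

test_that("higher kOff yields more bursts per unit time", {
  nb <- vapply(c(slow = 0.05, fast = 0.2), function(koff) {
    counts <- vapply(1:4, function(s) {
      cfg <- simConfig(nNucleiSide = 5L, kOn = 0.05, kOff = koff,
                       nFramesPerStage = 300L, seed = 100L + s)
      tr <- simulateTelegraph(cfg, nNuclei = 25L, initState = "stationary")
      runs <- groundTruthRuns(tr, dropCensored = FALSE)
      sum(runs$kind == "on")
    }, numeric(1))
    mean(counts)
  }, numeric(1))
  expect_gt(nb[["fast"]], nb[["slow"]])
})
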