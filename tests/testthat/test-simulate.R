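test_that("absorbing OFF: kOn = 0 keeps every nucleus silent", {
  cfg <- simConfig(nNucleiSide = 2L, kOn = 0, nFramesPerStage = 40L,
                   seed = 11L)
  tr <- simulateTelegraph(cfg)
  expect_true(all(tr@states == 0L))
  expect_true(all(tr@transcripts == 0L))
})

test_that("permanently ON promoter reaches the loading x dwell steady state", {
  # kOff = 0 starting ON never switches; nascent count is the number of
  # initiations in the trailing dwell window, a Poisson(loadingRate * dwell)
  # stationary queue once t > dwell
  cfg <- simConfig(nNucleiSide = 3L, kOff = 0, kOn = 0.02, loadingRate = 0.5,
                   transcriptDwellS = 30, frameIntervalS = 1.77,
                   nFramesPerStage = 4000L, seed = 5L)
  tr <- simulateTelegraph(cfg, nNuclei = 5L, initState = "on")
  expect_true(all(tr@states == 1L))
  burnIn <- ceiling(cfg@transcriptDwellS / cfg@frameIntervalS) + 1L
  cnt <- tr@transcripts[, burnIn:ncol(tr@transcripts)]
  expect_lt(abs(mean(cnt) - 0.5 * 30), 0.5)
})

test_that("stationary ON fraction matches kOn / (kOn + kOff)", {
  cfg <- simConfig(nNucleiSide = 7L, kOn = 0.02, kOff = 0.05,
                   nFramesPerStage = 500L, seed = 21L)
  tr <- simulateTelegraph(cfg, nNuclei = 40L, initState = "stationary")
  perNuc <- rowMeans(tr@states == 1L)
  est <- mean(perNuc)
  se <- sd(perNuc) / sqrt(length(perNuc))
  expect_lt(abs(est - 0.02 / 0.07), 3 * se)
})

test_that("mean discretized ON-run length approaches 1 / (kOff * dt)", {
  cfg <- simConfig(nNucleiSide = 7L, kOn = 0.05, kOff = 0.02,
                   frameIntervalS = 0.25, nFramesPerStage = 4000L, seed = 9L)
  tr <- simulateTelegraph(cfg, nNuclei = 30L, initState = "stationary")
  runs <- groundTruthRuns(tr)
  on <- runs$duration_s[runs$kind == "on"] / cfg@frameIntervalS
  se <- sd(on) / sqrt(length(on))
  # kOff * dt = 0.005 << 1, discretization bias is negligible here
  expect_lt(abs(mean(on) - 1 / (0.02 * 0.25)), 3 * se)
})

test_that("same seed reproduces identical truth and movie", {
  cfg <- cleanConfig(nNucleiSide = 2L, nFrames = 10L, seed = 33L, noiseSd = 3)
  t1 <- simulateTelegraph(cfg); t2 <- simulateTelegraph(cfg)
  expect_identical(t1@states, t2@states)
  expect_identical(t1@transcripts, t2@transcripts)
  expect_identical(t1@rowPos, t2@rowPos)
  m1 <- renderMovie(t1); m2 <- renderMovie(t2)
  expect_identical(m1@pixels, m2@pixels)
})

test_that("negative or non-finite rates are rejected", {
  expect_error(simConfig(kOn = -1), "rates")
  expect_error(simConfig(kOff = NaN), "rates")
})

test_that("zero transcripts and zero noise render a flat background", {
  cfg <- cleanConfig(nNucleiSide = 2L, nFrames = 4L, kOn = 0)
  tr <- simulateTelegraph(cfg)
  mv <- renderMovie(tr)
  green <- mv@pixels[, , , , 1L]
  expect_true(all(green == cfg@backgroundLevel))
})

test_that("rendered peak matches background + count x amplitude", {
  cfg <- simConfig(nNucleiSide = 1L, fieldSizePx = 33L, nFramesPerStage = 1L,
                   noiseSd = 0, ampPerTranscript = 20, backgroundLevel = 10,
                   bleachHalflifeS = Inf, dotDiffusionPx = 0, psfSigmaPx = 1.5,
                   seed = 2L, bitDepth = 16L)
  tr <- simulateTelegraph(cfg)
  tr@transcripts[1L, 1L] <- 5L   # pin the count; position is the grid centre
  tr@rowPos[1L, 1L] <- tr@nucleusRow[1L, 1L] <- 16
  tr@colPos[1L, 1L] <- tr@nucleusCol[1L, 1L] <- 16
  mv <- renderMovie(tr)
  peak <- max(mv@pixels[1L, 1L, , , 1L])
  expect_lt(abs(peak - (10 + 5 * 20)), 1.5)  # PSF discretization + rounding
})

test_that("rendering is linear in amplitude when noise-free", {
  base <- cleanConfig(nNucleiSide = 2L, nFrames = 6L, seed = 14L,
                      bitDepth = 16L)
  tr <- simulateTelegraph(base)
  doubled <- base
  doubled@ampPerTranscript <- 2 * base@ampPerTranscript
  m1 <- renderMovie(tr, base)
  m2 <- renderMovie(tr, doubled)
  g1 <- m1@pixels[, , , , 1L] - base@backgroundLevel
  g2 <- m2@pixels[, , , , 1L] - base@backgroundLevel
  expect_lt(max(abs(g2 - 2 * g1)), 1.5)   # rounding of each frame only
})

test_that("half-life equal to the movie span halves the last-frame scale", {
  cfg <- cleanConfig(nNucleiSide = 1L, nFrames = 11L)
  span <- 10 * cfg@frameIntervalS       # t of the last frame
  cfg@bleachHalflifeS <- span
  tr <- simulateTelegraph(cfg)
  expect_equal(tr@bleachFactor[11L], 0.5)
  expect_equal(tr@bleachFactor[1L], 1)
})

test_that("mitosis resets state to OFF at stage boundaries", {
  # kOn = 0 makes OFF absorbing: a nucleus started ON stays ON through stage 1
  # but every later stage restarts OFF and can never leave it
  cfg <- simConfig(nNucleiSide = 3L, stageLabels = c("nc12", "nc13", "nc14"),
                   nFramesPerStage = 30L, kOn = 0, kOff = 0, seed = 8L)
  tr <- simulateTelegraph(cfg, initState = "on")
  s1 <- seq_len(30L)
  expect_true(all(tr@states[, s1] == 1L))
  expect_true(all(tr@states[, -s1] == 0L))
  expect_true(all(tr@transcripts[, -s1] == 0L))
})

test_that("field too small for the nuclear grid is rejected", {
  expect_error(simulateTelegraph(simConfig(nNucleiSide = 10L,
                                           fieldSizePx = 20L)),
               "field too small")
})
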