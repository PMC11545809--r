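test_that("a drifting dot stays one track", {
  d <- dotRows(0:9, row = 10 + 2 * (0:9), col = 20)
  out <- linkFrames(d, trackingParams(maxLinkDistPx = 15))
  expect_equal(length(unique(out$track_id)), 1)
  expect_equal(out$track_id, rep(1L, 10))
})

test_that("two distant stationary dots keep distinct IDs with no swap", {
  d <- rbind(dotRows(0:19, row = 10, col = 10),
             dotRows(0:19, row = 60, col = 60))
  out <- linkFrames(d, trackingParams(maxLinkDistPx = 15))
  expect_equal(length(unique(out$track_id)), 2)
  idOf <- tapply(out$track_id, out$row, unique)
  expect_length(idOf[["10"]], 1)
  expect_length(idOf[["60"]], 1)
})

test_that("tracks persist through OFF gaps within the tolerance", {
  d <- dotRows(c(0:4, 7:10), row = 5, col = 5)
  out <- linkFrames(d, trackingParams(maxGapFrames = 10L))
  expect_equal(length(unique(out$track_id)), 1)
  runs <- trackRuns(out, frameIntervalS = 1)
  on <- runs[runs$kind == "on", ]
  off <- runs[runs$kind == "off", ]
  expect_equal(cbind(on$start_frame, on$end_frame),
               cbind(c(0L, 7L), c(4L, 10L)))
  expect_equal(cbind(off$start_frame, off$end_frame), cbind(5L, 6L))
})

test_that("gaps beyond the tolerance start a new track", {
  d <- dotRows(c(0:2, 6:8), row = 5, col = 5)
  out <- linkFrames(d, trackingParams(maxGapFrames = 2L))
  expect_equal(length(unique(out$track_id)), 2)
  out0 <- linkFrames(d, trackingParams(maxGapFrames = 10L))
  expect_equal(length(unique(out0$track_id)), 1)
})

test_that("maxGapFrames = 0 reproduces strict previous-frame linking", {
  d <- dotRows(c(0, 1, 3, 4), row = 5, col = 5)
  out <- linkFrames(d, trackingParams(maxGapFrames = 0L))
  expect_equal(length(unique(out$track_id)), 2)
})

test_that("every observation belongs to exactly one track", {
  set.seed(13)
  d <- do.call(rbind, lapply(0:14, function(f)
    dotRows(rep(f, 6), row = runif(6, 0, 100), col = runif(6, 0, 100))))
  out <- linkFrames(d, trackingParams(maxLinkDistPx = 8))
  expect_equal(nrow(out), nrow(d))
  expect_false(any(is.na(out$track_id)))
  # no duplicated (frame, track) pair: a track holds <= 1 dot per frame
  expect_false(any(duplicated(out[, c("frame", "track_id")])))
})

test_that("tracking never crosses a stage boundary", {
  d <- rbind(dotRows(0:9, row = 5, col = 5, stage = "nc13"),
             dotRows(10:19, row = 5, col = 5, stage = "nc14"))
  out <- linkFrames(d, trackingParams())
  byStage <- split(out$track_id, out$stage)
  expect_equal(unique(byStage$nc13), 1L)
  expect_equal(unique(byStage$nc14), 1L)   # IDs restart per stage
  expect_equal(length(unique(paste(out$stage, out$track_id))), 2)
})

test_that("Hungarian solver matches exhaustive search on random instances", {
  set.seed(99)
  for (i in 1:40) {
    n <- sample(1:5, 1); m <- sample(1:5, 1)
    cost <- matrix(round(runif(n * m, 0, 100), 1), n, m)
    if (runif(1) < 0.4) cost[runif(n * m) < 0.3] <- Inf
    got <- solveAssignment(cost)
    want <- bruteForceAssignment(cost)
    totalOf <- function(a) sum(cost[cbind(which(!is.na(a)),
                                          a[!is.na(a)])])
    expect_equal(sum(!is.na(got)), sum(!is.na(want)))
    expect_equal(totalOf(got), totalOf(want), tolerance = 1e-9)
    if (any(!is.na(got)))
      expect_false(any(duplicated(got[!is.na(got)])))
  }
})

test_that("greedy and optimal agree when candidates are unambiguous", {
  set.seed(7)
  for (i in 1:10) {
    # well-separated lattice of drifting dots: unique in-range candidates
    base <- expand.grid(row = c(10, 50, 90), col = c(10, 50, 90))
    d <- do.call(rbind, lapply(0:9, function(f)
      dotRows(rep(f, 9), row = base$row + rnorm(9), col = base$col + rnorm(9))))
    g <- linkFrames(d, trackingParams(assignment = "greedy"))
    o <- linkFrames(d, trackingParams(assignment = "optimal"))
    expect_equal(g$track_id, o$track_id)
  }
})

test_that("ambiguous links resolve by total distance in optimal mode", {
  # two tracks at rows 0 and 3; next frame dots at rows 1 and 9: greedy takes
  # (0 -> 1) leaving (3 -> 9, d = 6); optimal prefers (0 hangs back) pairing
  # that minimizes the sum: (1 <- 3 is nearer than 9 <- 3)
  d <- rbind(dotRows(c(0, 0), row = c(0, 3), col = 0),
             dotRows(c(1, 1), row = c(1, 9), col = 0))
  g <- linkFrames(d, trackingParams(maxLinkDistPx = 10, assignment = "greedy"))
  o <- linkFrames(d, trackingParams(maxLinkDistPx = 10, assignment = "optimal"))
  gRow1 <- g[g$frame == 1, ]
  oRow1 <- o[o$frame == 1, ]
  # greedy: dot at row 1 links to the nearest track (row 0)
  expect_equal(gRow1$track_id[gRow1$row == 1], 1L)
  # optimal: total cost 1+6=7 (greedy) vs 2+9 -> optimal keeps greedy's 7;
  # both assign all dots, but totals must be minimal
  dist <- function(out) {
    f0 <- out[out$frame == 0, ]; f1 <- out[out$frame == 1, ]
    sum(abs(f1$row[match(f0$track_id, f1$track_id)] - f0$row), na.rm = TRUE)
  }
  expect_lte(dist(o), dist(g))
})

test_that("tracks table round-trips observations losslessly", {
  set.seed(21)
  d <- do.call(rbind, lapply(0:5, function(f)
    dotRows(rep(f, 3), row = runif(3, 0, 50), col = runif(3, 0, 50),
            bright = runif(3, 60, 200), norm = runif(3))))
  out <- linkFrames(d, trackingParams())
  tab <- tracksToTable(out)
  expect_equal(nrow(tab), nrow(d))
  # regroup and compare as sets of observations
  key <- function(x) paste(x$frame, round(x$row, 9), round(x$col, 9))
  expect_setequal(key(tab), key(d))
  expect_equal(nrow(tracksToTable(ms2burst:::emptyDots())), 0)
})

test_that("clean fixtures give a track-to-nucleus bijection", {
  cfg <- cleanConfig(nNucleiSide = 3L, nFrames = 40L, seed = 3L)
  tr <- simulateTelegraph(cfg)
  mv <- maxProject(renderMovie(tr))
  dots <- linkFrames(detectMovie(mv, simStagePartition(cfg)),
                     trackingParams())
  # map each observation to its nearest true nucleus
  nn <- apply(cbind(dots$row, dots$col), 1, function(p)
    which.min((tr@nucleusRow[, 1] - p[1])^2 + (tr@nucleusCol[, 1] - p[2])^2))
  tab <- table(dots$track_id, nn)
  expect_true(all(rowSums(tab > 0) == 1))   # each track: one nucleus
  expect_true(all(colSums(tab > 0) <= 1))   # each nucleus: at most one track
})
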