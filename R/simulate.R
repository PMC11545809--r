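# Synthetic two-channel movie generator: telegraph-model transcription dots
# rendered with a Gaussian PSF over a nuclear field, with full ground truth.

# Continuous-time two-state trajectory over [0, tEnd); returns switch times
# and states. states[i] holds on (tSwitch[i], tSwitch[i+1]]-style segments:
# segment i spans [tSwitch[i], tSwitch[i+1]) with value stateSeq[i].
sampleTelegraphPath <- function(kOn, kOff, tEnd, initOn) {
  tSwitch <- 0
  stateSeq <- as.integer(initOn)
  t <- 0
  s <- initOn
  repeat {
    rate <- if (s) kOff else kOn
    if (rate <= 0) break              # absorbing state
    t <- t + stats::rexp(1L, rate)
    if (t >= tEnd) break
    s <- !s
    tSwitch <- c(tSwitch, t)
    stateSeq <- c(stateSeq, as.integer(s))
  }
  list(t = c(tSwitch, tEnd), state = stateSeq)
}

# State of a piecewise-constant path at query times.
pathStateAt <- function(path, times) {
  idx <- findInterval(times, path$t, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > length(path$state)] <- length(path$state)
  path$state[idx]
}

# ON intervals [a, b) of a path, clipped to [0, tEnd).
pathOnIntervals <- function(path) {
  k <- which(path$state == 1L)
  if (!length(k)) return(matrix(numeric(0), ncol = 2L))
  cbind(path$t[k], path$t[k + 1L])
}

#' Simulate telegraph-model transcription for a field of nuclei
#'
#' Each nucleus carries an independent two-state promoter switching ON at rate
#' \code{kOn} and OFF at rate \code{kOff} (continuous-time Markov chain).
#' While ON, transcripts initiate as a Poisson process at \code{loadingRate};
#' each initiated transcript contributes signal for a deterministic dwell of
#' \code{transcriptDwellS} seconds. The chain is discretized by its state at
#' each frame midpoint; the transcript count at a frame is the number of
#' initiation events inside the trailing dwell window ending at that midpoint.
#'
#' At every stage boundary (mitosis) all promoters reset to OFF, nascent
#' transcripts are cleared, and nucleus positions are re-jittered; there is no
#' lineage tracking. Dot centroids random-walk around the nucleus centre with
#' per-frame jitter SD \code{dotDiffusionPx}.
#'
#' @param config a [SimConfig-class]. Its \code{seed} drives all randomness;
#'   the caller's RNG state is left untouched.
#' @param nNuclei number of nuclei; defaults to \code{nNucleiSide^2}. Values
#'   other than the default override the grid count (positions are tiled on an
#'   enlarged grid if needed).
#' @param initState initial promoter state at movie start: \code{"off"}
#'   (default, as after mitosis), \code{"on"}, or \code{"stationary"}
#'   (Bernoulli with the equilibrium ON probability kOn/(kOn+kOff)).
#' @return A [GroundTruth-class].
#' @examples
#' cfg <- simConfig(nNucleiSide = 2L, nFramesPerStage = 30L, seed = 7L)
#' truth <- simulateTelegraph(cfg)
#' truth
#' @export
simulateTelegraph <- function(config, nNuclei = config@nNucleiSide^2,
                              initState = c("off", "on", "stationary")) {
  validObject(config)
  initState <- match.arg(initState)
  nNuclei <- as.integer(nNuclei)
  stopifnot(nNuclei >= 1L)
  dt <- config@frameIntervalS
  nStages <- length(config@stageLabels)
  nPerStage <- config@nFramesPerStage
  nT <- nStages * nPerStage
  fs <- config@fieldSizePx

  # grid of nucleus home positions (0-based pixel coords)
  side <- max(config@nNucleiSide, ceiling(sqrt(nNuclei)))
  pitch <- fs / side
  if (pitch < 4 * config@psfSigmaPx)
    stop("field too small for requested nuclei: pitch ", format(pitch),
         " px < 4 x psfSigmaPx")
  centres1d <- (seq_len(side) - 0.5) * pitch - 0.5
  grid <- expand.grid(row = centres1d, col = centres1d)[seq_len(nNuclei), ]

  states <- matrix(0L, nNuclei, nT)
  transcripts <- matrix(0L, nNuclei, nT)
  rowPos <- matrix(0, nNuclei, nT)
  colPos <- matrix(0, nNuclei, nT)
  nucleusRow <- matrix(0, nNuclei, nStages)
  nucleusCol <- matrix(0, nNuclei, nStages)
  stageStarts <- (seq_len(nStages) - 1L) * nPerStage

  withr::with_seed(config@seed, {
    for (s in seq_len(nStages)) {
      frames <- stageStarts[s] + seq_len(nPerStage)   # 1-based column idx
      tMid <- (seq_len(nPerStage) - 0.5) * dt          # within-stage time
      tEnd <- nPerStage * dt
      # mitotic re-jitter of nucleus centres (quarter-pitch SD, clipped)
      nucleusRow[, s] <- pmin(pmax(grid$row + stats::rnorm(nNuclei, 0, pitch / 8),
                                   0), fs - 1)
      nucleusCol[, s] <- pmin(pmax(grid$col + stats::rnorm(nNuclei, 0, pitch / 8),
                                   0), fs - 1)
      for (i in seq_len(nNuclei)) {
        startOn <- if (s > 1L) FALSE else switch(initState,
          off = FALSE, on = TRUE,
          stationary = stats::runif(1L) <
            config@kOn / max(config@kOn + config@kOff, .Machine$double.eps))
        path <- sampleTelegraphPath(config@kOn, config@kOff, tEnd, startOn)
        states[i, frames] <- pathStateAt(path, tMid)
        # transcript initiation events: Poisson within ON intervals
        onIv <- pathOnIntervals(path)
        if (nrow(onIv) && config@loadingRate > 0) {
          ev <- unlist(lapply(seq_len(nrow(onIv)), function(j) {
            len <- onIv[j, 2L] - onIv[j, 1L]
            n <- stats::rpois(1L, config@loadingRate * len)
            if (n > 0L) onIv[j, 1L] + sort(stats::runif(n, 0, len)) else numeric(0)
          }))
          if (length(ev)) {
            lo <- findInterval(tMid - config@transcriptDwellS, ev)
            hi <- findInterval(tMid, ev)
            transcripts[i, frames] <- as.integer(hi - lo)
          }
        }
        # dot centroid random walk about the nucleus centre
        jit <- config@dotDiffusionPx
        rowPos[i, frames] <- pmin(pmax(
          nucleusRow[i, s] + stats::rnorm(nPerStage, 0, jit), 0), fs - 1)
        colPos[i, frames] <- pmin(pmax(
          nucleusCol[i, s] + stats::rnorm(nPerStage, 0, jit), 0), fs - 1)
      }
    }
  })

  bleach <- 2^(-(seq_len(nT) - 1L) * dt / config@bleachHalflifeS)
  new("GroundTruth", states = states, transcripts = transcripts,
      rowPos = rowPos, colPos = colPos,
      nucleusRow = nucleusRow, nucleusCol = nucleusCol,
      stageStarts = stageStarts, stageLabels = config@stageLabels,
      bleachFactor = bleach, config = config)
}

#' Ground-truth ON/OFF run durations
#'
#' Run-length encodes each nucleus's frame-discretized state trajectory into
#' ON runs and OFF gaps, for validating parameter recovery. Runs touching a
#' stage boundary (censored by mitosis or the movie edge) can be dropped.
#'
#' @param truth a [GroundTruth-class]
#' @param dropCensored drop runs abutting stage boundaries (default TRUE)
#' @return \code{data.frame} with nucleus_id (0-based), stage, kind
#'   ("on"/"off"), start_frame, end_frame (0-based inclusive), and
#'   duration_s = frames x frameIntervalS.
#' @export
groundTruthRuns <- function(truth, dropCensored = TRUE) {
  cfg <- truth@config
  out <- list()
  nPerStage <- cfg@nFramesPerStage
  for (s in seq_along(truth@stageLabels)) {
    cols <- truth@stageStarts[s] + seq_len(nPerStage)
    for (i in seq_len(nrow(truth@states))) {
      r <- rle(truth@states[i, cols])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- rep(TRUE, length(r$lengths))
      if (dropCensored && length(keep)) {
        keep[1L] <- FALSE
        keep[length(keep)] <- FALSE
      }
      if (!any(keep)) next
      out[[length(out) + 1L]] <- data.frame(
        nucleus_id = i - 1L, stage = truth@stageLabels[s],
        kind = ifelse(r$values[keep] == 1L, "on", "off"),
        start_frame = truth@stageStarts[s] + starts[keep] - 1L,
        end_frame = truth@stageStarts[s] + ends[keep] - 1L,
        duration_s = r$lengths[keep] * cfg@frameIntervalS,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(nucleus_id = integer(0), stage = character(0),
                      kind = character(0), start_frame = integer(0),
                      end_frame = integer(0), duration_s = numeric(0)))
  do.call(rbind, out)
}

#' Censoring-aware mean ON/OFF sojourn estimates
#'
#' Estimates the mean ON-run and OFF-gap durations of the frame-discretized
#' promoter trajectories as exposure time divided by completed transitions —
#' the maximum-likelihood estimator for exponential sojourns under window
#' censoring. Per nucleus-stage trajectory the initial partial run is
#' discarded (its start is unobserved, so its length is inspection-biased);
#' the final, end-censored run contributes exposure but no event. Naively
#' averaging only the fully observed runs would instead under-estimate long
#' sojourns, which are the ones the stage window truncates.
#'
#' The standard error uses the exponential-theory approximation
#' \code{mean / sqrt(n_events)}.
#'
#' @param truth a [GroundTruth-class]
#' @return \code{data.frame} with kind ("on"/"off"), mean_s, se_s, n_events,
#'   exposure_s
#' @export
sojournEstimates <- function(truth) {
  cfg <- truth@config
  dt <- cfg@frameIntervalS
  nPerStage <- cfg@nFramesPerStage
  expo <- c(on = 0, off = 0)
  events <- c(on = 0L, off = 0L)
  for (s in seq_along(truth@stageLabels)) {
    cols <- truth@stageStarts[s] + seq_len(nPerStage)
    for (i in seq_len(nrow(truth@states))) {
      r <- rle(truth@states[i, cols])
      k <- length(r$lengths)
      if (k < 2L) next                     # no transition observed
      for (j in 2L:k) {
        kind <- if (r$values[j] == 1L) "on" else "off"
        expo[kind] <- expo[kind] + r$lengths[j]
        if (j < k) events[kind] <- events[kind] + 1L
      }
    }
  }
  mean_s <- ifelse(events > 0L, expo * dt / events, NA_real_)
  data.frame(kind = names(expo), mean_s = unname(mean_s),
             se_s = unname(ifelse(events > 0L, mean_s / sqrt(events),
                                  NA_real_)),
             n_events = unname(events), exposure_s = unname(expo * dt),
             stringsAsFactors = FALSE)
}

# Gaussian dot splat: adds amp * exp(-d^2 / (2 sigma^2)) to `img` around
# (r0, c0) (0-based), within a +-4 sigma window.
addGaussianDot <- function(img, r0, c0, amp, sigma) {
  n <- nrow(img); m <- ncol(img)
  w <- ceiling(4 * sigma)
  rs <- max(1L, floor(r0 + 1 - w)):min(n, ceiling(r0 + 1 + w))
  cs <- max(1L, floor(c0 + 1 - w)):min(m, ceiling(c0 + 1 + w))
  if (!length(rs) || !length(cs)) return(img)
  dr2 <- (rs - 1 - r0)^2
  dc2 <- (cs - 1 - c0)^2
  img[rs, cs] <- img[rs, cs] + amp * exp(-outer(dr2, dc2, "+") / (2 * sigma^2))
  img
}

# Nuclear-envelope ring around (r0, c0), radius rad, thickness th.
addRing <- function(img, r0, c0, rad, th, amp) {
  n <- nrow(img); m <- ncol(img)
  w <- ceiling(rad + th)
  rs <- max(1L, floor(r0 + 1 - w)):min(n, ceiling(r0 + 1 + w))
  cs <- max(1L, floor(c0 + 1 - w)):min(m, ceiling(c0 + 1 + w))
  if (!length(rs) || !length(cs)) return(img)
  d <- sqrt(outer((rs - 1 - r0)^2, (cs - 1 - c0)^2, "+"))
  img[rs, cs] <- img[rs, cs] + amp * (abs(d - rad) <= th / 2)
  img
}

#' Render a ground truth into a two-channel movie stack
#'
#' Forward model of the acquisition: the green channel is the sum of Gaussian
#' dots with amplitude \code{ampPerTranscript x transcript count x bleach
#' factor}, plus a flat background and (optionally) Gaussian read noise,
#' clipped to the sample bit depth. The red channel renders each nucleus as an
#' envelope ring. The bleach factor is \code{2^(-t / bleachHalflifeS)}. With
#' \code{nZPlanes > 1}, planes away from the central in-focus plane carry
#' defocused dot copies (wider, dimmer Gaussians), so maximum projection
#' recovers the in-focus image.
#'
#' Noise is seeded from \code{config@seed} (offset so it is independent of the
#' simulation draws); rendering the same truth twice gives identical pixels.
#'
#' @param truth a [GroundTruth-class]
#' @param config a [SimConfig-class] consistent with \code{truth} (defaults to
#'   the config embedded in \code{truth})
#' @return A [MovieStack-class] (T x Z x Y x X x C; C = 2: green, red).
#' @examples
#' cfg <- simConfig(nNucleiSide = 2L, fieldSizePx = 48L,
#'                  nFramesPerStage = 5L, noiseSd = 0)
#' mv <- renderMovie(simulateTelegraph(cfg))
#' mv
#' @export
renderMovie <- function(truth, config = truth@config) {
  validObject(config)
  nT <- ncol(truth@states)
  if (nT != length(config@stageLabels) * config@nFramesPerStage)
    stop("truth and config disagree on total frame count")
  fs <- config@fieldSizePx
  nZ <- config@nZPlanes
  maxVal <- 2^config@bitDepth - 1
  nNuc <- nrow(truth@states)
  side <- max(config@nNucleiSide, ceiling(sqrt(nNuc)))
  pitch <- fs / side
  nucRad <- 0.35 * pitch
  midZ <- (nZ + 1) / 2

  pix <- array(0, dim = c(nT, nZ, fs, fs, 2L))
  stageOf <- findInterval(seq_len(nT) - 1L, truth@stageStarts)
  withr::with_seed(config@seed + 1L, {
    for (f in seq_len(nT)) {
      bf <- truth@bleachFactor[f]
      s <- stageOf[f]
      for (z in seq_len(nZ)) {
        defocus <- abs(z - midZ)              # in plane units
        sig <- config@psfSigmaPx * (1 + 0.8 * defocus)
        att <- (config@psfSigmaPx / sig)^2    # conserve integrated signal
        g <- matrix(config@backgroundLevel, fs, fs)
        r <- matrix(config@backgroundLevel / 2, fs, fs)
        for (i in seq_len(nNuc)) {
          cnt <- truth@transcripts[i, f]
          if (cnt > 0L)
            g <- addGaussianDot(g, truth@rowPos[i, f], truth@colPos[i, f],
                                config@ampPerTranscript * cnt * bf * att, sig)
          r <- addRing(r, truth@nucleusRow[i, s], truth@nucleusCol[i, s],
                       nucRad, 2, 0.6 * maxVal * att)
        }
        if (config@noiseSd > 0) {
          g <- g + stats::rnorm(fs * fs, 0, config@noiseSd)
          r <- r + stats::rnorm(fs * fs, 0, config@noiseSd)
        }
        pix[f, z, , , 1L] <- pmin(pmax(round(g), 0), maxVal)
        pix[f, z, , , 2L] <- pmin(pmax(round(r), 0), maxVal)
      }
    }
  })
  new("MovieStack", pixels = pix, pixelSizeUm = 0.1,
      frameIntervalS = config@frameIntervalS, bitDepth = config@bitDepth,
      channelRoles = c(green = 1L, red = 2L))
}

#' Ground truth as a long-form table
#'
#' @param truth a [GroundTruth-class]
#' @return \code{data.frame} with nucleus_id, frame (0-based), stage, state
#'   (0/1), transcript_count, row, col — one row per nucleus per frame.
#' @export
truthTable <- function(truth) {
  nNuc <- nrow(truth@states)
  nT <- ncol(truth@states)
  stageOf <- truth@stageLabels[findInterval(seq_len(nT) - 1L,
                                            truth@stageStarts)]
  data.frame(
    nucleus_id = rep(seq_len(nNuc) - 1L, times = nT),
    frame = rep(seq_len(nT) - 1L, each = nNuc),
    stage = rep(stageOf, each = nNuc),
    state = as.integer(truth@states),
    transcript_count = as.integer(truth@transcripts),
    row = as.numeric(truth@rowPos),
    col = as.numeric(truth@colPos),
    stringsAsFactors = FALSE)
}
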