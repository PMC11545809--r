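# Burst metrics: per-frame aggregates, per-stage (tissue-level) summaries,
# and per-track (single-nucleus) features. All times are seconds, sizes are
# pixels; frame indices are 0-based.

#' Per-frame dot aggregates
#'
#' For each frame of the stated range: number of dots, mean and total dot size
#' (pixels), mean brightness and mean normalized brightness. Frames with no
#' dots get n_dots = 0, total_size_px = 0 and \code{NA} means.
#'
#' @param dots dots \code{data.frame} for one stage
#' @param frames integer vector of 0-based frames to cover; defaults to the
#'   full range seen in \code{dots}
#' @return \code{data.frame}: frame, n_dots, mean_size_px, total_size_px,
#'   mean_brightness, mean_norm_brightness
#' @examples
#' d <- data.frame(stage = "s", frame = 0L, row = 0, col = 0,
#'                 area_px = c(4L, 6L), mean_brightness = c(100, 200),
#'                 norm_brightness = c(0, 1), track_id = 1:2)
#' frameMetrics(d, frames = 0:1)
#' @export
frameMetrics <- function(dots, frames = NULL) {
  if (is.null(frames)) {
    if (!nrow(dots)) stop("no dots and no frame range given")
    frames <- min(dots$frame):max(dots$frame)
  }
  frames <- as.integer(frames)
  out <- data.frame(frame = frames, n_dots = 0L, mean_size_px = NA_real_,
                    total_size_px = 0L, mean_brightness = NA_real_,
                    mean_norm_brightness = NA_real_)
  if (nrow(dots)) {
    g <- split(seq_len(nrow(dots)), dots$frame)
    pos <- match(as.integer(names(g)), frames)
    for (k in seq_along(g)) {
      if (is.na(pos[k])) next
      ii <- g[[k]]
      out$n_dots[pos[k]] <- length(ii)
      out$mean_size_px[pos[k]] <- mean(dots$area_px[ii])
      out$total_size_px[pos[k]] <- sum(dots$area_px[ii])
      out$mean_brightness[pos[k]] <- mean(dots$mean_brightness[ii])
      out$mean_norm_brightness[pos[k]] <- mean(dots$norm_brightness[ii])
    }
  }
  out
}

# centered moving average, window w (odd); shorter windows at the edges
movingAverage <- function(x, w) {
  if (w <= 1L) return(x)
  h <- (w - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1L, i - h):min(n, i + h)]), numeric(1))
}

# first local maximum of a (smoothed) series: first index i with
# s[i] >= neighbors and s[i] > 0
firstPeakIndex <- function(x, w = 3L) {
  s <- movingAverage(x, w)
  n <- length(s)
  for (i in seq_len(n)) {
    leftOk <- i == 1L || s[i] >= s[i - 1L]
    rightOk <- i == n || s[i] >= s[i + 1L]
    if (leftOk && rightOk && s[i] > 0) return(i)
  }
  NA_integer_
}

#' Tissue-level stage summary
#'
#' Timing and magnitude summaries of one nuclear-cycle stage. Times are
#' seconds from the stage's first frame (\code{t = (frame - stageStart) *
#' frameIntervalS}):
#' \itemize{
#'   \item \code{t_first_dot_s}: first frame with any dot.
#'   \item \code{t_first_peak_s}: first local maximum of the n_dots series
#'     after moving-average smoothing (window \code{smoothW}) — the initial
#'     spike in active nuclei.
#'   \item \code{t_all_dots_s}: first frame at which n_dots reaches its stage
#'     maximum (time to initiation of all dots).
#'   \item \code{max_n_dots}: stage maximum of n_dots.
#'   \item \code{avg_transcription_rate}: stage mean of per-frame mean dot
#'     size (dot size proxies nascent transcript number).
#'   \item \code{init_total_pixels} / \code{init_active_nuclei}: total dot
#'     pixels / distinct active tracks within the transcription-initiation
#'     window, defined as the first \code{ceiling(initWindowFrac x stage
#'     length)} frames from first detection.
#'   \item \code{intensity_peak_sd}: SD across tracks of each track's peak
#'     (maximum) mean brightness.
#' }
#' A stage with zero dots yields missing times and \code{max_n_dots = 0}.
#'
#' @param fm per-frame metrics from [frameMetrics()] covering the whole stage
#' @param dots tracked dots of the stage (needs \code{track_id} for
#'   \code{init_active_nuclei} and \code{intensity_peak_sd}; untracked dots
#'   fall back to per-observation counting with a message)
#' @param frameIntervalS seconds per frame
#' @param initWindowFrac fraction of the stage length forming the initiation
#'   window (default 0.25)
#' @param smoothW moving-average window for peak finding, frames (default 3)
#' @param stageStart 0-based first frame of the stage (default:
#'   \code{min(fm$frame)})
#' @return one-row \code{data.frame} of the fields above plus n_frames
#' @export
stageMetrics <- function(fm, dots = NULL, frameIntervalS = 1,
                         initWindowFrac = 0.25, smoothW = 3L,
                         stageStart = min(fm$frame)) {
  nF <- nrow(fm)
  dt <- frameIntervalS
  res <- data.frame(n_frames = nF, t_first_dot_s = NA_real_,
                    t_first_peak_s = NA_real_, t_all_dots_s = NA_real_,
                    max_n_dots = max(fm$n_dots),
                    avg_transcription_rate = NA_real_,
                    init_total_pixels = NA_real_,
                    init_active_nuclei = NA_real_,
                    intensity_peak_sd = NA_real_)
  if (res$max_n_dots == 0L) return(res)
  firstIdx <- which(fm$n_dots > 0L)[1L]
  res$t_first_dot_s <- (fm$frame[firstIdx] - stageStart) * dt
  pk <- firstPeakIndex(fm$n_dots, smoothW)
  if (!is.na(pk)) res$t_first_peak_s <- (fm$frame[pk] - stageStart) * dt
  allIdx <- which(fm$n_dots == res$max_n_dots)[1L]
  res$t_all_dots_s <- (fm$frame[allIdx] - stageStart) * dt
  res$avg_transcription_rate <- mean(fm$mean_size_px, na.rm = TRUE)
  winLen <- ceiling(initWindowFrac * nF)
  winFrames <- fm$frame[firstIdx] + seq_len(winLen) - 1L
  inWin <- fm$frame %in% winFrames
  res$init_total_pixels <- sum(fm$total_size_px[inWin])
  if (!is.null(dots) && nrow(dots)) {
    dWin <- dots[dots$frame %in% winFrames, , drop = FALSE]
    if (all(!is.na(dots$track_id))) {
      res$init_active_nuclei <- length(unique(dWin$track_id))
      peaks <- tapply(dots$mean_brightness, dots$track_id, max)
      res$intensity_peak_sd <- if (length(peaks) > 1L) stats::sd(peaks)
                               else NA_real_
    } else {
      message("dots are untracked; init_active_nuclei counts observations")
      res$init_active_nuclei <- nrow(dWin)
    }
  }
  res
}

#' Per-track burst features
#'
#' Single-nucleus features of each track: onset time, frames present, average
#' size and brightness, maximum brightness, burst structure (a burst is a
#' maximal ON run, i.e. consecutive frames with an observation), mean ON-run
#' and OFF-gap durations, and the number of ON/OFF transitions inside the
#' track span (\code{2 * (n_bursts - 1)}).
#'
#' @param dots tracked dots \code{data.frame} (with \code{track_id})
#' @param frameIntervalS seconds per frame
#' @return \code{data.frame}, one row per (stage, track): stage, track_id,
#'   start_time_s, n_frames_present, avg_size_px, avg_brightness,
#'   avg_norm_brightness, max_brightness, max_norm_brightness, n_bursts,
#'   mean_on_run_s, mean_off_gap_s, n_transitions
#' @export
trackFeatures <- function(dots, frameIntervalS = 1) {
  if (!nrow(dots)) {
    return(data.frame(stage = character(0), track_id = integer(0),
                      start_time_s = numeric(0), n_frames_present = integer(0),
                      avg_size_px = numeric(0), avg_brightness = numeric(0),
                      avg_norm_brightness = numeric(0),
                      max_brightness = numeric(0),
                      max_norm_brightness = numeric(0), n_bursts = integer(0),
                      mean_on_run_s = numeric(0), mean_off_gap_s = numeric(0),
                      n_transitions = integer(0), stringsAsFactors = FALSE))
  }
  stopifnot(!any(is.na(dots$track_id)))
  runs <- trackRuns(dots, frameIntervalS)
  key <- interaction(dots$stage, dots$track_id, drop = TRUE)
  runKey <- interaction(runs$stage, runs$track_id, drop = TRUE)
  res <- lapply(levels(key), function(k) {
    ii <- which(key == k)
    rr <- runs[runKey == k, , drop = FALSE]
    on <- rr[rr$kind == "on", , drop = FALSE]
    off <- rr[rr$kind == "off", , drop = FALSE]
    data.frame(
      stage = dots$stage[ii[1L]], track_id = dots$track_id[ii[1L]],
      start_time_s = min(dots$frame[ii]) * frameIntervalS,
      n_frames_present = length(unique(dots$frame[ii])),
      avg_size_px = mean(dots$area_px[ii]),
      avg_brightness = mean(dots$mean_brightness[ii]),
      avg_norm_brightness = mean(dots$norm_brightness[ii]),
      max_brightness = max(dots$mean_brightness[ii]),
      max_norm_brightness = max(dots$norm_brightness[ii]),
      n_bursts = nrow(on),
      mean_on_run_s = mean(on$duration_s),
      mean_off_gap_s = if (nrow(off)) mean(off$duration_s) else NA_real_,
      n_transitions = 2L * (nrow(on) - 1L),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$stage, out$track_id), , drop = FALSE]
}

#' Dispersion summary of per-track values
#'
#' Sample standard deviation (n - 1 denominator) and standard error of the
#' mean. A single value yields \code{sd = NA} with \code{degenerate = TRUE}.
#'
#' @param values numeric vector, n >= 1
#' @return list with \code{sd}, \code{sem}, \code{n}, \code{degenerate}
#' @examples
#' dispersionStats(c(2, 4, 6))  # sd = 2, sem = 2/sqrt(3)
#' @export
dispersionStats <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) stop("dispersionStats needs at least one value")
  if (n == 1L)
    return(list(sd = NA_real_, sem = NA_real_, n = 1L, degenerate = TRUE))
  s <- stats::sd(values)
  list(sd = s, sem = s / sqrt(n), n = n, degenerate = FALSE)
}
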