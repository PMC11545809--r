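# Identity tracking: frame-by-frame centroid-proximity linking with gap
# tolerance, so a nucleus keeps its ID through transcriptionally silent (OFF)
# periods. Greedy ascending-distance matching by default; optional
# minimum-total-distance assignment via a Hungarian solver.

#' Minimum-cost assignment (Hungarian algorithm)
#'
#' Solves the rectangular linear assignment problem: given an n x m cost
#' matrix (n <= m is not required), find the matching of rows to columns
#' minimizing total cost. \code{Inf} entries mark forbidden pairs; rows or
#' columns with no affordable partner stay unmatched.
#'
#' O(n^3) shortest-augmenting-path implementation with potentials.
#'
#' @param cost numeric matrix; \code{Inf} forbids a pairing
#' @return integer vector of length \code{nrow(cost)}; entry i is the column
#'   assigned to row i, or \code{NA} if unmatched
#' @export
solveAssignment <- function(cost) {
  stopifnot(is.matrix(cost))
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) return(rep(NA_integer_, n))
  transposed <- FALSE
  if (n > m) { cost <- t(cost); transposed <- TRUE; tmp <- n; n <- m; m <- tmp }
  finite <- cost[is.finite(cost)]
  big <- if (length(finite)) (max(abs(finite)) + 1) * (n + m + 1) else 1
  cm <- cost
  cm[!is.finite(cm)] <- big
  # potentials over rows (u) and columns (v); col 0 is a virtual column.
  u <- numeric(n + 1L)
  v <- numeric(m + 1L)
  p <- integer(m + 1L)      # p[j+1]: row matched to column j (0 = none)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1L]) {
          curv <- cm[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (curv < minv[j + 1L]) {
            minv[j + 1L] <- curv
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0L:m) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) assign[p[j + 1L]] <- j
  # drop assignments that used a forbidden (Inf) pairing
  for (i in seq_len(n))
    if (!is.na(assign[i]) && !is.finite(cost[i, assign[i]]))
      assign[i] <- NA_integer_
  if (transposed) {
    out <- rep(NA_integer_, m)
    for (i in seq_len(n)) if (!is.na(assign[i])) out[assign[i]] <- i
    out
  } else assign
}

#' Link detected dots into tracks by centroid proximity
#'
#' Frame by frame, each current dot is matched to at most one active track
#' whose last centroid (seen within \code{maxGapFrames} frames) lies within
#' \code{maxLinkDistPx}. Greedy mode matches candidate pairs in ascending
#' distance order (ties broken by lower track ID); optimal mode solves the
#' minimum-total-distance assignment. Unmatched dots start new tracks with
#' fresh sequential IDs (1-based, in order of creation); tracks silent longer
#' than \code{maxGapFrames} are closed.
#'
#' Tracking is per stage: if \code{dots} spans several stage labels each stage
#' is linked independently and track IDs restart at 1 within each stage (no
#' track crosses a stage boundary).
#'
#' @param dots dots \code{data.frame} from [detectMovie()] / [detectDots()]
#' @param params a [TrackingParams-class]
#' @return the dots \code{data.frame} with \code{track_id} filled in, ordered
#'   by stage, frame, track_id
#' @export
linkFrames <- function(dots, params = trackingParams()) {
  stopifnot(is(params, "TrackingParams"))
  validObject(params)
  if (!nrow(dots)) return(dots)
  stages <- unique(dots$stage)
  if (length(stages) > 1L) {
    out <- lapply(stages, function(s)
      linkFrames(dots[dots$stage == s, , drop = FALSE], params))
    return(do.call(rbind, out))
  }
  dots <- dots[order(dots$frame), , drop = FALSE]
  frames <- sort(unique(dots$frame))
  # active-track state
  lastRow <- numeric(0); lastCol <- numeric(0); lastFrame <- integer(0)
  trackId <- integer(0)
  nextId <- 1L
  ids <- rep(NA_integer_, nrow(dots))
  rowIdxByFrame <- split(seq_len(nrow(dots)), dots$frame)
  for (f in frames) {
    live <- which(f - lastFrame <= params@maxGapFrames + 1L)
    cur <- rowIdxByFrame[[as.character(f)]]
    nC <- length(cur)
    assigned <- rep(NA_integer_, nC)      # index into `live`
    if (length(live) && nC) {
      dmat <- sqrt(outer(lastRow[live], dots$row[cur], "-")^2 +
                   outer(lastCol[live], dots$col[cur], "-")^2)
      dmat[dmat > params@maxLinkDistPx] <- Inf
      if (params@assignment == "greedy") {
        cand <- which(is.finite(dmat), arr.ind = TRUE)
        if (nrow(cand)) {
          ord <- order(dmat[cand], trackId[live][cand[, 1L]])
          usedT <- logical(length(live)); usedD <- logical(nC)
          for (k in ord) {
            ti <- cand[k, 1L]; di <- cand[k, 2L]
            if (!usedT[ti] && !usedD[di]) {
              usedT[ti] <- TRUE; usedD[di] <- TRUE
              assigned[di] <- ti
            }
          }
        }
      } else {
        sol <- solveAssignment(t(dmat))   # rows = dots, cols = tracks
        assigned <- sol
      }
    }
    for (d in seq_len(nC)) {
      if (!is.na(assigned[d])) {
        ti <- live[assigned[d]]
        ids[cur[d]] <- trackId[ti]
        lastRow[ti] <- dots$row[cur[d]]
        lastCol[ti] <- dots$col[cur[d]]
        lastFrame[ti] <- f
      } else {
        ids[cur[d]] <- nextId
        lastRow <- c(lastRow, dots$row[cur[d]])
        lastCol <- c(lastCol, dots$col[cur[d]])
        lastFrame <- c(lastFrame, f)
        trackId <- c(trackId, nextId)
        nextId <- nextId + 1L
      }
    }
  }
  dots$track_id <- ids
  dots[order(dots$frame, dots$track_id), , drop = FALSE]
}

#' ON runs and OFF gaps of tracked dots
#'
#' Run-length encodes each track's presence/absence over its span
#' [first_frame, last_frame]: maximal intervals of consecutive frames with an
#' observation are ON runs; maximal intervals of missing frames inside the
#' span are OFF gaps. Runs and gaps tile the span exactly.
#'
#' @param dots tracked dots \code{data.frame} (with \code{track_id})
#' @param frameIntervalS seconds per frame (for durations)
#' @return \code{data.frame}: stage, track_id, kind ("on"/"off"),
#'   start_frame, end_frame (0-based, inclusive), duration_s
#' @export
trackRuns <- function(dots, frameIntervalS = 1) {
  if (!nrow(dots)) {
    return(data.frame(stage = character(0), track_id = integer(0),
                      kind = character(0), start_frame = integer(0),
                      end_frame = integer(0), duration_s = numeric(0),
                      stringsAsFactors = FALSE))
  }
  stopifnot(!any(is.na(dots$track_id)))
  key <- interaction(dots$stage, dots$track_id, drop = TRUE)
  res <- lapply(split(seq_len(nrow(dots)), key), function(ii) {
    fr <- sort(unique(dots$frame[ii]))
    span <- fr[1L]:fr[length(fr)]
    present <- span %in% fr
    r <- rle(present)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(stage = dots$stage[ii[1L]], track_id = dots$track_id[ii[1L]],
               kind = ifelse(r$values, "on", "off"),
               start_frame = span[starts], end_frame = span[ends],
               duration_s = r$lengths * frameIntervalS,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$stage, out$track_id, out$start_frame), , drop = FALSE]
}

#' Long-form tracks table
#'
#' Lossless long-form export of tracked dots (the inverse of grouping rows by
#' track): one row per observation, ordered by stage, track, frame.
#'
#' @param dots tracked dots \code{data.frame}
#' @return \code{data.frame} with columns stage, track_id, frame, row, col,
#'   area_px, mean_brightness, norm_brightness
#' @export
tracksToTable <- function(dots) {
  cols <- c("stage", "track_id", "frame", "row", "col", "area_px",
            "mean_brightness", "norm_brightness")
  if (!nrow(dots)) {
    e <- emptyDots()
    return(e[, cols])
  }
  out <- dots[order(dots$stage, dots$track_id, dots$frame), cols,
              drop = FALSE]
  rownames(out) <- NULL
  out
}
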