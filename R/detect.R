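# Dot detection: strict green-channel thresholding, connected-component
# labeling (own implementation; the small-object BFS below is exercised
# against a brute-force flood-fill oracle in the tests), per-dot area and
# brightness, and per-stage min-max brightness normalization.

#' Label connected components of a binary mask
#'
#' Breadth/depth-first labeling over foreground pixels with 4- or
#' 8-connectivity. Labels are assigned in column-major scan order of the first
#' pixel reached, starting at 1.
#'
#' @param mask logical matrix
#' @param connectivity 4 or 8 (default 8)
#' @return integer matrix of the same shape; 0 = background
#' @export
labelComponents <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  fg <- which(mask)
  if (!length(fg)) return(labels)
  if (connectivity == 4L) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
    dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  }
  nd <- length(dr)
  cur <- 0L
  stack <- integer(256L)
  for (s in fg) {
    if (labels[s] != 0L) next
    cur <- cur + 1L
    top <- 1L
    stack[1L] <- s
    labels[s] <- cur
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      r <- ((p - 1L) %% nr) + 1L
      cl <- ((p - 1L) %/% nr) + 1L
      for (k in seq_len(nd)) {
        rr <- r + dr[k]; cc <- cl + dc[k]
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc) {
          q <- (cc - 1L) * nr + rr
          if (mask[q] && labels[q] == 0L) {
            labels[q] <- cur
            top <- top + 1L
            if (top > length(stack)) stack <- c(stack, integer(length(stack)))
            stack[top] <- q
          }
        }
      }
    }
  }
  labels
}

emptyDots <- function() {
  data.frame(stage = character(0), frame = integer(0), row = numeric(0),
             col = numeric(0), area_px = integer(0),
             mean_brightness = numeric(0), norm_brightness = numeric(0),
             track_id = integer(0), stringsAsFactors = FALSE)
}

#' Detect transcription dots in one green-channel frame
#'
#' Pixels strictly above \code{greenThreshold} (8-bit scale) are grouped into
#' connected components at the stated connectivity; components smaller than
#' \code{minAreaPx} are dropped. Per component: area = pixel count, centroid =
#' unweighted mean of member pixel coordinates (0-based row/col), mean
#' brightness = mean original intensity over the filled member pixels.
#'
#' @param frameImage 2-D numeric matrix on the 8-bit scale (whole values in
#'   [0, 255]; use [asEightBit()] to convert). Other scales are rejected.
#' @param params a [DetectionParams-class]
#' @param frame 0-based frame index recorded in the output (default 0)
#' @param stage stage label recorded in the output (default \code{NA})
#' @return \code{data.frame} with columns stage, frame, row, col, area_px,
#'   mean_brightness, norm_brightness (\code{NA} until [normalizeStage()]),
#'   track_id (\code{NA} until [linkFrames()]); one row per dot.
#' @examples
#' img <- matrix(0, 16, 16); img[3:5, 3:5] <- 200
#' detectDots(img, detectionParams())
#' @export
detectDots <- function(frameImage, params = detectionParams(), frame = 0L,
                       stage = NA_character_) {
  stopifnot(is(params, "DetectionParams"))
  validObject(params)
  if (!is.matrix(frameImage) || !is.numeric(frameImage))
    stop("frameImage must be a 2-D numeric matrix")
  if (min(frameImage) < 0 || max(frameImage) > 255)
    stop("frameImage must be on the 8-bit scale (convert with asEightBit)")
  mask <- frameImage > params@greenThreshold   # strict inequality
  labels <- labelComponents(mask, params@connectivity)
  k <- max(labels)
  if (k == 0L) return(emptyDots())
  idx <- which(labels > 0L)
  lab <- labels[idx]
  nr <- nrow(frameImage)
  rows0 <- ((idx - 1L) %% nr)          # 0-based coordinates
  cols0 <- ((idx - 1L) %/% nr)
  area <- tabulate(lab, nbins = k)
  cr <- rowsum(rows0, lab)[, 1L] / area
  cc <- rowsum(cols0, lab)[, 1L] / area
  mb <- rowsum(frameImage[idx], lab)[, 1L] / area
  keep <- area >= params@minAreaPx
  if (!any(keep)) return(emptyDots())
  data.frame(stage = stage, frame = as.integer(frame), row = cr[keep],
             col = cc[keep], area_px = as.integer(area[keep]),
             mean_brightness = mb[keep], norm_brightness = NA_real_,
             track_id = NA_integer_, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Segment nuclei in the red channel
#'
#' Automatic (Otsu) threshold of the red channel followed by hole filling, so
#' envelope rings become filled nuclear disks. A blank (constant) red channel
#' yields a full-field mask with a warning.
#'
#' @param redImage 2-D numeric matrix
#' @param method masking method; only \code{"otsu"} is implemented
#' @return logical matrix, TRUE inside nuclei
#' @export
nuclearMask <- function(redImage, method = "otsu") {
  stopifnot(is.matrix(redImage))
  method <- match.arg(method, "otsu")
  rng <- range(redImage)
  if (diff(rng) <= 0) {
    warning("blank red channel; returning full-field mask")
    return(matrix(TRUE, nrow(redImage), ncol(redImage)))
  }
  scaled <- (redImage - rng[1L]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  mask <- EBImage::fillHull(scaled > th)
  matrix(as.logical(mask), nrow(redImage), ncol(redImage))
}

#' Apply a nuclear mask to detected dots
#'
#' Drops dots whose centroid (rounded to the nearest pixel) falls outside the
#' mask.
#'
#' @param dots dots \code{data.frame} from [detectDots()]
#' @param mask logical matrix from [nuclearMask()]
#' @return filtered dots \code{data.frame}
#' @export
filterByMask <- function(dots, mask) {
  if (!nrow(dots)) return(dots)
  r <- pmin(pmax(round(dots$row) + 1L, 1L), nrow(mask))
  c <- pmin(pmax(round(dots$col) + 1L, 1L), ncol(mask))
  dots[mask[cbind(r, c)], , drop = FALSE]
}

#' Per-stage min-max brightness normalization
#'
#' Sets \code{norm_brightness = (mean_brightness - min) / (max - min)}, where
#' min and max are taken over every dot of the stage, all frames pooled
#' (per movie). If max equals min (e.g. a single dot), all norms are set to 0.
#'
#' @param dots dots \code{data.frame}; all rows must share one stage label
#' @return the same \code{data.frame} with \code{norm_brightness} filled in
#' @examples
#' d <- data.frame(stage = "nc14", frame = 0:2, row = 0, col = 0,
#'                 area_px = 1L, mean_brightness = c(60, 110, 160),
#'                 norm_brightness = NA_real_, track_id = NA_integer_)
#' normalizeStage(d)$norm_brightness  # 0, 0.5, 1
#' @export
normalizeStage <- function(dots) {
  if (!nrow(dots)) return(dots)
  if (length(unique(dots$stage)) > 1L)
    stop("normalizeStage expects dots from a single stage")
  lo <- min(dots$mean_brightness)
  hi <- max(dots$mean_brightness)
  dots$norm_brightness <- if (hi > lo)
    (dots$mean_brightness - lo) / (hi - lo) else 0
  dots
}

#' Detect and normalize dots across a whole movie
#'
#' Runs [detectDots()] on the 8-bit-converted green channel of every frame,
#' labels dots by stage via the partition, optionally filters by the
#' red-channel nuclear mask, and applies per-stage min-max normalization.
#' Frames outside every stage interval are skipped.
#'
#' @param movie a [Movie2D-class]
#' @param partition a [StagePartition-class]; default treats the whole movie
#'   as a single stage \code{"all"}
#' @param params a [DetectionParams-class]
#' @return dots \code{data.frame} (see [detectDots()]) with global 0-based
#'   frame indices, stage labels and \code{norm_brightness} set
#' @export
detectMovie <- function(movie, partition = NULL,
                        params = detectionParams()) {
  stopifnot(is(movie, "Movie2D"))
  nT <- dim(movie@pixels)[1L]
  if (is.null(partition))
    partition <- stagePartition("all", 0L, nT)
  perStage <- vector("list", length(partition@label))
  for (i in seq_along(partition@label)) {
    frames <- partition@start[i]:(partition@end[i] - 1L)
    res <- lapply(frames, function(f) {
      img <- asEightBit(frameChannel(movie, f, "green"), movie@bitDepth)
      d <- detectDots(img, params, frame = f, stage = partition@label[i])
      if (params@useNuclearMask && nrow(d)) {
        red <- frameChannel(movie, f, "red")
        d <- filterByMask(d, nuclearMask(red, params@nuclearMaskMethod))
      }
      d
    })
    perStage[[i]] <- normalizeStage(do.call(rbind, res))
  }
  out <- do.call(rbind, perStage)
  if (is.null(out) || !nrow(out)) emptyDots() else out
}
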