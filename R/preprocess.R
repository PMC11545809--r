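# Preprocessing: z-flattening, photobleaching correction, stage splitting.
# All quantitative processing stays in floating point; conversion to the 8-bit
# detection scale happens only at the detection boundary (asEightBit).

#' Maximum-intensity projection over z
#'
#' Flattens a T x Z x Y x X x C stack to T x Y x X x C by the per-pixel,
#' per-channel maximum over z. Metadata is preserved; applying it to an
#' already-flat movie is the identity.
#'
#' @param stack a [MovieStack-class] (or a [Movie2D-class], returned as is
#'   with provenance appended — projection is idempotent)
#' @return A [Movie2D-class].
#' @export
maxProject <- function(stack) {
  if (is(stack, "Movie2D")) return(stack)
  stopifnot(is(stack, "MovieStack"))
  d <- dim(stack@pixels)
  if (prod(d) == 0L) stop("empty stack")
  if (d[2L] == 1L) {
    flat <- array(stack@pixels[, 1L, , , , drop = FALSE],
                  dim = d[c(1L, 3L, 4L, 5L)])
  } else {
    # pmax over z slices keeps memory flat and vectorizes over T,Y,X,C
    flat <- array(stack@pixels[, 1L, , , ], dim = d[c(1L, 3L, 4L, 5L)])
    for (z in 2L:d[2L])
      flat <- pmax(flat, array(stack@pixels[, z, , , ],
                               dim = d[c(1L, 3L, 4L, 5L)]))
  }
  new("Movie2D", pixels = flat, provenance = "max_project",
      bleachFactors = rep(1, d[1L]), pixelSizeUm = stack@pixelSizeUm,
      frameIntervalS = stack@frameIntervalS, bitDepth = stack@bitDepth,
      channelRoles = stack@channelRoles)
}

#' Photobleaching correction
#'
#' Rescales each frame of one channel so the fluorophore decay is compensated.
#' \code{simple_ratio} scales every frame so its mean equals the frame-0 mean
#' (the lightest mode of the classic ImageJ CorrectBleach plugin).
#' \code{exponential_fit} fits \code{mean_t = a * exp(-b t) + c} to the
#' per-frame means and divides by the fitted decay normalized to t = 0; if the
#' fit does not converge it falls back to \code{simple_ratio} with a warning.
#'
#' @param movie a [Movie2D-class]
#' @param channel channel role to correct (default \code{"green"})
#' @param method \code{"simple_ratio"} (default) or \code{"exponential_fit"}
#' @return A [Movie2D-class] with corrected pixels; the per-frame scale
#'   factors applied are recorded in \code{bleachFactors}.
#' @export
bleachCorrect <- function(movie, channel = "green",
                          method = c("simple_ratio", "exponential_fit")) {
  stopifnot(is(movie, "Movie2D"))
  method <- match.arg(method)
  ch <- if (is.character(channel)) movie@channelRoles[[channel]]
        else as.integer(channel)
  if (is.null(ch) || is.na(ch)) stop("channel not present: ", channel)
  nT <- dim(movie@pixels)[1L]
  frameMeans <- vapply(seq_len(nT),
                       function(f) mean(movie@pixels[f, , , ch]), numeric(1))
  if (frameMeans[1L] <= 0) stop("all-zero reference frame (frame-0 mean <= 0)")

  if (method == "exponential_fit") {
    t <- (seq_len(nT) - 1L) * movie@frameIntervalS
    fit <- tryCatch({
      df <- data.frame(t = t, y = frameMeans)
      span <- max(frameMeans) - min(frameMeans)
      st <- list(a = max(span, 1e-6), b = 1 / max(t[nT], 1), c = min(frameMeans))
      minpack.lm::nlsLM(y ~ a * exp(-b * t) + c, data = df, start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }, error = function(e) NULL)
    ok <- !is.null(fit) && all(is.finite(stats::coef(fit))) &&
      stats::coef(fit)[["b"]] >= 0
    if (!ok) {
      warning("exponential bleach fit did not converge; ",
              "falling back to simple_ratio")
      method <- "simple_ratio"
    } else {
      cf <- stats::coef(fit)
      decay <- (cf[["a"]] * exp(-cf[["b"]] * t) + cf[["c"]]) /
        (cf[["a"]] + cf[["c"]])
      factors <- 1 / pmax(decay, .Machine$double.eps)
    }
  }
  if (method == "simple_ratio") factors <- frameMeans[1L] / frameMeans

  pix <- movie@pixels
  for (f in seq_len(nT)) pix[f, , , ch] <- pix[f, , , ch] * factors[f]
  new("Movie2D", pixels = pix,
      provenance = c(movie@provenance, paste0("bleach_", method)),
      bleachFactors = movie@bleachFactors * factors,
      pixelSizeUm = movie@pixelSizeUm,
      frameIntervalS = movie@frameIntervalS, bitDepth = movie@bitDepth,
      channelRoles = movie@channelRoles)
}

#' Split a movie into nuclear-cycle stages
#'
#' Extracts one [Movie2D-class] per partition entry. Frames covered by no
#' interval are excluded and reported via the \code{unassigned} attribute (and
#' a message). Concatenating the outputs plus the unassigned frames
#' reconstructs the input.
#'
#' @param movie a [Movie2D-class]
#' @param partition a [StagePartition-class] valid for the movie's T
#' @return Named list of [Movie2D-class], one per stage, with a
#'   \code{stageLabel} and \code{frameOffset} (0-based global first frame)
#'   attribute on each element; attribute \code{unassigned} lists dropped
#'   0-based frames.
#' @export
splitStages <- function(movie, partition) {
  stopifnot(is(movie, "Movie2D"), is(partition, "StagePartition"))
  validObject(partition)
  nT <- dim(movie@pixels)[1L]
  if (length(partition@end) && max(partition@end) > nT)
    stop("partition interval exceeds movie length (T = ", nT, ")")
  out <- vector("list", length(partition@label))
  names(out) <- partition@label
  covered <- logical(nT)
  for (i in seq_along(partition@label)) {
    idx <- (partition@start[i] + 1L):partition@end[i]
    covered[idx] <- TRUE
    sub <- new("Movie2D",
               pixels = movie@pixels[idx, , , , drop = FALSE],
               provenance = c(movie@provenance,
                              paste0("stage_", partition@label[i])),
               bleachFactors = movie@bleachFactors[idx],
               pixelSizeUm = movie@pixelSizeUm,
               frameIntervalS = movie@frameIntervalS,
               bitDepth = movie@bitDepth,
               channelRoles = movie@channelRoles)
    attr(sub, "stageLabel") <- partition@label[i]
    attr(sub, "frameOffset") <- partition@start[i]
    out[[i]] <- sub
  }
  unassigned <- which(!covered) - 1L
  if (length(unassigned))
    message(length(unassigned), " frame(s) covered by no stage interval; ",
            "excluded")
  attr(out, "unassigned") <- unassigned
  out
}

#' Convert a frame to the 8-bit detection scale
#'
#' Linearly rescales from the recorded bit depth to [0, 255], rounds and
#' clips. The fixed detection threshold is defined on 8-bit data, so this is
#' the single conversion point from the floating-point processing path.
#'
#' @param img numeric matrix (one channel of one frame)
#' @param bitDepth source bit depth, 8 or 16
#' @return numeric matrix of whole values in [0, 255]
#' @export
asEightBit <- function(img, bitDepth = 8L) {
  scale <- 255 / (2^bitDepth - 1)
  pmin(pmax(round(img * scale), 0), 255)
}
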