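#' @import methods
NULL

# ---------------------------------------------------------------------------
# Simulation configuration
# ---------------------------------------------------------------------------

#' Simulation configuration for synthetic MS2 movies
#'
#' Parameters of the synthetic-movie generator: a field of nuclei whose
#' promoters switch between ON and OFF states as a two-state (telegraph)
#' Markov chain, loading transcripts at \code{loadingRate} while ON. Each
#' nascent transcript contributes fluorescence for \code{transcriptDwellS}
#' seconds; the dot is rendered as a Gaussian of width \code{psfSigmaPx} on a
#' noisy background with exponential photobleaching.
#'
#' @slot nNucleiSide integer, nuclei per side of the square grid.
#' @slot fieldSizePx integer, field side length in pixels.
#' @slot frameIntervalS seconds between frames (acquisition cadence).
#' @slot nFramesPerStage integer, frames per nuclear-cycle stage.
#' @slot stageLabels character, ordered stage labels (e.g. nc12, nc13, nc14).
#' @slot kOn ON-switch rate (1/s).
#' @slot kOff OFF-switch rate (1/s).
#' @slot loadingRate transcript initiation rate while ON (transcripts/s).
#' @slot transcriptDwellS seconds a nascent transcript contributes signal.
#' @slot psfSigmaPx Gaussian PSF standard deviation in pixels.
#' @slot ampPerTranscript intensity units (8-bit scale) per transcript at the
#'   dot centre.
#' @slot backgroundLevel background intensity (8-bit scale).
#' @slot noiseSd Gaussian read-noise SD (intensity units).
#' @slot bleachHalflifeS photobleaching half-life in seconds (\code{Inf}
#'   disables bleaching).
#' @slot dotDiffusionPx per-frame dot-centroid jitter SD in pixels.
#' @slot nZPlanes integer, z-planes rendered per time point (1 = single
#'   in-focus plane; >1 adds defocused copies).
#' @slot bitDepth integer, 8 or 16.
#' @slot seed integer RNG seed.
#'
#' @seealso [simConfig()], [simulateTelegraph()], [renderMovie()]
#' @exportClass SimConfig
setClass("SimConfig", representation(
  nNucleiSide = "integer",
  fieldSizePx = "integer",
  frameIntervalS = "numeric",
  nFramesPerStage = "integer",
  stageLabels = "character",
  kOn = "numeric",
  kOff = "numeric",
  loadingRate = "numeric",
  transcriptDwellS = "numeric",
  psfSigmaPx = "numeric",
  ampPerTranscript = "numeric",
  backgroundLevel = "numeric",
  noiseSd = "numeric",
  bleachHalflifeS = "numeric",
  dotDiffusionPx = "numeric",
  nZPlanes = "integer",
  bitDepth = "integer",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  rates <- c(kOn = object@kOn, kOff = object@kOff,
             loadingRate = object@loadingRate)
  if (any(!is.finite(rates)) || any(rates < 0))
    msg <- c(msg, "rates (kOn, kOff, loadingRate) must be finite and >= 0")
  if (object@fieldSizePx <= 0L) msg <- c(msg, "fieldSizePx must be > 0")
  if (object@nNucleiSide <= 0L) msg <- c(msg, "nNucleiSide must be > 0")
  if (!is.finite(object@frameIntervalS) || object@frameIntervalS <= 0)
    msg <- c(msg, "frameIntervalS must be > 0")
  if (length(object@stageLabels) == 0L)
    msg <- c(msg, "stageLabels must be nonempty")
  if (object@nFramesPerStage <= 0L)
    msg <- c(msg, "nFramesPerStage must be > 0")
  if (object@transcriptDwellS < 0)
    msg <- c(msg, "transcriptDwellS must be >= 0")
  if (object@bleachHalflifeS <= 0)
    msg <- c(msg, "bleachHalflifeS must be > 0 (Inf disables bleaching)")
  if (!object@bitDepth %in% c(8L, 16L)) msg <- c(msg, "bitDepth must be 8 or 16")
  if (object@nZPlanes < 1L) msg <- c(msg, "nZPlanes must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults describe a small syncytial-blastoderm-like field imaged every
#' 1.77 s: sparse nuclei, slow two-state promoter switching
#' (\code{kOn} = 0.02/s, \code{kOff} = 0.05/s, i.e. mean OFF gap 50 s and mean
#' ON run 20 s), moderate transcript loading, and mild photobleaching.
#'
#' @param nNucleiSide nuclei per side of the square grid (default 4).
#' @param fieldSizePx field side length in pixels (default 128).
#' @param frameIntervalS seconds per frame (default 1.77).
#' @param nFramesPerStage frames per stage (default 100).
#' @param stageLabels ordered stage labels (default \code{"nc14"}).
#' @param kOn,kOff telegraph switching rates in 1/s (defaults 0.02, 0.05).
#' @param loadingRate transcripts/s while ON (default 0.5).
#' @param transcriptDwellS signal dwell per transcript in seconds (default 30).
#' @param psfSigmaPx PSF sigma in pixels (default 1.5).
#' @param ampPerTranscript peak intensity per transcript (default 15).
#' @param backgroundLevel background intensity (default 20).
#' @param noiseSd read-noise SD (default 4).
#' @param bleachHalflifeS bleach half-life in seconds (default 600).
#' @param dotDiffusionPx per-frame centroid jitter SD in px (default 1).
#' @param nZPlanes z-planes per time point (default 1).
#' @param bitDepth 8 or 16 (default 8).
#' @param seed integer RNG seed (default 1).
#' @return A [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nNucleiSide = 2L, nFramesPerStage = 20L)
#' cfg
#' @export
simConfig <- function(nNucleiSide = 4L, fieldSizePx = 128L,
                      frameIntervalS = 1.77, nFramesPerStage = 100L,
                      stageLabels = "nc14", kOn = 0.02, kOff = 0.05,
                      loadingRate = 0.5, transcriptDwellS = 30,
                      psfSigmaPx = 1.5, ampPerTranscript = 15,
                      backgroundLevel = 20, noiseSd = 4,
                      bleachHalflifeS = 600, dotDiffusionPx = 1,
                      nZPlanes = 1L, bitDepth = 8L, seed = 1L) {
  new("SimConfig",
      nNucleiSide = as.integer(nNucleiSide),
      fieldSizePx = as.integer(fieldSizePx),
      frameIntervalS = as.numeric(frameIntervalS),
      nFramesPerStage = as.integer(nFramesPerStage),
      stageLabels = as.character(stageLabels),
      kOn = as.numeric(kOn), kOff = as.numeric(kOff),
      loadingRate = as.numeric(loadingRate),
      transcriptDwellS = as.numeric(transcriptDwellS),
      psfSigmaPx = as.numeric(psfSigmaPx),
      ampPerTranscript = as.numeric(ampPerTranscript),
      backgroundLevel = as.numeric(backgroundLevel),
      noiseSd = as.numeric(noiseSd),
      bleachHalflifeS = as.numeric(bleachHalflifeS),
      dotDiffusionPx = as.numeric(dotDiffusionPx),
      nZPlanes = as.integer(nZPlanes),
      bitDepth = as.integer(bitDepth),
      seed = as.integer(seed))
}

# ---------------------------------------------------------------------------
# Ground truth
# ---------------------------------------------------------------------------

#' Ground truth of a simulated movie
#'
#' Per-nucleus promoter-state trajectories, transcript counts and true dot
#' centroids, plus the per-frame bleach factor, as emitted by
#' [simulateTelegraph()]. Matrices are nuclei x frames; frames are 0-based in
#' all exported tables.
#'
#' @slot states integer matrix (nuclei x frames), 1 = ON, 0 = OFF, sampled at
#'   frame midpoints.
#' @slot transcripts integer matrix (nuclei x frames), nascent transcripts
#'   contributing signal at each frame.
#' @slot rowPos,colPos numeric matrices (nuclei x frames), true dot centroids
#'   in 0-based pixel coordinates.
#' @slot nucleusRow,nucleusCol numeric matrices (nuclei x stages), nucleus
#'   centre per stage (re-jittered at each mitosis).
#' @slot stageStarts integer vector, 0-based first frame of each stage.
#' @slot stageLabels character vector of stage labels.
#' @slot bleachFactor numeric vector length T, signal scale 2^(-t/halflife).
#' @slot config the generating [SimConfig-class].
#' @exportClass GroundTruth
setClass("GroundTruth", representation(
  states = "matrix",
  transcripts = "matrix",
  rowPos = "matrix",
  colPos = "matrix",
  nucleusRow = "matrix",
  nucleusCol = "matrix",
  stageStarts = "integer",
  stageLabels = "character",
  bleachFactor = "numeric",
  config = "SimConfig"
))

setValidity("GroundTruth", function(object) {
  msg <- character()
  dm <- dim(object@states)
  if (!identical(dm, dim(object@transcripts)) ||
      !identical(dm, dim(object@rowPos)) ||
      !identical(dm, dim(object@colPos)))
    msg <- c(msg, "states, transcripts, rowPos, colPos must share dimensions")
  if (any(object@transcripts < 0L))
    msg <- c(msg, "transcript counts must be nonnegative")
  if (!all(object@states %in% c(0L, 1L)))
    msg <- c(msg, "states must be 0/1")
  if (length(object@bleachFactor) != ncol(object@states))
    msg <- c(msg, "bleachFactor length must equal total frames")
  fs <- object@config@fieldSizePx
  if (nrow(object@rowPos) > 0 &&
      (min(object@rowPos) < 0 || max(object@rowPos) > fs - 1 ||
       min(object@colPos) < 0 || max(object@colPos) > fs - 1))
    msg <- c(msg, "dot centroids must lie inside the field")
  if (length(msg)) msg else TRUE
})

#' @describeIn GroundTruth-class number of simulated nuclei
#' @param object,x a \code{GroundTruth}
#' @export
nNuclei <- function(x) nrow(x@states)

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@states), "nuclei x",
      ncol(object@states), "frames,",
      length(object@stageLabels), "stage(s)\n")
  cat("  ON fraction:",
      format(mean(object@states == 1L), digits = 3), "\n")
  cat("  mean transcripts while ON:",
      format(mean(object@transcripts[object@states == 1L]), digits = 3), "\n")
})

# ---------------------------------------------------------------------------
# Movie containers
# ---------------------------------------------------------------------------

#' Raw multi-channel z-stack movie
#'
#' A T x Z x Y x X x C intensity array with acquisition metadata. Channel
#' roles map colours to content: \code{green} = MCP-GFP transcription dots,
#' \code{red} = nuclear envelopes.
#'
#' @slot pixels 5-D numeric array, T x Z x Y x X x C.
#' @slot pixelSizeUm micrometres per pixel.
#' @slot frameIntervalS seconds per frame.
#' @slot bitDepth integer, 8 or 16; intensities lie in [0, 2^bitDepth - 1].
#' @slot channelRoles named integer vector mapping roles (\code{green},
#'   \code{red}) to channel indices.
#' @exportClass MovieStack
setClass("MovieStack", representation(
  pixels = "array",
  pixelSizeUm = "numeric",
  frameIntervalS = "numeric",
  bitDepth = "integer",
  channelRoles = "integer"
))

setValidity("MovieStack", function(object) {
  msg <- character()
  if (length(dim(object@pixels)) != 5L)
    msg <- c(msg, "pixels must be a 5-D array (T x Z x Y x X x C)")
  else {
    d <- dim(object@pixels)
    if (any(d[c(1L, 3L, 4L)] < 1L)) msg <- c(msg, "T, Y, X must be >= 1")
    if (!"green" %in% names(object@channelRoles))
      msg <- c(msg, "channelRoles must cover 'green'")
    else if (any(object@channelRoles < 1L | object@channelRoles > d[5L]))
      msg <- c(msg, "channelRoles indices out of range")
    if (!object@bitDepth %in% c(8L, 16L)) msg <- c(msg, "bitDepth must be 8 or 16")
    mx <- suppressWarnings(max(object@pixels))
    if (is.finite(mx) && (mx > 2^object@bitDepth - 1 || min(object@pixels) < 0))
      msg <- c(msg, "intensities must lie within the bit depth")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "MovieStack", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("MovieStack: T=%d Z=%d Y=%d X=%d C=%d, %d-bit, dt=%.3g s\n",
              d[1], d[2], d[3], d[4], d[5], object@bitDepth,
              object@frameIntervalS))
  cat("  channels:", paste(names(object@channelRoles),
                           object@channelRoles, sep = "=", collapse = ", "),
      "\n")
})

#' Flattened 2-D movie
#'
#' A T x Y x X x C array produced by [maxProject()] (and optionally
#' [bleachCorrect()]), carrying provenance and the per-frame bleach scale
#' factors applied.
#'
#' @slot pixels 4-D numeric array, T x Y x X x C (floating point; clipping to
#'   bit depth happens only at the detection boundary).
#' @slot provenance character, projection / correction methods applied.
#' @slot bleachFactors numeric length-T vector of scale factors applied
#'   (all 1 when uncorrected).
#' @slot pixelSizeUm micrometres per pixel.
#' @slot frameIntervalS seconds per frame.
#' @slot bitDepth integer, nominal bit depth of the source.
#' @slot channelRoles named integer vector as in [MovieStack-class].
#' @exportClass Movie2D
setClass("Movie2D", representation(
  pixels = "array",
  provenance = "character",
  bleachFactors = "numeric",
  pixelSizeUm = "numeric",
  frameIntervalS = "numeric",
  bitDepth = "integer",
  channelRoles = "integer"
))

setValidity("Movie2D", function(object) {
  msg <- character()
  if (length(dim(object@pixels)) != 4L)
    msg <- c(msg, "pixels must be a 4-D array (T x Y x X x C)")
  else {
    if (length(object@bleachFactors) != dim(object@pixels)[1L])
      msg <- c(msg, "bleachFactors length must equal T")
    if (any(object@bleachFactors <= 0))
      msg <- c(msg, "bleachFactors must be > 0")
    if (!"green" %in% names(object@channelRoles))
      msg <- c(msg, "channelRoles must cover 'green'")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "Movie2D", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("Movie2D: T=%d Y=%d X=%d C=%d, dt=%.3g s\n",
              d[1], d[2], d[3], d[4], object@frameIntervalS))
  cat("  provenance:", paste(object@provenance, collapse = " -> "), "\n")
})

#' Number of frames
#' @param x a [MovieStack-class] or [Movie2D-class]
#' @return integer frame count T
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "MovieStack", function(x) dim(x@pixels)[1L])

#' @rdname nFrames
#' @export
setMethod("nFrames", "Movie2D", function(x) dim(x@pixels)[1L])

#' Extract one channel of one frame
#'
#' @param x a [Movie2D-class]
#' @param frame 0-based frame index
#' @param channel channel role (\code{"green"} or \code{"red"}) or index
#' @return Y x X numeric matrix
#' @export
frameChannel <- function(x, frame, channel = "green") {
  stopifnot(is(x, "Movie2D"))
  ch <- if (is.character(channel)) x@channelRoles[[channel]] else as.integer(channel)
  x@pixels[frame + 1L, , , ch]
}

# ---------------------------------------------------------------------------
# Stage partition
# ---------------------------------------------------------------------------

#' Nuclear-cycle stage partition
#'
#' Maps stage labels (nc12, nc13, nc14, ...) to half-open, 0-based frame
#' intervals \code{[start, end)}. Stages are identified manually in practice
#' (counting backward from nc14), so the partition is user input, not
#' detected.
#'
#' @slot label character stage labels.
#' @slot start integer, inclusive 0-based start frames.
#' @slot end integer, exclusive end frames.
#' @exportClass StagePartition
setClass("StagePartition", representation(
  label = "character", start = "integer", end = "integer"
))

setValidity("StagePartition", function(object) {
  msg <- character()
  n <- length(object@label)
  if (length(object@start) != n || length(object@end) != n)
    msg <- c(msg, "label, start, end must have equal length")
  else if (n > 0L) {
    if (any(object@end <= object@start))
      msg <- c(msg, "intervals must be nonempty (end > start)")
    if (any(object@start < 0L))
      msg <- c(msg, "frame indices must be >= 0")
    if (n > 1L && any(object@start[-1L] < object@end[-n]))
      msg <- c(msg, "intervals must be ascending and non-overlapping")
    if (anyDuplicated(object@label))
      msg <- c(msg, "stage labels must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a stage partition
#'
#' @param label character vector of stage labels.
#' @param start inclusive 0-based start frames.
#' @param end exclusive end frames.
#' @return A [StagePartition-class].
#' @examples
#' stagePartition(c("nc12", "nc13"), start = c(0, 10), end = c(10, 30))
#' @export
stagePartition <- function(label, start, end) {
  new("StagePartition", label = as.character(label),
      start = as.integer(start), end = as.integer(end))
}

setMethod("show", "StagePartition", function(object) {
  cat("StagePartition:\n")
  for (i in seq_along(object@label))
    cat(sprintf("  %s: [%d, %d)\n", object@label[i],
                object@start[i], object@end[i]))
})

#' Stage partition implied by a simulation configuration
#'
#' Consecutive blocks of \code{nFramesPerStage} frames, one per stage label.
#'
#' @param config a [SimConfig-class]
#' @return A [StagePartition-class]
#' @export
simStagePartition <- function(config) {
  nS <- length(config@stageLabels)
  stagePartition(config@stageLabels,
                 start = (seq_len(nS) - 1L) * config@nFramesPerStage,
                 end = seq_len(nS) * config@nFramesPerStage)
}

# ---------------------------------------------------------------------------
# Parameter classes
# ---------------------------------------------------------------------------

#' Dot-detection parameters
#'
#' @slot greenThreshold intensity threshold on the 8-bit scale; pixels
#'   strictly above it are foreground. Default 55.
#' @slot connectivity 4 or 8 (default 8).
#' @slot minAreaPx minimum component area in pixels (default 1, no filter).
#' @slot useNuclearMask logical; drop dots whose centroid falls outside the
#'   red-channel nuclear mask (default \code{FALSE}).
#' @slot nuclearMaskMethod label of the masking method (default "otsu").
#' @exportClass DetectionParams
setClass("DetectionParams", representation(
  greenThreshold = "numeric",
  connectivity = "integer",
  minAreaPx = "integer",
  useNuclearMask = "logical",
  nuclearMaskMethod = "character"
))

setValidity("DetectionParams", function(object) {
  msg <- character()
  if (object@greenThreshold <= 0 || object@greenThreshold >= 255)
    msg <- c(msg, "greenThreshold must lie in (0, 255)")
  if (!object@connectivity %in% c(4L, 8L))
    msg <- c(msg, "connectivity must be 4 or 8")
  if (object@minAreaPx < 1L) msg <- c(msg, "minAreaPx must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct detection parameters
#'
#' @param greenThreshold 8-bit intensity threshold (default 55); strict
#'   inequality, pixels must exceed it.
#' @param connectivity 4 or 8 (default 8).
#' @param minAreaPx minimum dot area in pixels (default 1).
#' @param useNuclearMask drop dots outside the nuclear mask (default FALSE).
#' @param nuclearMaskMethod masking method label (default "otsu").
#' @return A [DetectionParams-class].
#' @export
detectionParams <- function(greenThreshold = 55, connectivity = 8L,
                            minAreaPx = 1L, useNuclearMask = FALSE,
                            nuclearMaskMethod = "otsu") {
  new("DetectionParams", greenThreshold = as.numeric(greenThreshold),
      connectivity = as.integer(connectivity),
      minAreaPx = as.integer(minAreaPx),
      useNuclearMask = as.logical(useNuclearMask),
      nuclearMaskMethod = as.character(nuclearMaskMethod))
}

#' Tracking parameters
#'
#' @slot maxLinkDistPx maximum centroid distance for linking (px), default 15.
#' @slot maxGapFrames frames a track may go dark and still be re-linked,
#'   default 10 (0 = strict previous-frame linking).
#' @slot assignment \code{"greedy"} (ascending distance) or \code{"optimal"}
#'   (minimum-total-distance assignment).
#' @exportClass TrackingParams
setClass("TrackingParams", representation(
  maxLinkDistPx = "numeric",
  maxGapFrames = "integer",
  assignment = "character"
))

setValidity("TrackingParams", function(object) {
  msg <- character()
  if (object@maxLinkDistPx <= 0) msg <- c(msg, "maxLinkDistPx must be > 0")
  if (object@maxGapFrames < 0L) msg <- c(msg, "maxGapFrames must be >= 0")
  if (!object@assignment %in% c("greedy", "optimal"))
    msg <- c(msg, "assignment must be 'greedy' or 'optimal'")
  if (length(msg)) msg else TRUE
})

#' Construct tracking parameters
#'
#' @param maxLinkDistPx maximum link distance in pixels (default 15).
#' @param maxGapFrames maximum tolerated dark gap in frames (default 10).
#' @param assignment \code{"greedy"} or \code{"optimal"} (default greedy).
#' @return A [TrackingParams-class].
#' @export
trackingParams <- function(maxLinkDistPx = 15, maxGapFrames = 10L,
                           assignment = "greedy") {
  new("TrackingParams", maxLinkDistPx = as.numeric(maxLinkDistPx),
      maxGapFrames = as.integer(maxGapFrames),
      assignment = match.arg(assignment, c("greedy", "optimal")))
}

# ---------------------------------------------------------------------------
# Test result
# ---------------------------------------------------------------------------

#' Result of a case-vs-control hypothesis test
#'
#' @slot method test label ("mann_whitney_u", "permutation", "t_student",
#'   "t_welch", "var_F", "var_levene").
#' @slot statistic test statistic.
#' @slot pValue primary p-value (for the permutation test: one-sided in the
#'   direction of the observed difference, the procedure used in the source
#'   analyses; see \code{pTwoSided} for the calibrated alternative).
#' @slot pTwoSided two-sided p-value when meaningful, else \code{NA}.
#' @slot sidedness "two_sided", "greater" or "less".
#' @slot nCase,nControl sample sizes.
#' @slot nPermutations number of permutations used, \code{NA} when not a
#'   resampling test.
#' @slot exact logical, exact enumeration vs approximation.
#' @slot observedDifference mean(case) - mean(control) for the permutation
#'   test, \code{NA} otherwise.
#' @slot seed RNG seed for Monte-Carlo permutations, \code{NA} otherwise.
#' @slot detail character, e.g. which t-test branch was chosen.
#' @exportClass TestResult
setClass("TestResult", representation(
  method = "character",
  statistic = "numeric",
  pValue = "numeric",
  pTwoSided = "numeric",
  sidedness = "character",
  nCase = "integer",
  nControl = "integer",
  nPermutations = "numeric",
  exact = "logical",
  observedDifference = "numeric",
  seed = "numeric",
  detail = "character"
))

setValidity("TestResult", function(object) {
  msg <- character()
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (!is.na(object@pTwoSided) &&
      (object@pTwoSided < 0 || object@pTwoSided > 1))
    msg <- c(msg, "pTwoSided must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

newTestResult <- function(method, statistic, pValue, sidedness,
                          nCase, nControl, pTwoSided = NA_real_,
                          nPermutations = NA_real_, exact = NA,
                          observedDifference = NA_real_, seed = NA_real_,
                          detail = "") {
  new("TestResult", method = method, statistic = as.numeric(statistic),
      pValue = as.numeric(pValue), pTwoSided = as.numeric(pTwoSided),
      sidedness = sidedness, nCase = as.integer(nCase),
      nControl = as.integer(nControl),
      nPermutations = as.numeric(nPermutations), exact = as.logical(exact),
      observedDifference = as.numeric(observedDifference),
      seed = as.numeric(seed), detail = as.character(detail))
}

setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g (%s%s)\n",
              object@method, object@statistic, object@pValue,
              object@sidedness,
              if (isTRUE(object@exact)) ", exact" else ""))
  if (!is.na(object@pTwoSided) && object@sidedness != "two_sided")
    cat(sprintf("  two-sided p = %.4g\n", object@pTwoSided))
  cat(sprintf("  n_case = %d, n_control = %d%s\n", object@nCase,
              object@nControl,
              if (nzchar(object@detail)) paste0(" [", object@detail, "]")
              else ""))
})

#' Accessor: p-value of a test result
#' @param x a [TestResult-class]
#' @return numeric p-value
#' @export
pValue <- function(x) x@pValue

#' Flatten a TestResult to a one-row data.frame
#' @param x a [TestResult-class]
#' @param row.names,optional,... ignored (S3 compatibility)
#' @return one-row \code{data.frame}
#' @export
as.data.frame.TestResult <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  data.frame(method = x@method, statistic = x@statistic, p = x@pValue,
             p_two_sided = x@pTwoSided, sidedness = x@sidedness,
             n_case = x@nCase, n_control = x@nControl,
             n_permutations = x@nPermutations, exact = x@exact,
             observed_difference = x@observedDifference, seed = x@seed,
             detail = x@detail, stringsAsFactors = FALSE)
}
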