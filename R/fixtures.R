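# Fixture I/O: movies as multi-page TIFF with a JSON metadata sidecar, ground
# truth as CSV, config echo as JSON. Round-trips are lossless at the recorded
# bit depth.

simConfigToList <- function(config) {
  nm <- slotNames("SimConfig")
  out <- lapply(nm, function(s) {
    v <- slot(config, s)
    if (is.numeric(v) && any(is.infinite(v))) "Inf" else v
  })
  names(out) <- nm
  out
}

simConfigFromList <- function(x) {
  num <- function(v) if (identical(v, "Inf")) Inf else as.numeric(v)
  simConfig(nNucleiSide = x$nNucleiSide, fieldSizePx = x$fieldSizePx,
            frameIntervalS = num(x$frameIntervalS),
            nFramesPerStage = x$nFramesPerStage,
            stageLabels = unlist(x$stageLabels),
            kOn = num(x$kOn), kOff = num(x$kOff),
            loadingRate = num(x$loadingRate),
            transcriptDwellS = num(x$transcriptDwellS),
            psfSigmaPx = num(x$psfSigmaPx),
            ampPerTranscript = num(x$ampPerTranscript),
            backgroundLevel = num(x$backgroundLevel),
            noiseSd = num(x$noiseSd),
            bleachHalflifeS = num(x$bleachHalflifeS),
            dotDiffusionPx = num(x$dotDiffusionPx),
            nZPlanes = x$nZPlanes, bitDepth = x$bitDepth, seed = x$seed)
}

#' Write a simulated movie and its ground truth to disk
#'
#' Writes \code{movie.tif} (multi-page TIFF, one page per (t, z) in t-major
#' order, channels as samples per pixel), \code{movie_meta.json} (axis order
#' and acquisition metadata), \code{truth.csv} (one row per nucleus per frame:
#' nucleus_id, frame, stage, state, transcript_count, row, col) and
#' \code{config.json} (verbatim config echo).
#'
#' @param movie a [MovieStack-class]
#' @param truth the matching [GroundTruth-class] (or \code{NULL} to skip)
#' @param dir output directory (created if missing)
#' @return (invisibly) named character vector of the files written
#' @export
writeFixture <- function(movie, truth, dir) {
  stopifnot(is(movie, "MovieStack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(movie@pixels)
  maxVal <- 2^movie@bitDepth - 1
  pages <- vector("list", d[1L] * d[2L])
  k <- 0L
  for (f in seq_len(d[1L])) {
    for (z in seq_len(d[2L])) {
      k <- k + 1L
      pages[[k]] <- array(movie@pixels[f, z, , , ] / maxVal,
                          dim = c(d[3L], d[4L], d[5L]))
    }
  }
  tifPath <- file.path(dir, "movie.tif")
  tiff::writeTIFF(pages, tifPath, bits.per.sample = movie@bitDepth,
                  compression = "none")
  metaPath <- file.path(dir, "movie_meta.json")
  jsonlite::write_json(list(
    axis_order = "TZYXC", dims = d, bit_depth = movie@bitDepth,
    pixel_size_um = movie@pixelSizeUm,
    frame_interval_s = movie@frameIntervalS,
    channel_roles = as.list(movie@channelRoles)),
    metaPath, auto_unbox = TRUE, digits = NA)
  files <- c(movie = tifPath, meta = metaPath)
  if (!is.null(truth)) {
    truthPath <- file.path(dir, "truth.csv")
    utils::write.csv(truthTable(truth), truthPath, row.names = FALSE)
    cfgPath <- file.path(dir, "config.json")
    jsonlite::write_json(simConfigToList(truth@config), cfgPath,
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, truth = truthPath, config = cfgPath)
  }
  invisible(files)
}

#' Read a movie fixture back from disk
#'
#' Inverse of [writeFixture()]: reconstructs the [MovieStack-class] from the
#' TIFF pages and the JSON sidecar; pixel values round-trip exactly at the
#' recorded bit depth.
#'
#' @param dir directory written by [writeFixture()]
#' @return list with \code{movie} ([MovieStack-class]), \code{truth}
#'   (\code{data.frame} or \code{NULL}) and \code{config} ([SimConfig-class]
#'   or \code{NULL})
#' @export
readFixture <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "movie_meta.json"),
                              simplifyVector = TRUE)
  d <- as.integer(meta$dims)
  # libtiff flags the 2nd channel of a greyscale+extra page as ExtraSamples;
  # harmless for our TZYXC layout, so muffle just that note
  pages <- withCallingHandlers(
    tiff::readTIFF(file.path(dir, "movie.tif"), all = TRUE),
    warning = function(w) {
      if (grepl("ExtraSamples", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  maxVal <- 2^meta$bit_depth - 1
  pix <- array(0, dim = d)
  k <- 0L
  for (f in seq_len(d[1L])) {
    for (z in seq_len(d[2L])) {
      k <- k + 1L
      pg <- pages[[k]]
      if (length(dim(pg)) == 2L) dim(pg) <- c(dim(pg), 1L)
      pix[f, z, , , ] <- round(pg * maxVal)
    }
  }
  roles <- unlist(meta$channel_roles)
  movie <- new("MovieStack", pixels = pix,
               pixelSizeUm = meta$pixel_size_um,
               frameIntervalS = meta$frame_interval_s,
               bitDepth = as.integer(meta$bit_depth),
               channelRoles = stats::setNames(as.integer(roles), names(roles)))
  truthPath <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truthPath))
    utils::read.csv(truthPath, stringsAsFactors = FALSE) else NULL
  cfgPath <- file.path(dir, "config.json")
  config <- if (file.exists(cfgPath))
    simConfigFromList(jsonlite::read_json(cfgPath, simplifyVector = TRUE))
    else NULL
  list(movie = movie, truth = truth, config = config)
}
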