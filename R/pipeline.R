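# End-to-end orchestration: simulate (or load) -> project -> bleach-correct ->
# split stages -> detect -> normalize -> track -> metrics -> case-vs-control
# statistics, with config echo and deterministic seeding throughout.

#' Assemble a pipeline configuration
#'
#' A plain named list validated here and echoed verbatim into the output
#' manifest. Either \code{conditions} (simulation mode: named list of
#' [simConfig()] argument overrides, e.g. \code{list(control = list(),
#' case = list(kOff = 0.2))}) or \code{inputDirs} (named list of fixture
#' directory vectors readable by [readFixture()]) must be given.
#'
#' @param conditions named list of simConfig overrides per condition
#' @param inputDirs named list of character vectors of fixture directories
#' @param nMovies movies simulated per condition (default 3)
#' @param baseSeed integer; movie m of condition k is seeded
#'   \code{baseSeed + 1000 * (k - 1) + m} (default 1)
#' @param detection a [DetectionParams-class]
#' @param tracking a [TrackingParams-class]
#' @param bleachMethod \code{"simple_ratio"}, \code{"exponential_fit"} or
#'   \code{"none"}
#' @param initWindowFrac,smoothW stage-metric options (see [stageMetrics()])
#' @param alpha significance level for the comparison battery (default 0.05)
#' @param nPermutations Monte-Carlo permutations (default 10000)
#' @param statsSeed seed for Monte-Carlo permutation tests (default baseSeed)
#' @param unit statistical unit for comparisons: \code{"movie"} (default;
#'   the embryo/movie is the replicate) or \code{"track"} (pooled per-track
#'   values, exploratory)
#' @param outputDir directory for CSV/JSON outputs, or \code{NULL} to skip
#'   writing
#' @return validated config list (class \code{ms2burst_config})
#' @export
pipelineConfig <- function(conditions = NULL, inputDirs = NULL, nMovies = 3L,
                           baseSeed = 1L, detection = detectionParams(),
                           tracking = trackingParams(),
                           bleachMethod = "simple_ratio",
                           initWindowFrac = 0.25, smoothW = 3L, alpha = 0.05,
                           nPermutations = 10000L, statsSeed = baseSeed,
                           unit = c("movie", "track"), outputDir = NULL) {
  if (is.null(conditions) && is.null(inputDirs))
    stop("either conditions (simulate mode) or inputDirs must be given")
  if (!is.null(conditions) &&
      (is.null(names(conditions)) || any(!nzchar(names(conditions)))))
    stop("conditions must be a named list")
  cfg <- list(conditions = conditions, inputDirs = inputDirs,
              nMovies = as.integer(nMovies), baseSeed = as.integer(baseSeed),
              detection = detection, tracking = tracking,
              bleachMethod = match.arg(bleachMethod,
                                       c("simple_ratio", "exponential_fit",
                                         "none")),
              initWindowFrac = initWindowFrac, smoothW = as.integer(smoothW),
              alpha = alpha, nPermutations = as.integer(nPermutations),
              statsSeed = as.integer(statsSeed),
              unit = match.arg(unit), outputDir = outputDir)
  class(cfg) <- "ms2burst_config"
  cfg
}

#' Analyze one movie end to end
#'
#' Maximum projection, optional bleach correction of the green channel, stage
#' splitting, dot detection with per-stage normalization, identity tracking,
#' and frame/stage/track metrics.
#'
#' @param stack a [MovieStack-class] or [Movie2D-class]
#' @param partition a [StagePartition-class] (default: one stage spanning the
#'   movie)
#' @param detection a [DetectionParams-class]
#' @param tracking a [TrackingParams-class]
#' @param bleachMethod \code{"simple_ratio"}, \code{"exponential_fit"} or
#'   \code{"none"}
#' @param initWindowFrac,smoothW see [stageMetrics()]
#' @return list: \code{dots} (tracked, normalized), \code{frame_metrics}
#'   (with stage column), \code{stage_metrics} (one row per stage),
#'   \code{track_features}
#' @export
analyzeMovie <- function(stack, partition = NULL,
                         detection = detectionParams(),
                         tracking = trackingParams(),
                         bleachMethod = "simple_ratio",
                         initWindowFrac = 0.25, smoothW = 3L) {
  movie <- maxProject(stack)
  if (!identical(bleachMethod, "none"))
    movie <- bleachCorrect(movie, "green", bleachMethod)
  nT <- dim(movie@pixels)[1L]
  if (is.null(partition)) partition <- stagePartition("all", 0L, nT)
  dots <- detectMovie(movie, partition, detection)
  dots <- linkFrames(dots, tracking)
  dt <- movie@frameIntervalS
  fmList <- list(); smList <- list()
  for (i in seq_along(partition@label)) {
    lab <- partition@label[i]
    sd <- dots[!is.na(dots$stage) & dots$stage == lab, , drop = FALSE]
    fm <- frameMetrics(sd, frames = partition@start[i]:(partition@end[i] - 1L))
    fm$stage <- lab
    fmList[[i]] <- fm
    sm <- stageMetrics(fm, sd, frameIntervalS = dt,
                       initWindowFrac = initWindowFrac, smoothW = smoothW,
                       stageStart = partition@start[i])
    sm$stage <- lab
    smList[[i]] <- sm
    message(sprintf("stage %s: %d dots, %d tracks, max n_dots %d", lab,
                    nrow(sd), length(unique(sd$track_id)), max(fm$n_dots)))
  }
  list(dots = dots,
       frame_metrics = do.call(rbind, fmList),
       stage_metrics = do.call(rbind, smList),
       track_features = trackFeatures(dots, dt))
}

rbindWithMovie <- function(lst) {
  out <- lapply(seq_along(lst), function(i) {
    df <- lst[[i]]
    if (is.null(df) || !nrow(df)) return(NULL)
    cbind(movie = i - 1L, df)
  })
  do.call(rbind, out)
}

#' Run the full pipeline over one or more conditions
#'
#' Simulation mode: for every named condition, \code{nMovies} movies are
#' generated (seeded \code{baseSeed + 1000 (k-1) + m}), rendered and analyzed.
#' Input mode: fixture directories are read with [readFixture()] and analyzed
#' with the partition implied by their config echo. When exactly two
#' conditions are present they are compared with [compareConditions()]; with
#' named conditions \code{case}/\code{control} those roles are used, otherwise
#' the first condition is the case. Identical config and seed reproduce
#' identical outputs.
#'
#' With \code{outputDir} set, writes per-condition \code{frame_metrics.csv},
#' \code{stage_metrics.csv}, \code{track_features.csv}, \code{dots.csv}, plus
#' \code{stats_results.csv}, \code{config.json} (verbatim echo) and
#' \code{manifest.json}. Per-movie failures are logged and skipped; the
#' \code{failed} element reports them.
#'
#' @param config a [pipelineConfig()] list
#' @return list: \code{conditions} (per condition: \code{movies} list of
#'   [analyzeMovie()] bundles plus pooled \code{stage_metrics} /
#'   \code{track_features} tables), \code{comparisons} (tidy stats table or
#'   \code{NULL}), \code{failed} (character), \code{config}
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "ms2burst_config"))
  condNames <- names(if (!is.null(config$conditions)) config$conditions
                     else config$inputDirs)
  results <- list()
  failed <- character(0)
  for (k in seq_along(condNames)) {
    cn <- condNames[k]
    bundles <- list()
    if (!is.null(config$conditions)) {
      for (m in seq_len(config$nMovies)) {
        seed <- config$baseSeed + 1000L * (k - 1L) + m
        args <- utils::modifyList(config$conditions[[cn]], list(seed = seed))
        simCfg <- do.call(simConfig, args)
        b <- tryCatch({
          truth <- simulateTelegraph(simCfg)
          stack <- renderMovie(truth)
          bun <- analyzeMovie(stack, simStagePartition(simCfg),
                              detection = config$detection,
                              tracking = config$tracking,
                              bleachMethod = config$bleachMethod,
                              initWindowFrac = config$initWindowFrac,
                              smoothW = config$smoothW)
          bun$truth <- truth
          bun$seed <- seed
          bun
        }, error = function(e) {
          warning(sprintf("condition %s movie %d failed: %s", cn, m,
                          conditionMessage(e)))
          NULL
        })
        if (is.null(b)) failed <- c(failed, sprintf("%s/movie%d", cn, m))
        else bundles[[length(bundles) + 1L]] <- b
      }
    } else {
      for (m in seq_along(config$inputDirs[[cn]])) {
        dirm <- config$inputDirs[[cn]][m]
        b <- tryCatch({
          fx <- readFixture(dirm)
          part <- if (!is.null(fx$config)) simStagePartition(fx$config)
                  else NULL
          analyzeMovie(fx$movie, part, detection = config$detection,
                       tracking = config$tracking,
                       bleachMethod = config$bleachMethod,
                       initWindowFrac = config$initWindowFrac,
                       smoothW = config$smoothW)
        }, error = function(e) {
          warning(sprintf("condition %s input %s failed: %s", cn, dirm,
                          conditionMessage(e)))
          NULL
        })
        if (is.null(b)) failed <- c(failed, sprintf("%s/%s", cn, dirm))
        else bundles[[length(bundles) + 1L]] <- b
      }
    }
    results[[cn]] <- list(
      movies = bundles,
      stage_metrics = rbindWithMovie(lapply(bundles, `[[`, "stage_metrics")),
      track_features = rbindWithMovie(lapply(bundles, `[[`, "track_features")))
  }
  comparisons <- NULL
  if (length(condNames) == 2L) {
    caseName <- if ("case" %in% condNames) "case" else condNames[1L]
    ctrlName <- setdiff(condNames, caseName)[1L]
    comparisons <- compareConditions(results[[caseName]], results[[ctrlName]],
                                     unit = config$unit, alpha = config$alpha,
                                     nPermutations = config$nPermutations,
                                     seed = config$statsSeed)
  }
  out <- list(conditions = results, comparisons = comparisons,
              failed = failed, config = config)
  if (!is.null(config$outputDir)) writePipelineOutputs(out, config$outputDir)
  out
}

writePipelineOutputs <- function(out, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (cn in names(out$conditions)) {
    cd <- file.path(dir, cn)
    if (!dir.exists(cd)) dir.create(cd)
    cond <- out$conditions[[cn]]
    if (!is.null(cond$stage_metrics))
      utils::write.csv(cond$stage_metrics,
                       file.path(cd, "stage_metrics.csv"), row.names = FALSE)
    if (!is.null(cond$track_features))
      utils::write.csv(cond$track_features,
                       file.path(cd, "track_features.csv"), row.names = FALSE)
    fm <- rbindWithMovie(lapply(cond$movies, `[[`, "frame_metrics"))
    if (!is.null(fm))
      utils::write.csv(fm, file.path(cd, "frame_metrics.csv"),
                       row.names = FALSE)
    dots <- rbindWithMovie(lapply(cond$movies, `[[`, "dots"))
    if (!is.null(dots))
      utils::write.csv(dots, file.path(cd, "dots.csv"), row.names = FALSE)
  }
  if (!is.null(out$comparisons))
    utils::write.csv(out$comparisons, file.path(dir, "stats_results.csv"),
                     row.names = FALSE)
  cfgEcho <- out$config
  cfgEcho$detection <- attributes(cfgEcho$detection)
  cfgEcho$tracking <- attributes(cfgEcho$tracking)
  cfgPath <- file.path(dir, "config.json")
  jsonlite::write_json(cfgEcho, cfgPath, auto_unbox = TRUE, force = TRUE,
                       digits = NA)
  jsonlite::write_json(list(
    package = "ms2burst",
    version = as.character(utils::packageVersion("ms2burst")),
    base_seed = out$config$baseSeed,
    stats_seed = out$config$statsSeed,
    config_md5 = unname(tools::md5sum(cfgPath)),
    failed = out$failed),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

# run the three-test battery on one metric, tolerant of degenerate input
testBattery <- function(case, control, metric, stage, level, alpha,
                        nPermutations, seed) {
  case <- case[!is.na(case)]; control <- control[!is.na(control)]
  if (length(case) < 2L || length(control) < 2L) return(NULL)
  rows <- list()
  add <- function(tr) {
    if (is.null(tr)) return()
    df <- as.data.frame(tr)
    rows[[length(rows) + 1L]] <<- cbind(metric = metric, stage = stage,
                                        level = level, df)
  }
  safe <- function(expr) tryCatch(suppressWarnings(expr),
                                  error = function(e) NULL)
  add(safe(mannWhitneyU(case, control)))
  add(safe(permutationTest(case, control, nPermutations = nPermutations,
                           seed = seed)))
  add(safe(tTestAuto(case, control, alpha = alpha)))
  add(safe(varianceCompare(case, control, "F")))
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Compare two analyzed conditions metric by metric
#'
#' Runs the full battery (Mann-Whitney U, mean-difference permutation test,
#' variance-gated t-test, F variance comparison) on every tissue-level stage
#' metric and every per-track burst feature, stage by stage. Stages present in
#' only one condition are skipped with a warning; the intersection is
#' analyzed.
#'
#' With \code{unit = "movie"} (default, the movie/embryo is the replicate)
#' track features are averaged within movie before testing; \code{unit =
#' "track"} pools tracks across movies (exploratory: tracks within a movie
#' are not independent).
#'
#' @param caseBundle,controlBundle condition bundles as produced by
#'   [runPipeline()] (lists with \code{stage_metrics} and
#'   \code{track_features} tables carrying a \code{movie} column)
#' @param unit \code{"movie"} or \code{"track"}
#' @param alpha significance level for the t-test variance gate and stars
#' @param nPermutations,seed Monte-Carlo permutation settings
#' @return tidy \code{data.frame}: metric, stage, level (tissue/track),
#'   method, statistic, p, p_two_sided, sidedness, n_case, n_control,
#'   n_permutations, exact, observed_difference, seed, detail, stars
#' @export
compareConditions <- function(caseBundle, controlBundle,
                              unit = c("movie", "track"), alpha = 0.05,
                              nPermutations = 10000L, seed = 1L) {
  unit <- match.arg(unit)
  out <- list()
  tissueMetrics <- c("t_first_dot_s", "t_first_peak_s", "t_all_dots_s",
                     "max_n_dots", "avg_transcription_rate",
                     "init_total_pixels", "init_active_nuclei",
                     "intensity_peak_sd")
  trackMetrics <- c("start_time_s", "n_frames_present", "avg_size_px",
                    "avg_brightness", "max_brightness", "n_bursts",
                    "mean_on_run_s", "mean_off_gap_s", "n_transitions")
  smCase <- caseBundle$stage_metrics
  smCtrl <- controlBundle$stage_metrics
  stages <- intersect(unique(smCase$stage), unique(smCtrl$stage))
  dropped <- setdiff(union(unique(smCase$stage), unique(smCtrl$stage)),
                     stages)
  if (length(dropped))
    warning("stage(s) present in only one condition, skipped: ",
            paste(dropped, collapse = ", "))
  for (s in stages) {
    for (metric in tissueMetrics) {
      out[[length(out) + 1L]] <- testBattery(
        smCase[[metric]][smCase$stage == s],
        smCtrl[[metric]][smCtrl$stage == s],
        metric, s, "tissue", alpha, nPermutations, seed)
    }
    tfCase <- caseBundle$track_features
    tfCtrl <- controlBundle$track_features
    for (metric in trackMetrics) {
      if (is.null(tfCase[[metric]]) || is.null(tfCtrl[[metric]])) next
      if (!any(tfCase$stage == s) || !any(tfCtrl$stage == s)) next
      if (unit == "movie") {
        vc <- tapply(tfCase[[metric]][tfCase$stage == s],
                     tfCase$movie[tfCase$stage == s], mean, na.rm = TRUE)
        vx <- tapply(tfCtrl[[metric]][tfCtrl$stage == s],
                     tfCtrl$movie[tfCtrl$stage == s], mean, na.rm = TRUE)
      } else {
        vc <- tfCase[[metric]][tfCase$stage == s]
        vx <- tfCtrl[[metric]][tfCtrl$stage == s]
      }
      out[[length(out) + 1L]] <- testBattery(
        as.numeric(vc), as.numeric(vx), metric, s,
        if (unit == "movie") "track_movie_mean" else "track_pooled",
        alpha, nPermutations, seed)
    }
    # total number of bursts per movie (summed over tracks, not averaged)
    if (!is.null(tfCase$n_bursts) && !is.null(tfCtrl$n_bursts) &&
        any(tfCase$stage == s) && any(tfCtrl$stage == s)) {
      vc <- tapply(tfCase$n_bursts[tfCase$stage == s],
                   tfCase$movie[tfCase$stage == s], sum)
      vx <- tapply(tfCtrl$n_bursts[tfCtrl$stage == s],
                   tfCtrl$movie[tfCtrl$stage == s], sum)
      out[[length(out) + 1L]] <- testBattery(
        as.numeric(vc), as.numeric(vx), "total_bursts", s, "movie_total",
        alpha, nPermutations, seed)
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) return(NULL)
  out$stars <- significanceStars(out$p)
  rownames(out) <- NULL
  out
}
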