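#' Default pipeline configuration
#'
#' Desk-scale defaults for [runPipeline()]: a two-metric cohort of 148
#' subjects, a reduced quantile grid and reduced MCMC/bootstrap sample
#' counts. \code{paperScale = TRUE} switches to the full settings (seven
#' quantile levels, 50000 MCMC samples per grid, 50000 bootstrap
#' replicates).
#'
#' @param outDir output directory.
#' @param seed integer seed used (via derived child seeds) by every
#'   stochastic step.
#' @param paperScale logical; use full-scale settings.
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function(outDir, seed = 1, paperScale = FALSE) {
  list(
    outDir = outDir,
    seed = seed,
    simulate = list(
      nSubjects = 148,
      metricNames = c("volume_loss", "cognitive_decline"),
      gridZ = rbind(c(-2, -1, 0, 1, 2), c(-2, -1, 0, 1, 2)),
      sequence = c(1, 2, 1, 2, 1, 2),
      noiseSd = 1,
      labelFlip = 0.1,
      signals = list(enabled = FALSE, nRegions = 6, duration = 10,
                     samplingRate = 256)),
    prep = list(
      covariates = c("age"),
      directions = NULL,           # default: all increasing
      anchorFraction = 0.1,
      levels = if (paperScale) seq(0.2, 0.8, by = 0.1) else c(0.3, 0.5, 0.7),
      nEvents = 3),
    fit = list(
      nStarts = if (paperScale) 10 else 4,
      ascentIter = if (paperScale) 1000 else 200,
      nSamples = if (paperScale) 50000 else 5000),
    compare = list(B = if (paperScale) 50000 else 5000,
                   metrics = NULL)  # default: all
  )
}

#' Run the staging pipeline
#'
#' Executes the pipeline steps \code{simulate}, \code{metrics},
#' \code{prep}, \code{fit}, \code{trajectories}, \code{compare} (any
#' subset, in that order), writing delimited-text/JSON artifacts and a
#' machine-readable run manifest (\code{manifest.json}: parameters,
#' seeds, inputs, outputs, package version) into the output directory.
#' Reruns with an identical configuration are bit-identical for the
#' stochastic steps because every random draw flows from the
#' configuration seed.
#'
#' @param config configuration list as from [defaultPipelineConfig()], or
#'   the path of a YAML file holding one.
#' @param steps character vector of steps to run.
#' @return invisibly, a named list of artifact paths.
#' @export
runPipeline <- function(config,
                        steps = c("simulate", "metrics", "prep", "fit",
                                  "trajectories", "compare")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$outDir)) stop("config error: outDir is required")
  if (is.null(config$seed)) stop("config error: seed is required")
  out <- config$outDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifestPath <- file.path(out, "manifest.json")
  manifest <- if (file.exists(manifestPath))
    jsonlite::fromJSON(manifestPath, simplifyVector = FALSE) else list()
  note <- function(step, params, outputs) {
    manifest[[step]] <<- list(step = step, params = params,
                              seed = config$seed, outputs = outputs,
                              version = as.character(
                                utils::packageVersion("ebmstager")))
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  paths <- list(cohort = file.path(out, "cohort.csv"),
                truth = file.path(out, "truth.json"),
                metrics = file.path(out, "metrics.csv"),
                adjusted = file.path(out, "adjusted.csv"),
                zscores = file.path(out, "zscores.csv"),
                grids = file.path(out, "grids.json"),
                fit = file.path(out, "fit.json"),
                posterior = file.path(out, "posterior.csv"),
                trajectories = file.path(out, "trajectories.csv"),
                proportions = file.path(out, "proportions.csv"),
                comparisons = file.path(out, "comparisons.csv"))

  if ("simulate" %in% steps) {
    sc <- config$simulate
    grid <- eventGrid(do.call(rbind, lapply(seq_len(nrow(as.matrix(sc$gridZ))),
                                            function(i) as.matrix(sc$gridZ)[i, ])),
                      metricNames = sc$metricNames)
    seqn <- eventSequence(unlist(sc$sequence), metricNames = sc$metricNames)
    cohort <- simulateCohort(sc$nSubjects, grid, seqn,
                             noiseSd = sc$noiseSd,
                             labelFlip = sc$labelFlip,
                             seed = .childSeed(config$seed, 1))
    writeCohortCSV(cohort, paths$cohort, truthPath = paths$truth)
    outputs <- c(paths$cohort, paths$truth)
    if (isTRUE(sc$signals$enabled)) {
      sigDir <- file.path(out, "signals")
      dir.create(sigDir, showWarnings = FALSE)
      for (j in seq_len(sc$nSubjects)) {
        sim <- simulateTimeSeries(sc$signals$nRegions,
                                  samplingRate = sc$signals$samplingRate,
                                  duration = sc$signals$duration,
                                  seed = .childSeed(config$seed, 100 + j))
        writeRegionalTimeSeries(sim$mixed,
                                file.path(sigDir,
                                          sprintf("subj_%03d.csv", j)))
      }
      outputs <- c(outputs, sigDir)
    }
    note("simulate", sc, outputs)
  }

  if ("metrics" %in% steps) {
    sigDir <- file.path(out, "signals")
    if (dir.exists(sigDir)) {
      files <- list.files(sigDir, pattern = "\\.csv$", full.names = TRUE)
      rows <- lapply(files, function(f) {
        ts <- readRegionalTimeSeries(f)
        sm <- scalarSynchronyMetrics(
          ts, segmentLength = min(1024, ncol(tsData(ts))),
          totalBand = frequencyBand("total", 0.5,
                                    min(55, samplingRate(ts) / 2 - 1)))
        stats::setNames(sm$value, sm$metric)
      })
      tab <- data.frame(subject_id = sub("\\.csv$", "", basename(files)),
                        do.call(rbind, rows))
      write.csv(tab, paths$metrics, row.names = FALSE)
      note("metrics", list(nFiles = length(files)), paths$metrics)
    } else {
      message("metrics: no signals directory; step skipped")
    }
  }

  if ("prep" %in% steps) {
    pc <- config$prep
    cohort <- readCohortCSV(paths$cohort)
    cohort <- adjustCovariates(cohort, covariates = pc$covariates)
    dirs <- pc$directions
    if (is.null(dirs))
      dirs <- setNames(rep("increasing", nrow(cohort)), rownames(cohort))
    z <- zscoreMetrics(cohort, dirs)
    write.csv(as.data.frame(t(assay(cohort))), paths$adjusted)
    write.csv(as.data.frame(t(zValues(z))), paths$zscores)
    anchors <- anchorEvents(z, fraction = pc$anchorFraction)
    grids <- quantileEventGrid(z, levels = unlist(pc$levels),
                               nEvents = pc$nEvents, anchors = anchors)
    jsonlite::write_json(
      list(metricNames = rownames(zValues(z)),
           directions = as.character(dirs),
           anchors = anchors,
           nGrids = length(grids),
           grids = lapply(grids, function(g)
             list(levels = g@levels, z = g@z))),
      paths$grids, auto_unbox = TRUE, digits = NA)
    note("prep", pc, c(paths$adjusted, paths$zscores, paths$grids))
  }

  if ("fit" %in% steps) {
    fc <- config$fit
    z <- t(as.matrix(read.csv(paths$zscores, row.names = 1,
                              check.names = FALSE)))
    gj <- jsonlite::fromJSON(paths$grids, simplifyVector = FALSE)
    grids <- lapply(gj$grids, function(g) {
      zm <- do.call(rbind, lapply(g$z, unlist))
      rownames(zm) <- unlist(gj$metricNames)
      eventGrid(zm, levels = do.call(rbind, lapply(g$levels, unlist)))
    })
    fit <- optimizeEventSettings(z, grids, nStarts = fc$nStarts,
                                 ascentIter = fc$ascentIter,
                                 nSamples = fc$nSamples,
                                 seed = .childSeed(config$seed, 2))
    post <- stagePosterior(z, bestModel(fit))
    write.csv(as.data.frame(post), paths$posterior)
    ev <- sequenceEvents(bestModel(fit)@sequence)
    jsonlite::write_json(
      list(logLik = bestLogLik(fit),
           sequence = ev,
           gridZ = bestModel(fit)@grid@z,
           gridLevels = bestModel(fit)@grid@levels,
           stageZ = stageMu(bestModel(fit)),
           nStages = nStages(bestModel(fit)),
           nGridsEvaluated = fit@nGrids,
           winningGrid = fit@gridIndex,
           positionalVariance = positionalVariance(fit),
           seed = fit@seed),
      paths$fit, auto_unbox = TRUE, digits = NA)
    note("fit", c(fc, list(nGridsEvaluated = fit@nGrids)),
         c(paths$fit, paths$posterior))
  }

  if ("trajectories" %in% steps) {
    adj <- t(as.matrix(read.csv(paths$adjusted, row.names = 1,
                                check.names = FALSE)))
    post <- as.matrix(read.csv(paths$posterior, row.names = 1,
                               check.names = FALSE))
    cohort <- readCohortCSV(paths$cohort)
    tra <- do.call(rbind, lapply(rownames(adj), function(m) {
      tr <- weightedStageMean(adj[m, ], post)
      cbind(metric = m, tr)
    }))
    write.csv(tra, paths$trajectories, row.names = FALSE)
    prop <- stageProportions(colData(cohort)$cdr, post)
    write.csv(data.frame(stage = seq_len(nrow(prop)), prop,
                         check.names = FALSE),
              paths$proportions, row.names = FALSE)
    note("trajectories", list(), c(paths$trajectories, paths$proportions))
  }

  if ("compare" %in% steps) {
    cc <- config$compare
    adj <- t(as.matrix(read.csv(paths$adjusted, row.names = 1,
                                check.names = FALSE)))
    post <- as.matrix(read.csv(paths$posterior, row.names = 1,
                               check.names = FALSE))
    metrics <- cc$metrics
    if (is.null(metrics)) metrics <- rownames(adj)
    cmp <- do.call(rbind, lapply(metrics, function(m)
      cbind(metric = m,
            compareAllStagePairs(adj[m, ], post, B = cc$B,
                                 seed = .childSeed(config$seed, 3)))))
    write.csv(cmp, paths$comparisons, row.names = FALSE)
    note("compare", cc, paths$comparisons)
  }

  invisible(paths)
}
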