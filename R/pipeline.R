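#' Pipeline configuration
#'
#' Bundles the stage settings: sliding-window spec, connection grouping,
#' sparse group LASSO ladder, metric variants, selection and kernel
#' settings, and the classifier protocol. Defaults follow the method's
#' reference operating point: window length 60 timepoints, step 1,
#' lambda2 = 0.4, lambda1 ladder 0.1..0.9, 36 discriminative subgraphs per
#' side. The cluster count defaults to \code{round(0.65 M)} connections
#' (at the acquisition-scale M = 231 this reproduces k = 150); pass
#' \code{k} to override.
#'
#' @param windowLength,windowStep sliding-window spec in timepoints.
#' @param k number of connection groups, or NULL for the proportional
#'   default.
#' @param restarts k-medoids restarts.
#' @param sglasso an \code{\link{SGLassoConfig}}.
#' @param hcc3Variant,hccpnDenom metric variants (see
#'   \code{\link{hypermetrics}}).
#' @param classifier a \code{\link{ClassifierConfig}}.
#' @param distanceMetric connection distance for clustering.
#' @param pooledGrouping cluster on the group-pooled relevant series
#'   (rows of all subjects stacked) instead of per subject.
#' @return list of class \code{"PipelineConfig"}.
#' @export
PipelineConfig <- function(windowLength = 60L, windowStep = 1L, k = NULL,
                           restarts = 10L, sglasso = SGLassoConfig(),
                           hcc3Variant = "normalized",
                           hccpnDenom = "geometric",
                           classifier = ClassifierConfig(),
                           distanceMetric = "correlation",
                           pooledGrouping = FALSE) {
  structure(list(windowLength = as.integer(windowLength),
                 windowStep = as.integer(windowStep),
                 k = if (is.null(k)) NULL else as.integer(k),
                 restarts = as.integer(restarts), sglasso = sglasso,
                 hcc3Variant = hcc3Variant, hccpnDenom = hccpnDenom,
                 classifier = classifier, distanceMetric = distanceMetric,
                 pooledGrouping = pooledGrouping),
            class = "PipelineConfig")
}

defaultK <- function(M) max(1L, as.integer(round(0.65 * M)))

# per-subject hypernetworks for one clustering seed
cohortHypernetworks <- function(relSeries, cfg, seed) {
  M <- ncol(relSeries[[1L]]@values)
  k <- cfg$k %||% defaultK(M)
  if (cfg$pooledGrouping) {
    pooled <- do.call(rbind, lapply(relSeries, relValues))
    rsAll <- relSeries[[1L]]
    rsAll@values <- pooled
    D <- connectionDistances(rsAll, cfg$distanceMetric)
    grp <- kmedoidsCluster(D, k, seed, cfg$restarts)
    grps <- rep(list(grp), length(relSeries))
  } else {
    grps <- lapply(seq_along(relSeries), function(s) {
      D <- connectionDistances(relSeries[[s]], cfg$distanceMetric)
      kmedoidsCluster(D, k, seed + 1000L * s, cfg$restarts)
    })
  }
  lapply(seq_along(relSeries), function(s) {
    buildHypernetwork(relSeries[[s]], grps[[s]], cfg$sglasso,
                      subjectId = sprintf("subject%02d", s))
  })
}

#' Run the full pipeline on a cohort
#'
#' Executes dynamic connectivity, connection grouping, hypernetwork
#' construction, metric extraction, feature and subgraph selection, kernel
#' fusion and leave-one-out SVM classification under the repetition
#' protocol (repetition r reruns clustering, hypernetworks, metrics and
#' classification with clustering seed baseSeed + r). Optionally writes
#' stage artifacts.
#'
#' @param subjects list of \linkS4class{SubjectTimeSeries} (e.g. from
#'   \code{\link{readCohort}} or \code{\link{generateCohort}}).
#' @param cfg a \code{\link{PipelineConfig}}.
#' @param outputDir if non-NULL, hypernetworks, metric tables and the
#'   report JSON are written there.
#' @param verbose log stage timings to stderr.
#' @return list with \code{aggregate} metrics, per-repetition results,
#'   \code{static} flag (single-window run), \code{configEcho} and
#'   \code{seeds}.
#' @export
runPipeline <- function(subjects, cfg = PipelineConfig(), outputDir = NULL,
                        verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  labels <- vapply(subjects, groupLabel, "")
  spec <- WindowSpec(cfg$windowLength, cfg$windowStep)
  t0 <- proc.time()[3L]
  relSeries <- lapply(subjects, buildRelevantSeries, spec = spec)
  W <- nrow(relSeries[[1L]]@values)
  say("dynconn: %d windows x %d connections [%.1fs]", W,
      ncol(relSeries[[1L]]@values), proc.time()[3L] - t0)

  ccfg <- cfg$classifier
  runOnce <- function(seed) {
    t1 <- proc.time()[3L]
    nets <- cohortHypernetworks(relSeries, cfg, seed)
    tables <- lapply(nets, metricTable, variant = cfg$hcc3Variant,
                     denom = cfg$hccpnDenom)
    feat <- localFeatureMatrix(tables)
    say("rep seed %d: hypernetworks + metrics [%.1fs]", seed,
        proc.time()[3L] - t1)
    res <- loocvClassify(feat, nets, labels, ccfg, repSeed = seed)
    res$networks <- nets
    res$metricTables <- tables
    say("rep seed %d: LOOCV done [%.1fs]", seed, proc.time()[3L] - t1)
    res
  }

  keep <- new.env(parent = emptyenv()); keep$last <- NULL
  protocol <- repeatProtocol(function(s) {
    r <- runOnce(s); keep$last <- r; r
  }, ccfg)

  report <- list(aggregate = protocol$aggregate,
                 repetitions = protocol$repetitions,
                 seeds = protocol$seeds,
                 static = (W == 1L),
                 n = length(subjects),
                 configEcho = configEcho(cfg))
  if (W == 1L) say("static run: single full-length window")

  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    last <- keep$last
    for (s in seq_along(last$networks)) {
      writeHyperedgeList(last$networks[[s]],
                         file.path(outputDir,
                                   sprintf("hypernet_%02d.txt", s)))
      writeMetricTable(last$metricTables[[s]],
                       file.path(outputDir,
                                 sprintf("metrics_%02d.tsv", s)))
    }
    writeReport(report, file.path(outputDir, "report.json"))
  }
  report
}

configEcho <- function(cfg) {
  cc <- cfg$classifier
  list(windowLength = cfg$windowLength, windowStep = cfg$windowStep,
       k = cfg$k, restarts = cfg$restarts,
       lambda1Set = cfg$sglasso$lambda1Set, lambda2 = cfg$sglasso$lambda2,
       hcc3Variant = cfg$hcc3Variant, hccpnDenom = cfg$hccpnDenom,
       distanceMetric = cfg$distanceMetric,
       pooledGrouping = cfg$pooledGrouping,
       cGrid = cc$cGrid, gammaGrid = cc$gammaGrid,
       innerFolds = cc$innerFolds, leakageMode = cc$leakageMode,
       repetitions = cc$repetitions, baseSeed = cc$baseSeed,
       q = cc$q, nPerm = cc$nPerm, t1 = cc$t1, t2 = cc$t2,
       wlIter = cc$wlIter)
}
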