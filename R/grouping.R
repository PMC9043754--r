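#' Pairwise distances between functional connections
#'
#' Distance between two connections is the correlation distance 1 - r
#' between their relevant-series columns (default; the grouping exists to
#' collect connections whose dynamics co-vary, which is what the group
#' penalty should act on), or the Euclidean distance between the columns
#' (sensitive to the overall correlation level as well as the dynamics).
#'
#' @param rs a \linkS4class{RelevantSeries}.
#' @param metric \code{"correlation"} (default) or \code{"euclidean"}.
#' @return symmetric M x M matrix with zero diagonal.
#' @export
connectionDistances <- function(rs, metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  V <- rs@values
  if (metric == "euclidean") {
    D <- as.matrix(stats::dist(t(V)))
  } else {
    R <- suppressWarnings(stats::cor(V))
    R[is.na(R)] <- 0
    D <- 1 - R
    diag(D) <- 0
  }
  dimnames(D) <- NULL
  D
}

# k-means++ style seeding on a distance matrix: first medoid uniform,
# subsequent medoids sampled with probability proportional to the squared
# distance to the nearest already-chosen medoid.
kppSeed <- function(D, k) {
  n <- nrow(D)
  med <- integer(k)
  med[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    for (j in 2L:k) {
      dmin <- apply(D[, med[seq_len(j - 1L)], drop = FALSE], 1L, min)
      w <- dmin^2
      if (sum(w) == 0) {
        # all points coincide with chosen medoids: pick lowest unused index
        med[j] <- setdiff(seq_len(n), med[seq_len(j - 1L)])[1L]
      } else {
        med[j] <- sample.int(n, 1L, prob = w)
      }
    }
  }
  med
}

#' k-medoids clustering of connections
#'
#' PAM-style k-medoids with k-means++ seeding, run \code{restarts} times;
#' the restart with the lowest total within-cluster distance wins (ties go
#' to the earliest restart). Deterministic given \code{seed}.
#'
#' @param D symmetric distance matrix (e.g. \code{\link{connectionDistances}}).
#' @param k number of groups, 1 <= k <= nrow(D).
#' @param seed integer seed.
#' @param restarts number of random restarts (default 10).
#' @param maxIter maximum swap sweeps per restart.
#' @return a \linkS4class{ConnectionGrouping}.
#' @examples
#' rs <- buildRelevantSeries(
#'   SubjectTimeSeries("s", "negative", matrix(rnorm(200), 50, 4)),
#'   WindowSpec(20, 10))
#' kmedoidsCluster(connectionDistances(rs), k = 2, seed = 1)
#' @export
kmedoidsCluster <- function(D, k, seed, restarts = 10L, maxIter = 100L) {
  n <- nrow(D)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must lie in 1..", n)
  best <- NULL
  seed <- as.integer(seed)
  old <- globalenv()$.Random.seed
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  for (r in seq_len(restarts)) {
    init <- sort(kppSeed(D, k))
    fit <- .pam_swap(D, init - 1L, as.integer(maxIter))
    if (is.null(best) || fit$cost < best$cost - 1e-12) best <- fit
  }
  new("ConnectionGrouping",
      assignments = as.integer(best$assignments) + 1L,
      medoids = as.integer(best$medoids) + 1L,
      cost = best$cost, seed = seed)
}
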