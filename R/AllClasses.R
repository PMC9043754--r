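#' One subject's component time series
#'
#' Container for a single subject's multivariate signal: a numeric matrix
#' with \code{T} timepoints (rows) and \code{N} components (columns), plus
#' the subject identifier and group label. Group labels are
#' \code{"positive"} (the patient group in clinical use) or
#' \code{"negative"}.
#'
#' @slot subjectId character scalar.
#' @slot group \code{"positive"} or \code{"negative"}.
#' @slot data numeric matrix, timepoints x components.
#' @export
setClass("SubjectTimeSeries",
  representation(subjectId = "character", group = "character",
                 data = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@subjectId) != 1L || !nzchar(object@subjectId))
      msg <- c(msg, "subjectId must be a non-empty string")
    if (!object@group %in% c("positive", "negative"))
      msg <- c(msg, "group must be 'positive' or 'negative'")
    d <- object@data
    if (!is.numeric(d)) msg <- c(msg, "data must be numeric")
    if (nrow(d) < 2L) msg <- c(msg, "need at least 2 timepoints")
    if (ncol(d) < 3L) msg <- c(msg, "need at least 3 components")
    if (anyNA(d)) msg <- c(msg, "data contains missing values")
    else {
      v <- apply(d, 2L, stats::var)
      if (any(v == 0)) {
        msg <- c(msg, sprintf("zero-variance component(s): %s",
                              paste(which(v == 0), collapse = ", ")))
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Sliding-window specification
#'
#' Window length \code{l} and step \code{s}, both in timepoints. A series of
#' length \code{T} yields \code{W = floor((T - l)/s + 1)} windows anchored at
#' rows \code{1, 1+s, 1+2s, ...}; a trailing partial window is discarded.
#' The single full-length window (\code{l = T}) is the static special case.
#'
#' @slot length window length in timepoints (>= 2).
#' @slot step window step in timepoints (>= 1).
#' @export
setClass("WindowSpec",
  representation(length = "integer", step = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@length < 2L) msg <- c(msg, "window length must be >= 2")
    if (object@step < 1L) msg <- c(msg, "window step must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Relevant time series of all functional connections
#'
#' The W x M matrix whose column m holds the windowed Pearson correlations
#' of the component pair mapped to connection m (lexicographic pair order,
#' see \code{\link{connectionIndex}}), i.e. the dynamic-connectivity trace
#' of that functional connection.
#'
#' @slot values numeric matrix, windows x connections, entries in [-1, 1].
#' @slot windowSpec the \linkS4class{WindowSpec} used.
#' @slot nComponents number of components N (so M = N(N-1)/2 columns).
#' @export
setClass("RelevantSeries",
  representation(values = "matrix", windowSpec = "WindowSpec",
                 nComponents = "integer"),
  validity = function(object) {
    msg <- character()
    N <- object@nComponents
    if (N < 3L) msg <- c(msg, "nComponents must be >= 3")
    if (ncol(object@values) != (N * (N - 1L)) %/% 2L)
      msg <- c(msg, "column count must equal N(N-1)/2")
    if (nrow(object@values) < 1L) msg <- c(msg, "need at least one window")
    v <- object@values
    if (any(v < -1 - 1e-8 | v > 1 + 1e-8))
      msg <- c(msg, "entries must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
  })

#' Grouping of connections for the group penalty
#'
#' k-medoids partition of the M connection nodes used as the preset groups
#' of the sparse group LASSO penalty.
#'
#' @slot assignments integer vector, group id in 1..k per node.
#' @slot medoids integer vector of k node ids, medoid of each group.
#' @slot cost total within-cluster distance at the solution.
#' @slot seed integer seed the clustering was run under.
#' @export
setClass("ConnectionGrouping",
  representation(assignments = "integer", medoids = "integer",
                 cost = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    k <- length(object@medoids)
    if (!all(object@assignments %in% seq_len(k)))
      msg <- c(msg, "assignments must reference medoid ids 1..k")
    if (!all(seq_len(k) %in% object@assignments))
      msg <- c(msg, "every group must be non-empty")
    if (any(object@assignments[object@medoids] != seq_len(k)))
      msg <- c(msg, "each medoid must belong to its own group")
    if (length(msg)) msg else TRUE
  })

#' A subject's high-order functional hypernetwork
#'
#' Nodes are the M functional connections; each hyperedge is the support of
#' one sparse group LASSO fit (seed node plus the connections with nonzero
#' coefficients), recorded with its seed node and lambda1 provenance.
#' Singleton supports are dropped and duplicate node-sets deduplicated at
#' construction.
#'
#' @slot nNodes number of connection nodes M.
#' @slot nodeLabels character labels, one per node (component-pair names).
#' @slot hyperedges list; each element has \code{nodes} (integer vector),
#'   \code{seed} (integer) and \code{lambda1} (numeric).
#' @slot subjectId subject the network belongs to.
#' @export
setClass("Hypernetwork",
  representation(nNodes = "integer", nodeLabels = "character",
                 hyperedges = "list", subjectId = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@nodeLabels) != object@nNodes)
      msg <- c(msg, "nodeLabels length must equal nNodes")
    for (e in object@hyperedges) {
      if (!all(e$nodes >= 1L & e$nodes <= object@nNodes)) {
        msg <- c(msg, "hyperedge references invalid node id"); break
      }
      if (!(e$seed %in% e$nodes)) {
        msg <- c(msg, "hyperedge must contain its seed node"); break
      }
      if (length(e$nodes) < 2L) {
        msg <- c(msg, "hyperedges must have at least 2 nodes"); break
      }
    }
    keys <- vapply(object@hyperedges,
                   function(e) paste(sort(e$nodes), collapse = ","), "")
    if (anyDuplicated(keys)) msg <- c(msg, "duplicate hyperedge node-sets")
    if (length(msg)) msg else TRUE
  })

#' Discriminative subgraph set
#'
#' The top subgraph patterns (hyperedge node-sets) ranked by the absolute
#' between-group frequency difference, at most \code{t1} from the
#' positive-sourced side and \code{t2} from the negative-sourced side.
#'
#' @slot patterns list; each element has \code{nodes}, \code{fqPos},
#'   \code{fqNeg}, \code{score} and \code{sourceGroup}.
#' @slot t1,t2 per-side limits used at selection.
#' @export
setClass("DiscriminativeSet",
  representation(patterns = "list", t1 = "integer", t2 = "integer"),
  validity = function(object) {
    msg <- character()
    for (p in object@patterns) {
      if (abs(p$score - abs(p$fqPos - p$fqNeg)) > 1e-12) {
        msg <- c(msg, "score must equal |fqPos - fqNeg|"); break
      }
    }
    nsrc <- vapply(object@patterns, function(p) p$sourceGroup, "")
    if (sum(nsrc == "positive") > object@t1 ||
        sum(nsrc == "negative") > object@t2)
      msg <- c(msg, "per-side limits exceeded")
    if (length(msg)) msg else TRUE
  })

#' Base kernels, alignment weights and fused kernel
#'
#' @slot kernels list of symmetric subjects x subjects base kernel matrices.
#' @slot y numeric label vector in {-1, +1}.
#' @slot mu unit-norm fusion weights.
#' @slot fused the combined kernel sum(mu_l K_l).
#' @export
setClass("KernelBundle",
  representation(kernels = "list", y = "numeric", mu = "numeric",
                 fused = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@mu) != length(object@kernels))
      msg <- c(msg, "one weight per kernel required")
    if (abs(sqrt(sum(object@mu^2)) - 1) > 1e-6)
      msg <- c(msg, "mu must have unit Euclidean norm")
    for (K in object@kernels) {
      if (max(abs(K - t(K))) > 1e-8) {
        msg <- c(msg, "base kernels must be symmetric"); break
      }
    }
    if (length(msg)) msg else TRUE
  })

setMethod("show", "SubjectTimeSeries", function(object) {
  cat(sprintf("SubjectTimeSeries '%s' (%s): %d timepoints x %d components\n",
              object@subjectId, object@group,
              nrow(object@data), ncol(object@data)))
})

setMethod("show", "RelevantSeries", function(object) {
  cat(sprintf(
    "RelevantSeries: %d window(s) x %d connections (N = %d, l = %d, s = %d)%s\n",
    nrow(object@values), ncol(object@values), object@nComponents,
    object@windowSpec@length, object@windowSpec@step,
    if (nrow(object@values) == 1L) " [static]" else ""))
})

setMethod("show", "Hypernetwork", function(object) {
  sz <- vapply(object@hyperedges, function(e) length(e$nodes), 1L)
  cat(sprintf("Hypernetwork '%s': %d nodes, %d hyperedges%s\n",
              object@subjectId, object@nNodes, length(object@hyperedges),
              if (length(sz)) sprintf(" (sizes %d-%d)", min(sz), max(sz))
              else ""))
})

setMethod("show", "ConnectionGrouping", function(object) {
  cat(sprintf("ConnectionGrouping: %d nodes in %d groups, cost %.4f (seed %d)\n",
              length(object@assignments), length(object@medoids),
              object@cost, object@seed))
})

setMethod("show", "DiscriminativeSet", function(object) {
  cat(sprintf("DiscriminativeSet: %d patterns (limits %d + %d)\n",
              length(object@patterns), object@t1, object@t2))
})

setMethod("show", "KernelBundle", function(object) {
  cat(sprintf("KernelBundle: %d base kernel(s) on %d subjects, mu = [%s]\n",
              length(object@kernels), length(object@y),
              paste(sprintf("%.3f", object@mu), collapse = ", ")))
})
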