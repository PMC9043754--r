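#' Node-level hypergraph metrics
#'
#' Five local topological metrics of a node v in a hypergraph with
#' hyperedge set \eqn{\zeta}: three single-node clustering coefficients
#' (HCC1, HCC2, HCC3), the pair-node clustering coefficient averaged over
#' neighbors (HCCPN), and the mean hypergraph shortest path (SP).
#' \code{N(v)} is the set of nodes sharing some hyperedge with v and
#' \code{S(v)} the set of hyperedges containing v.
#'
#' \itemize{
#'   \item \code{hcc1(v)}: fraction of unordered neighbor pairs \{u, t\}
#'     covered by some hyperedge that excludes v.
#'   \item \code{hcc2(v)}: fraction of neighbor pairs covered together with
#'     v by some hyperedge.
#'   \item \code{hcc3(v)}: extra-overlap of the hyperedges through v,
#'     \code{(sum_e (|e|-1) - |N(v)|) / (|N(v)| (|S(v)|-1))} in the
#'     normalized variant (range [0,1]); the \code{"literal2x"} variant
#'     doubles the numerator.
#'   \item \code{hccpn(v)}: mean over neighbors u of
#'     \code{|S(u) inter S(v)| / sqrt(|S(u)| |S(v)|)} (geometric-mean
#'     denominator; \code{"literal-product"} uses \code{|S(u)| |S(v)|}).
#'   \item \code{shortestPathAvg(v)}: mean over reachable peers of the
#'     minimum number of hyperedges traversed.
#' }
#'
#' Degenerate cases (fewer than two neighbors for HCC1/HCC2, fewer than two
#' incident edges for HCC3, no neighbors for HCCPN, isolated node for SP)
#' return 0 under the default policy, or raise an error when
#' \code{strict = TRUE}.
#'
#' @param H a \linkS4class{Hypernetwork}.
#' @param v node id (1..M).
#' @param variant HCC3 variant, \code{"normalized"} or \code{"literal2x"}.
#' @param denom HCCPN pair denominator, \code{"geometric"} or
#'   \code{"literal-product"}.
#' @param strict raise an error on degenerate nodes instead of returning 0.
#' @return a single numeric value.
#' @name hypermetrics
NULL

# incidence matrix: nodes x edges (logical)
incidenceMatrix <- function(H) {
  E <- length(H@hyperedges)
  B <- matrix(FALSE, H@nNodes, max(E, 0L))
  for (e in seq_len(E)) B[H@hyperedges[[e]]$nodes, e] <- TRUE
  B
}

nodeNeighbors <- function(B, v) {
  ev <- which(B[v, ])
  if (!length(ev)) return(integer())
  setdiff(which(rowSums(B[, ev, drop = FALSE]) > 0), v)
}

degenerate <- function(strict, what, v) {
  if (strict) stop(sprintf("degenerate node %d: %s", v, what))
  0
}

#' @rdname hypermetrics
#' @export
hcc1 <- function(H, v, strict = FALSE) {
  B <- incidenceMatrix(H)
  hcc1Impl(B, v, strict)
}

hcc1Impl <- function(B, v, strict = FALSE) {
  nb <- nodeNeighbors(B, v)
  if (length(nb) < 2L) return(degenerate(strict, "fewer than 2 neighbors", v))
  ex <- which(!B[v, ])                       # edges excluding v
  cov <- if (length(ex)) {
    A <- B[nb, ex, drop = FALSE] + 0
    tcrossprod(A) > 0                        # neighbor pairs co-covered
  } else matrix(FALSE, length(nb), length(nb))
  npairs <- sum(cov[upper.tri(cov)])
  npairs / choose(length(nb), 2L)
}

#' @rdname hypermetrics
#' @export
hcc2 <- function(H, v, strict = FALSE) {
  B <- incidenceMatrix(H)
  hcc2Impl(B, v, strict)
}

hcc2Impl <- function(B, v, strict = FALSE) {
  nb <- nodeNeighbors(B, v)
  if (length(nb) < 2L) return(degenerate(strict, "fewer than 2 neighbors", v))
  inc <- which(B[v, ])                       # edges containing v
  A <- B[nb, inc, drop = FALSE] + 0
  cov <- tcrossprod(A) > 0
  npairs <- sum(cov[upper.tri(cov)])
  npairs / choose(length(nb), 2L)
}

#' @rdname hypermetrics
#' @export
hcc3 <- function(H, v, variant = c("normalized", "literal2x"),
                 strict = FALSE) {
  variant <- match.arg(variant)
  B <- incidenceMatrix(H)
  hcc3Impl(B, v, variant, strict)
}

hcc3Impl <- function(B, v, variant = "normalized", strict = FALSE) {
  inc <- which(B[v, ])
  nb <- nodeNeighbors(B, v)
  if (length(inc) < 2L)
    return(degenerate(strict, "fewer than 2 incident hyperedges", v))
  if (!length(nb)) return(degenerate(strict, "no neighbors", v))
  num <- sum(colSums(B[, inc, drop = FALSE]) - 1L) - length(nb)
  if (variant == "literal2x") num <- 2 * num
  num / (length(nb) * (length(inc) - 1L))
}

#' @rdname hypermetrics
#' @param u second node for the pairwise coefficient.
#' @export
hccpnPair <- function(H, u, v, denom = c("geometric", "literal-product")) {
  denom <- match.arg(denom)
  B <- incidenceMatrix(H)
  hccpnPairImpl(B, u, v, denom)
}

hccpnPairImpl <- function(B, u, v, denom = "geometric") {
  su <- which(B[u, ]); sv <- which(B[v, ])
  if (!length(su) || !length(sv)) return(0)
  shared <- length(intersect(su, sv))
  d <- if (denom == "geometric") sqrt(length(su) * length(sv))
       else length(su) * length(sv)
  shared / d
}

#' @rdname hypermetrics
#' @export
hccpn <- function(H, v, denom = c("geometric", "literal-product"),
                  strict = FALSE) {
  denom <- match.arg(denom)
  B <- incidenceMatrix(H)
  hccpnImpl(B, v, denom, strict)
}

hccpnImpl <- function(B, v, denom = "geometric", strict = FALSE) {
  nb <- nodeNeighbors(B, v)
  if (!length(nb)) return(degenerate(strict, "no neighbors", v))
  mean(vapply(nb, function(u) hccpnPairImpl(B, u, v, denom), 0))
}

# co-membership graph: u ~ v iff they share a hyperedge; the hypergraph
# distance in hyperedge hops equals the unweighted shortest path here
comembershipGraph <- function(H) {
  B <- incidenceMatrix(H)
  A <- (tcrossprod(B + 0) > 0)
  diag(A) <- FALSE
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

#' @rdname hypermetrics
#' @export
shortestPathAvg <- function(H, v, strict = FALSE) {
  g <- comembershipGraph(H)
  shortestPathAvgImpl(g, v, strict, nNodes = H@nNodes)
}

shortestPathAvgImpl <- function(g, v, strict = FALSE, nNodes = NULL) {
  d <- igraph::distances(g, v = v)[1L, ]
  d <- d[-v]
  reach <- is.finite(d)
  if (!any(reach)) {
    if (strict) stop(sprintf("degenerate node %d: isolated", v))
    return(0)
  }
  if (strict && !all(reach))
    stop(sprintf("disconnected hypergraph at node %d", v))
  mean(d[reach])
}

#' Per-subject node metric table
#'
#' Assembles the M x 5 matrix of node metrics, columns
#' \code{HCC1, HCC2, HCC3, HCCPN, SP}, with degenerate cells set to 0 and
#' flagged.
#'
#' @inheritParams hypermetrics
#' @return list with \code{values} (M x 5 matrix) and \code{flags}
#'   (logical M x 5 matrix, TRUE where the degenerate policy fired).
#' @examples
#' H <- new("Hypernetwork", nNodes = 4L, nodeLabels = letters[1:4],
#'          hyperedges = list(list(nodes = 1:3, seed = 1L, lambda1 = 0.1)),
#'          subjectId = "toy")
#' metricTable(H)$values
#' @export
metricTable <- function(H, variant = c("normalized", "literal2x"),
                        denom = c("geometric", "literal-product")) {
  variant <- match.arg(variant)
  denom <- match.arg(denom)
  M <- H@nNodes
  B <- incidenceMatrix(H)
  g <- comembershipGraph(H)
  vals <- matrix(0, M, 5L,
                 dimnames = list(H@nodeLabels,
                                 c("HCC1", "HCC2", "HCC3", "HCCPN", "SP")))
  flags <- matrix(FALSE, M, 5L, dimnames = dimnames(vals))
  dall <- igraph::distances(g)
  for (v in seq_len(M)) {
    nb <- nodeNeighbors(B, v)
    inc <- which(B[v, ])
    if (length(nb) >= 2L) {
      vals[v, 1L] <- hcc1Impl(B, v)
      vals[v, 2L] <- hcc2Impl(B, v)
    } else flags[v, 1:2] <- TRUE
    if (length(inc) >= 2L && length(nb))
      vals[v, 3L] <- hcc3Impl(B, v, variant)
    else flags[v, 3L] <- TRUE
    if (length(nb)) vals[v, 4L] <- hccpnImpl(B, v, denom)
    else flags[v, 4L] <- TRUE
    d <- dall[v, -v]
    if (any(is.finite(d))) vals[v, 5L] <- mean(d[is.finite(d)])
    else flags[v, 5L] <- TRUE
  }
  list(values = vals, flags = flags)
}
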