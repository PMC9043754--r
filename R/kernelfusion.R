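#' Clique expansion of hyperedges
#'
#' Turns a node set or a whole hypernetwork into a labeled simple graph:
#' every hyperedge becomes a clique over its nodes, the graph is the union
#' of those cliques (set semantics, no multi-edges), and each node keeps
#' its global connection id as categorical label, so labels are comparable
#' across subjects.
#'
#' @param x an integer node set (one hyperedge) or a
#'   \linkS4class{Hypernetwork}.
#' @return list with \code{labels} (named integer vector: vertex ->
#'   label) and \code{adj} (list of neighbor positions per vertex).
#' @export
cliqueExpand <- function(x) {
  edgeSets <- if (is(x, "Hypernetwork")) {
    lapply(x@hyperedges, function(e) e$nodes)
  } else {
    list(sort(as.integer(x)))
  }
  verts <- sort(unique(unlist(edgeSets)))
  if (!length(verts)) stop("empty node set")
  pos <- match(verts, verts)
  names(pos) <- verts
  adj <- vector("list", length(verts))
  for (es in edgeSets) {
    p <- match(es, verts)
    for (i in p) adj[[i]] <- union(adj[[i]], setdiff(p, i))
  }
  adj <- lapply(adj, function(a) sort(a %||% integer()))
  list(labels = stats::setNames(as.integer(verts), verts), adj = adj)
}

# WL refinement feature map: counts of node-label strings across
# iterations 0..h. Labels at iteration i+1 are the string
# "<own>|<sorted neighbor labels>", uncompressed, so feature maps are
# globally consistent across graphs and inner products well defined.
wlFeatures <- function(g, h) {
  lab <- as.character(g$labels)
  counts <- table(lab)
  feats <- stats::setNames(as.numeric(counts), paste0("0#", names(counts)))
  if (h >= 1L) {
    for (it in seq_len(h)) {
      newlab <- vapply(seq_along(lab), function(i) {
        nb <- g$adj[[i]]
        paste0(lab[i], "|", paste(sort(lab[nb]), collapse = ","))
      }, "")
      lab <- newlab
      counts <- table(lab)
      feats <- c(feats, stats::setNames(as.numeric(counts),
                                        paste0(it, "#", names(counts))))
    }
  }
  feats
}

# inner product of two sparse named count vectors
dotNamed <- function(f1, f2) {
  common <- intersect(names(f1), names(f2))
  if (!length(common)) return(0)
  sum(f1[common] * f2[common])
}

#' Weisfeiler-Lehman subtree kernel
#'
#' \code{k(G1, G2) = sum_{i=0..h} <c_i(G1), c_i(G2)>} where \code{c_i} are
#' label-count vectors after i WL refinements (each node's label replaced
#' by its label plus the sorted multiset of neighbor labels).
#'
#' @param g1,g2 labeled graphs from \code{\link{cliqueExpand}}.
#' @param h number of WL refinement iterations (default 3).
#' @return numeric kernel value.
#' @examples
#' t1 <- cliqueExpand(c(1, 2, 3))
#' wlKernel(t1, t1, h = 1)
#' @export
wlKernel <- function(g1, g2, h = 3L) {
  stopifnot(h >= 0L)
  dotNamed(wlFeatures(g1, h), wlFeatures(g2, h))
}

# cosine-normalized WL kernel between two labeled graphs
wlSimilarity <- function(g1, g2, h) {
  f1 <- wlFeatures(g1, h); f2 <- wlFeatures(g2, h)
  num <- dotNamed(f1, f2)
  if (num == 0) return(0)
  num / sqrt(sum(f1^2) * sum(f2^2))
}

#' WL isomorphism score of a pattern against a hypernetwork
#'
#' The discriminative pattern (as a clique over its node set) is compared
#' with every hyperedge of the subject's hypernetwork (each a clique over
#' its node set, the subgraphs the hypernetwork is made of) by the
#' cosine-normalized WL subtree kernel; the best match is returned. The
#' score is 1 exactly when some hyperedge has the same node set as the
#' pattern, and grades partial label overlap (penalizing oversized
#' hyperedges) below 1.
#'
#' @param H a \linkS4class{Hypernetwork}.
#' @param nodes integer node set of the pattern.
#' @param h WL iterations.
#' @return similarity in [0, 1].
#' @export
wlMatchScore <- function(H, nodes, h = 3L) {
  # closed form of the cosine-normalized WL kernel for cliques with
  # distinct id labels: iteration 0 contributes |A inter B|; every later
  # iteration contributes |A| iff the node sets coincide (a clique node's
  # refined label encodes its whole clique), so the score is 1 for an
  # exact node-set match and |A inter B| / ((h+1) sqrt(|A| |B|)) otherwise.
  # Equals wlKernel() on the two clique expansions (see tests).
  nodes <- sort(as.integer(nodes))
  a <- length(nodes)
  best <- 0
  for (e in H@hyperedges) {
    b <- length(e$nodes)
    cc <- length(intersect(e$nodes, nodes))
    if (cc == 0L) next
    s <- if (cc == a && b == a) 1 else cc / ((h + 1) * sqrt(a * b))
    if (s > best) best <- s
    if (best >= 1) break
  }
  best
}

#' WL graph-feature vector of a subject
#'
#' Entry i is the WL isomorphism score (\code{\link{wlMatchScore}}) of
#' discriminative pattern i against the subject's hypernetwork: 1 when the
#' pattern is realized exactly as a hyperedge, partial credit when only
#' some of its nodes co-occur. The vector is then L2-normalized (an
#' all-zero vector is left as zero, e.g. for an empty hypernetwork).
#'
#' @param H a \linkS4class{Hypernetwork}.
#' @param dset a \linkS4class{DiscriminativeSet}.
#' @param h WL iterations.
#' @return numeric vector of length \code{length(patterns(dset))}.
#' @export
subjectGraphFeatures <- function(H, dset, h = 3L) {
  pats <- dset@patterns
  if (!length(pats)) stop("discriminative set is empty")
  if (!length(H@hyperedges)) return(numeric(length(pats)))
  v <- vapply(pats, function(p) wlMatchScore(H, p$nodes, h), 0)
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v / nrm else v
}

# scale a symmetric kernel so that the trace over refIdx equals
# length(refIdx) (reference indices default to all subjects)
traceNormalize <- function(K, refIdx = seq_len(nrow(K))) {
  tr <- sum(diag(K)[refIdx])
  if (tr <= 0) return(K)
  K * (length(refIdx) / tr)
}

#' Base kernels for fusion
#'
#' The vector kernel is a Gaussian RBF on z-scored selected local features,
#' \code{exp(-gamma ||x - z||^2)}; the graph kernel is the linear kernel on
#' the L2-normalized WL feature vectors. Both are trace-normalized so the
#' mean diagonal over \code{refIdx} is 1.
#'
#' @param localFeat subjects x d matrix of (already standardized) selected
#'   local features.
#' @param graphFeat subjects x |patterns| matrix of
#'   \code{\link{subjectGraphFeatures}} rows.
#' @param gamma RBF width.
#' @param refIdx indices used for trace normalization (training subjects
#'   under nested cross-validation).
#' @return list with \code{Kvec} and \code{Kgraph}.
#' @export
baseKernels <- function(localFeat, graphFeat, gamma, refIdx = NULL) {
  localFeat <- as.matrix(localFeat); graphFeat <- as.matrix(graphFeat)
  if (nrow(localFeat) != nrow(graphFeat))
    stop("feature matrices must share subject order")
  if (is.null(refIdx)) refIdx <- seq_len(nrow(localFeat))
  D2 <- as.matrix(stats::dist(localFeat))^2
  Kvec <- exp(-gamma * D2)
  Kgraph <- tcrossprod(graphFeat)
  list(Kvec = traceNormalize(Kvec, refIdx),
       Kgraph = traceNormalize(Kgraph, refIdx))
}

#' Closed-form kernel-target alignment weights
#'
#' With \code{b_l = <K_l, y y'>_F} and \code{F_mn = <K_m, K_n>_F}, the
#' alignment-maximizing combination over unit-norm weights is
#' \code{mu = F^{-1} b / ||F^{-1} b||} (pseudo-inverse when F is singular).
#' Components may be negative.
#'
#' By default the kernels (and the target) are centered before the weights
#' are computed: trace-normalized base kernels share a large constant
#' background, and on the raw matrices the closed form resolves that
#' collinearity by giving one kernel a negative weight, which subtracts an
#' informative kernel from the fusion. Centering removes the background
#' and restores interpretable nonneg-leaning weights;
#' \code{centered = FALSE} evaluates the literal uncentered form.
#'
#' @param Klist list of symmetric kernel matrices.
#' @param y numeric label vector in \{-1, +1\}.
#' @param centered center kernels and target before weighting (default
#'   TRUE).
#' @return unit-norm numeric weight vector.
#' @examples
#' y <- c(-1, 1, 1, -1)
#' alignWeights(list(tcrossprod(y)), y)  # single kernel -> mu = 1
#' @export
alignWeights <- function(Klist, y, centered = TRUE) {
  L <- length(Klist)
  stopifnot(L >= 1L)
  n <- length(y)
  if (centered) {
    H <- diag(n) - 1 / n
    Klist <- lapply(Klist, function(K) H %*% K %*% H)
    Ky <- tcrossprod(y - mean(y))
  } else {
    Ky <- tcrossprod(y)
  }
  b <- vapply(Klist, function(K) sum(K * Ky), 0)
  if (all(abs(b) < 1e-14)) stop("uninformative kernels: all alignments zero")
  Fm <- matrix(0, L, L)
  for (i in seq_len(L)) for (j in i:L) {
    Fm[i, j] <- Fm[j, i] <- sum(Klist[[i]] * Klist[[j]])
  }
  mu <- tryCatch(solve(Fm, b), error = function(e) MASS::ginv(Fm) %*% b)
  mu <- drop(mu)
  mu / sqrt(sum(mu^2))
}

#' Combine base kernels with fixed weights
#'
#' @param Klist list of kernel matrices.
#' @param mu unit-norm weights.
#' @param psdShift add \code{eps I} when the combination has a negative
#'   minimum eigenvalue, so downstream solvers receive a valid kernel.
#' @return fused kernel matrix.
#' @export
combineKernels <- function(Klist, mu, psdShift = TRUE) {
  stopifnot(abs(sqrt(sum(mu^2)) - 1) < 1e-6)
  Kf <- Reduce(`+`, Map(function(K, m) m * K, Klist, mu))
  Kf <- (Kf + t(Kf)) / 2
  if (psdShift) {
    ev <- eigen(Kf, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 0) {
      eps <- 1e-8 * max(abs(sum(diag(Kf))) / nrow(Kf), 1)
      Kf <- Kf + diag(abs(min(ev)) + eps, nrow(Kf))
    }
  }
  Kf
}

#' Assemble a kernel bundle
#'
#' Convenience wrapper: alignment weights are fit on \code{refIdx} (the
#' training block under nested cross-validation) and the fused kernel is
#' formed over all subjects.
#'
#' @param Klist list of base kernels over all subjects.
#' @param y full label vector in \{-1, +1\}.
#' @param refIdx subjects used to fit mu (default all).
#' @return a \linkS4class{KernelBundle}.
#' @export
kernelBundle <- function(Klist, y, refIdx = NULL) {
  if (is.null(refIdx)) refIdx <- seq_along(y)
  mu <- alignWeights(lapply(Klist, function(K) K[refIdx, refIdx]),
                     y[refIdx])
  new("KernelBundle", kernels = Klist, y = as.numeric(y), mu = mu,
      fused = combineKernels(Klist, mu))
}
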