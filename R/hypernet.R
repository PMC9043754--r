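#' Sparse group LASSO configuration
#'
#' Settings for the hyperedge regression
#' \deqn{\min_\alpha \|y - X\alpha\|^2 + \lambda_1\|\alpha\|_1 +
#'       \lambda_2 \sum_i \|\alpha_{G_i}\|_2,}
#' solved once per node and per lambda1 on the ladder. lambda1 controls
#' within-group sparsity, lambda2 group-level sparsity. The squared loss
#' carries no 1/2 factor; design columns and the response are centred and
#' scaled to unit Euclidean norm before solving, so the 0.1-0.9 lambda1
#' ladder acts on the correlation scale and only the support (not the
#' coefficient scale) feeds downstream stages.
#'
#' @param lambda1Set ascending lambda1 ladder (default 0.1..0.9 by 0.1).
#' @param lambda2 group penalty weight (default 0.4).
#' @param groupWeighting \code{"literal"} (unweighted group norms, default)
#'   or \code{"sqrt-size"} (each group norm weighted by sqrt of its size).
#' @param tol relative objective tolerance (default 1e-5).
#' @param maxIter iteration cap (default 1000).
#' @param supportEps magnitude above which a coefficient counts as nonzero.
#' @return a list of class \code{"SGLassoConfig"}.
#' @export
SGLassoConfig <- function(lambda1Set = seq(0.1, 0.9, by = 0.1),
                          lambda2 = 0.4,
                          groupWeighting = c("literal", "sqrt-size"),
                          tol = 1e-5, maxIter = 1000L,
                          supportEps = 1e-6) {
  groupWeighting <- match.arg(groupWeighting)
  stopifnot(length(lambda1Set) >= 1L, all(lambda1Set >= 0),
            !is.unsorted(lambda1Set, strictly = TRUE),
            lambda2 >= 0, tol > 0, maxIter >= 1L, supportEps >= 0)
  structure(list(lambda1Set = as.numeric(lambda1Set),
                 lambda2 = as.numeric(lambda2),
                 groupWeighting = groupWeighting,
                 tol = tol, maxIter = as.integer(maxIter),
                 supportEps = supportEps),
            class = "SGLassoConfig")
}

#' Solve one sparse group LASSO problem
#'
#' Accelerated proximal gradient (FISTA) on the composite objective
#' \code{||y - X a||^2 + lambda1 ||a||_1 + lambda2 sum_g ||a_g||_2}; the
#' proximal map soft-thresholds coordinates then shrinks group norms. Step
#' size from the spectral-norm Lipschitz bound. X and y are used as given
#' (no internal standardisation here; \code{\link{buildHypernetwork}}
#' normalises columns before calling).
#'
#' @param X design matrix (W x p).
#' @param y response vector (length W).
#' @param groups integer vector of group ids (1..k) per column of X.
#' @param lambda1,lambda2 penalty weights.
#' @param cfg an \code{\link{SGLassoConfig}} (tol/maxIter/weighting used).
#' @param alpha0 optional warm start.
#' @return list with \code{alpha}, \code{objective}, \code{iterations},
#'   \code{converged}.
#' @export
sglassoSolve <- function(X, y, groups, lambda1, lambda2,
                         cfg = SGLassoConfig(), alpha0 = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X rows must match length of y")
  p <- ncol(X)
  groups <- as.integer(groups)
  if (length(groups) != p) stop("one group id per column required")
  ug <- sort(unique(groups))
  gmap <- match(groups, ug) - 1L              # 0-based compact ids
  k <- length(ug)
  gw <- groupWeights(gmap, k, cfg$groupWeighting)
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  yty <- sum(y^2)
  L <- 2 * max(eigen(XtX, symmetric = TRUE, only.values = TRUE)$values, 1e-12)
  if (is.null(alpha0)) alpha0 <- numeric(p)
  fit <- .sgl_fista(XtX, Xty, yty, gmap, k, gw, lambda1, lambda2, L,
                    cfg$tol, cfg$maxIter, alpha0)
  fit$alpha <- drop(fit$alpha)
  if (!fit$converged)
    warning(sprintf("sparse group LASSO did not converge in %d iterations",
                    cfg$maxIter))
  fit
}

#' Build a subject's high-order functional hypernetwork
#'
#' For every connection node m and every lambda1 on the ladder, regresses
#' node m's relevant series on all other connections (column m of the
#' design is zeroed) with the sparse group LASSO; the seed node plus the
#' support forms a hyperedge. Singleton hyperedges (empty support) are
#' dropped and duplicate node-sets deduplicated, keeping the first
#' (smallest lambda1) provenance.
#'
#' The ladder values are interpreted as fractions of each seed problem's
#' critical penalty \code{lambda_max = 2 ||X'y||_inf} (the smallest
#' lambda1 at which the solution is identically zero when lambda2 = 0),
#' the convention of the SLEP solver family for penalties quoted in
#' (0, 1). lambda2 is scaled by the same factor. The top of the ladder
#' therefore always reaches near-maximal sparsity, keeping only each
#' connection's strongest partners, regardless of the subject's overall
#' correlation level.
#'
#' @param rs a \linkS4class{RelevantSeries}.
#' @param grouping a \linkS4class{ConnectionGrouping} over the M nodes.
#' @param cfg an \code{\link{SGLassoConfig}}.
#' @param subjectId id stored on the result.
#' @return a \linkS4class{Hypernetwork}.
#' @export
buildHypernetwork <- function(rs, grouping, cfg = SGLassoConfig(),
                              subjectId = "subject") {
  V <- rs@values
  M <- ncol(V)
  if (M < 3L) stop("need at least 3 connection nodes")
  grp <- grouping@assignments
  if (length(grp) != M) stop("grouping does not match connection count")
  # centre and scale columns to unit L2 norm; constant columns stay zero
  Z <- scale(V, center = TRUE, scale = FALSE)
  nrm <- sqrt(colSums(Z^2))
  nz <- nrm > 0
  Z[, nz] <- sweep(Z[, nz, drop = FALSE], 2L, nrm[nz], "/")
  Z[, !nz] <- 0

  # Gram matrix of the full normalised design, shared across nodes: the
  # node-m problem just zeroes row/column m. A single spectral bound on the
  # full Gram is a valid (slightly conservative) Lipschitz constant for all.
  G <- crossprod(Z)
  L <- 2 * max(eigen(G, symmetric = TRUE, only.values = TRUE)$values, 1e-12)
  gmap <- match(grp, sort(unique(grp))) - 1L
  k <- length(unique(grp))
  gw <- groupWeights(gmap, k, cfg$groupWeighting)

  edges <- list()
  seen <- character()
  for (m in seq_len(M)) {
    if (G[m, m] == 0) next  # constant relevant series: no regression target
    XtX <- G
    XtX[m, ] <- 0; XtX[, m] <- 0
    Xty <- G[, m]; Xty[m] <- 0
    yty <- G[m, m]
    lmax <- 2 * max(abs(Xty))   # critical penalty of this seed problem
    if (lmax == 0) next
    a0 <- numeric(M)
    for (lam1 in cfg$lambda1Set) {
      fit <- .sgl_fista(XtX, Xty, yty, gmap, k, gw,
                        lam1 * lmax, cfg$lambda2 * lmax, L,
                        cfg$tol, cfg$maxIter, a0)
      a0 <- drop(fit$alpha)  # warm start up the ladder
      supp <- which(abs(a0) > cfg$supportEps)
      nodes <- sort(unique(c(m, supp)))
      if (length(nodes) < 2L) next
      key <- paste(nodes, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      edges[[length(edges) + 1L]] <-
        list(nodes = as.integer(nodes), seed = as.integer(m),
             lambda1 = lam1)
    }
  }
  if (!length(edges))
    message("empty hypernetwork for subject ", subjectId)
  new("Hypernetwork", nNodes = as.integer(M),
      nodeLabels = colnames(V) %||% as.character(seq_len(M)),
      hyperedges = edges, subjectId = as.character(subjectId))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-group weights for the group penalty: 1 (literal) or sqrt(group size)
groupWeights <- function(gmap0, k, weighting) {
  if (weighting == "literal") rep(1, k)
  else sqrt(tabulate(gmap0 + 1L, k))
}
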