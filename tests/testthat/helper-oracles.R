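# Independent brute-force oracles. These re-derive every quantity from the
# definitions with plain loops and are deliberately written without reusing
# any package internals beyond the object containers.

# --- hypergraph metrics ----------------------------------------------------

oracleNeighbors <- function(edgeSets, v) {
  nb <- integer()
  for (e in edgeSets) if (v %in% e) nb <- union(nb, setdiff(e, v))
  sort(nb)
}

oracleHcc1 <- function(edgeSets, v) {
  nb <- oracleNeighbors(edgeSets, v)
  if (length(nb) < 2) return(0)
  cnt <- 0
  pairs <- utils::combn(nb, 2)
  for (p in seq_len(ncol(pairs))) {
    u <- pairs[1, p]; t <- pairs[2, p]
    hit <- FALSE
    for (e in edgeSets) if (u %in% e && t %in% e && !(v %in% e)) hit <- TRUE
    if (hit) cnt <- cnt + 1
  }
  cnt / choose(length(nb), 2)
}

oracleHcc2 <- function(edgeSets, v) {
  nb <- oracleNeighbors(edgeSets, v)
  if (length(nb) < 2) return(0)
  cnt <- 0
  pairs <- utils::combn(nb, 2)
  for (p in seq_len(ncol(pairs))) {
    u <- pairs[1, p]; t <- pairs[2, p]
    hit <- FALSE
    for (e in edgeSets) if (u %in% e && t %in% e && v %in% e) hit <- TRUE
    if (hit) cnt <- cnt + 1
  }
  cnt / choose(length(nb), 2)
}

oracleHcc3 <- function(edgeSets, v, literal2x = FALSE) {
  S <- Filter(function(e) v %in% e, edgeSets)
  nb <- oracleNeighbors(edgeSets, v)
  if (length(S) < 2 || !length(nb)) return(0)
  num <- sum(vapply(S, function(e) length(e) - 1, 0)) - length(nb)
  if (literal2x) num <- 2 * num
  num / (length(nb) * (length(S) - 1))
}

oracleHccpnPair <- function(edgeSets, u, v, product = FALSE) {
  Su <- which(vapply(edgeSets, function(e) u %in% e, TRUE))
  Sv <- which(vapply(edgeSets, function(e) v %in% e, TRUE))
  if (!length(Su) || !length(Sv)) return(0)
  shared <- length(intersect(Su, Sv))
  den <- if (product) length(Su) * length(Sv)
         else sqrt(length(Su) * length(Sv))
  shared / den
}

oracleHccpn <- function(edgeSets, v) {
  nb <- oracleNeighbors(edgeSets, v)
  if (!length(nb)) return(0)
  mean(vapply(nb, function(u) oracleHccpnPair(edgeSets, u, v), 0))
}

# BFS over hyperedge hops
oracleSp <- function(edgeSets, v, nNodes) {
  dist <- rep(Inf, nNodes)
  dist[v] <- 0
  frontier <- v
  while (length(frontier)) {
    nxt <- integer()
    for (u in frontier) {
      for (e in edgeSets) {
        if (u %in% e) {
          for (w in setdiff(e, u)) {
            if (dist[w] > dist[u] + 1) {
              dist[w] <- dist[u] + 1
              nxt <- c(nxt, w)
            }
          }
        }
      }
    }
    frontier <- unique(nxt)
  }
  d <- dist[-v]
  if (!any(is.finite(d))) return(0)
  mean(d[is.finite(d)])
}

# --- WL kernel -------------------------------------------------------------

# dictionary-based WL feature map on an adjacency-matrix graph with integer
# labels; independent of the package's string-based implementation
oracleWlKernel <- function(A1, lab1, A2, lab2, h) {
  relabel <- function(A, lab, dict) {
    newlab <- character(nrow(A))
    for (i in seq_len(nrow(A))) {
      nb <- which(A[i, ] > 0)
      newlab[i] <- paste0(lab[i], ":", paste(sort(lab[nb]), collapse = "."))
    }
    newlab
  }
  k <- 0
  l1 <- as.character(lab1); l2 <- as.character(lab2)
  for (it in 0:h) {
    t1 <- table(l1); t2 <- table(l2)
    common <- intersect(names(t1), names(t2))
    k <- k + sum(as.numeric(t1[common]) * as.numeric(t2[common]))
    if (it < h) {
      l1 <- relabel(A1, l1, NULL)
      l2 <- relabel(A2, l2, NULL)
    }
  }
  k
}

graphToAdjacency <- function(g) {
  n <- length(g$labels)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) A[i, g$adj[[i]]] <- 1
  A
}

# --- sparse group LASSO ----------------------------------------------------

sglObjective <- function(alpha, X, y, groups, lam1, lam2) {
  r <- y - X %*% alpha
  gp <- sum(vapply(unique(groups), function(g)
    sqrt(sum(alpha[groups == g]^2)), 0))
  sum(r^2) + lam1 * sum(abs(alpha)) + lam2 * gp
}

# slow reference: plain (non-accelerated) proximal gradient, many iterations
sglReference <- function(X, y, groups, lam1, lam2, iters = 50000) {
  p <- ncol(X)
  a <- numeric(p)
  L <- 2 * max(eigen(crossprod(X), symmetric = TRUE,
                     only.values = TRUE)$values, 1e-12)
  st <- 1 / L
  for (it in seq_len(iters)) {
    g <- 2 * (crossprod(X, X %*% a - y))
    a <- a - st * g
    a <- sign(a) * pmax(abs(a) - st * lam1, 0)
    for (gr in unique(groups)) {
      idx <- groups == gr
      ng <- sqrt(sum(a[idx]^2))
      a[idx] <- if (ng <= st * lam2) 0 else a[idx] * (1 - st * lam2 / ng)
    }
  }
  a
}

# KKT residual of the sparse group LASSO at alpha (0 if optimal)
sglKktResidual <- function(alpha, X, y, groups, lam1, lam2, eps = 1e-8) {
  grad <- as.numeric(2 * crossprod(X, X %*% alpha - y))
  res <- 0
  for (gr in unique(groups)) {
    idx <- which(groups == gr)
    ag <- alpha[idx]
    ng <- sqrt(sum(ag^2))
    for (jj in seq_along(idx)) {
      j <- idx[jj]
      if (abs(alpha[j]) > eps) {
        v <- grad[j] + lam1 * sign(alpha[j]) + lam2 * ag[jj] / ng
        res <- max(res, abs(v))
      } else if (ng > eps) {
        # zero coordinate in an active group: subgradient of |.| in [-1,1]
        v <- max(0, abs(grad[j]) - lam1)
        res <- max(res, v)
      } else {
        # fully zero group: joint subdifferential condition; a sufficient
        # check is dist(grad_G, lam1-ball_inf) <= lam2
        gg <- grad[idx]
        excess <- pmax(abs(gg) - lam1, 0)
        v <- max(0, sqrt(sum(excess^2)) - lam2)
        res <- max(res, v)
        break
      }
    }
  }
  res
}

# --- selection -------------------------------------------------------------

oracleBhStepUp <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  kmax <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) kmax <- i
  sel <- logical(m)
  if (kmax > 0) sel[o[seq_len(kmax)]] <- TRUE
  sel
}

oracleKsStat <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(abs(vapply(grid, function(g) mean(x <= g) - mean(y <= g), 0)))
}
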