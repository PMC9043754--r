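test_that("clique expansion: triangles, paths, union semantics", {
  g <- cliqueExpand(c(1, 2, 3))
  expect_equal(unname(g$labels), c(1L, 2L, 3L))
  expect_equal(g$adj, list(c(2L, 3L), c(1L, 3L), c(1L, 2L)))
  H <- toyHypernetwork(list(c(1, 2), c(2, 3)), 3)
  gp <- cliqueExpand(H)
  expect_equal(gp$adj, list(2L, c(1L, 3L), 2L))   # path 1-2-3
  Ho <- toyHypernetwork(list(c(1, 2, 3), c(2, 3)), 3)
  expect_equal(cliqueExpand(Ho)$adj,
               list(c(2L, 3L), c(1L, 3L), c(1L, 2L)))  # no multi-edges
})

test_that("WL kernel: documented small cases", {
  t2 <- cliqueExpand(c(1, 2))
  expect_equal(wlKernel(t2, t2, h = 1), 4)      # 2 at i=0 + 2 at i=1
  g1 <- cliqueExpand(c(1, 2, 3))
  g2 <- cliqueExpand(c(7, 8))
  expect_equal(wlKernel(g1, g2, h = 3), 0)      # disjoint alphabets
  expect_equal(wlKernel(g1, g1, h = 0), 3)
})

test_that("WL kernel equals the dictionary-based oracle on random labeled
           graphs with <= 6 nodes", {
  set.seed(7)
  mkGraph <- function() {
    n <- sample(2:6, 1)
    labels <- sample(1:8, n)                    # shared label alphabet
    A <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < 0.5) A[i, j] <- A[j, i] <- 1
    }
    adj <- lapply(seq_len(n), function(i) which(A[i, ] > 0))
    list(g = list(labels = stats::setNames(as.integer(labels),
                                           labels), adj = adj),
         A = A, lab = labels)
  }
  graphs <- lapply(1:12, function(i) mkGraph())
  for (h in c(0, 1, 3)) {
    for (i in 1:12) for (j in i:12) {
      got <- wlKernel(graphs[[i]]$g, graphs[[j]]$g, h)
      want <- oracleWlKernel(graphs[[i]]$A, graphs[[i]]$lab,
                             graphs[[j]]$A, graphs[[j]]$lab, h)
      expect_equal(got, want)
    }
  }
})

test_that("WL Gram matrices are positive semidefinite", {
  set.seed(8)
  graphs <- lapply(1:10, function(i) {
    H <- randomHypernetwork(nNodes = 6, maxEdges = 4)
    cliqueExpand(H)
  })
  for (h in c(1, 3)) {
    K <- outer(seq_along(graphs), seq_along(graphs),
               Vectorize(function(i, j) wlKernel(graphs[[i]], graphs[[j]], h)))
    expect_equal(K, t(K))
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
  }
})

test_that("match score equals the cosine-normalized WL kernel over
           hyperedges (closed form vs literal computation)", {
  set.seed(9)
  for (r in 1:25) {
    H <- randomHypernetwork(nNodes = 7, maxEdges = 5)
    pat <- sort(sample.int(7, sample(2:4, 1)))
    for (h in c(0L, 2L)) {
      lit <- 0
      gp <- cliqueExpand(pat)
      for (e in hyperedges(H)) {
        ge <- cliqueExpand(e$nodes)
        num <- wlKernel(gp, ge, h)
        if (num > 0) {
          lit <- max(lit, num / sqrt(wlKernel(gp, gp, h) *
                                     wlKernel(ge, ge, h)))
        }
      }
      expect_equal(wlMatchScore(H, pat, h), lit)
    }
  }
})

test_that("subject graph features: exact realization scores 1 before
           normalization, absent patterns 0, empty network zero vector", {
  H <- toyHypernetwork(list(c(1, 2), c(3, 4, 5)), 6)
  ds <- new("DiscriminativeSet", patterns = list(
    list(nodes = c(1L, 2L), fqPos = 1, fqNeg = 0, score = 1,
         sourceGroup = "positive"),
    list(nodes = c(5L, 6L), fqPos = 0.5, fqNeg = 0, score = 0.5,
         sourceGroup = "positive")), t1 = 2L, t2 = 2L)
  v <- subjectGraphFeatures(H, ds, h = 0)
  raw <- c(wlMatchScore(H, c(1, 2), 0), wlMatchScore(H, c(5, 6), 0))
  expect_equal(v, raw / sqrt(sum(raw^2)))
  expect_equal(wlMatchScore(H, c(1, 2), 0), 1)
  expect_equal(wlMatchScore(toyHypernetwork(list(c(1, 2)), 6), c(3, 4), 0), 0)
  Hempty <- toyHypernetwork(list(), nNodes = 6)
  expect_equal(subjectGraphFeatures(Hempty, ds), c(0, 0))
  expect_equal(sqrt(sum(subjectGraphFeatures(H, ds, 0)^2)), 1)
})

test_that("base kernels: RBF limits, PSD graph kernel, trace normalization", {
  set.seed(10)
  lf <- matrix(rnorm(12), 6, 2)
  gfm <- matrix(runif(18), 6, 3)
  ks <- baseKernels(lf, gfm, gamma = 1e-12)
  expect_true(all(abs(ks$Kvec - mean(ks$Kvec)) < 1e-6))  # gamma -> 0 limit
  ks2 <- baseKernels(lf, gfm, gamma = 0.5)
  expect_equal(sum(diag(ks2$Kvec)), 6)
  ev <- eigen(ks2$Kgraph, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  expect_error(baseKernels(lf, gfm[1:5, ], 0.5), "subject order")
})

test_that("alignment weights: single kernel, forced orthogonality, and
           global optimality against dense search", {
  y <- c(1, 1, -1, -1)
  expect_equal(alignWeights(list(tcrossprod(y)), y), 1)
  # uncentered closed form on an orthogonal pair
  K1 <- tcrossprod(y)
  K2 <- diag(c(1, -1, 1, -1)) %*% tcrossprod(c(1, -1, 1, -1)) %*%
        diag(c(1, -1, 1, -1))
  K2 <- tcrossprod(c(1, -1, -1, 1))    # orthogonal to yy' in Frobenius
  expect_equal(sum(K1 * K2), 0)
  mu <- alignWeights(list(K1, K2), y, centered = FALSE)
  expect_equal(mu, c(1, 0))
  # optimality over the unit circle on random two-kernel instances
  set.seed(11)
  alignment <- function(K, y) {
    sum(K * tcrossprod(y)) / sqrt(sum(K * K))
  }
  for (r in 1:5) {
    A <- crossprod(matrix(rnorm(36), 6))
    B <- crossprod(matrix(rnorm(36), 6))
    yy <- sample(c(-1, 1), 6, replace = TRUE)
    if (length(unique(yy)) < 2) yy[1] <- -yy[1]
    mu <- alignWeights(list(A, B), yy, centered = FALSE)
    best <- alignment(mu[1] * A + mu[2] * B, yy)
    theta <- runif(10000, 0, 2 * pi)
    for (t in theta) {
      K <- cos(t) * A + sin(t) * B
      expect_lte(alignment(K, yy), abs(best) + 1e-9)
    }
  }
})

test_that("kernel combination: selection, scaling, linearity, PSD shift", {
  set.seed(12)
  K1 <- crossprod(matrix(rnorm(25), 5))
  K2 <- crossprod(matrix(rnorm(25), 5))
  expect_equal(combineKernels(list(K1, K2), c(1, 0)), K1)
  expect_equal(combineKernels(list(K1, K1), c(1, 1) / sqrt(2)),
               sqrt(2) * K1)
  a <- 1 / sqrt(2)
  expect_equal(combineKernels(list(K1, K2), c(a, a)),
               a * K1 + a * K2)
  # negative weight can make the sum indefinite; shift restores PSD
  Kf <- combineKernels(list(K1, K2), c(0.1, -0.995) /
                         sqrt(0.1^2 + 0.995^2))
  ev <- eigen(Kf, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
})

test_that("kernel bundle fits weights on the reference block only", {
  set.seed(13)
  y <- rep(c(1, -1), each = 4)
  K1 <- tcrossprod(y) + diag(8) * 0.01
  K2 <- crossprod(matrix(rnorm(64), 8))
  kb <- kernelBundle(list(K1, K2), y, refIdx = 1:6)
  expect_equal(sqrt(sum(fusionWeights(kb)^2)), 1)
  expect_equal(dim(fusedKernel(kb)), c(8L, 8L))
})
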