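test_that("penalty dominating the gradient at zero yields the zero solution", {
  set.seed(1)
  X <- matrix(rnorm(40), 10)
  y <- rnorm(10)
  lam1 <- 2 * max(abs(crossprod(X, y))) * 1.01
  fit <- sglassoSolve(X, y, groups = rep(1, 4), lambda1 = lam1, lambda2 = 0)
  expect_equal(fit$alpha, numeric(4))
})

test_that("orthogonal response gives the zero solution for any penalties", {
  X <- cbind(c(1, -1, 0, 0), c(0, 0, 1, -1))
  y <- c(1, 1, 1, 1)          # X'y = 0
  fit <- sglassoSolve(X, y, groups = c(1, 2), lambda1 = 0.3, lambda2 = 0.2)
  expect_equal(fit$alpha, numeric(2))
})

test_that("unpenalized solution matches least squares on a tiny instance", {
  set.seed(2)
  X <- matrix(rnorm(10), 5, 2)
  y <- rnorm(5)
  fit <- sglassoSolve(X, y, groups = c(1, 2), lambda1 = 0, lambda2 = 0,
                      cfg = SGLassoConfig(tol = 1e-12, maxIter = 20000L))
  ls <- solve(crossprod(X), crossprod(X, y))
  expect_equal(fit$alpha, as.numeric(ls), tolerance = 1e-5)
})

test_that("solver matches a slow reference and satisfies KKT on random
           instances", {
  skipIters <- 20000
  set.seed(7)
  for (rep in 1:20) {
    W <- 8; p <- 6
    X <- matrix(rnorm(W * p), W)
    y <- rnorm(W)
    groups <- rep(1:2, each = 3)
    lam1 <- runif(1, 0.1, 1.5)
    lam2 <- runif(1, 0.1, 1.5)
    fit <- sglassoSolve(X, y, groups, lam1, lam2,
                        cfg = SGLassoConfig(tol = 1e-12, maxIter = 50000L))
    ref <- sglReference(X, y, groups, lam1, lam2, iters = skipIters)
    objFit <- sglObjective(fit$alpha, X, y, groups, lam1, lam2)
    objRef <- sglObjective(ref, X, y, groups, lam1, lam2)
    expect_lt(objFit, objRef + 1e-4)
    expect_lte(objFit, sglObjective(numeric(p), X, y, groups, lam1, lam2))
    expect_lt(sglKktResidual(fit$alpha, X, y, groups, lam1, lam2), 1e-3)
  }
})

test_that("objective decreases relative to the zero vector", {
  set.seed(10)
  X <- matrix(rnorm(60), 12)
  y <- rnorm(12)
  groups <- c(1, 1, 2, 2, 3)
  fit <- sglassoSolve(X, y, groups, lambda1 = 0.2, lambda2 = 0.2)
  expect_lte(fit$objective,
             sglObjective(numeric(5), X, y, groups, 0.2, 0.2) + 1e-10)
})

test_that("sqrt-size group weighting changes the effective group penalty", {
  set.seed(11)
  X <- matrix(rnorm(48), 12)
  y <- X %*% c(1, 1, 0.2, 0.2) + rnorm(12, sd = 0.1)
  groups <- c(1, 1, 2, 2)
  f1 <- sglassoSolve(X, y, groups, 0.1, 2,
                     cfg = SGLassoConfig(groupWeighting = "literal"))
  f2 <- sglassoSolve(X, y, groups, 0.1, 2,
                     cfg = SGLassoConfig(groupWeighting = "sqrt-size"))
  expect_gte(sum(abs(f1$alpha)), sum(abs(f2$alpha)) - 1e-9)
})

mkRelevant <- function(V, N) {
  new("RelevantSeries", values = V, windowSpec = WindowSpec(2, 1),
      nComponents = as.integer(N))
}

trivialGrouping <- function(M) {
  new("ConnectionGrouping", assignments = seq_len(M),
      medoids = seq_len(M), cost = 0, seed = 1L)
}

test_that("independent white-noise columns at a high-only ladder give a
           (near-)empty hypernetwork", {
  set.seed(12)
  V <- matrix(rnorm(40 * 6, sd = 0.2), 40, 6)
  V <- V / max(abs(V))
  rs <- mkRelevant(V, 4)
  H <- suppressMessages(
    buildHypernetwork(rs, trivialGrouping(6),
                      SGLassoConfig(lambda1Set = 0.9, lambda2 = 0.4)))
  expect_lte(length(hyperedges(H)), 1L)
})

test_that("a duplicated column is linked to its twin at the smallest lambda1", {
  set.seed(13)
  V <- matrix(rnorm(30 * 6, sd = 0.2), 30, 6)
  V[, 2] <- V[, 1]
  V <- V / max(abs(V))
  rs <- mkRelevant(V, 4)
  H <- buildHypernetwork(rs, trivialGrouping(6), SGLassoConfig())
  seeded1 <- Filter(function(e) e$seed == 1L, hyperedges(H))
  expect_true(length(seeded1) >= 1L)
  expect_true(all(vapply(seeded1, function(e) 2L %in% e$nodes, TRUE)))
})

test_that("an enormous ladder value produces no hyperedges", {
  set.seed(14)
  V <- matrix(rnorm(20 * 6, sd = 0.2), 20, 6)
  V <- V / max(abs(V))
  rs <- mkRelevant(V, 4)
  # lambda1 = 1 is the critical ratio: support empty at or above it
  H <- suppressMessages(
    buildHypernetwork(rs, trivialGrouping(6),
                      SGLassoConfig(lambda1Set = 1, lambda2 = 0)))
  expect_length(hyperedges(H), 0L)
})

test_that("hypernetwork structure: seeds in nodes, sizes >= 2, unique sets,
           and edge count non-increasing in lambda1 on average", {
  set.seed(15)
  counts <- matrix(0, 20, 3)
  lams <- c(0.3, 0.6, 0.9)
  for (r in 1:20) {
    V <- matrix(rnorm(30 * 10, sd = 0.3), 30, 10)
    V[, 2] <- V[, 1] + rnorm(30, sd = 0.1)
    V <- V / max(abs(V))
    rs <- mkRelevant(V, 5)
    H <- suppressMessages(buildHypernetwork(rs, trivialGrouping(10),
                                            SGLassoConfig(lambda1Set = lams)))
    keys <- character()
    for (e in hyperedges(H)) {
      expect_true(e$seed %in% e$nodes)
      expect_gte(length(e$nodes), 2L)
      keys <- c(keys, paste(e$nodes, collapse = ","))
      li <- match(e$lambda1, lams)
      counts[r, li] <- counts[r, li] + 1
    }
    expect_false(anyDuplicated(keys) > 0)
  }
  avg <- colMeans(counts)
  expect_true(all(diff(avg) <= 0))
})
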