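test_that("KS statistic matches stats::ks.test and the grid oracle", {
  set.seed(1)
  for (r in 1:20) {
    x <- rnorm(sample(3:12, 1))
    y <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    D <- ksPermTest(x, y, nPerm = 5, seed = 1)$statistic
    expect_equal(D, unname(suppressWarnings(ks.test(x, y)$statistic)))
    expect_equal(D, oracleKsStat(x, y))
  }
})

test_that("identical samples give D = 0 and p = 1; disjoint supports D = 1", {
  x <- c(1, 2, 3)
  out <- ksPermTest(x, x, seed = 1)
  expect_equal(out$statistic, 0)
  expect_equal(out$p.value, 1)
  out2 <- ksPermTest(c(0, 0, 0), c(1, 1, 1), seed = 1)
  expect_equal(out2$statistic, 1)
})

test_that("exact permutation p at n1 = n2 = 3 equals full enumeration", {
  set.seed(2)
  x <- rnorm(3); y <- rnorm(3, 1)
  out <- ksPermTest(x, y, seed = 1)      # 20 splits -> exact branch
  z <- c(x, y)
  splits <- utils::combn(6, 3)
  Dstar <- apply(splits, 2, function(ix) oracleKsStat(z[ix], z[-ix]))
  expect_equal(out$p.value, mean(Dstar >= out$statistic - 1e-12))
})

test_that("sampled permutation p is deterministic given the seed and valid", {
  set.seed(3)
  x <- rnorm(10); y <- rnorm(12, 0.5)
  a <- ksPermTest(x, y, nPerm = 200, seed = 9, exactLimit = 10)
  b <- ksPermTest(x, y, nPerm = 200, seed = 9, exactLimit = 10)
  expect_identical(a, b)
  expect_gte(a$p.value, 1 / 201)
  expect_lte(a$p.value, 1)
})

test_that("BH step-up equals the brute-force oracle on 1000 random vectors", {
  set.seed(4)
  for (r in 1:1000) {
    m <- sample(1:12, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.2), 1)
    expect_identical(bhFdr(p, q), oracleBhStepUp(p, q))
  }
  expect_identical(bhFdr(c(0.01, 0.02, 0.03, 0.5), 0.05),
                   c(TRUE, TRUE, TRUE, FALSE))
  expect_false(any(bhFdr(rep(1, 5), 0.05)))
  expect_true(bhFdr(c(0, 0.9), 0.05)[1])
})

test_that("a perfectly separated column is selected; permutation p-values
           agree with the single-column test", {
  set.seed(5)
  n <- 16
  labels <- rep(c("positive", "negative"), each = n / 2)
  feat <- matrix(rnorm(n * 6), n)
  feat[, 3] <- ifelse(labels == "positive", 5, 0) + rnorm(n, sd = 0.1)
  sel <- selectLocalFeatures(feat, labels, q = 0.05, nPerm = 400, seed = 2)
  expect_true(sel$selected[3])
  expect_equal(sel$statistic[3], 1)
  # constant column gets p = 1
  feat2 <- cbind(feat, 7)
  sel2 <- selectLocalFeatures(feat2, labels, nPerm = 100, seed = 2)
  expect_equal(sel2$p[7], 1)
})

test_that("null selection rate is controlled under label exchangeability", {
  set.seed(6)
  n <- 12
  labels <- rep(c("positive", "negative"), each = 6)
  hits <- 0; cols <- 0
  for (r in 1:30) {
    feat <- matrix(rnorm(n * 10), n)
    sel <- selectLocalFeatures(feat, labels, q = 0.05, nPerm = 200,
                               seed = r, refineFactor = 4L)
    hits <- hits + sum(sel$selected)
    cols <- cols + 10
  }
  # BH at q = 0.05 on null data: false selections should be rare
  expect_lt(hits / cols, 0.05)
})

test_that("subgraph scoring: frequencies, score and source group", {
  Hs <- list(toyHypernetwork(list(c(1, 2), c(2, 3)), 4),
             toyHypernetwork(list(c(1, 2)), 4),
             toyHypernetwork(list(c(3, 4)), 4),
             toyHypernetwork(list(c(2, 3)), 4))
  labels <- c("positive", "positive", "negative", "negative")
  s <- fsfsScore(c(1, 2), Hs, labels)
  expect_equal(s$fqPos, 1)
  expect_equal(s$fqNeg, 0)
  expect_equal(s$score, 1)
  expect_equal(s$sourceGroup, "positive")
  s2 <- fsfsScore(c(1, 4), Hs, labels)    # absent everywhere
  expect_equal(s2$score, 0)
  s3 <- fsfsScore(c(2, 3), Hs, labels)    # fq 0.5 vs 0.5
  expect_equal(s3$score, 0)
  expect_equal(s3$sourceGroup, "positive")  # tie goes to positive
  # subset containment counts super-edges
  s4 <- fsfsScore(c(2, 3), Hs, labels, containment = "subset")
  expect_equal(s4$fqPos, 0.5)
})

test_that("fsfs selection matches hand scoring on a toy cohort and is
           invariant to subject and hyperedge order", {
  mk <- function(sets) toyHypernetwork(sets, 5)
  posNets <- list(mk(list(c(1, 2), c(3, 4, 5))), mk(list(c(1, 2))),
                  mk(list(c(1, 2), c(2, 3))), mk(list(c(2, 3))))
  negNets <- list(mk(list(c(4, 5))), mk(list(c(4, 5), c(2, 3))),
                  mk(list(c(2, 3))), mk(list(c(4, 5))))
  nets <- c(posNets, negNets)
  labels <- rep(c("positive", "negative"), each = 4)
  ds <- fsfsSelect(nets, labels, t1 = 2, t2 = 2, minSupport = 2)
  keys <- vapply(patterns(ds), function(p) paste(p$nodes, collapse = ","), "")
  # hand scoring: {1,2}: 3/4 vs 0 -> 0.75 (pos); {4,5}: 0 vs 3/4 (neg);
  # {2,3}: 2/4 vs 2/4 -> 0 but support 2 (tie to positive); {3,4,5} support 1
  expect_true("1,2" %in% keys)
  expect_true("4,5" %in% keys)
  expect_false("3,4,5" %in% keys)       # below min support
  p12 <- patterns(ds)[[match("1,2", keys)]]
  expect_equal(p12$score, 0.75)
  # order invariance
  perm <- c(5, 3, 7, 1, 8, 2, 6, 4)
  ds2 <- fsfsSelect(nets[perm], labels[perm], t1 = 2, t2 = 2)
  keys2 <- vapply(patterns(ds2), function(p)
    paste(p$nodes, collapse = ","), "")
  expect_setequal(keys, keys2)
})

test_that("t limits are honored and zero limits give an empty set", {
  Hs <- list(toyHypernetwork(list(c(1, 2)), 3),
             toyHypernetwork(list(c(1, 2)), 3),
             toyHypernetwork(list(c(2, 3)), 3),
             toyHypernetwork(list(c(2, 3)), 3))
  labels <- c("positive", "positive", "negative", "negative")
  ds <- fsfsSelect(Hs, labels, t1 = 0, t2 = 0)
  expect_length(patterns(ds), 0L)
  ds1 <- fsfsSelect(Hs, labels, t1 = 1, t2 = 1)
  expect_lte(sum(vapply(patterns(ds1), function(p)
    p$sourceGroup == "positive", TRUE)), 1L)
})
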