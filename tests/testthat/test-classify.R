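test_that("performance metrics reproduce hand-computed rates", {
  # confusion TP=35 FN=3 TN=24 FP=4
  labels <- c(rep("positive", 38), rep("negative", 28))
  pred <- c(rep("positive", 35), rep("negative", 3),
            rep("negative", 24), rep("positive", 4))
  dec <- ifelse(pred == "positive", 1, -1)
  m <- evaluateMetrics(pred, dec, labels)
  expect_equal(100 * m$accuracy, 89.39, tolerance = 0.01)
  expect_equal(100 * m$sensitivity, 92.11, tolerance = 0.01)
  expect_equal(100 * m$specificity, 85.71, tolerance = 0.01)
  expect_equal(100 * m$bac, 88.91, tolerance = 0.01)
  expect_equal(m$bac, (m$sensitivity + m$specificity) / 2)
  expect_equal(m$accuracy,
               (m$confusion["TP"] + m$confusion["TN"]) / 66,
               ignore_attr = TRUE)
})

test_that("perfect predictions give unit rates; constant decisions AUC 0.5", {
  labels <- rep(c("positive", "negative"), 5)
  m <- evaluateMetrics(labels, ifelse(labels == "positive", 2, -2), labels)
  expect_equal(unlist(m[c("accuracy", "sensitivity", "specificity",
                          "bac", "auc")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1,
                 bac = 1, auc = 1))
  m2 <- evaluateMetrics(labels, rep(0, 10), labels)
  expect_equal(m2$auc, 0.5)
  expect_error(evaluateMetrics(rep("positive", 3), 1:3,
                               rep("positive", 3)), "one class")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  labels <- sample(rep(c("positive", "negative"), each = 10))
  dec <- rnorm(20) + (labels == "positive")
  m <- evaluateMetrics(ifelse(dec > 0, "positive", "negative"), dec, labels)
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = labels, predictor = dec, levels = c("negative", "positive"),
    direction = "<")))
  expect_equal(m$auc, as.numeric(ref))
})

test_that("balanced accuracy is the mean of sensitivity and specificity on
           the printed percent scale", {
  expect_equal(balancedAccuracy(93.63, 90.20), 91.915)
  expect_equal(balancedAccuracy(1, 0), 0.5)
})

test_that("LOOCV separates a wide-margin synthetic cohort and runs the
           minimal 2+2 case", {
  set.seed(15)
  n <- 12
  labels <- rep(c("positive", "negative"), each = n / 2)
  # local features with a planted difference; identical hypernetworks so
  # the graph kernel is uninformative but well defined
  feat <- matrix(rnorm(n * 10), n)
  feat[, 1] <- ifelse(labels == "positive", 4, -4) + rnorm(n, sd = 0.2)
  feat[, 2] <- ifelse(labels == "positive", -3, 3) + rnorm(n, sd = 0.2)
  nets <- c(lapply(1:(n / 2), function(i)
              toyHypernetwork(list(c(1, 2), c(2, 3)), 5)),
            lapply(1:(n / 2), function(i)
              toyHypernetwork(list(c(3, 4), c(4, 5)), 5)))
  cfg <- ClassifierConfig(nPerm = 200L, innerFolds = 3L)
  res <- loocvClassify(feat, nets, labels, cfg, repSeed = 5)
  m <- evaluateMetrics(res$pred, res$decision, res$labels)
  expect_gte(m$accuracy, 0.9)
  # minimal smoke case
  labels4 <- c("positive", "positive", "negative", "negative")
  feat4 <- matrix(rnorm(4 * 6), 4)
  nets4 <- lapply(1:4, function(i) toyHypernetwork(list(c(1, 2)), 4))
  cfg4 <- ClassifierConfig(cGrid = c(0.1, 1), gammaGrid = c(0.1, 1),
                           innerFolds = 2L, nPerm = 50L)
  res4 <- loocvClassify(feat4, nets4, labels4, cfg4, repSeed = 1)
  expect_length(res4$pred, 4L)
})

test_that("LOOCV is deterministic under a fixed repetition seed", {
  set.seed(16)
  n <- 8
  labels <- rep(c("positive", "negative"), each = 4)
  feat <- matrix(rnorm(n * 8), n)
  nets <- lapply(1:n, function(i)
    randomHypernetwork(nNodes = 5, maxEdges = 3))
  cfg <- ClassifierConfig(cGrid = c(0.5, 2), gammaGrid = c(0.5, 2),
                          innerFolds = 2L, nPerm = 60L)
  a <- loocvClassify(feat, nets, labels, cfg, repSeed = 3)
  b <- loocvClassify(feat, nets, labels, cfg, repSeed = 3)
  expect_identical(a$pred, b$pred)
  expect_equal(a$decision, b$decision)
  expect_identical(a$chosen, b$chosen)
})

test_that("nested mode ignores the held-out subject's features when
           training (leakage probe)", {
  set.seed(17)
  n <- 8
  labels <- rep(c("positive", "negative"), each = 4)
  feat <- matrix(rnorm(n * 8), n)
  feat[, 1] <- ifelse(labels == "positive", 2, -2)
  nets <- lapply(1:n, function(i)
    toyHypernetwork(list(c(1, 2), c(2, 3)), 4))
  cfg <- ClassifierConfig(cGrid = c(0.5, 2), gammaGrid = c(0.5, 2),
                          innerFolds = 2L, nPerm = 60L)
  base <- loocvClassify(feat, nets, labels, cfg, repSeed = 7)
  # corrupt subject 1's local features wildly: every OTHER subject's
  # held-out prediction pipeline sees the corruption only through its own
  # training set, so subject 2..n outcomes may change; subject 1's own
  # trained model must not (it never sees its own features in training)
  feat2 <- feat
  feat2[1, ] <- feat2[1, ] * 0 + 100
  probe <- loocvClassify(feat2, nets, labels, cfg, repSeed = 7)
  # the model for fold 1 is unchanged => its chosen hyperparameters match
  expect_identical(probe$chosen[1, ], base$chosen[1, ])
  expect_identical(probe$nSelected[1], base$nSelected[1])
})

test_that("repetition protocol: single repetition equals the run, fixed
           seeds are bit-identical, aggregate is the mean", {
  set.seed(18)
  n <- 8
  labels <- rep(c("positive", "negative"), each = 4)
  feat <- matrix(rnorm(n * 8), n)
  feat[, 3] <- ifelse(labels == "positive", 3, -3) + rnorm(n, sd = 0.3)
  nets <- lapply(1:n, function(i)
    toyHypernetwork(list(c(1, 2)), 4))
  cfg <- ClassifierConfig(cGrid = c(0.5, 2), gammaGrid = c(0.5, 2),
                          innerFolds = 2L, nPerm = 60L,
                          repetitions = 3L, baseSeed = 10L)
  runOnce <- function(s) loocvClassify(feat, nets, labels, cfg, repSeed = s)
  prot <- repeatProtocol(runOnce, cfg)
  expect_length(prot$repetitions, 3L)
  expect_equal(prot$seeds, 11:13)
  for (k in c("accuracy", "sensitivity", "specificity", "bac", "auc")) {
    expect_equal(prot$aggregate[[k]],
                 mean(vapply(prot$repetitions, `[[`, 0, k)),
                 tolerance = 1e-12)
  }
  cfg1 <- ClassifierConfig(cGrid = c(0.5, 2), gammaGrid = c(0.5, 2),
                           innerFolds = 2L, nPerm = 60L,
                           repetitions = 1L, baseSeed = 10L)
  p1 <- repeatProtocol(runOnce, cfg1)
  expect_equal(p1$aggregate$accuracy, p1$repetitions[[1]]$accuracy)
  p2 <- repeatProtocol(runOnce, cfg)
  expect_identical(prot$aggregate, p2$aggregate)
})
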