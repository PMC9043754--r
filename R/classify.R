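#' Classifier configuration
#'
#' SVM and cross-validation settings. The (C, gamma) grid spans powers of
#' two over [2^-7, 2^7]; the default uses step 2^2 (8 points per axis), the
#' full 2^1 ladder (15 points) is available via \code{gridStep = 1}. Inner
#' model selection is stratified K-fold (default 5) on the training
#' subjects of each leave-one-out fold; ties are broken toward the smallest
#' C then the smallest gamma.
#'
#' \code{leakageMode = "nested"} (default) refits feature selection,
#' kernels, standardization and fusion weights inside every leave-one-out
#' fold; \code{"global"} performs one global feature selection and
#' standardization on the whole cohort before the outer loop, reproducing
#' the published protocol at the price of selection leakage.
#'
#' @param cGrid,gammaGrid numeric grids (default powers of two).
#' @param gridStep exponent step used when grids are not given.
#' @param innerFolds stratified folds for the inner search (>= 2).
#' @param leakageMode \code{"nested"} or \code{"global"}.
#' @param repetitions repetitions of the whole protocol (default 50).
#' @param baseSeed integer base seed; repetition r uses baseSeed + r.
#' @param q,nPerm local-feature selection settings (FDR level,
#'   permutations).
#' @param t1,t2 discriminative-subgraph limits per side.
#' @param wlIter WL refinement iterations for the pattern match score
#'   (default 0). Patterns and hyperedges are cliques under clique
#'   expansion, so WL refinement adds no structural information there —
#'   a clique node's refined label is determined by the clique's node set
#'   — and deeper iterations only down-weight partial matches relative to
#'   exact ones (by 1/(h+1)). At 0 the score is the label-set cosine.
#' @return list of class \code{"ClassifierConfig"}.
#' @export
ClassifierConfig <- function(cGrid = NULL, gammaGrid = NULL, gridStep = 2L,
                             innerFolds = 5L,
                             leakageMode = c("nested", "global"),
                             repetitions = 50L, baseSeed = 1L,
                             q = 0.05, nPerm = 1000L,
                             t1 = 36L, t2 = 36L, wlIter = 0L) {
  leakageMode <- match.arg(leakageMode)
  if (is.null(cGrid)) cGrid <- 2^seq(-7L, 7L, by = gridStep)
  if (is.null(gammaGrid)) gammaGrid <- 2^seq(-7L, 7L, by = gridStep)
  stopifnot(length(cGrid) >= 1L, length(gammaGrid) >= 1L, innerFolds >= 2L,
            repetitions >= 1L)
  structure(list(cGrid = cGrid, gammaGrid = gammaGrid,
                 innerFolds = as.integer(innerFolds),
                 leakageMode = leakageMode,
                 repetitions = as.integer(repetitions),
                 baseSeed = as.integer(baseSeed),
                 q = q, nPerm = as.integer(nPerm),
                 t1 = as.integer(t1), t2 = as.integer(t2),
                 wlIter = as.integer(wlIter)),
            class = "ClassifierConfig")
}

# stratified fold assignment, deterministic given the RNG state
stratifiedFolds <- function(labels, k) {
  fold <- integer(length(labels))
  for (g in unique(labels)) {
    ix <- which(labels == g)
    fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
  }
  fold
}

# explicit feature embedding Z of a PSD kernel (K = Z Z'): a kernel SVM on
# K is exactly a linear SVM on Z, which lets the C-SVC run through libsvm
kernelEmbedding <- function(K) {
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(ev), length(ev))
}

# fit a linear C-SVC (libsvm) on embedding rows `trainIdx`, predict rows
# `testIdx`; decision values oriented so larger = positive class
svmEmbedPredict <- function(Z, y, trainIdx, testIdx, C,
                            withDecision = TRUE) {
  yf <- factor(y[trainIdx], levels = c("negative", "positive"))
  fit <- e1071::svm(Z[trainIdx, , drop = FALSE], yf, scale = FALSE,
                    type = "C-classification", kernel = "linear", cost = C)
  pr <- stats::predict(fit, Z[testIdx, , drop = FALSE],
                       decision.values = withDecision)
  pred <- as.character(pr)
  if (!withDecision)
    return(list(pred = pred, decision = rep(NA_real_, length(testIdx))))
  dv <- attr(pr, "decision.values")
  dec <- as.numeric(dv[, 1L])
  # libsvm orients the axis toward the first class named in the column
  if (startsWith(colnames(dv)[1L], "negative")) dec <- -dec
  list(pred = pred, decision = dec)
}

# inner stratified K-fold accuracy for one (C, embedded-kernel) setting
innerCvAccuracy <- function(Z, y, folds, C) {
  acc <- 0; n <- 0
  for (f in sort(unique(folds))) {
    te <- which(folds == f); tr <- which(folds != f)
    if (length(unique(y[tr])) < 2L) next
    out <- svmEmbedPredict(Z, y, tr, te, C, withDecision = FALSE)
    acc <- acc + sum(out$pred == y[te]); n <- n + length(te)
  }
  if (n == 0) return(NA_real_)
  acc / n
}

#' Leave-one-out classification of a cohort
#'
#' For each held-out subject, the training stage (local-feature selection,
#' standardization, discriminative-subgraph selection, kernel construction,
#' fusion-weight estimation and the inner stratified K-fold (C, gamma)
#' search) is fit on the remaining subjects only (nested mode); the fitted
#' model then predicts the held-out subject. In global mode the
#' feature selection and standardization are done once on the full cohort.
#'
#' @param localFeat subjects x (5M) local feature matrix
#'   (\code{\link{localFeatureMatrix}}).
#' @param networks list of per-subject \linkS4class{Hypernetwork}.
#' @param labels character vector of \code{"positive"}/\code{"negative"}.
#' @param cfg a \code{\link{ClassifierConfig}}.
#' @param repSeed integer seed for this repetition (inner folds, selection
#'   permutations).
#' @return list with \code{pred}, \code{decision}, \code{labels},
#'   \code{chosen} (per-fold C and gamma), \code{nSelected} (local features
#'   kept per fold), \code{mu} (per-fold fusion weights).
#' @export
loocvClassify <- function(localFeat, networks, labels, cfg = ClassifierConfig(),
                          repSeed = 1L) {
  n <- length(labels)
  stopifnot(nrow(localFeat) == n, length(networks) == n)
  if (n < 4L) stop("need at least 4 subjects")
  if (length(unique(labels)) < 2L) stop("both groups must be present")

  old <- globalenv()$.Random.seed
  set.seed(as.integer(repSeed))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  literal <- cfg$leakageMode == "global"
  if (literal) {
    selGlobal <- selectLocalFeatures(localFeat, labels, q = cfg$q,
                                     nPerm = cfg$nPerm, seed = repSeed)
    keepG <- which(selGlobal$selected)
    XG <- if (length(keepG)) {
      Xs <- scale(localFeat[, keepG, drop = FALSE])
      Xs[is.nan(Xs)] <- 0
      Xs
    } else NULL
    dsetG <- fsfsSelect(networks, labels, t1 = cfg$t1, t2 = cfg$t2)
    gfG <- if (length(dsetG@patterns)) {
      gr <- vapply(networks, subjectGraphFeatures, dset = dsetG,
                   h = cfg$wlIter, numeric(length(dsetG@patterns)))
      if (length(dsetG@patterns) == 1L) matrix(gr, ncol = 1L) else t(gr)
    } else matrix(0, n, 1L)
  }

  pred <- character(n); dec <- numeric(n)
  chosen <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("C", "gamma")))
  nSel <- integer(n); muMat <- matrix(NA_real_, n, 2L)
  wlCache <- new.env(parent = emptyenv())

  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (length(unique(labels[tr])) < 2L) stop("single-class training fold")

    if (!literal) {
      sel <- selectLocalFeatures(localFeat[tr, , drop = FALSE], labels[tr],
                                 q = cfg$q, nPerm = cfg$nPerm,
                                 seed = repSeed + i)
      keep <- which(sel$selected)
      X <- if (length(keep)) {
        mu0 <- colMeans(localFeat[tr, keep, drop = FALSE])
        sd0 <- apply(localFeat[tr, keep, drop = FALSE], 2L, stats::sd)
        sd0[sd0 == 0] <- 1
        sweep(sweep(localFeat[, keep, drop = FALSE], 2L, mu0), 2L,
              sd0, "/")
      } else NULL                       # no surviving local features:
                                        # the vector kernel drops out
      dset <- fsfsSelect(networks[tr], labels[tr],
                         t1 = cfg$t1, t2 = cfg$t2)
      gf <- graphFeatureMatrix(networks, dset, cfg$wlIter, wlCache)
    } else {
      keep <- keepG; X <- XG; dset <- dsetG; gf <- gfG
    }
    nSel[i] <- length(keep)

    y <- labels
    folds <- integer(n)
    folds[tr] <- stratifiedFolds(labels[tr], cfg$innerFolds)

    D2 <- if (!is.null(X)) as.matrix(stats::dist(X))^2 else NULL
    Kgraph <- traceNormalize(tcrossprod(gf), tr)
    ytr <- ifelse(labels[tr] == "positive", 1, -1)

    gammas <- if (!is.null(D2)) sort(cfg$gammaGrid) else NA_real_
    Cs <- sort(cfg$cGrid)
    embeds <- vector("list", length(gammas))
    mus <- vector("list", length(gammas))
    accs <- matrix(NA_real_, length(Cs), length(gammas))
    for (gi in seq_along(gammas)) {
      if (!is.null(D2)) {
        Kvec <- traceNormalize(exp(-gammas[gi] * D2), tr)
        mus[[gi]] <- alignWeights(list(Kvec[tr, tr], Kgraph[tr, tr]), ytr)
        Kf <- combineKernels(list(Kvec, Kgraph), mus[[gi]])
      } else {
        mus[[gi]] <- c(NA_real_, 1)
        Kf <- combineKernels(list(Kgraph), 1)
      }
      embeds[[gi]] <- kernelEmbedding(Kf)
      for (ci in seq_along(Cs)) {
        accs[ci, gi] <- innerCvAccuracy(embeds[[gi]][tr, , drop = FALSE],
                                        y[tr], folds[tr], Cs[ci])
      }
    }
    # best inner accuracy; ties -> smallest C, then smallest gamma
    cand <- which(accs >= max(accs, na.rm = TRUE) - 1e-12, arr.ind = TRUE)
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    ci <- cand[1L, 1L]; gi <- cand[1L, 2L]
    best <- list(C = Cs[ci], gamma = gammas[gi], Z = embeds[[gi]],
                 mu = mus[[gi]])
    chosen[i, ] <- c(best$C, best$gamma)
    muMat[i, ] <- best$mu
    out <- svmEmbedPredict(best$Z, y, tr, i, best$C)
    pred[i] <- out$pred; dec[i] <- out$decision
  }
  list(pred = pred, decision = dec, labels = labels, chosen = chosen,
       nSelected = nSel, mu = muMat)
}

# graph features for all subjects; (subject, pattern) WL values cached
# across leave-one-out folds (patterns recur between folds)
graphFeatureMatrix <- function(networks, dset, h, cache) {
  n <- length(networks)
  if (!length(dset@patterns)) return(matrix(0, n, 1L))
  patKeys <- vapply(dset@patterns, function(p) patternKey(p$nodes), "")
  res <- vapply(seq_len(n), function(s) {
    v <- vapply(seq_along(patKeys), function(i) {
      key <- paste0(s, "#", h, "#", patKeys[i])
      if (is.null(cache[[key]])) {
        cache[[key]] <- wlMatchScore(networks[[s]],
                                     dset@patterns[[i]]$nodes, h)
      }
      cache[[key]]
    }, 0)
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v / nrm else v
  }, numeric(length(patKeys)))
  if (length(patKeys) == 1L) matrix(res, ncol = 1L) else t(res)
}

#' Classification performance metrics
#'
#' Sensitivity is computed with the patient (\code{"positive"}) class as
#' positive: TP/(TP+FN); specificity TN/(TN+FP); balanced accuracy their
#' mean; AUC by the Mann-Whitney ranking of decision values (ties give
#' 0.5 contributions).
#'
#' @param pred predicted labels.
#' @param decision decision values, larger = more positive.
#' @param labels true labels.
#' @return list with \code{accuracy}, \code{sensitivity},
#'   \code{specificity}, \code{bac}, \code{auc} and confusion counts.
#' @examples
#' evaluateMetrics(c("positive", "negative"), c(1, -1),
#'                 c("positive", "negative"))
#' @export
evaluateMetrics <- function(pred, decision, labels) {
  stopifnot(length(pred) == length(labels),
            length(decision) == length(labels))
  if (length(unique(labels)) < 2L)
    stop("undefined rates: only one class present")
  tp <- sum(pred == "positive" & labels == "positive")
  fn <- sum(pred == "negative" & labels == "positive")
  tn <- sum(pred == "negative" & labels == "negative")
  fp <- sum(pred == "positive" & labels == "negative")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  dpos <- decision[labels == "positive"]
  dneg <- decision[labels == "negative"]
  cmp <- outer(dpos, dneg, `-`)
  auc <- mean((cmp > 0) + 0.5 * (cmp == 0))
  list(accuracy = (tp + tn) / length(labels),
       sensitivity = sens, specificity = spec,
       bac = (sens + spec) / 2, auc = auc,
       confusion = c(TP = tp, FN = fn, TN = tn, FP = fp))
}

#' Balanced accuracy
#'
#' Mean of sensitivity and specificity (inputs and result on whatever
#' scale the inputs use, e.g. percent).
#'
#' @param sensitivity,specificity numeric.
#' @export
balancedAccuracy <- function(sensitivity, specificity) {
  (sensitivity + specificity) / 2
}

#' Repetition protocol over clustering seeds
#'
#' Reruns the pipeline \code{repetitions} times; repetition r uses
#' clustering seed \code{baseSeed + r} so the random k-medoids
#' initialization is averaged out. The aggregate report is the mean of the
#' per-repetition metrics.
#'
#' @param runOnce function(seed) returning the per-repetition result of
#'   \code{\link{loocvClassify}}.
#' @param cfg a \code{\link{ClassifierConfig}} (repetitions, baseSeed).
#' @return list with \code{aggregate}, \code{repetitions} (per-repetition
#'   metric lists) and \code{seeds}.
#' @export
repeatProtocol <- function(runOnce, cfg = ClassifierConfig()) {
  seeds <- cfg$baseSeed + seq_len(cfg$repetitions)
  reps <- lapply(seeds, function(s) {
    res <- runOnce(s)
    m <- evaluateMetrics(res$pred, res$decision, res$labels)
    m$seed <- s
    m
  })
  keys <- c("accuracy", "sensitivity", "specificity", "bac", "auc")
  agg <- lapply(keys, function(k2) mean(vapply(reps, `[[`, 0, k2)))
  names(agg) <- keys
  list(aggregate = agg, repetitions = reps, seeds = seeds)
}
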