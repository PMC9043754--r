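# two-sample KS statistic D = sup |ECDF_x - ECDF_y|, computed directly;
# with ties the sup is evaluated only where the pooled sorted value changes
ksStatistic <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  z <- c(x, y)
  o <- order(z)
  ind <- c(rep(1 / n1, n1), rep(-1 / n2, n2))[o]
  cs <- cumsum(ind)
  keep <- c(diff(z[o]) != 0, TRUE)
  max(abs(cs[keep]))
}

#' Two-sample Kolmogorov-Smirnov permutation test
#'
#' The KS statistic with a permutation null: group labels are shuffled and
#' the statistic recomputed. When the number of distinct group splits is at
#' most \code{exactLimit} the null is enumerated exactly (p = fraction of
#' splits with D* >= D); otherwise \code{nPerm} random shuffles are drawn
#' and p = (1 + #\{D* >= D\}) / (1 + nPerm). The asymptotic KS p-value is
#' available via \code{null = "asymptotic"}.
#'
#' @param x,y numeric samples (each length >= 2).
#' @param nPerm number of random permutations.
#' @param seed integer seed for the shuffles.
#' @param null \code{"permutation"} (default) or \code{"asymptotic"}.
#' @param exactLimit enumerate all splits when choose(n1+n2, n1) is below
#'   this bound.
#' @return list with \code{statistic} (D) and \code{p.value}.
#' @examples
#' ksPermTest(rnorm(5), rnorm(5) + 3, nPerm = 200, seed = 1)
#' @export
ksPermTest <- function(x, y, nPerm = 1000L, seed = 1L,
                       null = c("permutation", "asymptotic"),
                       exactLimit = 1e4) {
  null <- match.arg(null)
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs >= 2 values")
  D <- ksStatistic(x, y)
  if (null == "asymptotic") {
    p <- suppressWarnings(stats::ks.test(x, y)$p.value)
    return(list(statistic = D, p.value = p))
  }
  n1 <- length(x); n <- n1 + length(y)
  z <- c(x, y)
  if (choose(n, n1) <= exactLimit) {
    splits <- utils::combn(n, n1)
    Dstar <- apply(splits, 2L, function(ix) ksStatistic(z[ix], z[-ix]))
    p <- mean(Dstar >= D - 1e-12)
  } else {
    old <- globalenv()$.Random.seed
    set.seed(as.integer(seed))
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    Dstar <- vapply(seq_len(nPerm), function(i) {
      ix <- sample.int(n, n1)
      ksStatistic(z[ix], z[-ix])
    }, 0)
    p <- (1 + sum(Dstar >= D - 1e-12)) / (1 + nPerm)
  }
  list(statistic = D, p.value = p)
}

#' Benjamini-Hochberg selection mask
#'
#' Step-up FDR rule at level \code{q}: reject the hypotheses whose sorted
#' rank is at most \code{max\{i : p_(i) <= i q / m\}}.
#'
#' @param p vector of p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return logical vector, TRUE where selected.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.5))
#' @export
bhFdr <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH") <= q
}

#' Select discriminative local metric features
#'
#' Column-wise KS permutation tests between the two groups across all
#' 5 x M local-metric columns jointly, followed by BH-FDR at level
#' \code{q}. Label shuffles are shared across columns (one shuffle per
#' permutation iteration), preserving cross-column dependence. Constant
#' columns get p = 1.
#'
#' Columns whose observed statistic is rarely exceeded in the first pass
#' are re-examined with \code{refineFactor} times more shuffles, so the
#' attainable p-value floor (1/(total permutations + 1)) lies below the
#' Benjamini-Hochberg threshold q/m even for a single strong column;
#' without refinement no column could ever survive FDR control at this
#' sample size.
#'
#' @param feat subjects x (5M) numeric matrix (metric-major column order,
#'   see \code{\link{localFeatureMatrix}}).
#' @param labels character vector, \code{"positive"}/\code{"negative"}.
#' @param q FDR level.
#' @param nPerm permutations for the shared-shuffle null.
#' @param seed integer seed.
#' @param refineFactor extra shuffles (as a multiple of nPerm) for
#'   candidate columns; 0 disables refinement.
#' @return list with \code{p} (per-column p-values), \code{selected}
#'   (logical mask), \code{statistic} (per-column D).
#' @export
selectLocalFeatures <- function(feat, labels, q = 0.05, nPerm = 1000L,
                                seed = 1L, refineFactor = 19L) {
  feat <- as.matrix(feat)
  pos <- labels == "positive"
  if (!any(pos) || all(pos)) stop("both groups must be present")
  n <- nrow(feat); n1 <- sum(pos)
  m <- ncol(feat)

  constant <- apply(feat, 2L, function(col) length(unique(col)) == 1L)
  Dobs <- numeric(m)
  for (j in which(!constant))
    Dobs[j] <- ksStatistic(feat[pos, j], feat[!pos, j])

  old <- globalenv()$.Random.seed
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  # one label shuffle per iteration, applied to every column:
  # Z[i, b] = 1/n1 if subject i lands in the pseudo-positive group else -1/n2
  shuffleMatrix <- function(B) {
    Z <- matrix(0, n, B)
    for (b in seq_len(B)) {
      ix <- sample.int(n, n1)
      zb <- rep(-1 / (n - n1), n)
      zb[ix] <- 1 / n1
      Z[, b] <- zb
    }
    Z
  }
  Lmat <- matrix(0, n, n)                     # cumulative-sum operator
  Lmat[lower.tri(Lmat, diag = TRUE)] <- 1
  countExceed <- function(j, Z) {
    o <- order(feat[, j])
    keep <- which(c(diff(feat[o, j]) != 0, TRUE))  # tie-correct positions
    CS <- abs(Lmat %*% Z[o, , drop = FALSE])  # n x B running ECDF gaps
    Dstar <- do.call(pmax, lapply(keep, function(i) CS[i, ]))
    sum(Dstar >= Dobs[j] - 1e-12)
  }

  Z <- shuffleMatrix(nPerm)
  p <- rep(1, m)
  exceed <- integer(m)
  total <- rep(nPerm, m)
  for (j in which(!constant)) exceed[j] <- countExceed(j, Z)
  if (refineFactor > 0L) {
    cand <- which(!constant & exceed <= 10L)
    if (length(cand)) {
      Z2 <- shuffleMatrix(as.integer(refineFactor) * nPerm)
      for (j in cand) {
        exceed[j] <- exceed[j] + countExceed(j, Z2)
        total[j] <- total[j] + ncol(Z2)
      }
    }
  }
  p[!constant] <- (1 + exceed[!constant]) / (1 + total[!constant])
  list(p = p, selected = bhFdr(p, q), statistic = Dobs)
}

#' Flatten per-subject metric tables into the local feature matrix
#'
#' Metric-major order: all HCC1 columns (nodes 1..M), then all HCC2, HCC3,
#' HCCPN, SP.
#'
#' @param tables list of \code{\link{metricTable}} results (one per
#'   subject).
#' @return subjects x (5M) matrix with auditable column names
#'   \code{<metric>.<node label>}.
#' @export
localFeatureMatrix <- function(tables) {
  rows <- lapply(tables, function(tb) as.vector(tb$values))
  X <- do.call(rbind, rows)
  v1 <- tables[[1L]]$values
  colnames(X) <- paste(rep(colnames(v1), each = nrow(v1)),
                       rep(rownames(v1), times = ncol(v1)), sep = ".")
  X
}

patternKey <- function(nodes) paste(sort(nodes), collapse = ",")

subjectEdgeKeys <- function(H) {
  unique(vapply(H@hyperedges, function(e) patternKey(e$nodes), ""))
}

#' Score one subgraph pattern
#'
#' A pattern is contained in a subject when some hyperedge's node-set
#' equals it exactly (default) or contains it (\code{containment =
#' "subset"}). Frequencies are per-group fractions of containing subjects;
#' the discriminative score is their absolute difference. The source group
#' is the higher-frequency side, ties to positive.
#'
#' @param nodes integer node set of the pattern.
#' @param networks list of \linkS4class{Hypernetwork}.
#' @param labels per-subject group labels.
#' @param containment \code{"exact"} or \code{"subset"}.
#' @return list with \code{nodes}, \code{fqPos}, \code{fqNeg},
#'   \code{score}, \code{sourceGroup}.
#' @export
fsfsScore <- function(nodes, networks, labels,
                      containment = c("exact", "subset")) {
  containment <- match.arg(containment)
  stopifnot(length(nodes) >= 1L)
  nodes <- sort(as.integer(nodes))
  has <- vapply(networks, function(H) {
    if (containment == "exact") patternKey(nodes) %in% subjectEdgeKeys(H)
    else any(vapply(H@hyperedges,
                    function(e) all(nodes %in% e$nodes), TRUE))
  }, TRUE)
  pos <- labels == "positive"
  fqPos <- if (any(pos)) mean(has[pos]) else 0
  fqNeg <- if (any(!pos)) mean(has[!pos]) else 0
  list(nodes = nodes, fqPos = fqPos, fqNeg = fqNeg,
       score = abs(fqPos - fqNeg),
       sourceGroup = if (fqPos >= fqNeg) "positive" else "negative")
}

#' Select discriminative subgraphs by frequency difference
#'
#' Candidate patterns are all distinct hyperedge node-sets across the
#' cohort. Each candidate is scored by \code{\link{fsfsScore}} and assigned
#' to its higher-frequency side; within each side patterns are sorted by
#' score descending (ties: smaller pattern, then lexicographic node order)
#' and the top \code{t1} (positive side) / \code{t2} (negative side) kept.
#'
#' Only frequent patterns are candidates: a pattern must occur in at least
#' \code{minSupport} subjects of its source group. Patterns carried by a
#' single subject act as that subject's fingerprint — a classifier
#' separates the training set perfectly on them and generalizes exactly
#' wrongly — so they are excluded by default.
#'
#' @param networks list of \linkS4class{Hypernetwork}.
#' @param labels per-subject group labels.
#' @param t1,t2 per-side limits (default 36 each).
#' @param containment see \code{\link{fsfsScore}}.
#' @param minSupport minimum number of source-group subjects containing a
#'   candidate pattern (default 2).
#' @return a \linkS4class{DiscriminativeSet}.
#' @export
fsfsSelect <- function(networks, labels, t1 = 36L, t2 = 36L,
                       containment = c("exact", "subset"),
                       minSupport = 2L) {
  containment <- match.arg(containment)
  if (length(unique(labels)) < 2L) stop("cohort must contain both groups")
  pos <- labels == "positive"

  keysBySubject <- lapply(networks, subjectEdgeKeys)
  allKeys <- unique(unlist(keysBySubject))
  if (!length(allKeys))
    return(new("DiscriminativeSet", patterns = list(),
               t1 = as.integer(t1), t2 = as.integer(t2)))
  nodesOf <- lapply(strsplit(allKeys, ","), as.integer)

  if (containment == "exact") {
    inSubject <- vapply(keysBySubject,
                        function(ks) allKeys %in% ks,
                        logical(length(allKeys)))
    inSubject <- matrix(inSubject, nrow = length(allKeys))
    fqPos <- rowMeans(inSubject[, pos, drop = FALSE])
    fqNeg <- rowMeans(inSubject[, !pos, drop = FALSE])
    cand <- lapply(seq_along(allKeys), function(i) {
      list(nodes = nodesOf[[i]], fqPos = fqPos[i], fqNeg = fqNeg[i],
           score = abs(fqPos[i] - fqNeg[i]),
           sourceGroup = if (fqPos[i] >= fqNeg[i]) "positive" else "negative")
    })
  } else {
    cand <- lapply(nodesOf, fsfsScore, networks = networks,
                   labels = labels, containment = containment)
  }

  nPos <- sum(pos); nNeg <- sum(!pos)
  cand <- Filter(function(p) {
    src <- if (p$sourceGroup == "positive") p$fqPos * nPos
           else p$fqNeg * nNeg
    src >= minSupport - 1e-9
  }, cand)

  takeTop <- function(side, tmax) {
    sub <- Filter(function(p) p$sourceGroup == side, cand)
    if (!length(sub) || tmax < 1L) return(list())
    sc <- vapply(sub, function(p) p$score, 0)
    sz <- vapply(sub, function(p) length(p$nodes), 1L)
    lex <- vapply(sub, function(p) paste(sprintf("%06d", p$nodes),
                                         collapse = ","), "")
    ord <- order(-sc, sz, lex)
    sub[ord][seq_len(min(tmax, length(sub)))]
  }
  sel <- c(takeTop("positive", as.integer(t1)),
           takeTop("negative", as.integer(t2)))
  new("DiscriminativeSet", patterns = sel,
      t1 = as.integer(t1), t2 = as.integer(t2))
}
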