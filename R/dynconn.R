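#' Number of sliding windows
#'
#' A series of \code{T} timepoints sliced by windows of length \code{l} and
#' step \code{s} yields \code{W = floor((T - l)/s + 1)} complete windows;
#' a trailing partial window is discarded.
#'
#' @param T total number of timepoints.
#' @param spec a \linkS4class{WindowSpec}.
#' @return integer window count W >= 1.
#' @examples
#' countWindows(248, WindowSpec(60, 1))  # 189
#' @export
countWindows <- function(T, spec) {
  T <- as.integer(T)
  if (spec@length > T)
    stop("invalid window: length ", spec@length, " exceeds series length ", T)
  W <- (T - spec@length) %/% spec@step + 1L
  if (W < 1L) stop("invalid window: no complete window fits")
  W
}

#' Windowed Pearson correlation networks
#'
#' Computes, for each sliding window, the N x N Pearson correlation matrix
#' of the components over that window (a low-order functional network per
#' window).
#'
#' @param ts a \linkS4class{SubjectTimeSeries}.
#' @param spec a \linkS4class{WindowSpec}.
#' @param zeroVarPolicy what to do when a component is constant within a
#'   window: \code{"error"} (default) or \code{"zero"} (substitute r = 0 for
#'   the affected pairs, with a warning).
#' @return list of W symmetric correlation matrices with unit diagonal.
#' @examples
#' sts <- SubjectTimeSeries("s1", "negative", matrix(rnorm(60), 20, 3))
#' length(windowedCorrelations(sts, WindowSpec(10, 5)))
#' @export
windowedCorrelations <- function(ts, spec, zeroVarPolicy = c("error", "zero")) {
  zeroVarPolicy <- match.arg(zeroVarPolicy)
  X <- ts@data
  W <- countWindows(nrow(X), spec)
  l <- spec@length; s <- spec@step
  lapply(seq_len(W), function(w) {
    rows <- (w - 1L) * s + seq_len(l)
    seg <- X[rows, , drop = FALSE]
    sds <- apply(seg, 2L, stats::sd)
    if (any(sds == 0)) {
      bad <- which(sds == 0)
      if (zeroVarPolicy == "error")
        stop(sprintf("degenerate window %d: component(s) %s constant",
                     w, paste(bad, collapse = ", ")))
      warning(sprintf("window %d: component(s) %s constant, r set to 0",
                      w, paste(bad, collapse = ", ")))
      R <- suppressWarnings(stats::cor(seg))
      R[bad, ] <- 0; R[, bad] <- 0
      diag(R) <- 1
      return(R)
    }
    stats::cor(seg)
  })
}

#' Relevant time series of every functional connection
#'
#' Links the windowed correlations of each component pair across windows
#' into one column: entry (w, m) is the Pearson correlation of the pair
#' mapped to connection m over window w. Column order follows
#' \code{\link{connectionIndex}}.
#'
#' @inheritParams windowedCorrelations
#' @return a \linkS4class{RelevantSeries}.
#' @examples
#' sts <- SubjectTimeSeries("s1", "negative", matrix(rnorm(80), 20, 4))
#' rs <- buildRelevantSeries(sts, WindowSpec(10, 2))
#' dim(relValues(rs))  # 6 windows x 6 connections
#' @export
buildRelevantSeries <- function(ts, spec,
                                zeroVarPolicy = c("error", "zero")) {
  zeroVarPolicy <- match.arg(zeroVarPolicy)
  mats <- windowedCorrelations(ts, spec, zeroVarPolicy)
  N <- ncol(ts@data)
  idx <- connectionIndex(N)
  flat <- cbind(idx[, 1L], idx[, 2L])
  vals <- t(vapply(mats, function(R) R[flat], numeric(nrow(idx))))
  colnames(vals) <- connectionLabels(N)
  new("RelevantSeries", values = vals, windowSpec = spec,
      nComponents = as.integer(N))
}
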