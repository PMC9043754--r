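#' Functional-connection indexing
#'
#' A functional connection is an unordered pair (i, j), i < j, of component
#' indices. Connections are numbered 1..M, M = N(N-1)/2, in lexicographic
#' order of (i, j): (1,2), (1,3), ..., (1,N), (2,3), ... This order is fixed
#' across the whole package; every hypernetwork node id refers to it.
#'
#' @param N number of components.
#' @return \code{connectionIndex} returns an M x 2 integer matrix with
#'   columns \code{i}, \code{j}; row m is the pair of connection m.
#' @examples
#' connectionIndex(4)
#' connectionCount(22)   # 231
#' pairToConnection(2, 4, 5)
#' connectionToPair(5, 5)
#' @export
connectionIndex <- function(N) {
  N <- as.integer(N)
  stopifnot(N >= 2L)
  p <- t(utils::combn(N, 2L))
  colnames(p) <- c("i", "j")
  storage.mode(p) <- "integer"
  p
}

#' @rdname connectionIndex
#' @export
connectionCount <- function(N) {
  N <- as.integer(N)
  stopifnot(N >= 2L)
  (N * (N - 1L)) %/% 2L
}

#' @rdname connectionIndex
#' @param i,j component indices, i < j.
#' @export
pairToConnection <- function(i, j, N) {
  N <- as.integer(N)
  stopifnot(i >= 1L, j <= N, i < j)
  # number of pairs preceding block i, plus offset within block
  as.integer((i - 1L) * N - (i * (i - 1L)) %/% 2L + (j - i))
}

#' @rdname connectionIndex
#' @param m connection index in 1..M.
#' @export
connectionToPair <- function(m, N) {
  idx <- connectionIndex(N)
  stopifnot(m >= 1L, m <= nrow(idx))
  idx[m, ]
}

#' @rdname connectionIndex
#' @param componentNames optional component names; defaults to
#'   \code{"IC1".."ICN"}.
#' @export
connectionLabels <- function(N, componentNames = paste0("IC", seq_len(N))) {
  idx <- connectionIndex(N)
  paste0(componentNames[idx[, 1L]], "-", componentNames[idx[, 2L]])
}
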