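#' Synthetic cohort configuration
#'
#' Two-group cohorts of band-limited component signals emulating the
#' statistical structure the hypernetwork construction assumes: every
#' component is band-pass-filtered Gaussian noise (passband 0.01-0.10 Hz at
#' a 2 s sampling interval, 248 volumes by default), and in the positive
#' group the components spanned by a planted connection module additionally
#' receive a shared signal whose coupling strength is modulated by a slow
#' (0.005 Hz) raised sinusoid. The windowed correlations of the planted
#' pairs therefore rise and fall together, which is exactly the
#' co-variation the sparse group LASSO stage is meant to link into
#' hyperedges. The negative group receives no modulation.
#'
#' @param nPos,nNeg subjects per group (default 16 each, about half the
#'   acquisition-scale cohort; sized so that a strongly separated metric
#'   column (two-sample KS statistic near 0.7) can attain a p-value below
#'   the Benjamini-Hochberg threshold q/m of the selection stage, which is
#'   impossible for any effect size with 10 subjects per group).
#' @param N components (default 12; use 22 to emulate acquisition-scale
#'   dimensions).
#' @param T timepoints (default 248).
#' @param tr sampling interval in seconds (default 2).
#' @param passband two frequencies in Hz (default c(0.01, 0.10)).
#' @param plantedPairs two-column matrix of component pairs; their
#'   connections form the planted module (default six disjoint pairs
#'   (1,2), (3,4), ..., (11,12), so that the only structure linking the
#'   module's connections is the shared modulator).
#' @param beta modulation depth in [0, 1] (effect size, default 1): the
#'   instantaneous within-pair correlation is beta * m(t), sweeping 0 to
#'   beta over a modulator cycle, so the default plants full transient
#'   synchronization at the modulator peak; 0 = null cohort.
#' @param modFreq modulator frequency in Hz (default 0.0035, about 1.7
#'   cycles over the default run, slow enough that 120 s windows resolve
#'   the rise and fall without averaging it away).
#' @param seed integer seed.
#' @return list of class \code{"SyntheticConfig"}.
#' @export
SyntheticConfig <- function(nPos = 16L, nNeg = 16L, N = 12L, T = 248L,
                            tr = 2, passband = c(0.01, 0.10),
                            plantedPairs = cbind(seq(1L, 11L, 2L),
                                                 seq(2L, 12L, 2L)),
                            beta = 1,
                            modFreq = 0.0035, seed = 1L) {
  plantedPairs <- matrix(as.integer(plantedPairs), ncol = 2L)
  stopifnot(nPos >= 2L, nNeg >= 2L, N >= 3L, T >= 8L, beta >= 0, beta <= 1,
            length(passband) == 2L, passband[1L] < passband[2L],
            all(plantedPairs >= 1L & plantedPairs <= N),
            all(plantedPairs[, 1L] < plantedPairs[, 2L]),
            nrow(plantedPairs) >= 1L)
  nyquist <- 1 / (2 * tr)
  if (passband[2L] > nyquist)
    stop("passband upper edge exceeds the Nyquist frequency ", nyquist)
  df <- 1 / (T * tr)                       # frequency resolution
  if (floor(passband[2L] / df) < ceiling(passband[1L] / df) ||
      passband[2L] < df)
    stop("passband infeasible: no spectral bin inside [",
         passband[1L], ", ", passband[2L], "] Hz at T = ", T,
         ", interval = ", tr, " s")
  structure(list(nPos = as.integer(nPos), nNeg = as.integer(nNeg),
                 N = as.integer(N), T = as.integer(T), tr = tr,
                 passband = passband, plantedPairs = plantedPairs,
                 beta = beta, modFreq = modFreq, seed = as.integer(seed)),
            class = "SyntheticConfig")
}

# band-pass filter columns of a matrix by zeroing FFT bins outside the band
bandpassColumns <- function(X, tr, passband) {
  T <- nrow(X)
  freqs <- (seq_len(T) - 1) / (T * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)     # two-sided spectrum
  keep <- freqs >= passband[1L] & freqs <= passband[2L]
  apply(X, 2L, function(x) {
    xf <- stats::fft(x)
    xf[!keep] <- 0
    Re(stats::fft(xf, inverse = TRUE)) / T
  })
}

#' Generate a synthetic two-group cohort
#'
#' @param cfg a \code{\link{SyntheticConfig}}.
#' @return list with \code{subjects} (list of
#'   \linkS4class{SubjectTimeSeries}) and \code{truth} (planted connection
#'   ids in the package-wide lexicographic indexing, the per-subject
#'   modulator trace, and the group effect flag).
#' @examples
#' coh <- generateCohort(SyntheticConfig(nPos = 2, nNeg = 2, T = 64))
#' length(coh$subjects)
#' @export
generateCohort <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  old <- globalenv()$.Random.seed
  set.seed(cfg$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  tgrid <- (seq_len(cfg$T) - 1) * cfg$tr
  modulator <- 0.5 * (1 + sin(2 * pi * cfg$modFreq * tgrid))
  pp <- cfg$plantedPairs
  plantedIds <- apply(pp, 1L, function(p)
    pairToConnection(p[1L], p[2L], cfg$N))

  mkSubject <- function(id, group, planted) {
    base <- bandpassColumns(matrix(stats::rnorm(cfg$T * cfg$N),
                                   cfg$T, cfg$N), cfg$tr, cfg$passband)
    base <- scale(base)                     # unit-variance components
    attributes(base)[c("scaled:center", "scaled:scale")] <- NULL
    if (planted && cfg$beta > 0) {
      # variance-preserving time-varying mixture: each planted pair gets
      # its own shared band-limited signal, mixed in with weight
      # w(t) = sqrt(beta * m(t)) so the pair's instantaneous correlation
      # is exactly beta * m(t). All pairs share the modulator m(t): their
      # windowed correlations rise and fall together, which is the
      # co-variation the hypernetwork stage is meant to link into
      # hyperedges.
      w <- sqrt(cfg$beta * modulator)
      for (r in seq_len(nrow(pp))) {
        shared <- drop(bandpassColumns(matrix(stats::rnorm(cfg$T),
                                              ncol = 1L),
                                       cfg$tr, cfg$passband))
        shared <- drop(scale(shared))
        for (comp in pp[r, ]) {
          base[, comp] <- sqrt(1 - w^2) * base[, comp] + w * shared
        }
      }
    }
    SubjectTimeSeries(id, group, base)
  }
  subjects <- c(
    lapply(seq_len(cfg$nPos), function(i)
      mkSubject(sprintf("pos%02d", i), "positive", TRUE)),
    lapply(seq_len(cfg$nNeg), function(i)
      mkSubject(sprintf("neg%02d", i), "negative", FALSE)))

  list(subjects = subjects,
       truth = list(plantedConnections = as.integer(plantedIds),
                    modulator = modulator,
                    groupEffect = cfg$beta > 0,
                    config = cfg))
}

#' Planted-module recovery score
#'
#' Fraction of positive-group subjects whose hypernetwork contains at
#' least one hyperedge that is seeded at a planted connection and contains
#' at least one other planted connection.
#'
#' @param networks list of \linkS4class{Hypernetwork} for the positive
#'   subjects.
#' @param truth the \code{truth} element of \code{\link{generateCohort}}.
#' @return fraction in [0, 1].
#' @export
recoveryScore <- function(networks, truth) {
  stopifnot(length(networks) >= 1L)
  planted <- truth$plantedConnections
  hit <- vapply(networks, function(H) {
    any(vapply(H@hyperedges, function(e) {
      e$seed %in% planted && length(intersect(setdiff(e$nodes, e$seed),
                                              planted)) >= 1L
    }, TRUE))
  }, TRUE)
  mean(hit)
}
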