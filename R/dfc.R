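# Sliding-window dynamic functional connectivity construction.

#' Sliding-window configuration
#'
#' @param window_length window length Lw in time points (default 30).
#' @param step step size s in time points (default 2).
#' @param rescale_to_unit map correlations r in `[-1, 1]` affinely to
#'   `[0, 1]` via `(r + 1) / 2` (default `TRUE`; the VAE decoder is
#'   sigmoid-bounded, so its inputs must live in the unit interval).
#' @return A list with class `"DFCConfig"`.
#' @examples
#' cfg <- dfcConfig()
#' countWindows(137, cfg)
#' @export
dfcConfig <- function(window_length = 30L, step = 2L, rescale_to_unit = TRUE) {
  window_length <- as.integer(window_length)
  step <- as.integer(step)
  if (window_length < 1L) stop("window_length must be positive")
  if (step < 1L || step > window_length)
    stop("step must satisfy 1 <= step <= window_length")
  structure(list(window_length = window_length, step = step,
                 rescale_to_unit = isTRUE(rescale_to_unit)),
            class = "DFCConfig")
}

#' Z-score each ROI time series across time
#'
#' Centers and scales every ROI row to temporal mean 0 and *population*
#' standard deviation 1 (divisor T, not T-1): this is a normalization, not a
#' variance estimate, and the within-window Pearson correlations downstream
#' are invariant to the choice anyway.
#'
#' @param ts a [ROITimeSeries-class] object.
#' @return The same object with normalized `data`.
#' @examples
#' ts <- ROITimeSeries("s", "s1", 0L, rbind(1:3, c(2, 0, 1)), 3)
#' rowMeans(seriesData(zscoreNormalize(ts)))
#' @export
zscoreNormalize <- function(ts) {
  stopifnot(is(ts, "ROITimeSeries"))
  x <- ts@data
  mu <- rowMeans(x)
  xc <- x - mu
  sdev <- sqrt(rowMeans(xc^2))
  bad <- which(sdev == 0)
  if (length(bad))
    stop(sprintf("zero variance in ROI row(s): %s (flat or failed extraction)",
                 paste(bad, collapse = ", ")))
  ts@data <- xc / sdev
  ts
}

#' Number of sliding windows
#'
#' `K = floor((T - Lw) / s) + 1` for a series of T time points, window
#' length Lw and step s; the trailing remainder is dropped.
#'
#' @param n_timepoints total number of time points T.
#' @param cfg a [dfcConfig()] list.
#' @return Integer window count K.
#' @examples
#' countWindows(137, dfcConfig(30, 2))  # 54
#' @export
countWindows <- function(n_timepoints, cfg = dfcConfig()) {
  T <- as.integer(n_timepoints)
  if (T < cfg$window_length)
    stop(sprintf("session too short: T = %d < window_length = %d",
                 T, cfg$window_length))
  as.integer((T - cfg$window_length) %/% cfg$step + 1L)
}

#' Pearson correlation matrix of one window
#'
#' Pairwise Pearson correlation of the rows of an N x Lw window. The result
#' is symmetric with unit diagonal, clamped to `[-1, 1]` against
#' floating-point overshoot. Rows with zero within-window variance get all
#' their off-diagonal correlations set to 0 (with a warning) rather than
#' propagating NaN; globally flat ROIs are already rejected by
#' [zscoreNormalize()].
#'
#' @param window numeric N x Lw matrix.
#' @return N x N correlation matrix.
#' @export
windowPearson <- function(window) {
  n <- nrow(window)
  xc <- window - rowMeans(window)
  ss <- rowSums(xc^2)
  flat <- ss == 0
  denom <- sqrt(ss)
  denom[flat] <- 1  # placeholder; rows zeroed below
  R <- tcrossprod(xc / denom)
  if (any(flat)) {
    warning(sprintf("zero within-window variance in ROI row(s) %s; correlations set to 0",
                    paste(which(flat), collapse = ", ")))
    R[flat, ] <- 0
    R[, flat] <- 0
  }
  R[R > 1] <- 1
  R[R < -1] <- -1
  diag(R) <- 1
  R
}

#' Vectorize the upper triangle of a correlation matrix
#'
#' Extracts the strictly-upper-triangular entries in row-major order over
#' 0-based pairs (i, j), i < j: (0,1), (0,2), ..., (0,N-1), (1,2), ... The
#' result has length D = N(N-1)/2.
#'
#' @param R symmetric N x N matrix with unit diagonal.
#' @param tol asymmetry tolerance (default 1e-8).
#' @return Numeric vector of length N(N-1)/2.
#' @seealso [devectorize()] for the inverse.
#' @export
vectorizeUpper <- function(R, tol = 1e-8) {
  if (nrow(R) != ncol(R)) stop("R must be square")
  if (max(abs(R - t(R))) > tol) stop("R is asymmetric beyond tolerance")
  # t(R)[lower.tri] walks the upper triangle row by row
  t(R)[lower.tri(R)]
}

#' Rebuild a symmetric matrix from its vectorized upper triangle
#'
#' Inverse of [vectorizeUpper()]. Used both for round-tripping correlation
#' matrices (`diagonal = 1`) and for mapping vectorized attribution scores
#' back to an N x N map (`diagonal = 0`).
#'
#' @param v numeric vector of length N(N-1)/2.
#' @param n_rois N.
#' @param diagonal value to place on the diagonal (default 1).
#' @return N x N symmetric matrix.
#' @export
devectorize <- function(v, n_rois, diagonal = 1) {
  n <- as.integer(n_rois)
  if (length(v) != n * (n - 1L) / 2L)
    stop(sprintf("length(v) = %d but N = %d needs %d entries",
                 length(v), n, n * (n - 1L) / 2L))
  R <- matrix(0, n, n)
  R[lower.tri(R)] <- v   # fills column-major = row-major upper triangle
  R <- t(R)
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  diag(R) <- diagonal
  R
}

#' Affinely rescale correlations to the unit interval
#'
#' `(r + 1) / 2`, the minimal invertible map from `[-1, 1]` onto `[0, 1]`,
#' applied before the sigmoid-bounded VAE decoder.
#'
#' @param v numeric vector (or matrix) with entries in `[-1, 1]`.
#' @return Rescaled object of the same shape.
#' @export
rescaleUnit <- function(v) {
  if (any(v < -1 - 1e-12 | v > 1 + 1e-12))
    stop("entries outside [-1, 1]")
  (v + 1) / 2
}

#' Build the vectorized dFC sequence of one session
#'
#' The full sliding-window pipeline: z-score each ROI across time, slide
#' windows of length `Lw` at step `s` (0-based half-open `[start,
#' start + Lw)` with `start = k * s`), compute the Pearson correlation
#' matrix of each window, vectorize its upper triangle, and optionally
#' rescale to `[0, 1]`. Deterministic: identical input gives bit-identical
#' output.
#'
#' @param ts a [ROITimeSeries-class] object.
#' @param cfg a [dfcConfig()] list.
#' @return A [DFCSequence-class] with K = `countWindows(T, cfg)` rows of
#'   D = N(N-1)/2 features.
#' @examples
#' ts <- ROITimeSeries("s", "s1", 0L, matrix(rnorm(5 * 60), 5, 60), 3)
#' dim(dfcVectors(buildDFC(ts, dfcConfig(30, 2))))
#' @export
buildDFC <- function(ts, cfg = dfcConfig()) {
  ts <- zscoreNormalize(ts)
  x <- ts@data
  n <- nrow(x)
  K <- countWindows(ncol(x), cfg)
  D <- n * (n - 1L) / 2L
  starts <- (seq_len(K) - 1L) * cfg$step
  vecs <- matrix(NA_real_, K, D)
  for (k in seq_len(K)) {
    idx <- (starts[k] + 1L):(starts[k] + cfg$window_length)
    vecs[k, ] <- vectorizeUpper(windowPearson(x[, idx, drop = FALSE]))
  }
  if (cfg$rescale_to_unit) vecs <- rescaleUnit(vecs)
  new("DFCSequence",
      subject_id = ts@subject_id, session_id = ts@session_id,
      label = ts@label, vectors = vecs, window_starts = starts,
      n_rois = n, rescaled = cfg$rescale_to_unit)
}

#' Window overlap fraction
#'
#' `(Lw - s) / Lw`; 93.33% for the default Lw = 30, s = 2, conventionally
#' printed as 93%.
#'
#' @param cfg a [dfcConfig()] list.
#' @return Overlap fraction in `[0, 1)`.
#' @export
windowOverlap <- function(cfg = dfcConfig()) {
  (cfg$window_length - cfg$step) / cfg$window_length
}
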