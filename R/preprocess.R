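#' Savitzky-Golay smoothing of spectra
#'
#' Smooths each spectrum independently along the wavelength axis with a
#' Savitzky-Golay local polynomial filter. Output has the same length as the
#' input: the asymmetric edge windows are handled by the filter's polynomial
#' edge rows, so channel indexing downstream is unaffected and polynomials up
#' to `polyorder` pass through exactly.
#'
#' @param x a [SpectralSet-class] or a samples x channels matrix.
#' @param window odd window length in channels (default 11, a common choice
#'   at 4 cm^-1 resolution).
#' @param polyorder polynomial order, must be < `window` (default 2).
#' @return object of the same type with smoothed absorbance.
#' @export
sgFilter <- function(x, window = 11L, polyorder = 2L) {
  if (window %% 2L == 0L) stop("'window' must be odd")
  if (polyorder >= window) stop("'polyorder' must be smaller than 'window'")
  mat <- if (is(x, "SpectralSet")) absorbance(x) else as.matrix(x)
  if (window > ncol(mat)) stop("'window' exceeds the number of channels")
  sm <- t(apply(mat, 1L, signal::sgolayfilt, p = polyorder, n = window))
  dimnames(sm) <- dimnames(mat)
  if (is(x, "SpectralSet")) {
    SummarizedExperiment::assay(x, "absorbance") <- t(sm)
    x
  } else {
    sm
  }
}

#' Assign a random calibration/prediction split
#'
#' Randomly partitions samples into a calibration (training) and prediction
#' (held-out test) set, e.g. the conventional 2:1 split. The calibration
#' count is `round(ratio * n)`; assignment is a seeded uniform shuffle and is
#' fully reproducible.
#'
#' @param x a [SpectralSet-class].
#' @param ratio calibration fraction in (0, 1); default 2/3.
#' @param seed integer seed controlling the shuffle.
#' @return `x` with split labels assigned.
#' @export
splitCalibrationPrediction <- function(x, ratio = 2 / 3, seed = 1L) {
  if (!(ratio > 0 && ratio < 1)) stop("'ratio' must be in (0, 1)")
  n <- ncol(x)
  if (n < 3L) stop("need at least 3 samples to split")
  ncal <- round(ratio * n)
  ncal <- max(1L, min(n - 1L, ncal))
  idx <- withr::with_seed(seed, sample.int(n))
  lab <- rep("prediction", n)
  lab[idx[seq_len(ncal)]] <- "calibration"
  splitLabels(x) <- lab
  x
}

#' Explained-variance summary of a spectral PCA
#'
#' Mean-centres the spectra and returns the proportion of total spectral
#' variance explained by each of the first `k` principal components.
#'
#' @param x a [SpectralSet-class] or samples x channels matrix.
#' @param k number of leading components.
#' @return numeric vector of `k` proportions in `[0, 1]`, non-increasing,
#'   summing to at most 1.
#' @export
pcaSummary <- function(x, k = 3L) {
  mat <- if (is(x, "SpectralSet")) absorbance(x) else as.matrix(x)
  kmax <- min(nrow(mat) - 1L, ncol(mat))
  if (!isWholeNumber(k) || k < 1L || k > kmax) {
    stop("'k' must be an integer in [1, ", kmax, "]")
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  (ev / sum(ev))[seq_len(k)]
}
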