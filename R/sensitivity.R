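#' Estimate per-analyte unit spectra by classical least squares
#'
#' Regresses the absorbance at each channel on the analyte concentration
#' vector with a non-negativity constraint, giving each analyte's estimated
#' absorbance per unit content (its unit spectrum). Because pure-component
#' spectra are usually not measured, this classical-least-squares estimate is
#' the practical route to the sensitivity factors.
#'
#' The plain multi-channel OLS solution is computed in one pass; only
#' channels with negative coefficients are refitted under the constraint
#' (active-set NNLS). Note that an additive baseline shifts the estimates
#' unless an intercept column is included: set `intercept = TRUE` when the
#' spectra carry an uncorrected baseline.
#'
#' @param ds a [SpectralSet-class] (typically the calibration set) or a list
#'   `(absorbance, targets)` of matrices.
#' @param intercept include an unconstrained intercept column (default
#'   FALSE).
#' @return analytes x channels matrix of non-negative unit absorbances.
#' @export
estimateUnitSpectra <- function(ds, intercept = FALSE) {
  if (is(ds, "SpectralSet")) {
    A <- absorbance(ds); C <- targets(ds)
  } else {
    A <- as.matrix(ds$absorbance); C <- as.matrix(ds$targets)
  }
  k <- ncol(C)
  if (qr(scale(C, scale = FALSE))$rank < k) {
    stop("analyte concentrations are collinear; unit spectra unidentifiable")
  }
  D <- if (intercept) cbind(`(intercept)` = 1, C) else C
  ## one-shot OLS across all channels
  B <- qr.coef(qr(D), A)                      # (k[+1]) x channels
  # refit under the constraint only where the OLS violation is material;
  # tiny negatives (rounding on near-exact fits, where the active-set
  # iteration can stall on a zero residual) are clipped instead
  tol <- 1e-8 * max(abs(B), 1e-300)
  neg <- which(apply(B, 2L, function(b) any(b < -tol)))
  for (j in neg) {
    B[, j] <- tryCatch(pracma::lsqnonneg(D, A[, j])$x,
                       error = function(e) pmax(B[, j], 0))
  }
  B[B < 0] <- 0
  S <- if (intercept) B[-1L, , drop = FALSE] else B
  rownames(S) <- colnames(C)
  S
}

#' Sensitivity factors from unit spectra
#'
#' The sensitivity factor of analyte i at a wavelength is its unit-content
#' absorbance divided by the sum of all analytes' unit-content absorbances
#' there: `alpha_i = A_i / sum_i(A_i)`. A large alpha means the analyte
#' dominates the signal at that wavelength (good signal separation).
#' Channels where no analyte absorbs get alpha = 0 for every analyte and are
#' flagged.
#'
#' @param unit_spectra non-negative analytes x channels matrix (e.g. from
#'   [estimateUnitSpectra()]).
#' @return list with `alpha` (analytes x channels, each absorbing channel's
#'   column summing to 1), `unitSpectra`, and `zeroTotal` (logical mask of
#'   non-absorbing channels).
#' @export
sensitivityFactors <- function(unit_spectra) {
  S <- as.matrix(unit_spectra)
  if (any(S < 0)) stop("unit spectra must be non-negative")
  tot <- colSums(S)
  zero <- tot <= 0
  alpha <- sweep(S, 2L, ifelse(zero, 1, tot), `/`)
  alpha[, zero] <- 0
  list(alpha = alpha, unitSpectra = S, zeroTotal = zero)
}

#' Fine-grained pruning of a combination interval by sensitivity factors
#'
#' For each interval of the optimal combination, computes each analyte's
#' mean sensitivity factor over the interval and retains a channel when its
#' factor reaches that mean for at least one target analyte (ties keep, so a
#' perfectly uniform interval is retained whole; an analyte with zero mean
#' sensitivity in the interval does not retain channels). The surviving runs may
#' have varying widths - this is the segmentation that removes wavelengths
#' mistakenly swept in by the equal-width coarse partition.
#'
#' @param combination output of [combineIntervals()].
#' @param profile output of [sensitivityFactors()].
#' @param partition the [partitionSpectrum()] table used upstream.
#' @param wn wavenumber grid (for the result's wavenumbers).
#' @param analytes indices or names of the target analytes (default: all
#'   rows of the profile).
#' @return a [SelectionResult-class] with per-stage provenance.
#' @export
sensitivitySegment <- function(combination, profile, partition, wn,
                               analytes = NULL) {
  if (length(combination$members) == 0L) stop("empty combination")
  alpha <- profile$alpha
  if (is.null(analytes)) analytes <- seq_len(nrow(alpha))
  if (is.character(analytes)) analytes <- match(analytes, rownames(alpha))
  keep <- integer(0)
  means <- list()
  for (m in combination$members) {
    ch <- seq(partition$start[partition$interval == m],
              partition$end[partition$interval == m])
    abar <- rowMeans(alpha[analytes, ch, drop = FALSE])
    means[[as.character(m)]] <- abar
    # a channel survives when some target analyte reaches its interval-mean
    # sensitivity (ties keep); an analyte whose mean is zero never absorbs
    # in the interval and cannot justify keeping anything
    pass <- colSums((alpha[analytes, ch, drop = FALSE] >= abar - 1e-12) &
                      (abar > 0)) > 0L
    keep <- c(keep, ch[pass])
  }
  if (length(keep) == 0L) {
    stop("sensitivity segmentation removed every channel")
  }
  newSelectionResult(keep, wn, "fic-ss", provenance = list(
    combination_members = combination$members,
    combination_channels = combination$channels,
    interval_mean_alpha = means
  ))
}

#' FIC-SS wavelength selection
#'
#' The full two-stage pipeline:
#' 1. full-spectrum screener thresholds (cross-validated per-analyte RMSE
#'    and R-squared on the calibration set);
#' 2. equal-width partition into `p` sub-intervals;
#' 3. local screener per interval, eliminating intervals that beat the
#'    thresholds for no analyte;
#' 4.-5. exhaustive enumeration of the surviving-interval combinations,
#'    keeping the union with minimal aggregate RMSE;
#' 6. per-channel pruning of the optimal combination by sensitivity factors
#'    estimated from the calibration data.
#'
#' Deterministic: the screener uses deterministic CV folds and no RNG.
#'
#' @param ds a [SpectralSet-class] with split assigned.
#' @param p number of equal-width sub-intervals (default 20).
#' @param screener a [plsScreener()] configuration.
#' @param q_cap cap on intervals entering the exhaustive search (default 12).
#' @param analytes target analytes for the segmentation stage (default all).
#' @param intercept passed to [estimateUnitSpectra()] (default TRUE: the
#'   generator and real instruments both leave an additive baseline).
#' @return a [SelectionResult-class]; provenance records thresholds,
#'   interval scores, survivors and the optimal combination.
#' @export
ficssSelect <- function(ds, p = 20L, screener = plsScreener(), q_cap = 12L,
                        analytes = NULL, intercept = TRUE) {
  if (p == nChannels(ds)) {
    warning("p equals the number of channels: interval screening ",
            "degenerates to per-channel screening")
  }
  thr <- globalThresholds(ds, screener)
  part <- partitionSpectrum(nChannels(ds), p)
  scores <- screenIntervals(ds, part, thr, screener)
  comb <- combineIntervals(ds, scores, screener, q_cap)
  S <- estimateUnitSpectra(calibrationSet(ds), intercept = intercept)
  prof <- sensitivityFactors(S)
  res <- sensitivitySegment(comb, prof, part, wavenumbers(ds), analytes)
  res@provenance <- c(res@provenance, list(
    thresholds = thr,
    survivors = scores$interval[scores$survived],
    interval_scores = scores,
    p = p
  ))
  res
}
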