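#' Monte-Carlo uninformative variable elimination (MC-UVE)
#'
#' Augments the spectral matrix with an equal number of tiny random noise
#' variables, repeatedly fits a PLS model on random calibration subsamples,
#' and scores every column by its stability: the mean of its regression
#' coefficient across runs divided by the coefficient's standard deviation.
#' Real channels whose stability does not exceed the noise-column cutoff are
#' eliminated as uninformative. With multiple analytes a channel's
#' reliability is its best absolute stability across analytes, so a channel
#' informative for any analyte is kept.
#'
#' @param ds a [SpectralSet-class] with split assigned.
#' @param n_mc_runs Monte-Carlo subsampling runs (default 500; must be >= 2
#'   for the stability SD to exist).
#' @param frac calibration subsampling fraction per run (default 0.8).
#' @param n_noise number of appended noise variables (default: one per real
#'   channel, doubling the matrix).
#' @param cutoff_quantile quantile of the noise-column reliabilities used as
#'   the cutoff (default 0.99; use 1 for the strict maximum rule).
#' @param maxNcomp PLS component cap (default 10).
#' @param seed RNG seed.
#' @return a [SelectionResult-class]; provenance records the reliability
#'   profile and the cutoff.
#' @export
mcuveSelect <- function(ds, n_mc_runs = 500L, frac = 0.8, n_noise = NULL,
                        cutoff_quantile = 0.99, maxNcomp = 10L, seed = 1L) {
  if (n_mc_runs < 2L) stop("n_mc_runs must be >= 2 (stability needs an SD)")
  cal <- calibrationSet(ds)
  X <- absorbance(cal); Y <- targets(cal)
  n <- nrow(X); p <- ncol(X)
  if (is.null(n_noise)) n_noise <- p
  sds <- pmax(apply(Y, 2L, stats::sd), .Machine$double.eps)
  ## component count chosen by CV on the real channels: with a fixed large
  ## ncomp the subsample models overfit noise columns consistently (the
  ## subsamples overlap), which destroys the stability contrast
  ncomp_cv <- screenerEval(X, Y,
                           plsScreener(maxNcomp = maxNcomp))$ncomp
  run <- withr::with_seed(seed, {
    noise <- matrix(stats::runif(n * n_noise) * 1e-10, n, n_noise)
    Xa <- cbind(X, noise)
    nsub <- max(3L, round(frac * n))
    coef_sum <- matrix(0, p + n_noise, ncol(Y))
    coef_sq <- matrix(0, p + n_noise, ncol(Y))
    ncomp <- min(ncomp_cv, nsub - 1L)
    for (r in seq_len(n_mc_runs)) {
      idx <- sample.int(n, nsub)
      fit <- simpls(Xa[idx, , drop = FALSE], Y[idx, , drop = FALSE], ncomp)
      B <- simplsCoef(fit, fit$ncomp)$B
      coef_sum <- coef_sum + B
      coef_sq <- coef_sq + B^2
    }
    list(mean = coef_sum / n_mc_runs,
         var = pmax(coef_sq / n_mc_runs - (coef_sum / n_mc_runs)^2, 0))
  })
  sd_b <- sqrt(run$var * n_mc_runs / (n_mc_runs - 1L))
  zero_sd <- sd_b == 0
  if (any(zero_sd & run$mean != 0)) {
    warning(sum(zero_sd & run$mean != 0),
            " coefficient(s) with zero variability; stability set to Inf")
  }
  stab <- run$mean / sd_b
  stab[zero_sd & run$mean != 0] <- Inf
  stab[zero_sd & run$mean == 0] <- 0
  ## scale per analyte for comparability, then take the best across analytes
  rel <- apply(abs(stab), 1L, max)
  cutoff <- stats::quantile(rel[(p + 1L):(p + n_noise)], cutoff_quantile,
                            names = FALSE)
  keep <- which(rel[seq_len(p)] > cutoff)
  if (length(keep) == 0L) {
    stop("MC-UVE eliminated every channel; lower 'cutoff_quantile'")
  }
  newSelectionResult(keep, wavenumbers(ds), "mc-uve",
                     provenance = list(
                       reliability = rel[seq_len(p)],
                       noise_cutoff = cutoff,
                       n_mc_runs = n_mc_runs,
                       seed = seed))
}
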