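#' Competitive adaptive reweighted sampling (CARS)
#'
#' Iterative wavelength selection: at each iteration a PLS model is fitted
#' on a Monte-Carlo subsample of the calibration set, channels are ranked by
#' the magnitude of their regression coefficients (scaled per analyte so the
#' responses contribute comparably, then summed), an exponentially
#' decreasing function (EDF) forces the retained count down from all
#' channels to two, and adaptive reweighted sampling stochastically thins
#' the survivors in proportion to their weights. The iteration subset with
#' the smallest cross-validated aggregate RMSE is returned.
#'
#' @param ds a [SpectralSet-class] with split assigned.
#' @param n_iterations number of sampling runs / EDF steps (default 100).
#' @param mc_frac fraction of calibration samples drawn per iteration
#'   (default 0.8).
#' @param folds CV folds for per-iteration subset scoring (default 5).
#' @param maxNcomp PLS component cap (default 10).
#' @param seed RNG seed; the whole trajectory is reproducible.
#' @return a [SelectionResult-class]; provenance records the EDF retention
#'   counts and the per-iteration CV RMSE path.
#' @export
carsSelect <- function(ds, n_iterations = 100L, mc_frac = 0.8,
                       folds = 5L, maxNcomp = 10L, seed = 1L) {
  cal <- calibrationSet(ds)
  X <- absorbance(cal); Y <- targets(cal)
  n <- nrow(X); p <- ncol(X)
  if (p < 3L) stop("too few channels for CARS")
  sds <- pmax(apply(Y, 2L, stats::sd), .Machine$double.eps)
  ## EDF through (1, p) and (n_iterations, 2)
  kk <- log(p / 2) / (n_iterations - 1L)
  edf_counts <- pmax(2L, pmin(p, round(p * exp(-kk * (seq_len(n_iterations) - 1L)))))
  screener <- plsScreener(folds = folds, maxNcomp = maxNcomp)
  subsets <- vector("list", n_iterations)
  cv_rmse <- rep(NA_real_, n_iterations)
  seeds <- childSeeds(seed, n_iterations)
  retained <- seq_len(p)
  for (i in seq_len(n_iterations)) {
    mc <- withr::with_seed(seeds[i], sample.int(n, max(2L, round(mc_frac * n))))
    ncomp_i <- min(maxNcomp, length(mc) - 1L, length(retained))
    fit <- simpls(X[mc, retained, drop = FALSE], Y[mc, , drop = FALSE], ncomp_i)
    B <- simplsCoef(fit, fit$ncomp)$B
    w <- rowSums(abs(sweep(B, 2L, sds, `/`)))
    keep_n <- min(edf_counts[i], length(retained))
    ord <- order(w, decreasing = TRUE)
    retained <- retained[ord[seq_len(keep_n)]]
    w <- w[ord[seq_len(keep_n)]]
    if (any(w > 0) && length(retained) > 2L) {
      draw <- withr::with_seed(seeds[i] + 1L, sample(
        seq_along(retained), size = keep_n, replace = TRUE,
        prob = w / sum(w)))
      retained <- sort(unique(retained[draw]))
    } else {
      retained <- sort(retained)
    }
    subsets[[i]] <- retained
    ev <- screenerEval(X[, retained, drop = FALSE], Y, screener)
    cv_rmse[i] <- ev$aggregate
  }
  best <- which.min(cv_rmse)
  newSelectionResult(subsets[[best]], wavenumbers(ds), "cars",
                     provenance = list(
                       edf_counts = edf_counts,
                       cv_rmse = cv_rmse,
                       best_iteration = best,
                       seed = seed))
}
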