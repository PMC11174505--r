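#' Fit a calibration model on selected channels and evaluate both phases
#'
#' Convenience wrapper used by the benchmark: fits PLS or ELM on the
#' calibration samples (optionally restricted to a channel subset) and
#' reports RMSEC/Rc2 and RMSEP/Rp2/RPD per analyte.
#'
#' Because a single random-weight ELM draw is unstable, the ELM branch
#' follows the repeated-initialisation protocol: when `grid` has more than
#' one candidate, the hidden-node count is chosen by 5-fold cross-validated
#' committee RMSE on the calibration set, and the reported model averages
#' the predictions of `repeats` networks with derived seeds. Set
#' `repeats = 1` and a single-value `grid` for one bare network.
#'
#' @param ds a [SpectralSet-class] with split assigned.
#' @param channels channel subset (default NULL = full spectrum).
#' @param model `"elm"` or `"pls"`.
#' @param grid candidate hidden-node counts (default `c(10, 14, 20, 26)`).
#' @param repeats ELM committee size (default 10).
#' @param seed master seed for the ELM committee.
#' @param maxNcomp PLS component cap when `model = "pls"`.
#' @return data.frame with one row per analyte and phase.
#' @export
trainEvaluate <- function(ds, channels = NULL, model = c("elm", "pls"),
                          grid = c(10L, 14L, 20L, 26L), repeats = 10L,
                          seed = 1L, maxNcomp = 15L) {
  model <- match.arg(model)
  if (!is.null(channels)) ds <- selectChannels(ds, channels)
  cal <- calibrationSet(ds); pred <- predictionSet(ds)
  Xc <- absorbance(cal); Yc <- targets(cal)
  Xp <- absorbance(pred); Yp <- targets(pred)
  if (model == "elm") {
    seeds <- childSeeds(seed, max(repeats, 5L))
    l <- if (length(grid) > 1L) {
      elmPickNodes(Xc, Yc, grid, seeds[seq_len(min(5L, repeats))])
    } else {
      grid[1L]
    }
    fits <- lapply(seeds[seq_len(repeats)], function(s)
      elmFit(Xc, Yc, l = l, seed = s))
    Pc <- Reduce(`+`, lapply(fits, function(m) elmPredict(m, Xc))) / repeats
    Pp <- Reduce(`+`, lapply(fits, function(m) elmPredict(m, Xp))) / repeats
  } else {
    fit <- plsFit(Xc, Yc, maxNcomp = maxNcomp)
    Pc <- plsPredict(fit, Xc); Pp <- plsPredict(fit, Xp)
  }
  rbind(evaluationReport(Yc, Pc, "calibration"),
        evaluationReport(Yp, Pp, "prediction"))
}

## Hidden-node count minimising the 5-fold CV scaled RMSE of a small
## committee (variance reduction keeps the choice stable across seeds).
elmPickNodes <- function(X, Y, grid, seeds, folds = 5L) {
  fid <- cvFolds(nrow(X), folds)
  sds <- pmax(apply(Y, 2L, stats::sd), .Machine$double.eps)
  cvl <- vapply(grid, function(l) {
    P <- matrix(0, nrow(X), ncol(Y))
    for (s in seeds) {
      Pi <- matrix(NA_real_, nrow(X), ncol(Y))
      for (f in unique(fid)) {
        tr <- fid != f
        m <- elmFit(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], l, seed = s)
        Pi[!tr, ] <- elmPredict(m, X[!tr, , drop = FALSE])
      }
      P <- P + Pi
    }
    scaledRmse(Y, P / length(seeds), sds)
  }, numeric(1))
  grid[which.min(cvl)]
}

#' Benchmark full-spectrum and selector-based models
#'
#' Mirrors the standard comparison protocol: full-spectrum PLS and ELM, and
#' an ELM on the channels chosen by each requested wavelength selector.
#' Output is one table with the selection statistics (NFW/NWI/AWIW) and the
#' calibration/prediction figures of merit per analyte.
#'
#' @param ds a [SpectralSet-class] with split assigned.
#' @param selectors subset of `c("fic-ss", "cars", "mc-uve", "spa")`.
#' @param grid,repeats ELM committee settings (see [trainEvaluate()]).
#' @param seed seed for the stochastic stages (ELM weights, CARS, MC-UVE).
#' @param p,q_cap FIC-SS partition size and combination cap.
#' @param mcuve_runs MC-UVE Monte-Carlo runs (default 500).
#' @param screener shared [plsScreener()] configuration.
#' @return list with `table` (data.frame shaped like the usual comparison
#'   tables) and `selections` (named list of [SelectionResult-class]).
#' @export
runBenchmark <- function(ds, selectors = c("fic-ss", "cars", "mc-uve", "spa"),
                         grid = c(10L, 14L, 20L, 26L), repeats = 10L,
                         seed = 1L, p = 20L, q_cap = 12L,
                         mcuve_runs = 500L, screener = plsScreener()) {
  selectors <- match.arg(selectors, several.ok = TRUE)
  rows <- list()
  addRows <- function(model_label, rep, stats = NULL) {
    rep$model <- model_label
    rep$nfw <- if (is.null(stats)) nChannels(ds) else stats$nfw
    rep$nwi <- if (is.null(stats)) 1L else stats$nwi
    rep$awiw <- if (is.null(stats)) nChannels(ds) else stats$awiw
    rows[[length(rows) + 1L]] <<- rep
  }
  addRows("PLS", trainEvaluate(ds, model = "pls"))
  addRows("ELM", trainEvaluate(ds, model = "elm", grid = grid,
                               repeats = repeats, seed = seed))
  selections <- list()
  for (s in selectors) {
    res <- switch(s,
      "fic-ss" = ficssSelect(ds, p = p, screener = screener, q_cap = q_cap),
      "cars" = carsSelect(ds, seed = seed),
      "mc-uve" = mcuveSelect(ds, n_mc_runs = mcuve_runs, seed = seed),
      "spa" = spaSelect(ds))
    selections[[s]] <- res
    addRows(paste0(toupper(s), "-ELM"),
            trainEvaluate(ds, channels = selectedChannels(res),
                          model = "elm", grid = grid, repeats = repeats,
                          seed = seed),
            res@stats)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[, c("model", "analyte", "phase", "n", "nfw", "nwi", "awiw",
                 "rmse", "r2", "rpd")]
  list(table = tab, selections = selections)
}
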