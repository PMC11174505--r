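#' Partition the wavelength axis into equal-width sub-intervals
#'
#' Divides `n_channels` contiguous channels into `p` intervals whose widths
#' differ by at most one channel; remainder channels are given one each to
#' the leading intervals.
#'
#' @param n_channels grid size.
#' @param p number of sub-intervals.
#' @return data.frame with columns `interval`, `start`, `end` (1-based,
#'   inclusive) and `width`.
#' @examples
#' partitionSpectrum(10, 3)  # widths 4, 3, 3
#' @export
partitionSpectrum <- function(n_channels, p) {
  if (!isWholeNumber(p) || p < 1L || p > n_channels) {
    stop("'p' must be an integer in [1, n_channels]")
  }
  base <- n_channels %/% p
  widths <- rep(base, p) + c(rep(1L, n_channels %% p),
                             rep(0L, p - n_channels %% p))
  end <- cumsum(widths)
  data.frame(interval = seq_len(p), start = end - widths + 1L,
             end = end, width = widths)
}

intervalChannels <- function(partition, ids) {
  unlist(lapply(ids, function(i) {
    seq(partition$start[i], partition$end[i])
  }), use.names = FALSE)
}

#' PLS screener configuration
#'
#' The screener is the cheap deterministic model used by the coarse FIC
#' stages to score intervals and interval combinations: a PLS2 model whose
#' component count is chosen by deterministic k-fold cross-validation on the
#' calibration set (the held-out prediction set is never touched).
#'
#' @param folds CV folds (default 5).
#' @param maxNcomp cap on PLS components (default 10).
#' @return a screener configuration list.
#' @export
plsScreener <- function(folds = 5L, maxNcomp = 10L) {
  structure(list(folds = as.integer(folds), maxNcomp = as.integer(maxNcomp)),
            class = "plsScreener")
}

## Cross-validated screener evaluation on one channel subset: pooled
## out-of-fold predictions at the component count minimising the aggregate
## scaled RMSE. Returns per-analyte CV RMSE/R2 and the aggregate, plus the
## calibration-fit (RMSEC/Rc2) statistics at the same component count --
## interval screening compares local fit against the global CV thresholds.
screenerEval <- function(X, Y, screener, fit = FALSE) {
  sds <- pmax(apply(Y, 2L, stats::sd), .Machine$double.eps)
  preds <- plsCvPredictions(X, Y, screener$maxNcomp, screener$folds)
  agg <- apply(preds, 3L, function(P) scaledRmse(Y, P, sds))
  best <- which.min(agg)
  P <- preds[, , best, drop = FALSE][, , 1L]
  out <- list(
    rmse = vapply(seq_len(ncol(Y)), function(j) rmse(Y[, j], P[, j]),
                  numeric(1)),
    r2 = vapply(seq_len(ncol(Y)), function(j) rSquared(Y[, j], P[, j]),
                numeric(1)),
    aggregate = agg[best], ncomp = best
  )
  if (fit) {
    m <- plsFit(X, Y, ncomp = best)
    Pf <- plsPredict(m, X)
    out$rmse_fit <- vapply(seq_len(ncol(Y)),
                           function(j) rmse(Y[, j], Pf[, j]), numeric(1))
    out$r2_fit <- vapply(seq_len(ncol(Y)),
                         function(j) rSquared(Y[, j], Pf[, j]), numeric(1))
  }
  out
}

#' Full-spectrum screening thresholds
#'
#' Fits the screener on the full spectrum of the calibration set and returns
#' the per-analyte cross-validated RMSE and R-squared that serve as the
#' interval survival thresholds.
#'
#' @param ds a [SpectralSet-class] with split assigned.
#' @param screener a [plsScreener()] configuration.
#' @return data.frame with columns `analyte`, `rmse`, `r2`.
#' @export
globalThresholds <- function(ds, screener = plsScreener()) {
  cal <- calibrationSet(ds)
  ev <- screenerEval(absorbance(cal), targets(cal), screener)
  data.frame(analyte = analyteNames(ds), rmse = ev$rmse, r2 = ev$r2)
}

#' Score and screen spectral sub-intervals
#'
#' Fits a local screener model on each sub-interval of the calibration set.
#' An interval survives when, for at least one analyte, its local
#' calibration-set RMSEC is at most the global (cross-validated) RMSE AND
#' its local Rc-squared is at least the global R-squared (both comparisons
#' inclusive, so boundary ties survive). The local statistics are the
#' calibration fit at the interval's own CV-chosen component count: an
#' interval containing real structure for an analyte fits it tightly, while
#' a pure-noise interval's CV picks very few components and its fit stays
#' poor, so the contrast separates informative from junk intervals without
#' turning survival into a coin flip between two equally honest CV
#' estimates.
#'
#' @param ds a [SpectralSet-class] with split assigned.
#' @param partition from [partitionSpectrum()].
#' @param thresholds from [globalThresholds()].
#' @param screener a [plsScreener()] configuration.
#' @return data.frame with one row per interval: bounds, per-analyte CV
#'   `rmse_*` / `r2_*` and calibration-fit `rmsec_*` / `rc2_*` columns,
#'   aggregate scaled CV RMSE and the `survived` flag.
#' @export
screenIntervals <- function(ds, partition, thresholds,
                            screener = plsScreener()) {
  cal <- calibrationSet(ds)
  X <- absorbance(cal); Y <- targets(cal)
  k <- ncol(Y)
  out <- partition
  rmse_m <- matrix(NA_real_, nrow(partition), k)
  r2_m <- matrix(NA_real_, nrow(partition), k)
  agg <- numeric(nrow(partition))
  rmse_fit <- matrix(NA_real_, nrow(partition), k)
  r2_fit <- matrix(NA_real_, nrow(partition), k)
  for (i in seq_len(nrow(partition))) {
    ch <- seq(partition$start[i], partition$end[i])
    ev <- screenerEval(X[, ch, drop = FALSE], Y, screener, fit = TRUE)
    rmse_m[i, ] <- ev$rmse; r2_m[i, ] <- ev$r2; agg[i] <- ev$aggregate
    rmse_fit[i, ] <- ev$rmse_fit; r2_fit[i, ] <- ev$r2_fit
  }
  survived <- vapply(seq_len(nrow(partition)), function(i) {
    any(rmse_fit[i, ] <= thresholds$rmse & r2_fit[i, ] >= thresholds$r2)
  }, logical(1))
  colnames(rmse_m) <- paste0("rmse_", analyteNames(ds))
  colnames(r2_m) <- paste0("r2_", analyteNames(ds))
  colnames(rmse_fit) <- paste0("rmsec_", analyteNames(ds))
  colnames(r2_fit) <- paste0("rc2_", analyteNames(ds))
  out <- cbind(out, rmse_m, r2_m, rmse_fit, r2_fit)
  out$aggregate <- agg
  out$survived <- survived
  if (!any(survived)) {
    stop("no interval survived screening; consider a larger 'p' or ",
         "relaxed thresholds")
  }
  out
}

#' Exhaustive search over interval combinations
#'
#' Enumerates every non-empty subset of the surviving intervals, scores each
#' union of channels with the cross-validated screener, and returns the
#' subset minimising the aggregate scaled RMSE (mean over analytes of RMSE
#' divided by the analyte's calibration SD). Ties at 1e-12 resolution are
#' broken in favour of fewer channels, then lower interval ids. When more
#' than `q_cap` intervals survive, only the `q_cap` best (by local aggregate
#' RMSE) enter the enumeration.
#'
#' @param ds a [SpectralSet-class] with split assigned.
#' @param scores output of [screenIntervals()].
#' @param screener a [plsScreener()] configuration.
#' @param q_cap maximum number of intervals searched exhaustively
#'   (default 12, i.e. at most 4095 candidate combinations).
#' @return list with `members` (interval ids), `channels`, per-analyte
#'   `rmse` and `r2`, `aggregate`, and `n_enumerated`.
#' @export
combineIntervals <- function(ds, scores, screener = plsScreener(),
                             q_cap = 12L) {
  surv <- scores$interval[scores$survived]
  if (length(surv) == 0L) stop("no surviving intervals to combine")
  if (length(surv) > q_cap) {
    ord <- order(scores$aggregate[match(surv, scores$interval)])
    surv <- sort(surv[ord[seq_len(q_cap)]])
  }
  cal <- calibrationSet(ds)
  X <- absorbance(cal); Y <- targets(cal)
  q <- length(surv)
  best <- NULL
  n_enum <- 0L
  ## ties on aggregate RMSE (1e-12) go to fewer channels, then to the
  ## lexicographically smaller sorted member-id vector
  beats <- function(cand, inc) {
    if (is.null(inc)) return(TRUE)
    if (cand$aggregate < inc$aggregate - 1e-12) return(TRUE)
    if (cand$aggregate > inc$aggregate + 1e-12) return(FALSE)
    if (length(cand$channels) != length(inc$channels)) {
      return(length(cand$channels) < length(inc$channels))
    }
    d <- which(cand$members[seq_len(min(length(cand$members),
                                        length(inc$members)))] !=
               inc$members[seq_len(min(length(cand$members),
                                       length(inc$members)))])
    if (length(d)) return(cand$members[d[1L]] < inc$members[d[1L]])
    length(cand$members) < length(inc$members)
  }
  for (code in seq_len(2L^q - 1L)) {
    members <- surv[bitwAnd(code, 2L^(seq_len(q) - 1L)) > 0L]
    ch <- intervalChannels(scores, match(members, scores$interval))
    ev <- screenerEval(X[, ch, drop = FALSE], Y, screener)
    n_enum <- n_enum + 1L
    cand <- list(members = members, channels = ch, rmse = ev$rmse,
                 r2 = ev$r2, aggregate = ev$aggregate)
    if (beats(cand, best)) best <- cand
  }
  names(best$rmse) <- names(best$r2) <- analyteNames(ds)
  best$n_enumerated <- n_enum
  best
}
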