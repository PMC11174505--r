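#' Root-mean-square error
#'
#' `sqrt(mean((yhat - y)^2))`, in the units of the target.
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @return non-negative scalar.
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  sqrt(mean((y_pred - y_true)^2))
}

#' Coefficient of determination
#'
#' `1 - SSres/SStot` with the total sum of squares taken about the mean of
#' the measured values. Can be negative when predictions are worse than the
#' mean.
#'
#' @param y_true measured values (must not be constant).
#' @param y_pred predicted values.
#' @return scalar, at most 1.
#' @export
rSquared <- function(y_true, y_pred) {
  if (length(y_true) < 2L) stop("need at least 2 observations")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  sstot <- sum((y_true - mean(y_true))^2)
  if (sstot == 0) stop("constant y_true: R-squared undefined")
  1 - sum((y_pred - y_true)^2) / sstot
}

#' Residual prediction deviation
#'
#' `RPD = 1/sqrt(1 - R^2)`, the ratio of the reference-value standard
#' deviation to the prediction error standard deviation. Values of 3 or more
#' conventionally indicate a calibration usable for quantification.
#'
#' @param r2 coefficient of determination, must be < 1 for a finite result.
#' @return scalar; `Inf` (with a warning) when `r2 >= 1`.
#' @examples
#' rpd(0.75)  # 2
#' @export
rpd <- function(r2) {
  if (!is.numeric(r2) || length(r2) != 1L) stop("'r2' must be a scalar")
  if (r2 >= 1) {
    warning("r2 >= 1: RPD is unbounded")
    return(Inf)
  }
  1 / sqrt(1 - r2)
}

#' Per-analyte evaluation report
#'
#' Computes RMSE, R-squared and RPD for each analyte, labelled by phase
#' (RMSEC/Rc2 on the calibration set, RMSEP/Rp2 on the prediction set).
#'
#' @param Y measured samples x analytes matrix.
#' @param Yhat predicted matrix of the same shape.
#' @param phase `"calibration"` or `"prediction"`.
#' @return data.frame with columns analyte, phase, n, rmse, r2, rpd.
#' @export
evaluationReport <- function(Y, Yhat, phase = c("prediction", "calibration")) {
  phase <- match.arg(phase)
  Y <- as.matrix(Y); Yhat <- as.matrix(Yhat)
  stopifnot(all(dim(Y) == dim(Yhat)))
  nm <- colnames(Y)
  if (is.null(nm)) nm <- paste0("analyte_", seq_len(ncol(Y)))
  r2 <- vapply(seq_len(ncol(Y)), function(j) rSquared(Y[, j], Yhat[, j]),
               numeric(1))
  data.frame(
    analyte = nm, phase = phase, n = nrow(Y),
    rmse = vapply(seq_len(ncol(Y)), function(j) rmse(Y[, j], Yhat[, j]),
                  numeric(1)),
    r2 = r2,
    rpd = vapply(r2, function(x) if (x >= 1) Inf else 1 / sqrt(1 - x),
                 numeric(1)),
    row.names = NULL
  )
}

#' Wavelength-selection statistics
#'
#' Summarises a selected wavelength set by NFW (number of feature
#' wavelengths), NWI (number of maximal runs of consecutive channels, i.e.
#' contiguous wavelength intervals) and AWIW (average wavelength interval
#' width, NFW/NWI).
#'
#' @param selected integer channel indices (1-based) on the wavelength grid.
#' @param n_channels optional grid size for bounds checking.
#' @return list with `nfw`, `nwi`, `awiw`.
#' @examples
#' selectionStats(c(1:5, 10, 12))  # nfw 7, nwi 3
#' @export
selectionStats <- function(selected, n_channels = NULL) {
  selected <- sort(unique(as.integer(selected)))
  if (length(selected) == 0L) stop("empty selection")
  if (any(selected < 1L)) stop("channel indices must be >= 1")
  if (!is.null(n_channels) && any(selected > n_channels)) {
    stop("channel index exceeds grid size")
  }
  nfw <- length(selected)
  nwi <- 1L + sum(diff(selected) > 1L)
  list(nfw = nfw, nwi = nwi, awiw = nfw / nwi)
}
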