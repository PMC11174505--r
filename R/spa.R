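#' Successive projections algorithm (SPA)
#'
#' Collinearity-minimising forward selection: starting from a candidate
#' column, each step adds the unselected channel with the largest norm of
#' its component orthogonal to the span of the channels already selected.
#' For every chain prefix a multiple linear regression model is scored by
#' cross-validated aggregate RMSE on the calibration set, and the prefix
#' (over all starts) with the smallest RMSE wins. Deterministic; projection
#' ties break to the lowest channel index.
#'
#' @param ds a [SpectralSet-class] with split assigned.
#' @param max_vars maximum chain length (default `min(30, n_cal - 2)`).
#' @param n_starts number of evenly spaced candidate start columns
#'   (default 20). Enumerating every column as a start adds nothing at NIR
#'   grid sizes and costs O(p^2); a spread subset is used instead.
#' @param folds CV folds for the MLR scoring (default 5).
#' @return a [SelectionResult-class]; provenance records the winning start
#'   and the RMSE-by-length profile.
#' @export
spaSelect <- function(ds, max_vars = NULL, n_starts = 20L, folds = 5L) {
  cal <- calibrationSet(ds)
  X <- absorbance(cal); Y <- targets(cal)
  n <- nrow(X); p <- ncol(X)
  if (is.null(max_vars)) max_vars <- min(30L, n - 2L)
  if (max_vars > min(n - 1L, p)) stop("max_vars exceeds min(n-1, n_channels)")
  sds <- pmax(apply(Y, 2L, stats::sd), .Machine$double.eps)
  Xc <- scale(X, scale = FALSE)
  starts <- unique(round(seq(1L, p, length.out = min(n_starts, p))))
  fid <- cvFolds(n, folds)

  chainFrom <- function(s0) {
    sel <- s0
    R <- Xc                                   # residuals orthogonal to span
    nrm0 <- sqrt(colSums(R^2))
    for (step in seq_len(max_vars - 1L)) {
      q <- R[, sel[length(sel)]]
      qn <- sqrt(sum(q^2))
      if (qn < 1e-10 * max(nrm0)) break
      q <- q / qn
      R <- R - q %*% crossprod(q, R)
      nrm <- sqrt(colSums(R^2))
      nrm[sel] <- -Inf
      ## exact linear combinations of the selection have zero residual norm
      cand <- which(nrm > 1e-10 * max(nrm0))
      if (length(cand) == 0L) {
        warning("SPA stopped early: remaining channels are numerically ",
                "collinear with the selection")
        break
      }
      best <- cand[which.max(nrm[cand])]     # which.max takes lowest index on ties
      sel <- c(sel, best)
    }
    sel
  }

  cvScore <- function(sel) {
    P <- matrix(NA_real_, n, ncol(Y))
    for (f in unique(fid)) {
      tr <- fid != f
      D <- cbind(1, X[tr, sel, drop = FALSE])
      cf <- qr.coef(qr(D), Y[tr, , drop = FALSE])
      cf[is.na(cf)] <- 0
      P[!tr, ] <- cbind(1, X[!tr, sel, drop = FALSE]) %*% cf
    }
    scaledRmse(Y, P, sds)
  }

  best <- NULL
  for (s0 in starts) {
    chain <- chainFrom(s0)
    for (len in seq_along(chain)) {
      sc <- cvScore(chain[seq_len(len)])
      if (is.null(best) || sc < best$score - 1e-12) {
        best <- list(sel = chain[seq_len(len)], score = sc, start = s0,
                     len = len)
      }
    }
  }
  newSelectionResult(best$sel, wavenumbers(ds), "spa",
                     provenance = list(start = best$start,
                                       chain_length = best$len,
                                       cv_rmse = best$score))
}

#' Jaccard stability of repeated selections
#'
#' Mean pairwise Jaccard index of the selected channel sets, a simple
#' summary of how reproducible a stochastic selector is across seeds.
#'
#' @param results list of [SelectionResult-class] objects.
#' @return scalar in `[0, 1]`.
#' @export
selectionJaccard <- function(results) {
  if (length(results) < 2L) stop("need at least two selections")
  sets <- lapply(results, selectedChannels)
  pairs <- utils::combn(length(sets), 2L)
  mean(apply(pairs, 2L, function(ij) {
    a <- sets[[ij[1L]]]; b <- sets[[ij[2L]]]
    length(intersect(a, b)) / length(union(a, b))
  }))
}
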