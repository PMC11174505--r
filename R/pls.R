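#' PLSModel: multi-response partial least squares calibration
#'
#' Multi-response (PLS2) regression fitted by the SIMPLS algorithm. With as
#' many components as the rank of the centred predictor matrix, the fitted
#' coefficients coincide with ordinary least squares on the same data.
#'
#' @slot ncomp number of latent variables used.
#' @slot coefficients regression coefficient matrix (predictors x responses).
#' @slot intercept per-response intercepts.
#' @slot xMeans,yMeans centring vectors.
#' @slot cvRmse mean cross-validated scaled RMSE per candidate component
#'   count (empty when `ncomp` was given explicitly).
#' @export
setClass("PLSModel", representation(
  ncomp = "integer",
  coefficients = "matrix",
  intercept = "numeric",
  xMeans = "numeric",
  yMeans = "numeric",
  cvRmse = "numeric"
))

setMethod("show", "PLSModel", function(object) {
  cat("PLSModel:", nrow(object@coefficients), "predictors ->",
      ncol(object@coefficients), "responses,", object@ncomp, "components\n")
})

## SIMPLS with nested component sequence. Returns score weights R, response
## loadings Q, and means, from which the coefficient matrix at any component
## count a is R[, 1:a] %*% t(Q[, 1:a]).
simpls <- function(X, Y, ncomp) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2L, xm); Yc <- sweep(Y, 2L, ym)
  ncomp <- min(ncomp, n - 1L, p)
  R <- matrix(0, p, ncomp); Q <- matrix(0, m, ncomp); V <- matrix(0, p, ncomp)
  S <- crossprod(Xc, Yc)
  a <- 0L
  for (i in seq_len(ncomp)) {
    if (m == 1L) {
      r <- S[, 1L]
    } else {
      r <- svd(S, nu = 1L, nv = 0L)$u[, 1L]
    }
    t_sc <- Xc %*% r
    normt <- sqrt(sum(t_sc^2))
    if (!is.finite(normt) || normt < 1e-12 * sqrt(n)) break
    t_sc <- t_sc / normt; r <- r / normt
    p_load <- crossprod(Xc, t_sc)[, 1L]
    q_load <- crossprod(Yc, t_sc)[, 1L]
    v <- p_load
    if (i > 1L) {
      Vi <- V[, seq_len(i - 1L), drop = FALSE]
      v <- v - Vi %*% crossprod(Vi, v)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) break
    v <- v / nv
    S <- S - v %*% crossprod(v, S)
    R[, i] <- r; Q[, i] <- q_load; V[, i] <- v
    a <- i
  }
  list(R = R[, seq_len(max(a, 1L)), drop = FALSE],
       Q = Q[, seq_len(max(a, 1L)), drop = FALSE],
       xMeans = xm, yMeans = ym, ncomp = a)
}

simplsCoef <- function(fit, a) {
  a <- min(a, fit$ncomp)
  B <- fit$R[, seq_len(a), drop = FALSE] %*% t(fit$Q[, seq_len(a), drop = FALSE])
  list(B = B, intercept = fit$yMeans - drop(fit$xMeans %*% B))
}

## Pooled out-of-fold predictions for every candidate component count.
## One SIMPLS fit per fold covers the whole nested sequence.
plsCvPredictions <- function(X, Y, maxNcomp, folds = 5L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  fid <- cvFolds(n, folds)
  maxNcomp <- min(maxNcomp, n - max(table(fid)) - 1L, ncol(X))
  maxNcomp <- max(maxNcomp, 1L)
  preds <- array(NA_real_, c(n, ncol(Y), maxNcomp))
  for (f in unique(fid)) {
    tr <- fid != f
    fit <- simpls(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], maxNcomp)
    for (a in seq_len(maxNcomp)) {
      co <- simplsCoef(fit, a)
      preds[!tr, , a] <- sweep(X[!tr, , drop = FALSE] %*% co$B, 2L,
                               co$intercept, `+`)
    }
  }
  preds
}

#' Fit a PLS2 calibration model
#'
#' @param X samples x predictors matrix.
#' @param Y samples x responses matrix (a vector is treated as one column).
#' @param ncomp number of latent variables. When `NULL` (default), chosen by
#'   5-fold cross-validation minimising the mean scaled RMSE across
#'   responses, capped at `maxNcomp`.
#' @param maxNcomp cap on the candidate component counts (default 15).
#' @param folds folds for the internal CV (contiguous, deterministic).
#' @return a [PLSModel-class].
#' @export
plsFit <- function(X, Y, ncomp = NULL, maxNcomp = 15L, folds = 5L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must be row-aligned")
  if (anyNA(X) || anyNA(Y)) stop("X and Y must not contain missing values")
  cap <- min(nrow(X) - 1L, ncol(X))
  cv <- numeric(0)
  if (is.null(ncomp)) {
    preds <- plsCvPredictions(X, Y, min(maxNcomp, cap), folds)
    sds <- pmax(apply(Y, 2L, stats::sd), .Machine$double.eps)
    cv <- apply(preds, 3L, function(P) scaledRmse(Y, P, sds))
    ncomp <- which.min(cv)
  }
  if (!isWholeNumber(ncomp) || ncomp < 1L || ncomp > cap) {
    stop("'ncomp' must be an integer in [1, ", cap, "]")
  }
  fit <- simpls(X, Y, ncomp)
  co <- simplsCoef(fit, fit$ncomp)
  dimnames(co$B) <- list(colnames(X), colnames(Y))
  new("PLSModel", ncomp = fit$ncomp, coefficients = co$B,
      intercept = co$intercept, xMeans = fit$xMeans, yMeans = fit$yMeans,
      cvRmse = cv)
}

#' Predict from a PLSModel
#'
#' @param model a [PLSModel-class].
#' @param X samples x predictors matrix with the training column count.
#' @return samples x responses prediction matrix.
#' @export
plsPredict <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(model@coefficients)) {
    stop("X has ", ncol(X), " columns; model expects ",
         nrow(model@coefficients))
  }
  sweep(X %*% model@coefficients, 2L, model@intercept, `+`)
}
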