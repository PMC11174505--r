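## Internal numerical helpers shared across modules.

#' @importFrom withr with_seed
NULL

## Deterministic contiguous fold assignment (venetian blinds). Used wherever a
## cross-validation split must be reproducible without touching the RNG.
cvFolds <- function(n, k) {
  k <- min(k, n)
  rep_len(seq_len(k), n)
}

## Moore-Penrose pseudoinverse via SVD with an rcond-style cutoff.
## Singular values below eps * max(dim) * s_1 are treated as zero.
pinvTol <- function(A) {
  if (length(A) == 0L) stop("empty matrix has no pseudoinverse")
  sv <- svd(A)
  tol <- .Machine$double.eps * max(dim(A)) * sv$d[1L]
  keep <- sv$d > tol
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  sv$v[, keep, drop = FALSE] %*%
    ((1 / sv$d[keep]) * t(sv$u[, keep, drop = FALSE]))
}

## Mean over analytes of RMSE scaled by each analyte's reference SD, so that
## analytes reported in different concentration ranges contribute comparably.
scaledRmse <- function(Y, Yhat, scale_sd) {
  stopifnot(ncol(Y) == ncol(Yhat), length(scale_sd) == ncol(Y))
  per <- sqrt(colMeans((Yhat - Y)^2))
  mean(per / scale_sd)
}

## Derive a stream of child seeds from one user seed, keeping every derived
## seed inside the 32-bit integer range.
childSeeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

isWholeNumber <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && abs(x - round(x)) < 1e-8
}
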