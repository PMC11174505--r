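#' ELMModel: extreme learning machine calibration
#'
#' Single-hidden-layer feedforward network whose input weights and biases are
#' drawn uniformly from \[-1, 1\] and whose output weights are solved in
#' closed form by the Moore-Penrose pseudoinverse of the hidden-layer output
#' matrix. One network models all analytes simultaneously (one output neuron
#' per analyte). Given (seed, number of hidden nodes, training data) the
#' fitted model is bit-reproducible.
#'
#' @slot inputWeights hidden x inputs matrix, U\[-1, 1\].
#' @slot biases hidden-node biases, U\[-1, 1\].
#' @slot outputWeights hidden x outputs matrix solved by least squares.
#' @slot nHidden number of hidden nodes.
#' @slot seed RNG seed used to draw weights and biases.
#' @slot xCenter,xScale per-input standardisation statistics (training set).
#' @export
setClass("ELMModel", representation(
  inputWeights = "matrix",
  biases = "numeric",
  outputWeights = "matrix",
  nHidden = "integer",
  seed = "integer",
  xCenter = "numeric",
  xScale = "numeric"
))

setMethod("show", "ELMModel", function(object) {
  cat("ELMModel:", ncol(object@inputWeights), "inputs ->",
      object@nHidden, "sigmoid hidden nodes ->",
      ncol(object@outputWeights), "outputs (seed", object@seed, ")\n")
})

sigmoid <- function(z) 1 / (1 + exp(-z))

elmHidden <- function(X, W, b) {
  sigmoid(sweep(X %*% t(W), 2L, b, `+`))
}

elmStandardize <- function(X, center, scale) {
  sweep(sweep(X, 2L, center), 2L, scale, `/`)
}

#' Fit an extreme learning machine
#'
#' Draws input weights and biases from U\[-1, 1\] under `seed`, computes the
#' hidden-layer output matrix H through the sigmoid activation, and solves
#' the output weights as the minimum-norm least-squares solution
#' `beta = pinv(H) %*% C`.
#'
#' Inputs are centred per column using training statistics and Pareto
#' scaled (divided by the square root of the channel SD) with an overall
#' normalisation that keeps the total input variance at 1, so the random
#' pre-activations stay inside the sigmoid's dynamic range whatever the
#' channel count (on raw absorbance scales, or with many inputs, the
#' sigmoid saturates and the hidden layer degenerates). Pareto scaling is
#' the usual chemometric compromise: full z-scoring amplifies bare-noise
#' channels to unit variance, no scaling lets the strongest bands crowd
#' weak analyte bands out of the random projections. Disable with
#' `standardize = FALSE`.
#'
#' @param X samples x inputs matrix.
#' @param C samples x outputs target matrix (vector = one output).
#' @param l number of hidden nodes.
#' @param seed integer seed for the random weights.
#' @param standardize standardise inputs with training mean/sd (default TRUE).
#' @return an [ELMModel-class].
#' @export
elmFit <- function(X, C, l, seed = 1L, standardize = TRUE) {
  X <- as.matrix(X); C <- as.matrix(C)
  if (nrow(X) == 0L || ncol(X) == 0L) stop("empty training matrix")
  if (nrow(X) != nrow(C)) stop("X and C must be row-aligned")
  if (anyNA(X) || anyNA(C)) stop("X and C must not contain missing values")
  if (!isWholeNumber(l) || l < 1L) stop("'l' must be a positive integer")
  if (l >= 10L * nrow(X)) {
    warning("l = ", l, " is >= 10x the number of training samples; ",
            "the network is deep in the interpolation regime")
  }
  center <- if (standardize) colMeans(X) else rep(0, ncol(X))
  scl <- if (standardize) {
    sdv <- pmax(apply(X, 2L, stats::sd), .Machine$double.eps)
    sqrt(sdv) * sqrt(sum(sdv))  # Pareto scale; total input variance = 1
  } else {
    rep(1, ncol(X))
  }
  Xs <- elmStandardize(X, center, scl)
  wb <- withr::with_seed(seed, {
    list(W = matrix(stats::runif(l * ncol(X), -1, 1), l, ncol(X)),
         b = stats::runif(l, -1, 1))
  })
  H <- elmHidden(Xs, wb$W, wb$b)
  beta <- pinvTol(H) %*% C
  new("ELMModel", inputWeights = wb$W, biases = wb$b,
      outputWeights = beta, nHidden = as.integer(l),
      seed = as.integer(seed), xCenter = center, xScale = scl)
}

#' Predict from an ELMModel
#'
#' Evaluates `y = g(X w' + b) beta` with the sigmoid activation g.
#'
#' @param model an [ELMModel-class].
#' @param X samples x inputs matrix with the training input dimension.
#' @return samples x outputs prediction matrix.
#' @export
elmPredict <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(model@inputWeights)) {
    stop("X has ", ncol(X), " columns; model expects ",
         ncol(model@inputWeights))
  }
  Xs <- elmStandardize(X, model@xCenter, model@xScale)
  elmHidden(Xs, model@inputWeights, model@biases) %*% model@outputWeights
}

#' Select the ELM hidden-node count
#'
#' Grid search over candidate hidden-node counts. Because the random input
#' weights make any single fit unstable, each candidate is fitted `repeats`
#' times with distinct seeds; the candidate with the smallest mean
#' cross-validated scaled RMSE (averaged over analytes and repeats) wins.
#' The conventional protocol searches 4 to 40 nodes in steps of 2 with 50
#' repeats.
#'
#' @param X,C calibration inputs and targets.
#' @param grid integer candidates (default `seq(4, 40, 2)`).
#' @param repeats random restarts per candidate (default 50).
#' @param folds CV folds on the calibration set (default 5); the held-out
#'   prediction set must play no part in this search.
#' @param seed master seed from which per-repeat seeds are derived.
#' @return list with `best_l` and `mean_rmse`, the per-candidate mean CV
#'   scaled RMSE (named by candidate).
#' @export
elmSelectHiddenNodes <- function(X, C, grid = seq(4L, 40L, 2L),
                                 repeats = 50L, folds = 5L, seed = 1L) {
  X <- as.matrix(X); C <- as.matrix(C)
  if (length(grid) == 0L) stop("'grid' must be non-empty")
  if (repeats < 1L) stop("'repeats' must be >= 1")
  n <- nrow(X)
  fid <- cvFolds(n, folds)
  if (length(unique(fid)) < 2L) stop("not enough samples for validation folds")
  sds <- pmax(apply(C, 2L, stats::sd), .Machine$double.eps)
  seeds <- childSeeds(seed, repeats)
  mean_rmse <- vapply(grid, function(l) {
    per_rep <- vapply(seeds, function(s) {
      P <- matrix(NA_real_, n, ncol(C))
      for (f in unique(fid)) {
        tr <- fid != f
        m <- elmFit(X[tr, , drop = FALSE], C[tr, , drop = FALSE], l, seed = s)
        P[!tr, ] <- elmPredict(m, X[!tr, , drop = FALSE])
      }
      scaledRmse(C, P, sds)
    }, numeric(1))
    mean(per_rep)
  }, numeric(1))
  names(mean_rmse) <- grid
  list(best_l = grid[which.min(mean_rmse)], mean_rmse = mean_rmse)
}

#' Serialize / restore an ELMModel as JSON
#'
#' Stores weights, biases, seed and standardisation statistics so a model
#' reloads exactly.
#'
#' @param model an [ELMModel-class].
#' @param path output (input) JSON path.
#' @return `writeElmModel` the path, invisibly; `readElmModel` the model.
#' @export
writeElmModel <- function(model, path) {
  obj <- list(
    n_hidden = model@nHidden, seed = model@seed,
    input_weights = model@inputWeights, biases = model@biases,
    output_weights = model@outputWeights,
    x_center = model@xCenter, x_scale = model@xScale
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeElmModel
#' @export
readElmModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("ELMModel",
      inputWeights = as.matrix(o$input_weights), biases = as.numeric(o$biases),
      outputWeights = as.matrix(o$output_weights),
      nHidden = as.integer(o$n_hidden), seed = as.integer(o$seed),
      xCenter = as.numeric(o$x_center), xScale = as.numeric(o$x_scale))
}
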