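test_that("ELM output weights solve the least-squares problem", {
  withr::with_seed(7, {
    X <- matrix(rnorm(6 * 3), 6, 3)
    C <- matrix(rnorm(6 * 4), 6, 4)
  })
  m <- elmFit(X, C, l = 4, seed = 1)
  # independent minimum-norm LS oracle: explicit SVD of H
  H <- 1 / (1 + exp(-(sweep(sweep(X, 2, m@xCenter), 2, m@xScale, "/") %*%
                        t(m@inputWeights) +
                        matrix(m@biases, 6, 4, byrow = TRUE))))
  sv <- svd(H)
  keep <- sv$d > 1e-10
  beta_oracle <- sv$v[, keep] %*% diag(1 / sv$d[keep]) %*%
    t(sv$u[, keep]) %*% C
  expect_equal(unname(m@outputWeights), unname(beta_oracle),
               tolerance = 1e-8)

  # the solution minimises ||H beta - C|| against random probes
  res0 <- norm(H %*% m@outputWeights - C, "F")
  probes <- withr::with_seed(8, replicate(100, {
    norm(H %*% (m@outputWeights + matrix(rnorm(16, sd = 0.1), 4, 4)) - C, "F")
  }))
  expect_true(all(probes >= res0 - 1e-12))
})

test_that("ELM degenerate and exact-fit cases behave", {
  X <- withr::with_seed(3, matrix(rnorm(8 * 2), 8, 2))
  mz <- elmFit(X, matrix(0, 8, 3), l = 5, seed = 2)
  expect_equal(max(abs(mz@outputWeights)), 0)
  expect_equal(max(abs(elmPredict(mz, X))), 0)

  # l = n with full-rank H interpolates the training targets
  C <- withr::with_seed(4, matrix(rnorm(8 * 2), 8, 2))
  suppressWarnings(mi <- elmFit(X, C, l = 8, seed = 5))
  expect_equal(elmPredict(mi, X), C, tolerance = 1e-6)

  expect_error(elmFit(matrix(numeric(0), 0, 2), matrix(0, 0, 1), l = 2),
               "empty")
  expect_warning(elmFit(X, C, l = 90, seed = 1), "interpolation")
})

test_that("elm_predict equals the per-sample neuron sum", {
  X <- matrix(c(0.1, 0.4, -0.2, 0.8, 0.5, -0.6), 3, 2)
  C <- matrix(c(1, 2, 3), 3, 1)
  m <- elmFit(X, C, l = 3, seed = 9, standardize = FALSE)
  # naive loop over Eq.-style sums
  naive <- matrix(0, 3, 1)
  for (i in 1:3) {
    for (j in 1:3) {
      z <- sum(m@inputWeights[j, ] * X[i, ]) + m@biases[j]
      naive[i, 1] <- naive[i, 1] + m@outputWeights[j, 1] / (1 + exp(-z))
    }
  }
  expect_equal(elmPredict(m, X), naive, tolerance = 1e-12)
  expect_error(elmPredict(m, matrix(0, 2, 5)), "columns")
})

test_that("ELM is reproducible and serialises exactly", {
  X <- withr::with_seed(1, matrix(rnorm(10 * 4), 10, 4))
  C <- withr::with_seed(2, matrix(rnorm(10 * 2), 10, 2))
  m1 <- elmFit(X, C, l = 6, seed = 77)
  m2 <- elmFit(X, C, l = 6, seed = 77)
  expect_identical(m1@outputWeights, m2@outputWeights)

  path <- withr::local_tempfile(fileext = ".json")
  writeElmModel(m1, path)
  m3 <- readElmModel(path)
  expect_equal(m3@outputWeights, m1@outputWeights, tolerance = 0)
  expect_equal(elmPredict(m3, X), elmPredict(m1, X), tolerance = 0)
})

test_that("hidden-node search averages repeats and prefers capacity on clean data", {
  # noiseless rank-2 nonlinear-free data: more nodes should not hurt
  withr::with_seed(21, {
    Z <- matrix(rnorm(40 * 2), 40, 2)
    X <- Z %*% matrix(rnorm(2 * 12), 2, 12)
    C <- Z %*% matrix(c(1, -1, 0.5, 2), 2, 2)
  })
  sel <- elmSelectHiddenNodes(X, C, grid = c(4, 20), repeats = 3, seed = 1)
  expect_named(sel$mean_rmse, c("4", "20"))
  expect_lte(sel$mean_rmse[["20"]], sel$mean_rmse[["4"]])

  s1 <- elmSelectHiddenNodes(X, C, grid = c(4, 8), repeats = 1, seed = 5)
  s2 <- elmSelectHiddenNodes(X, C, grid = c(4, 8), repeats = 1, seed = 5)
  expect_identical(s1, s2)
  expect_error(elmSelectHiddenNodes(X, C, grid = integer(0)), "non-empty")
})

test_that("PLS at full rank equals ordinary least squares", {
  withr::with_seed(31, {
    X <- matrix(rnorm(10 * 3), 10, 3)
    B <- matrix(rnorm(3 * 2), 3, 2)
    Y <- X %*% B + matrix(rnorm(10 * 2), 10, 2) * 0.3
  })
  m <- plsFit(X, Y, ncomp = 3)
  # normal-equations oracle
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  B_ols <- solve(crossprod(Xc), crossprod(Xc, Yc))
  expect_equal(unname(m@coefficients), unname(B_ols), tolerance = 1e-8)
  expect_equal(plsPredict(m, X),
               sweep(Xc %*% B_ols, 2, colMeans(Y), `+`), tolerance = 1e-8)
})

test_that("PLS handles collinear, constant and permuted inputs sensibly", {
  x <- seq(-1, 1, length.out = 12)
  y <- 2 * x + 1
  m <- plsFit(cbind(x), cbind(y), ncomp = 1)
  expect_equal(rSquared(y, drop(plsPredict(m, cbind(x)))), 1,
               tolerance = 1e-10)

  # constant target column: prediction constant, coefficients ~ 0
  withr::with_seed(5, X <- matrix(rnorm(15 * 4), 15, 4))
  Y <- cbind(v = X[, 1] + rnorm(15, sd = 0.1), const = rep(2, 15))
  m2 <- plsFit(X, Y, ncomp = 2)
  expect_equal(max(abs(m2@coefficients[, "const"])), 0, tolerance = 1e-8)
  expect_equal(unname(plsPredict(m2, X)[, "const"]), rep(2, 15),
               tolerance = 1e-8)

  # column permutation of X permutes coefficients identically
  perm <- c(3, 1, 4, 2)
  m3 <- plsFit(X[, perm], Y, ncomp = 2)
  expect_equal(unname(m3@coefficients), unname(m2@coefficients[perm, ]),
               tolerance = 1e-8)

  expect_error(plsFit(X, Y, ncomp = 99), "ncomp")
})
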