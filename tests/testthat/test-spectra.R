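test_that("CSV round trip is lossless and preserves ordering", {
  ds <- tinySet(n = 3, k = 5)
  splitLabels(ds) <- c("calibration", "prediction", "calibration")
  sp <- withr::local_tempfile(fileext = ".csv")
  tg <- withr::local_tempfile(fileext = ".csv")
  writeSpectralSet(ds, sp, tg)
  back <- readSpectralSet(sp, tg)
  expect_equal(nSamples(back), 3)
  expect_equal(nChannels(back), 5)
  expect_identical(sampleIds(back), sampleIds(ds))
  expect_equal(absorbance(back), absorbance(ds), tolerance = 0)
  expect_equal(targets(back), targets(ds), tolerance = 0)
  expect_equal(wavenumbers(back), wavenumbers(ds))
  expect_identical(unname(splitLabels(back)), unname(splitLabels(ds)))
})

test_that("reader rejects misaligned and malformed files", {
  ds <- tinySet(n = 3, k = 4)
  sp <- withr::local_tempfile(fileext = ".csv")
  tg <- withr::local_tempfile(fileext = ".csv")
  writeSpectralSet(ds, sp, tg)
  # drop one id from the targets file
  t2 <- read.csv(tg, check.names = FALSE)[-2, ]
  write.csv(t2, tg, row.names = FALSE)
  expect_error(readSpectralSet(sp, tg), "mismatch")
  # non-numeric wavenumber header
  s2 <- read.csv(sp, check.names = FALSE)
  colnames(s2)[3] <- "not_a_number"
  write.csv(s2, sp, row.names = FALSE)
  writeSpectralSet(ds, sp, tg <- withr::local_tempfile(fileext = ".csv"))
  colnames(s2)[1] <- "sample_id"
  sp2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(s2, sp2, row.names = FALSE)
  expect_error(readSpectralSet(sp2, tg), "wavenumber")
})

test_that("SpectralSet validity catches bad inputs", {
  expect_error(SpectralSet(c(4008, 4004, 4000), matrix(1, 2, 3),
                           cbind(a = c(1, 2))), "increasing")
  expect_error(SpectralSet(c(4000, 4004), matrix(c(1, NA), 1, 2),
                           cbind(a = 1)), "finite")
  expect_error(SpectralSet(c(4000, 4004), matrix(1, 1, 2),
                           cbind(a = -1)), "non-negative")
  expect_error(SpectralSet(c(4000, 4004), matrix(1, 2, 2),
                           cbind(a = c(1, 2)), sampleIds = c("s", "s")),
               "unique")
})

test_that("absorbance_from_reflectance follows A = log10(1/R)", {
  expect_equal(absorbanceFromReflectance(c(1, 0.1, 0.01)), c(0, 1, 2))
  expect_error(absorbanceFromReflectance(c(0.5, 0)), "positive")
  expect_warning(a <- absorbanceFromReflectance(1.5), "negative")
  expect_lt(a, 0)
})

test_that("SG filter preserves polynomials up to its order and smooths noise", {
  x <- seq_len(60)
  poly2 <- 2 + 3 * x + 0.05 * x^2
  ds <- SpectralSet(4000 + 4 * (x - 1),
                    rbind(rep(1.5, 60), poly2 / max(poly2)),
                    cbind(a = c(1, 2)))
  sm <- sgFilter(ds, window = 11, polyorder = 2)
  expect_equal(absorbance(sm)[1, ], absorbance(ds)[1, ], tolerance = 1e-10)
  expect_equal(absorbance(sm)[2, ], absorbance(ds)[2, ], tolerance = 1e-10)

  # white noise variance shrinks
  noise <- withr::with_seed(9, matrix(rnorm(5 * 200), 5, 200))
  smn <- sgFilter(noise, window = 11, polyorder = 2)
  expect_lt(mean(apply(smn, 1, var)), mean(apply(noise, 1, var)))

  # adding a constant commutes with the filter
  shifted <- sgFilter(noise + 3, window = 11, polyorder = 2)
  expect_equal(shifted, smn + 3, tolerance = 1e-10)

  expect_error(sgFilter(noise, window = 10), "odd")
  expect_error(sgFilter(noise, window = 5, polyorder = 5), "smaller")
})

test_that("calibration/prediction split matches the 2:1 convention", {
  ds <- generateSpectra(makeReferenceScenario(), seed = 3)$dataset
  ds <- splitCalibrationPrediction(ds, ratio = 2 / 3, seed = 1)
  sp <- splitLabels(ds)
  expect_equal(sum(sp == "calibration"), 70)
  expect_equal(sum(sp == "prediction"), 35)
  # partition: every sample in exactly one set
  expect_true(all(sp %in% c("calibration", "prediction")))

  ds2 <- splitCalibrationPrediction(ds, ratio = 2 / 3, seed = 1)
  expect_identical(splitLabels(ds2), sp)

  small <- tinySet(n = 10, k = 4)
  small <- splitCalibrationPrediction(small, ratio = 0.5, seed = 2)
  expect_equal(as.vector(table(splitLabels(small))[c("calibration", "prediction")]),
               c(5L, 5L))
  expect_error(splitCalibrationPrediction(tinySet(n = 2, k = 3)), "3 samples")
})

test_that("pca_summary matches a brute-force eigendecomposition", {
  X <- withr::with_seed(11, matrix(rnorm(5 * 8), 5, 8))
  ds <- SpectralSet(4000 + 4 * (0:7), X, cbind(a = rep(1, 5) + (1:5) / 10))
  got <- pcaSummary(ds, k = 4)
  ev <- eigen(cov(X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(got, (ev / sum(ev))[1:4], tolerance = 1e-10)
  expect_true(all(diff(got) <= 1e-12))
  expect_equal(sum(pcaSummary(ds, k = 4)), 1, tolerance = 1e-10)

  # rank-1 data: first proportion is 1
  r1 <- outer(1:6, seq(0.1, 0.8, length.out = 5))
  expect_equal(pcaSummary(r1, k = 1), 1, tolerance = 1e-10)
  expect_error(pcaSummary(r1, k = 10), "k")
})
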