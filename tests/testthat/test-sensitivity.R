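test_that("unit spectra are recovered exactly from a clean linear mixture", {
  sc <- smallScenario(n = 60, noise = 0)
  sc@baseline <- c(0, 0, 0)
  g <- generateSpectra(sc, seed = 4)
  # A = C S exactly, so classical least squares returns S
  S_hat <- estimateUnitSpectra(g$dataset)
  expect_equal(unname(S_hat), unname(g$unitSpectra), tolerance = 1e-8)
})

test_that("an analyte that never absorbs gets a zero row", {
  sc <- smallScenario(n = 50, noise = 0)
  sc@baseline <- c(0, 0, 0)
  sc@bands$B$height <- 0
  g <- generateSpectra(sc, seed = 6)
  S_hat <- estimateUnitSpectra(g$dataset)
  expect_equal(max(S_hat["B", ]), 0, tolerance = 1e-10)
})

test_that("a baseline offset biases estimates unless an intercept is included", {
  sc <- smallScenario(n = 60, noise = 0)
  sc@baseline <- c(0.2, 0, 0)
  g <- generateSpectra(sc, seed = 8)
  biased <- estimateUnitSpectra(g$dataset, intercept = FALSE)
  clean <- estimateUnitSpectra(g$dataset, intercept = TRUE)
  expect_equal(unname(clean), unname(g$unitSpectra), tolerance = 1e-8)
  expect_gt(max(abs(biased - g$unitSpectra)), 0.01)
})

test_that("collinear concentrations are rejected", {
  A <- withr::with_seed(2, matrix(runif(20), 10, 2))
  C <- cbind(a = 1:10, b = 2 * (1:10))
  expect_error(estimateUnitSpectra(list(absorbance = A, targets = C)),
               "collinear")
})

test_that("sensitivity factors normalise to one at absorbing channels", {
  S <- rbind(a = c(1, 0, 2, 0), b = c(0, 0.5, 2, 0), c = c(0, 0.5, 0, 0))
  prof <- sensitivityFactors(S)
  # exclusive channel
  expect_equal(prof$alpha[, 1], c(a = 1, b = 0, c = 0))
  # equal split
  expect_equal(prof$alpha[, 2], c(a = 0, b = 0.5, c = 0.5))
  # column sums are 1 wherever anything absorbs
  absorbing <- colSums(S) > 0
  expect_equal(unname(colSums(prof$alpha[, absorbing])), rep(1, 3))
  # silent channel: all zero and flagged
  expect_equal(unname(prof$alpha[, 4]), rep(0, 3))
  expect_identical(unname(prof$zeroTotal), c(FALSE, FALSE, FALSE, TRUE))
  expect_error(sensitivityFactors(rbind(c(-1, 2))), "non-negative")

  k <- 4
  eq <- matrix(1, k, 6)
  expect_true(all(sensitivityFactors(eq)$alpha == 1 / k))
})

test_that("segmentation keeps uniform intervals whole and drops interferent-dominated channels", {
  part <- partitionSpectrum(20, 2)
  wn <- 4000 + 4 * (0:19)
  # interval 1: uniform alpha across targets -> everything retained
  # interval 2: channels 15:16 dominated by a non-target interferent
  alpha <- matrix(0.5, 3, 20, dimnames = list(c("t1", "t2", "int"), NULL))
  alpha["int", ] <- 0
  alpha[, 15:16] <- c(0.05, 0.05, 0.9)
  # renormalise columns
  alpha <- sweep(alpha, 2, colSums(alpha), "/")
  prof <- list(alpha = alpha)
  comb <- list(members = c(1, 2), channels = 1:20)
  res <- sensitivitySegment(comb, prof, part, wn, analytes = c("t1", "t2"))
  expect_true(all(1:10 %in% selectedChannels(res)))
  expect_false(any(c(15, 16) %in% selectedChannels(res)))
  expect_lte(res@stats$nfw, length(comb$channels))

  # pruning everything is an error
  allint <- list(alpha = rbind(t1 = rep(0, 20), big = rep(1, 20)))
  expect_error(
    sensitivitySegment(list(members = 1, channels = 1:10), allint, part, wn,
                       analytes = "t1"),
    "removed every channel")
})

test_that("fic-ss pipeline is deterministic and warns on degenerate p", {
  ds <- smallSplitSet()
  r1 <- ficssSelect(ds, p = 6)
  r2 <- ficssSelect(ds, p = 6)
  expect_identical(selectedChannels(r1), selectedChannels(r2))
  expect_s4_class(r1, "SelectionResult")
  expect_warning(
    tryCatch(ficssSelect(ds, p = nChannels(ds)), error = function(e) NULL),
    "per-channel")
})

test_that("selection results serialise with 0-based indices and stats", {
  ds <- smallSplitSet()
  res <- ficssSelect(ds, p = 6)
  path <- withr::local_tempfile(fileext = ".json")
  writeSelectionResult(res, path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(raw$channels_0based, selectedChannels(res) - 1L)
  back <- readSelectionResult(path)
  expect_identical(selectedChannels(back), selectedChannels(res))
  expect_equal(back@stats$nfw, res@stats$nfw)
})
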