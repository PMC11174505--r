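# Shared fixtures, all built in code.

# Tiny deterministic dataset: k channels, n samples, m analytes.
tinySet <- function(n = 6, k = 5, m = 2, seed = 42) {
  withr::with_seed(seed, {
    A <- matrix(runif(n * k, 0.1, 0.9), n, k)
    Y <- matrix(runif(n * m, 0.5, 2), n, m,
                dimnames = list(NULL, paste0("an", seq_len(m))))
  })
  SpectralSet(wavenumbers = 4000 + 4 * (seq_len(k) - 1), absorbance = A,
              targets = Y)
}

# Small synthetic mixture with a split, cheap enough for selector tests:
# the reference chemistry on a reduced grid is not available (bands are
# grid-anchored), so this builds a fresh two-analyte scenario.
smallScenario <- function(n = 40, nch = 120, noise = 0.002) {
  # band placement scales with the grid; at the default nch = 120 each band
  # is contained in a single 20-channel screening interval (channels 21-40
  # and 61-80 for a 6-way partition), mirroring the reference scenario's
  # interval-contained band layout
  cA <- 4000 + 4 * round(0.252 * (nch - 1))
  cB <- 4000 + 4 * round(0.588 * (nch - 1))
  span <- 4 * (nch - 1)
  new("SyntheticScenario",
      nSamples = as.integer(n), wnStart = 4000, wnStep = 4,
      nChannels = as.integer(nch),
      analyteNames = c("A", "B"),
      bands = list(
        A = data.frame(center = cA, sigma = max(4, 0.025 * span), height = 0.5),
        B = data.frame(center = cB, sigma = max(4, 0.021 * span), height = 0.3)),
      concMean = c(1, 2), concSd = c(0.2, 0.4),
      concCor = matrix(c(1, 0.3, 0.3, 1), 2),
      baseline = c(0.05, 0.02, 0.01),
      responseCurvature = 0, noiseSd = noise, scatterSd = 0,
      seed = 1L)
}

smallSplitSet <- function(seed = 5, ...) {
  g <- generateSpectra(smallScenario(...), seed = seed)
  splitCalibrationPrediction(g$dataset, seed = seed)
}
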