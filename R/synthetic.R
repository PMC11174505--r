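#' SyntheticScenario: configuration for NIR-like mixture spectra
#'
#' Describes a Beer-Lambert mixture experiment with known ground truth: a
#' regular wavenumber grid, per-analyte Gaussian absorption bands (the unit
#' spectra), a correlated concentration distribution truncated at zero, an
#' optional concave per-analyte response, a gentle polynomial baseline, an
#' optional per-sample multiplicative scatter gain, and iid Gaussian noise.
#'
#' @slot nSamples number of samples to draw.
#' @slot wnStart,wnStep,nChannels wavenumber grid: `wnStart + wnStep * (0:(nChannels-1))` cm^-1.
#' @slot analyteNames analyte labels.
#' @slot bands list (one element per analyte) of data.frames with columns
#'   `center` (cm^-1), `sigma` (cm^-1) and `height` (absorbance per unit
#'   concentration).
#' @slot concMean,concSd concentration distribution parameters.
#' @slot concCor symmetric positive-definite correlation matrix.
#' @slot baseline coefficients (c0, c1, c2) of a quadratic baseline in the
#'   normalised wavenumber u in \[0, 1\]: `c0 + c1*u + c2*u^2`.
#' @slot responseCurvature curvature `t >= 0` of the per-analyte concave
#'   response: the effective contribution of analyte a is
#'   `mu_a + sd_a * psi_t((c_a - mu_a)/sd_a)` with
#'   `psi_t(z) = (1 - exp(-t z))/t`, a monotone saturating map with unit
#'   slope at the mean (`t = 0` is the identity, i.e. exact Beer-Lambert
#'   proportionality), floored at zero so a low-concentration tail sample
#'   cannot contribute negative absorbance. This emulates the blunted absorbance response of
#'   strongly absorbing, self-associating constituents and is what makes
#'   the concentration-absorbance relationship genuinely nonlinear for a
#'   linear calibration model: no linear functional of the spectra can
#'   exceed R-squared = t^2/(exp(t^2) - 1) for any analyte.
#' @slot noiseSd SD of iid Gaussian absorbance noise.
#' @slot scatterSd SD of the per-sample log-normal multiplicative scatter
#'   gain. Ground powders measured in diffuse reflectance show sample-to-
#'   sample path-length variation that multiplies the whole spectrum; since
#'   the preprocessing chain applies only Savitzky-Golay smoothing (no
#'   SNV/MSC), this uncorrected gain is what makes the concentration-
#'   absorbance relationship nonlinear for a linear calibration model.
#'   `0` gives the exact linear Beer-Lambert mixture.
#' @slot seed default RNG seed for [generateSpectra()].
#' @export
setClass("SyntheticScenario", representation(
  nSamples = "integer",
  wnStart = "numeric",
  wnStep = "numeric",
  nChannels = "integer",
  analyteNames = "character",
  bands = "list",
  concMean = "numeric",
  concSd = "numeric",
  concCor = "matrix",
  baseline = "numeric",
  responseCurvature = "numeric",
  noiseSd = "numeric",
  scatterSd = "numeric",
  seed = "integer"
))

setValidity("SyntheticScenario", function(object) {
  msg <- character()
  k <- length(object@analyteNames)
  if (length(object@bands) != k) msg <- c(msg, "one band table per analyte required")
  wn_max <- object@wnStart + object@wnStep * (object@nChannels - 1L)
  for (b in object@bands) {
    if (!all(c("center", "sigma", "height") %in% colnames(b))) {
      msg <- c(msg, "band tables need columns center, sigma, height")
    } else if (any(b$center < object@wnStart | b$center > wn_max)) {
      msg <- c(msg, "band centers must lie inside the wavenumber grid")
    }
  }
  if (length(object@concMean) != k || length(object@concSd) != k) {
    msg <- c(msg, "concMean/concSd must have one entry per analyte")
  }
  cc <- object@concCor
  if (!isTRUE(all.equal(cc, t(cc))) ||
      min(eigen(cc, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    msg <- c(msg, "concCor must be symmetric positive-definite")
  }
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@scatterSd < 0) msg <- c(msg, "scatterSd must be >= 0")
  if (object@responseCurvature < 0) {
    msg <- c(msg, "responseCurvature must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticScenario", function(object) {
  cat("SyntheticScenario:", object@nSamples, "samples,",
      object@nChannels, "channels,",
      length(object@analyteNames), "analytes\n")
  cat(sprintf(
    "  grid %.0f..%.0f cm-1 step %g; noise SD %g; curvature %g; scatter SD %g\n",
    object@wnStart,
    object@wnStart + object@wnStep * (object@nChannels - 1L),
    object@wnStep, object@noiseSd, object@responseCurvature,
    object@scatterSd))
})

#' Reference synthetic scenario
#'
#' A frozen scenario emulating a multi-catechin NIR calibration study:
#' 105 samples on the 4000-9996 cm^-1 grid at 4 cm^-1 resolution (1500
#' channels); four analytes (EC, ECG, EGC, EGCG) whose absorption bands sit
#' in three regions (5500-6200, 6400-6700 and 8200-8500 cm^-1), with the
#' highest-wavenumber region shared by all four components (EC, ECG and
#' EGC contribute weak overtone bands on top of EGCG's main band there, the
#' classic severe-overlap situation); positive concentration correlations
#' with one near-zero pair (ECG-EGC, r = 0.098); concentration means and
#' spreads on the scale of percent dry mass, with EGCG and ECG the most
#' abundant; a gentle quadratic baseline; a concave per-analyte response
#' (see [SyntheticScenario-class]) that caps every linear calibration
#' model's attainable R-squared near 0.78 while leaving the map invertible
#' for nonlinear models; and iid absorbance noise.
#'
#' @param nSamples number of samples (default 105).
#' @param noiseSd absorbance noise SD (default 0.0015).
#' @param responseCurvature concave-response curvature (default 0.7;
#'   `0` for an exactly linear Beer-Lambert mixture).
#' @param scatterSd log-normal multiplicative scatter SD (default 0).
#' @param seed default generation seed.
#' @return a [SyntheticScenario-class].
#' @export
makeReferenceScenario <- function(nSamples = 105L, noiseSd = 0.0015,
                                  responseCurvature = 0.7, scatterSd = 0,
                                  seed = 20260101L) {
  band <- function(...) {
    m <- matrix(c(...), ncol = 3L, byrow = TRUE)
    data.frame(center = m[, 1L], sigma = m[, 2L], height = m[, 3L])
  }
  cn <- c("EC", "ECG", "EGC", "EGCG")
  cc <- matrix(c(
    1.000, 0.300, 0.250, 0.350,
    0.300, 1.000, 0.098, 0.300,
    0.250, 0.098, 1.000, 0.200,
    0.350, 0.300, 0.200, 1.000), 4L, 4L, dimnames = list(cn, cn))
  new("SyntheticScenario",
    nSamples = as.integer(nSamples),
    wnStart = 4000, wnStep = 4, nChannels = 1500L,
    analyteNames = cn,
    bands = list(
      EC   = band(5620, 40, 0.45,    8390, 25, 0.0025),
      ECG  = band(5920, 40, 0.12,    8430, 20, 0.0008),
      EGC  = band(6520, 40, 0.17,    8260, 25, 0.0008),
      EGCG = band(8320, 40, 0.045)
    ),
    concMean = c(0.8, 3.0, 2.0, 8.0),
    concSd = c(0.065, 0.55, 0.85, 2.0),
    concCor = cc,
    baseline = c(0.05, 0.03, 0.02),
    responseCurvature = responseCurvature,
    noiseSd = noiseSd,
    scatterSd = scatterSd,
    seed = as.integer(seed)
  )
}

#' Evaluate a scenario's unit spectra on its grid
#'
#' @param scenario a [SyntheticScenario-class].
#' @return analytes x channels matrix of unit-concentration absorbance.
#' @export
scenarioUnitSpectra <- function(scenario) {
  wn <- scenario@wnStart + scenario@wnStep * (seq_len(scenario@nChannels) - 1L)
  S <- t(vapply(scenario@bands, function(b) {
    rowSums(vapply(seq_len(nrow(b)), function(i) {
      b$height[i] * exp(-(wn - b$center[i])^2 / (2 * b$sigma[i]^2))
    }, numeric(length(wn))))
  }, numeric(length(wn))))
  rownames(S) <- scenario@analyteNames
  S
}

#' Generate a synthetic mixture dataset with ground truth
#'
#' Draws concentrations from a correlated Gaussian truncated at zero
#' (rejection sampling), applies the scenario's concave per-analyte
#' response, forms the Beer-Lambert mixture
#' `A = response(concentrations) x unit_spectra + baseline`, multiplies
#' each sample's spectrum by its log-normal scatter gain, and adds iid
#' Gaussian noise. With `responseCurvature = 0` and `scatterSd = 0` the
#' mixture is exactly linear in the concentrations. The
#' informative-channel mask marks channels where the total unit absorbance
#' exceeds 1% of its maximum.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param seed RNG seed; defaults to the scenario's own.
#' @return list with elements `dataset` (a [SpectralSet-class], split
#'   unassigned), `unitSpectra` (analytes x channels),
#'   `informative` (logical mask per channel), and `concentrations`.
#' @importFrom MASS mvrnorm
#' @export
generateSpectra <- function(scenario, seed = scenario@seed) {
  validObject(scenario)
  n <- scenario@nSamples
  k <- length(scenario@analyteNames)
  wn <- scenario@wnStart + scenario@wnStep * (seq_len(scenario@nChannels) - 1L)
  S <- scenarioUnitSpectra(scenario)
  Sigma <- diag(scenario@concSd) %*% scenario@concCor %*% diag(scenario@concSd)
  dat <- withr::with_seed(seed, {
    C <- MASS::mvrnorm(n, mu = scenario@concMean, Sigma = Sigma)
    for (iter in seq_len(1000L)) {
      bad <- which(apply(C, 1L, function(r) any(r < 0)))
      if (!length(bad)) break
      C[bad, ] <- MASS::mvrnorm(length(bad), mu = scenario@concMean,
                                Sigma = Sigma)
      if (is.null(dim(C[bad, , drop = FALSE]))) C[bad, ] <- t(C[bad, ])
    }
    C[C < 0] <- 0  # pathological tails after capped rejection
    E <- matrix(stats::rnorm(n * length(wn), sd = scenario@noiseSd),
                n, length(wn))
    gain <- exp(stats::rnorm(n, 0, scenario@scatterSd))
    list(C = C, E = E, gain = gain)
  })
  colnames(dat$C) <- scenario@analyteNames
  u <- (wn - min(wn)) / (max(wn) - min(wn))
  bl <- scenario@baseline[1] + scenario@baseline[2] * u +
    scenario@baseline[3] * u^2
  t_curv <- scenario@responseCurvature
  Fm <- dat$C
  if (t_curv > 0) {
    for (a in seq_len(k)) {
      z <- (dat$C[, a] - scenario@concMean[a]) / scenario@concSd[a]
      # floor at zero: psi is unbounded below, but an effective
      # contribution cannot absorb negatively
      Fm[, a] <- pmax(0, scenario@concMean[a] +
                        scenario@concSd[a] * (1 - exp(-t_curv * z)) / t_curv)
    }
  }
  A <- Fm %*% S
  A <- sweep(A, 2L, bl, `+`)
  A <- A * dat$gain
  A <- A + dat$E
  tot <- colSums(S)
  ds <- SpectralSet(wavenumbers = wn, absorbance = A, targets = dat$C)
  list(dataset = ds, unitSpectra = S,
       informative = tot > 0.01 * max(tot),
       concentrations = dat$C)
}
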