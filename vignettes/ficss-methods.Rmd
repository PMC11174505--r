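---
title: "FIC-SS wavelength selection and ELM calibration: methods and validation"
author: "ficss package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FIC-SS wavelength selection and ELM calibration: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the calibration
model and the selection algorithm, their assumptions and tunable
parameters, the design of the synthetic validation scenario, the numerical
choices underneath, and — importantly — what the passing test suite does
and does not establish.

# The calibration problem

Near-infrared spectra of multi-component mixtures are dominated by broad,
overlapping overtone and combination bands. When several analytes share
functional groups (the four tea catechins EC, ECG, EGC and EGCG are the
motivating case), no channel is specific to one analyte, concentrations
are positively correlated across samples, and most of a 1500-channel
spectrum carries only baseline and noise. Two consequences drive the
package design:

* **Wavelength selection matters.** Full-spectrum models average signal
  with noise; models built on a few informative intervals are both more
  accurate and more interpretable.
* **The response is not exactly linear.** Instrument and matrix effects
  blunt the concentration–absorbance relationship, capping what any
  linear model (PLS included) can achieve; a modestly nonlinear regressor
  can recover the remainder.

The data model is a `SpectralSet` (extending
`SummarizedExperiment`: channels are rows/features, samples are columns;
the accessors `absorbance()` and `targets()` return the
samples × variables orientation the modelling code uses). Invariants —
strictly increasing wavenumbers, finite absorbances, finite non-negative
targets, a calibration/prediction split label per sample — are enforced by
the S4 validity method.

# FIC-SS: feature interval combination with sensitivity segmentation

`ficssSelect()` composes six deterministic steps (no RNG anywhere in the
selector; cross-validation folds are assigned by a fixed venetian-blind
rule):

**Step 1 — global thresholds.** A full-spectrum PLS2 model (SIMPLS) is
cross-validated on the calibration set; the number of latent variables is
the CV minimiser of the aggregate scaled RMSE. Its per-analyte RMSECV and
Rcv² become the screening thresholds (`globalThresholds()`).

**Step 2 — partition.** The axis is cut into `p` equal-width
sub-intervals (`partitionSpectrum()`, default `p = 20`; any remainder goes
to the leading intervals, widths differ by at most one channel).

**Step 3 — screening.** Each interval gets a local PLS model (its own
CV-chosen component count). The interval survives when its *calibration
fit* beats the *global cross-validated* thresholds — RMSEC ≤ global
RMSECV **and** Rc² ≥ global Rcv², with ties passing — for at least one
analyte. Comparing a local fit statistic against a global CV statistic is
deliberate: an interval containing a real band fits its analyte tightly
and passes with margin, while a noise interval cannot even *fit* the
concentrations as well as the global model *predicts* them.

**Steps 4–5 — exhaustive combination.** All `2^q − 1` non-empty subsets
of the `q` survivors are enumerated (`combineIntervals()`); each subset's
union of channels is scored by CV aggregate scaled RMSE, and the minimum
wins. Ties break to fewer channels, then lexicographically, so the result
is reproducible to the bit. `q` is capped (default 12, i.e. 4095 fits);
more survivors than the cap keeps the best-scoring `q_cap` individually.

**Step 6 — sensitivity segmentation.** Per-analyte *unit spectra* (the
absorbance per unit concentration) are estimated from the calibration data
by classical least squares with a non-negativity constraint
(`estimateUnitSpectra()`; an intercept column absorbs the additive
baseline). The sensitivity factor of analyte *i* at channel λ is

$$\alpha_i(\lambda) = \frac{A_i(\lambda)}{\sum_j A_j(\lambda)},$$

the fraction of the total unit absorbance owned by analyte *i*
(`sensitivityFactors()`; columns sum to 1 wherever anything absorbs). For
each interval of the optimal combination, a channel is retained when some
*target* analyte's α reaches the analyte's interval mean ᾱ (ties keep;
an analyte with ᾱ = 0 never absorbs in the interval and cannot retain
channels). This prunes interferent-dominated and non-absorbing channels
that the equal-width partition swept in.

A consequence worth knowing: when *all* analytes in the profile are
targets, the keep-if-any rule is nearly a no-op at absorbing channels —
because the α's sum to 1, at least one analyte is always at or above its
interval mean. Segmentation bites when the target set is a strict subset
of the absorbers (the practical case: baselines and interferents absorb
too, and their absorbance enters the α denominator through the estimated
profile) or when channels absorb nothing at all.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `p` | 20 | number of equal-width screening intervals |
| `q_cap` | 12 | cap on intervals entering the exhaustive search |
| `screener` | `plsScreener()` | PLS CV configuration: 5 folds, up to 10 components |
| `intercept` | `TRUE` | intercept column in the unit-spectra regression |
| `analytes` | all | target analytes for the segmentation stage |

`p` trades resolution against stability: wide intervals (small `p`) are
screened reliably but drag neighbours in; narrow intervals approach
per-channel selection and inherit its variance (the degenerate
`p = nChannels` case warns). The default 20 makes 75-channel intervals on
the 1500-channel grid — wide enough for a whole band, narrow enough that
the combination stage has real choices.

# The regressors

**PLS** is implemented as SIMPLS (`plsFit()`), multi-response, components
chosen by deterministic 5-fold CV; it doubles as the screening engine and
the full-spectrum baseline. At full rank it reproduces the OLS solution,
which the tests exploit as an oracle.

**ELM** (`elmFit()`) is a single-hidden-layer network: input weights and
biases drawn from U[−1, 1] under an explicit seed, sigmoid activations,
and output weights solved in closed form as the minimum-norm least-squares
solution `pinv(H) %*% C`. One network carries all analytes (one output
neuron each). Two protocol details matter in practice:

* *Input scaling.* With 1500 raw-absorbance inputs the random
  pre-activations have standard deviation in the tens and the sigmoid
  saturates. Inputs are therefore centred and Pareto-scaled (divided by
  the square root of the channel SD) with the total input variance
  normalised to 1. Pareto scaling is the usual chemometric compromise:
  z-scoring would amplify bare-noise channels to unit variance, no scaling
  would let the strongest band crowd weak analyte bands out of the random
  projections.
* *Stability.* A single random draw on a 35-sample prediction set is
  noisy, so `trainEvaluate()` selects the hidden-node count on a small
  grid by cross-validation and averages the predictions of a committee of
  networks (default 10 seeds). `elmSelectHiddenNodes()` implements the
  fuller conventional search (4–40 nodes, step 2, 50 random restarts).

# Figures of merit

`rmse()`, `rSquared()`, `rpd()` and `selectionStats()` implement the
reporting conventions: RPD is computed as $1/\sqrt{1 - R^2}$, the
algebraic identity linking the two when R² is taken against the reference
variance; NFW counts selected wavelengths, NWI the contiguous runs, and
AWIW = NFW/NWI the average interval width.

# Baseline selectors

* **CARS** (`carsSelect()`): Monte-Carlo sampling with an exponentially
  decreasing forced-retention schedule (from all channels down to 2) and
  adaptive reweighted sampling on PLS coefficient magnitudes; the
  iteration with the best CV RMSE wins.
* **MC-UVE** (`mcuveSelect()`): the stability of each channel's PLS
  coefficient (mean/SD over Monte-Carlo subsamples) is compared against
  artificial noise channels; channels above the noise-stability quantile
  are kept. The component count is cross-validated *before* the noise
  augmentation — fixing it large lets the overlapping subsamples overfit
  the same noise columns consistently and destroys the separation.
* **SPA** (`spaSelect()`): chains of successive orthogonal projections
  from several evenly spaced starting channels, scored by MLR CV; selects
  minimally collinear subsets.

All selectors return the same `SelectionResult` (1-based channels
in memory, 0-based in the JSON serialisation, with NFW/NWI/AWIW and
per-stage provenance), so they are interchangeable downstream.

# The synthetic validation scenario

Real multi-catechin NIR data is not freely available, so validation rests
on a generator (`makeReferenceScenario()`, `generateSpectra()`) with full
ground truth: known unit spectra, known informative channels, known
concentrations. Its defaults are frozen study conditions, not knobs:

* **Grid and size:** 1500 channels, 4000–9996 cm⁻¹ at 4 cm⁻¹; 105
  samples split 2:1 (70 calibration / 35 prediction).
* **Bands:** Gaussian bands in three regions (5500–6200, 6400–6700,
  8200–8500 cm⁻¹). Each of EC, ECG, EGC has one strong specific band;
  the 8200–8500 cm⁻¹ region is shared by all four analytes — EGCG's only
  band sits there underneath weak EC/ECG/EGC overtones, reproducing the
  severe-overlap situation that motivates sensitivity segmentation. Each
  main band is contained in a single default screening interval, so every
  informative interval is indispensable to some analyte.
* **Concentrations:** correlated Gaussian truncated at zero (rejection
  sampling), positive correlations with one near-zero pair
  (ECG–EGC, r = 0.098); means and spreads on the percent-dry-mass scale
  with EGCG most abundant.
* **Nonlinearity:** a concave per-analyte response. Analyte *a*
  contributes $\mu_a + \sigma_a\,\psi_t\!\big((c_a-\mu_a)/\sigma_a\big)$
  with $\psi_t(z) = (1 - e^{-tz})/t$ — monotone, unit slope at the mean,
  floored at zero so a deep low-concentration tail cannot absorb
  negatively; `t = 0` is the exact linear Beer–Lambert mixture. The
  transform acts on the *analyte*, not the channel, so a linear model
  cannot undo it by recombining channels: for curvature `t`, no linear
  functional of the spectra can exceed $R^2 = t^2/(e^{t^2}-1)$ for that
  analyte (≈ 0.78 at the default `t = 0.7`). This is the mechanism that
  separates ELM from PLS in the benchmark. Simpler mechanisms were
  rejected: per-channel saturation is defeated by linear recombination
  of channels sitting at different absorbance levels, and multiplicative
  scatter is corrected implicitly by the global model via baseline
  channels, which breaks interval screening for the wrong reason.
* **Baseline and noise:** a gentle quadratic baseline and iid Gaussian
  absorbance noise. The noise SD (0.0015) is the one generator parameter
  calibrated to a specification rather than frozen a priori: it is chosen
  so that full-spectrum PLS prediction R² lands in 0.7–0.85 per analyte,
  the regime where wavelength selection and nonlinear calibration have
  something to gain.

# What the passing tests establish — and what they do not

The acceptance suite (`tests/testthat/test-acceptance.R`) checks:

1. *Metric identities* — `rpd()` reproduces, to 2 decimal places, every
   (R², RPD) pair in the reference comparison tables, and
   `selectionStats()` reproduces the reported AWIW values from their
   NFW/NWI shapes. This validates the formulas, exactly.
2. *Oracle equivalence* — ELM output weights equal the explicit SVD
   least-squares solution; PLS at full rank equals OLS; the SG filter
   passes polynomials of degree ≤ `polyorder` untouched. This validates
   the numerical cores against independent implementations.
3. *Ground-truth recovery* — over 10 seeds of the reference scenario,
   FIC-SS recovers a median ≥ 80% of planted informative channels with
   ≤ 10% contamination from pure-noise channels, and unit spectra are
   recovered to < 5% relative error at zero noise.
4. *Comparative pattern* — median prediction R² ordering FIC-SS-ELM ≥
   full-spectrum ELM ≥ full-spectrum PLS for every analyte, and every
   selector's ELM at or above full-spectrum PLS, over 10 seeds.
5. *Combinatorial exactness* — the combination stage enumerates exactly
   `2^q − 1` subsets and attains the exhaustive minimum.
6. *Normalisation* — sensitivity factors sum to 1 at every absorbing
   channel.

What they do **not** establish: the headline black-tea accuracies. Those
were measured on spectra and HPLC references that are available on request
only, and no synthetic scenario can certify performance on data it was not
built from. The suite shows that the *algorithms are implemented
correctly* (identities, oracles, exactness) and that the *qualitative
claims hold* on a mixture model engineered to have the same difficulty
profile (overlap, correlation, mild nonlinearity, realistic noise) — not
that the same numbers would be obtained on tea.

# Numerical and protocol choices

* **SIMPLS, implemented in-package** — deterministic, multi-response, and
  dependency-light; one decomposition yields all component counts for the
  CV sweep, which the interval screener calls thousands of times.
* **Deterministic CV folds** (venetian blinds, `rep_len(1:k, n)`) — makes
  every selector stage reproducible without seed bookkeeping.
* **Pseudoinverse tolerance** — singular values below `1e-10` of the
  largest are treated as zero in the ELM solve, matching the oracle test.
* **Exact serialisation** — model and dataset round trips are bit-exact:
  JSON numerics are written with 17 significant digits and CSV numerics
  as `%.17g` strings (both formats round-trip IEEE doubles exactly; the
  general-purpose writers default to 15 digits, which does not).
* **Scaled-down problem sizes in tests** — the unit suites run on a
  two-analyte, 120-channel scenario and the acceptance suite uses 10
  seeds, 500 MC-UVE runs scaled down where statistically safe. These
  sizes are this package's own testing choices, made to keep the default
  suite inside a practical time budget; the reference scenario itself is
  never shrunk in the acceptance criteria that cite it.

# Limitations

* The screening rule compares a fit statistic with a CV statistic; on
  datasets where the global model is extremely strong (many redundant
  informative channels), informative-but-partial intervals can sit near
  the threshold. Band-in-one-interval layouts are the friendly case.
* Exhaustive combination is exponential in the survivor count; `q_cap`
  bounds the cost but makes the search greedy above the cap.
* The ELM's accuracy on small prediction sets has genuine random-draw
  variance; the committee protocol reduces but does not eliminate it.
* The generator emulates overlap, correlation, baseline, noise and a
  concave response — not instrument physics (wavelength jitter, detector
  nonlinearity, scatter needing MSC/SNV).

# Session info

```{r, eval = TRUE}
sessionInfo()
```
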