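#' SpectralSet: a multi-analyte NIR spectral dataset
#'
#' `SpectralSet` extends [SummarizedExperiment::SummarizedExperiment] to hold
#' an absorbance matrix on a regular wavenumber grid together with per-sample
#' analyte concentrations and a calibration/prediction split. Following the
#' Bioconductor convention, spectral channels are rows (features) and samples
#' are columns; the user-facing accessors [absorbance()] and [targets()]
#' return matrices in the samples-by-variables orientation used by the
#' modelling functions.
#'
#' @slot analyteNames character vector naming the target analyte columns
#'   (for tea catechins typically EC, ECG, EGC, EGCG).
#'
#' @details
#' Invariants enforced by the validity method:
#' * wavenumbers (rowData column `wavenumber`, cm^-1) strictly increasing;
#' * absorbance values all finite;
#' * targets finite and non-negative;
#' * the `split` column, when set, only contains `"calibration"`,
#'   `"prediction"` or `NA`.
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @import methods
#' @export
setClass("SpectralSet",
  contains = "SummarizedExperiment",
  slots = c(analyteNames = "character")
)

setValidity("SpectralSet", function(object) {
  msg <- character()
  wn <- SummarizedExperiment::rowData(object)$wavenumber
  if (is.null(wn)) {
    msg <- c(msg, "rowData must contain a 'wavenumber' column")
  } else {
    if (any(!is.finite(wn))) msg <- c(msg, "wavenumbers must be finite")
    if (length(wn) > 1L && any(diff(wn) <= 0)) {
      msg <- c(msg, "wavenumbers must be strictly increasing")
    }
  }
  a <- SummarizedExperiment::assay(object, "absorbance")
  if (any(!is.finite(a))) msg <- c(msg, "absorbance values must be finite")
  tn <- object@analyteNames
  cd <- SummarizedExperiment::colData(object)
  if (!all(tn %in% colnames(cd))) {
    msg <- c(msg, "all analyteNames must be columns of colData")
  } else if (length(tn)) {
    tm <- as.matrix(as.data.frame(cd[, tn, drop = FALSE]))
    if (any(!is.finite(tm))) msg <- c(msg, "targets must be finite")
    if (any(tm < 0)) msg <- c(msg, "targets must be non-negative")
  }
  if ("split" %in% colnames(cd)) {
    sp <- cd$split
    if (!all(is.na(sp) | sp %in% c("calibration", "prediction"))) {
      msg <- c(msg, "split labels must be 'calibration' or 'prediction'")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpectralSet
#'
#' @param wavenumbers numeric vector of channel positions in cm^-1, strictly
#'   increasing.
#' @param absorbance numeric matrix, samples x channels.
#' @param targets numeric matrix or data frame, samples x analytes,
#'   non-negative concentrations.
#' @param sampleIds optional character vector of unique sample labels;
#'   defaults to `rownames(absorbance)` or `sample_1`, `sample_2`, ...
#' @param split optional character vector of `"calibration"`/`"prediction"`
#'   labels (or `NA` for unassigned).
#'
#' @return a [SpectralSet-class] object.
#' @examples
#' ss <- SpectralSet(
#'   wavenumbers = c(4000, 4004, 4008),
#'   absorbance = matrix(runif(6), 2, 3),
#'   targets = cbind(EC = c(0.5, 0.7), ECG = c(2.1, 2.6))
#' )
#' nChannels(ss)
#' @export
SpectralSet <- function(wavenumbers, absorbance, targets,
                        sampleIds = NULL, split = NULL) {
  absorbance <- as.matrix(absorbance)
  if (is.data.frame(targets)) targets <- as.matrix(targets)
  if (is.null(dim(targets))) targets <- cbind(target = targets)
  if (nrow(absorbance) != nrow(targets)) {
    stop("absorbance and targets must have one row per sample")
  }
  if (ncol(absorbance) != length(wavenumbers)) {
    stop("absorbance must have one column per wavenumber")
  }
  if (is.null(colnames(targets))) {
    colnames(targets) <- paste0("analyte_", seq_len(ncol(targets)))
  }
  if (is.null(sampleIds)) {
    sampleIds <- rownames(absorbance)
    if (is.null(sampleIds)) {
      sampleIds <- paste0("sample_", seq_len(nrow(absorbance)))
    }
  }
  if (anyDuplicated(sampleIds)) stop("sample ids must be unique")
  # dimnames are carried by rowData/colData only, so accessors return the
  # same dimnames regardless of how the input matrix was labelled
  dimnames(absorbance) <- NULL
  if (is.null(split)) split <- rep(NA_character_, nrow(absorbance))
  cd <- S4Vectors::DataFrame(targets, split = split, row.names = sampleIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(absorbance = t(absorbance)),
    rowData = S4Vectors::DataFrame(wavenumber = as.numeric(wavenumbers)),
    colData = cd
  )
  new("SpectralSet", se, analyteNames = colnames(targets))
}

#' @describeIn SpectralSet number of samples.
#' @param x a `SpectralSet`.
#' @export
nSamples <- function(x) ncol(x)

#' @describeIn SpectralSet number of spectral channels.
#' @export
nChannels <- function(x) nrow(x)

#' Accessors for SpectralSet components
#'
#' @param x a [SpectralSet-class].
#' @return `wavenumbers()` the numeric grid (cm^-1); `absorbance()` the
#'   samples x channels absorbance matrix; `targets()` the samples x analytes
#'   concentration matrix; `analyteNames()` / `sampleIds()` the labels;
#'   `splitLabels()` the per-sample split assignment.
#' @name SpectralSet-accessors
NULL

#' @rdname SpectralSet-accessors
#' @export
wavenumbers <- function(x) SummarizedExperiment::rowData(x)$wavenumber

#' @rdname SpectralSet-accessors
#' @export
absorbance <- function(x) t(SummarizedExperiment::assay(x, "absorbance"))

#' @rdname SpectralSet-accessors
#' @export
targets <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  m <- as.matrix(as.data.frame(cd[, x@analyteNames, drop = FALSE]))
  rownames(m) <- rownames(cd)
  m
}

#' @rdname SpectralSet-accessors
#' @export
analyteNames <- function(x) x@analyteNames

#' @rdname SpectralSet-accessors
#' @export
sampleIds <- function(x) colnames(x)

#' @rdname SpectralSet-accessors
#' @export
splitLabels <- function(x) {
  sp <- SummarizedExperiment::colData(x)$split
  stats::setNames(as.character(sp), colnames(x))
}

#' @rdname SpectralSet-accessors
#' @param value replacement split labels.
#' @export
`splitLabels<-` <- function(x, value) {
  stopifnot(length(value) == ncol(x))
  SummarizedExperiment::colData(x)$split <- as.character(value)
  validObject(x)
  x
}

#' Subset a SpectralSet to one side of the calibration/prediction split
#'
#' @param x a [SpectralSet-class] with split labels assigned.
#' @return the samples belonging to the requested set.
#' @seealso [splitCalibrationPrediction()]
#' @export
calibrationSet <- function(x) {
  sp <- splitLabels(x)
  if (all(is.na(sp))) stop("no split assigned; run splitCalibrationPrediction() first")
  x[, which(sp == "calibration")]
}

#' @rdname calibrationSet
#' @export
predictionSet <- function(x) {
  sp <- splitLabels(x)
  if (all(is.na(sp))) stop("no split assigned; run splitCalibrationPrediction() first")
  x[, which(sp == "prediction")]
}

#' Restrict a SpectralSet to a subset of spectral channels
#'
#' @param x a [SpectralSet-class].
#' @param channels integer indices into the wavenumber grid (1-based).
#' @return a `SpectralSet` containing only the requested channels, order
#'   preserved along the grid.
#' @export
selectChannels <- function(x, channels) {
  channels <- sort(unique(as.integer(channels)))
  if (length(channels) == 0L) stop("empty channel selection")
  if (any(channels < 1L | channels > nrow(x))) stop("channel index out of range")
  x[channels, ]
}

setMethod("show", "SpectralSet", function(object) {
  wn <- wavenumbers(object)
  sp <- splitLabels(object)
  cat("SpectralSet:", ncol(object), "samples x", nrow(object), "channels\n")
  if (length(wn)) {
    cat(sprintf("  wavenumbers: %.0f..%.0f cm-1 (step %.4g)\n",
                min(wn), max(wn), if (length(wn) > 1) wn[2] - wn[1] else NA))
  }
  cat("  analytes:", paste(analyteNames(object), collapse = ", "), "\n")
  if (any(!is.na(sp))) {
    cat(sprintf("  split: %d calibration / %d prediction\n",
                sum(sp == "calibration", na.rm = TRUE),
                sum(sp == "prediction", na.rm = TRUE)))
  } else {
    cat("  split: unassigned\n")
  }
})
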