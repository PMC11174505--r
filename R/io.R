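#' Read a SpectralSet from paired CSV files
#'
#' The spectra file has one header row `sample_id,<wn_1>,...,<wn_K>` with
#' wavenumbers (cm^-1) as numeric column headers and one row per sample.
#' The targets file is `sample_id,<analyte>,...` with one concentration
#' column per analyte. Rows are aligned by sample id; the ordering of the
#' spectra file is preserved. An optional `split` column in the targets file
#' is honoured.
#'
#' @param spectraPath path to the spectra CSV.
#' @param targetsPath path to the targets CSV.
#' @return a [SpectralSet-class].
#' @importFrom data.table fread fwrite
#' @export
readSpectralSet <- function(spectraPath, targetsPath) {
  sp <- data.table::fread(spectraPath, header = TRUE, data.table = FALSE)
  tg <- data.table::fread(targetsPath, header = TRUE, data.table = FALSE)
  if (colnames(sp)[1] != "sample_id" || colnames(tg)[1] != "sample_id") {
    stop("first column of both CSV files must be 'sample_id'")
  }
  wn <- suppressWarnings(as.numeric(colnames(sp)[-1]))
  if (any(is.na(wn))) {
    bad <- colnames(sp)[-1][is.na(wn)]
    stop("non-numeric wavenumber headers in spectra file: ",
         paste(utils::head(bad, 3), collapse = ", "))
  }
  ids <- as.character(sp$sample_id)
  missing <- setdiff(ids, as.character(tg$sample_id))
  extra <- setdiff(as.character(tg$sample_id), ids)
  if (length(missing) || length(extra)) {
    stop("sample id mismatch between spectra and targets files: ",
         if (length(missing)) paste("missing in targets:",
                                    paste(utils::head(missing, 3), collapse = ", ")),
         if (length(extra)) paste(" absent from spectra:",
                                  paste(utils::head(extra, 3), collapse = ", ")))
  }
  A <- as.matrix(sp[, -1, drop = FALSE])
  if (!is.numeric(A)) {
    bad <- which(!vapply(sp[-1], is.numeric, logical(1)))[1]
    stop("non-numeric absorbance values in spectra column '",
         colnames(sp)[-1][bad], "'")
  }
  tg <- tg[match(ids, as.character(tg$sample_id)), , drop = FALSE]
  split <- NULL
  if ("split" %in% colnames(tg)) {
    split <- as.character(tg$split)
    tg$split <- NULL
  }
  tmat <- as.matrix(tg[, -1, drop = FALSE])
  if (!is.numeric(tmat)) stop("non-numeric values in targets file")
  SpectralSet(wavenumbers = wn, absorbance = A, targets = tmat,
              sampleIds = ids, split = split)
}

#' Write a SpectralSet to paired CSV files
#'
#' Inverse of [readSpectralSet()]; the round trip is lossless at double
#' precision. The split assignment, when present, is written as a `split`
#' column of the targets file.
#'
#' @param x a [SpectralSet-class].
#' @param spectraPath,targetsPath output CSV paths.
#' @return invisibly, the two paths.
#' @export
writeSpectralSet <- function(x, spectraPath, targetsPath) {
  # 17 significant digits round-trip IEEE doubles exactly
  full <- function(m) {
    d <- as.data.frame(m)
    d[] <- lapply(d, function(v) sprintf("%.17g", v))
    d
  }
  sp <- data.frame(sample_id = sampleIds(x), full(absorbance(x)),
                   check.names = FALSE)
  colnames(sp) <- c("sample_id", format(wavenumbers(x), digits = 15, trim = TRUE))
  tg <- data.frame(sample_id = sampleIds(x), full(targets(x)),
                   check.names = FALSE)
  lab <- splitLabels(x)
  if (any(!is.na(lab))) tg$split <- unname(lab)
  data.table::fwrite(sp, spectraPath)
  data.table::fwrite(tg, targetsPath)
  invisible(c(spectraPath, targetsPath))
}

#' Convert reflectance to absorbance
#'
#' Applies the Beer-Lambert reflectance convention A = log10(1/R)
#' elementwise.
#'
#' @param R numeric vector or matrix of reflectances in (0, 1]. Values above
#'   1 are tolerated with a warning (they yield negative absorbance, which
#'   can arise from reference-beam drift); values <= 0 are an error.
#' @return absorbance of the same shape as `R`.
#' @examples
#' absorbanceFromReflectance(c(1, 0.1, 0.01))  # 0 1 2
#' @export
absorbanceFromReflectance <- function(R) {
  if (any(!is.finite(R)) || any(R <= 0)) {
    stop("reflectance values must be finite and strictly positive")
  }
  if (any(R > 1)) {
    warning(sum(R > 1), " reflectance value(s) exceed 1; ",
            "corresponding absorbances are negative")
  }
  log10(1 / R)
}
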