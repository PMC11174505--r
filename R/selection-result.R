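#' SelectionResult: a selected wavelength set with provenance
#'
#' Common return type of every wavelength selector ([ficssSelect()],
#' [carsSelect()], [mcuveSelect()], [spaSelect()]): the selected channel
#' indices, their wavenumbers, the selector name, a stage-by-stage
#' provenance list, and the NFW/NWI/AWIW selection statistics.
#'
#' @slot selected integer channel indices (1-based, sorted).
#' @slot wavenumbers the corresponding wavenumbers (cm^-1).
#' @slot method selector name.
#' @slot provenance list of per-stage intermediates.
#' @slot stats list with nfw, nwi, awiw (see [selectionStats()]).
#' @export
setClass("SelectionResult", representation(
  selected = "integer",
  wavenumbers = "numeric",
  method = "character",
  provenance = "list",
  stats = "list"
))

newSelectionResult <- function(selected, wn, method, provenance = list()) {
  selected <- sort(unique(as.integer(selected)))
  st <- selectionStats(selected, length(wn))
  new("SelectionResult", selected = selected,
      wavenumbers = wn[selected], method = method,
      provenance = provenance, stats = st)
}

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult (", object@method, "): ",
      object@stats$nfw, " wavelengths in ", object@stats$nwi,
      " intervals (AWIW ", sprintf("%.2f", object@stats$awiw), ")\n",
      sep = "")
})

#' @describeIn SelectionResult the selected channel indices (1-based).
#' @param x a `SelectionResult`.
#' @export
selectedChannels <- function(x) x@selected

#' Serialize / restore a SelectionResult as JSON
#'
#' Channel indices are written 0-based alongside their wavenumbers; the
#' stage provenance and the NFW/NWI/AWIW statistics are included.
#'
#' @param x a [SelectionResult-class].
#' @param path JSON path.
#' @return `writeSelectionResult` the path, invisibly;
#'   `readSelectionResult` the restored object.
#' @export
writeSelectionResult <- function(x, path) {
  obj <- list(
    method = x@method,
    channels_0based = x@selected - 1L,
    wavenumbers = x@wavenumbers,
    stats = x@stats,
    provenance = x@provenance
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeSelectionResult
#' @export
readSelectionResult <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  sel <- as.integer(o$channels_0based) + 1L
  new("SelectionResult", selected = sel,
      wavenumbers = as.numeric(o$wavenumbers),
      method = o$method,
      provenance = if (is.null(o$provenance)) list() else as.list(o$provenance),
      stats = lapply(o$stats, as.numeric))
}
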