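#' Accessors for flowSDC classes
#'
#' Small accessor generics: `exprs()` returns the event matrix of a
#' [CytoFrame-class]; `sampleId()` its identifier; `channels()` its
#' channel names; `nEvents()` its event count; `truthLabels()` its label
#' table. For a [CytoCohort-class], `frames()`, `sampleSheet()` and
#' `truthTable()` return the sample list, metadata and per-cell truth.
#' For a [SOMModel-class], `codebook()`, `gridDim()` and `somMarkers()`
#' expose the trained map. For a [GateSpec-class], `gateConstraints()`,
#' `gateF1()` and `markerImportanceScores()` expose the fitted gate.
#'
#' @param object A flowSDC object.
#' @return The corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprs", function(object) standardGeneric("exprs"))
#' @rdname accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("channels", function(object) standardGeneric("channels"))
#' @rdname accessors
#' @export
setGeneric("nEvents", function(object) standardGeneric("nEvents"))
#' @rdname accessors
#' @export
setGeneric("truthLabels", function(object) standardGeneric("truthLabels"))
#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("sampleSheet", function(object) standardGeneric("sampleSheet"))
#' @rdname accessors
#' @export
setGeneric("truthTable", function(object) standardGeneric("truthTable"))
#' @rdname accessors
#' @export
setGeneric("codebook", function(object) standardGeneric("codebook"))
#' @rdname accessors
#' @export
setGeneric("gridDim", function(object) standardGeneric("gridDim"))
#' @rdname accessors
#' @export
setGeneric("somMarkers", function(object) standardGeneric("somMarkers"))
#' @rdname accessors
#' @export
setGeneric("gateConstraints", function(object) standardGeneric("gateConstraints"))
#' @rdname accessors
#' @export
setGeneric("gateF1", function(object) standardGeneric("gateF1"))
#' @rdname accessors
#' @export
setGeneric("markerImportanceScores",
           function(object) standardGeneric("markerImportanceScores"))

#' @rdname accessors
#' @export
setMethod("exprs", "CytoFrame", function(object) object@exprs)
#' @rdname accessors
#' @export
setMethod("sampleId", "CytoFrame", function(object) object@sampleId)
#' @rdname accessors
#' @export
setMethod("channels", "CytoFrame", function(object) colnames(object@exprs))
#' @rdname accessors
#' @export
setMethod("nEvents", "CytoFrame", function(object) nrow(object@exprs))
#' @rdname accessors
#' @export
setMethod("truthLabels", "CytoFrame", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("frames", "CytoCohort", function(object) object@frames)
#' @rdname accessors
#' @export
setMethod("sampleSheet", "CytoCohort", function(object) object@sampleSheet)
#' @rdname accessors
#' @export
setMethod("truthTable", "CytoCohort", function(object) object@truth)
#' @rdname accessors
#' @export
setMethod("codebook", "SOMModel", function(object) object@codebook)
#' @rdname accessors
#' @export
setMethod("gridDim", "SOMModel", function(object) object@gridDim)
#' @rdname accessors
#' @export
setMethod("somMarkers", "SOMModel", function(object) object@markers)
#' @rdname accessors
#' @export
setMethod("gateConstraints", "GateSpec", function(object) object@constraints)
#' @rdname accessors
#' @export
setMethod("gateF1", "GateSpec", function(object) object@f1)
#' @rdname accessors
#' @export
setMethod("markerImportanceScores", "GateSpec",
          function(object) object@importance)

setMethod("show", "CytoFrame", function(object) {
  cat(sprintf("CytoFrame '%s': %d events x %d channels\n",
              object@sampleId, nrow(object@exprs), ncol(object@exprs)))
  if (!is.na(object@timeChannel))
    cat(" time channel:", object@timeChannel, "\n")
  if (ncol(object@labels))
    cat(" labels:", paste(names(object@labels), collapse = ", "), "\n")
})

setMethod("show", "CytoCohort", function(object) {
  ss <- object@sampleSheet
  cat(sprintf("CytoCohort: %d samples (%s)\n", length(object@frames),
              paste(sprintf("%s n=%d", names(table(ss$group)),
                            as.integer(table(ss$group))), collapse = ", ")))
  n <- vapply(object@frames, nEvents, integer(1))
  cat(sprintf(" events per sample: %d-%d\n", min(n), max(n)))
  if (nrow(object@truth)) cat(" ground truth available\n")
})

setMethod("show", "SOMModel", function(object) {
  cat(sprintf("SOMModel: %dx%d grid, %d markers, seed %s\n",
              object@gridDim[1], object@gridDim[2], length(object@markers),
              as.character(object@meta$seed %||% NA)))
})

setMethod("show", "GateSpec", function(object) {
  cat(sprintf("GateSpec for '%s': F1 = %.3f\n", object@target, object@f1))
  cs <- object@constraints
  if (!nrow(cs)) { cat(" (empty gate: all events pass)\n"); return(invisible()) }
  for (i in seq_len(nrow(cs)))
    cat(sprintf("  %s in [%s, %s]\n", cs$marker[i],
                formatC(cs$lower[i], digits = 4),
                formatC(cs$upper[i], digits = 4)))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
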