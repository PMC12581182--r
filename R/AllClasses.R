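#' @import methods
NULL

#' CytoFrame: one sample's event-level cytometry matrix
#'
#' Holds a cells x channels matrix of raw (untransformed) intensities for
#' a single sample, the name of the acquisition-time channel, and an
#' optional per-cell label table (ground truth for synthetic data).
#'
#' @slot exprs Numeric matrix, cells x channels, with unique column names.
#' @slot sampleId Single character sample identifier.
#' @slot timeChannel Name of the acquisition-time channel (or `NA`).
#' @slot labels A data.frame with one row per cell (possibly 0 columns).
#'
#' @export
setClass("CytoFrame",
  representation(exprs = "matrix", sampleId = "character",
                 timeChannel = "character", labels = "data.frame"))

setValidity("CytoFrame", function(object) {
  msg <- character(0)
  e <- object@exprs
  if (!is.numeric(e)) msg <- c(msg, "exprs must be a numeric matrix")
  cn <- colnames(e)
  if (is.null(cn) || anyDuplicated(cn) || any(!nzchar(cn)))
    msg <- c(msg, "exprs must have unique non-empty column names")
  if (any(is.nan(e))) msg <- c(msg, "exprs must not contain NaN")
  if (length(object@sampleId) != 1L)
    msg <- c(msg, "sampleId must be a single string")
  tc <- object@timeChannel
  if (length(tc) != 1L) msg <- c(msg, "timeChannel must be length 1")
  else if (!is.na(tc) && !is.null(cn) && !(tc %in% cn))
    msg <- c(msg, sprintf("timeChannel '%s' not among channels", tc))
  if (nrow(object@labels) && nrow(object@labels) != nrow(e))
    msg <- c(msg, "labels must have one row per event")
  if (length(msg)) msg else TRUE
})

#' Construct a CytoFrame
#'
#' @param exprs Cells x channels numeric matrix of raw intensities with
#'   column names.
#' @param sampleId Sample identifier.
#' @param timeChannel Name of the acquisition-time channel, or `NA` if
#'   absent.
#' @param labels Optional per-cell data.frame (e.g. synthetic truth).
#' @return A [CytoFrame-class] object.
#' @export
CytoFrame <- function(exprs, sampleId = "sample", timeChannel = NA_character_,
                      labels = data.frame()) {
  new("CytoFrame", exprs = exprs, sampleId = as.character(sampleId),
      timeChannel = as.character(timeChannel), labels = labels)
}

#' CytoCohort: a collection of samples with metadata and ground truth
#'
#' @slot frames Named list of [CytoFrame-class] objects, one per sample.
#' @slot sampleSheet data.frame with columns `sample_id` and `group`
#'   (plus any user columns); row order defines sample order.
#' @slot truth Per-cell ground-truth table for synthetic cohorts
#'   (columns `sample_id`, `cell`, `population`, `doublet`, `dead`,
#'   `anomaly`), empty for real data.
#' @slot latent Per-sample latent-factor table used by injected
#'   ligand-receptor couplings (empty if none).
#' @export
setClass("CytoCohort",
  representation(frames = "list", sampleSheet = "data.frame",
                 truth = "data.frame", latent = "data.frame"))

setValidity("CytoCohort", function(object) {
  msg <- character(0)
  if (!all(vapply(object@frames, is, logical(1), "CytoFrame")))
    msg <- c(msg, "frames must all be CytoFrame objects")
  ss <- object@sampleSheet
  if (!all(c("sample_id", "group") %in% names(ss)))
    msg <- c(msg, "sampleSheet needs 'sample_id' and 'group' columns")
  else {
    if (anyDuplicated(ss$sample_id))
      msg <- c(msg, "duplicate sample_id in sampleSheet")
    if (!identical(names(object@frames), as.character(ss$sample_id)))
      msg <- c(msg, "names(frames) must match sampleSheet$sample_id")
  }
  if (length(msg)) msg else TRUE
})

#' SOMModel: a trained self-organising map
#'
#' @slot codebook Nodes x markers weight matrix (row i = node i).
#' @slot gridDim Integer vector (rows, cols); nodes = rows * cols.
#' @slot markers Marker names used for training, in codebook column order.
#' @slot meta List of training metadata (epochs, radius schedule, learning
#'   rates, seed).
#' @export
setClass("SOMModel",
  representation(codebook = "matrix", gridDim = "integer",
                 markers = "character", meta = "list"))

setValidity("SOMModel", function(object) {
  msg <- character(0)
  if (length(object@gridDim) != 2L || any(object@gridDim < 1L))
    msg <- c(msg, "gridDim must be two positive integers")
  else if (nrow(object@codebook) != prod(object@gridDim))
    msg <- c(msg, "codebook rows must equal rows*cols of the grid")
  if (any(!is.finite(object@codebook)))
    msg <- c(msg, "codebook must be finite")
  if (ncol(object@codebook) != length(object@markers))
    msg <- c(msg, "codebook columns must match markers")
  if (length(msg)) msg else TRUE
})

#' GateSpec: an axis-aligned gate reproducing a population
#'
#' @slot constraints data.frame with columns `marker`, `lower`, `upper`
#'   (bounds may be `-Inf`/`Inf`), in the order they were added.
#' @slot f1 Achieved F1 score in `[0, 1]`.
#' @slot importance Named numeric vector: F1 drop when each gated
#'   marker's constraints are ignored, sorted decreasing.
#' @slot target Name of the gated population.
#' @export
setClass("GateSpec",
  representation(constraints = "data.frame", f1 = "numeric",
                 importance = "numeric", target = "character"))

setValidity("GateSpec", function(object) {
  msg <- character(0)
  cs <- object@constraints
  if (!all(c("marker", "lower", "upper") %in% names(cs)))
    msg <- c(msg, "constraints needs marker/lower/upper columns")
  else if (nrow(cs) && any(is.na(cs$lower) | is.na(cs$upper)))
    msg <- c(msg, "bounds must be finite or +-Inf, not NA")
  if (length(object@f1) != 1L || object@f1 < 0 || object@f1 > 1)
    msg <- c(msg, "f1 must be a single value in [0, 1]")
  if (length(object@importance) &&
      (any(object@importance < -1) || any(object@importance > 1)))
    msg <- c(msg, "importance values must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' CohortSpec: parameters of a synthetic cytometry cohort
#'
#' @slot groups data.frame with columns `group` and `n` (samples per
#'   group); at least two groups.
#' @slot cellsPerSample Positive integer, events drawn per sample before
#'   artefacts.
#' @slot markers Ordered unique marker names (excluding the time channel,
#'   which is always added).
#' @slot metaclusters Named list; each element has `proportions` (named
#'   per-group mixing weights summing to 1 across metaclusters within
#'   each group), `mean` and `sd` (named per-marker values on the
#'   transformed scale; unlisted markers fall back to a background
#'   level).
#' @slot couplings List of ligand-receptor couplings (see
#'   [lrCoupling()]).
#' @slot doubletFrac,deadFrac Artefact fractions in `[0, 1]`.
#' @slot anomalyWindows List of time-anomaly settings (see
#'   [simulateCohort()]).
#' @slot seed Integer seed; equal seeds give identical cohorts.
#' @export
setClass("CohortSpec",
  representation(groups = "data.frame", cellsPerSample = "integer",
                 markers = "character", metaclusters = "list",
                 couplings = "list", doubletFrac = "numeric",
                 deadFrac = "numeric", anomalyWindows = "list",
                 seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character(0)
  g <- object@groups
  if (!all(c("group", "n") %in% names(g)) || nrow(g) < 2L)
    msg <- c(msg, "at least 2 groups with columns 'group' and 'n'")
  if (object@cellsPerSample < 1L)
    msg <- c(msg, "cellsPerSample must be positive")
  if (anyDuplicated(object@markers))
    msg <- c(msg, "marker names must be unique")
  if (!length(object@metaclusters) || is.null(names(object@metaclusters)))
    msg <- c(msg, "metaclusters must be a named non-empty list")
  else if (all(c("group", "n") %in% names(g))) {
    for (grp in g$group) {
      pr <- vapply(object@metaclusters,
                   function(mc) unname(mc$proportions[[grp]]), numeric(1))
      if (any(pr < 0 | pr > 1))
        msg <- c(msg, sprintf("proportions for group '%s' outside [0,1]", grp))
      if (abs(sum(pr) - 1) > 1e-8)
        msg <- c(msg, sprintf("proportions for group '%s' do not sum to 1", grp))
    }
    for (mc in object@metaclusters)
      if (any(mc$sd <= 0)) msg <- c(msg, "metacluster sds must be > 0")
  }
  if (object@doubletFrac < 0 || object@doubletFrac > 1 ||
      object@deadFrac < 0 || object@deadFrac > 1)
    msg <- c(msg, "artefact fractions must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
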