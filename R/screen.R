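#' Median-fluorescence-intensity profiles per sample and population
#'
#' Per sample x population x marker median of the event intensities (on
#' the raw scale by default; `scale = "transformed"` applies the logicle
#' first). Populations represented by fewer than `minCells` cells in a
#' sample yield missing (`NA`) entries, never silent zeros; per-entry
#' cell counts are recorded.
#'
#' @param frames Named list of [CytoFrame-class] objects.
#' @param assignments data.frame with columns `sample_id` and
#'   `population`, one row per event of each frame, in event order
#'   (e.g. a cohort truth table, or SOM metacluster assignments).
#' @param markers Markers to profile (default: all shared non-time
#'   channels).
#' @param scale `"raw"` or `"transformed"`.
#' @param minCells Minimum cells per (sample, population) entry
#'   (default 10).
#' @param transform [logicleParams()] used when `scale = "transformed"`.
#' @return A long-format data.frame (`sample_id`, `population`,
#'   `marker`, `mfi`, `n`) of class `MCProfile` with attribute `scale`.
#' @export
medianProfile <- function(frames, assignments, markers = NULL,
                          scale = c("raw", "transformed"), minCells = 10,
                          transform = logicleParams()) {
  scale <- match.arg(scale)
  stopifnot(all(c("sample_id", "population") %in% names(assignments)))
  sids <- names(frames)
  markers <- markers %||% setdiff(channels(frames[[1]]),
                                  frames[[1]]@timeChannel)
  rows <- list()
  for (sid in sids) {
    e <- exprs(frames[[sid]])[, markers, drop = FALSE]
    if (scale == "transformed")
      e <- apply(e, 2, logicleTransform, p = transform)
    pop <- assignments$population[assignments$sample_id == sid]
    if (length(pop) != nrow(e))
      stop(sprintf("assignments do not cover all events of '%s'", sid))
    for (pp in sort(unique(assignments$population))) {
      idx <- which(pop == pp)
      med <- if (length(idx) >= minCells)
        apply(e[idx, , drop = FALSE], 2, stats::median)
      else rep(NA_real_, length(markers))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, population = pp, marker = markers,
        mfi = unname(med), n = length(idx), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "scale") <- scale
  class(out) <- c("MCProfile", "data.frame")
  out
}

.profileVector <- function(profile, population, marker) {
  sel <- profile$population == population & profile$marker == marker
  stats::setNames(profile$mfi[sel], profile$sample_id[sel])
}

# one screened pair: log-z both vectors over pairwise-complete samples,
# then signed dcor + permutation p
.screenPair <- function(x, y, nPerm, seed, minSamples = 4L) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < minSamples) return(NULL)
  xs <- as.numeric(logZScale(x[ok]))
  ys <- as.numeric(logZScale(y[ok]))
  sd <- signedDcor(xs, ys)
  p <- dcorPvalue(xs, ys, nPerm = nPerm, seed = seed)
  list(n = n, dcor = abs(as.numeric(sd)),
       pearson = attr(sd, "pearson"), signed = as.numeric(sd),
       p = as.numeric(p), method = attr(p, "method"))
}

#' Ligand-receptor communication screen
#'
#' For every catalogue axis and every (sender population, receiver
#' population) combination, correlates the sender's MFI of one partner
#' marker with the receiver's MFI of the other across samples - in both
#' orientations when both markers are measured on both populations'
#' panels (sender ligand vs receiver receptor, and sender receptor vs
#' receiver ligand). MFI vectors are log-transformed and z-normalised
#' before the calculation; association is scored by signed distance
#' correlation with a permutation p-value; pairs with `p < alpha` are
#' flagged significant and Benjamini-Hochberg adjusted p-values over
#' the whole screen are always reported. Axes whose markers are absent
#' from the profiles are skipped and listed in the `skipped` attribute.
#'
#' @param profile An `MCProfile` from [medianProfile()].
#' @param catalogue data.frame of `ligand`, `receptor` pairs (default
#'   [defaultLRCatalogue()]).
#' @param senders,receivers Population names to screen.
#' @param alpha Significance level on the raw permutation p (default
#'   0.05).
#' @param nPerm,seed Passed to [dcorPvalue()].
#' @param minSamples Minimum pairwise-complete samples per pair.
#' @return data.frame with columns `sender`, `senderMarker`, `receiver`,
#'   `receiverMarker`, `axis`, `n`, `dcor`, `pearson`, `signed`, `p`,
#'   `p_adj`, `method`, `significant`, sorted by p then decreasing
#'   |signed|.
#' @export
lrScreen <- function(profile, catalogue = defaultLRCatalogue(), senders,
                     receivers, alpha = 0.05, nPerm = 9999, seed = 1L,
                     minSamples = 4L) {
  stopifnot(inherits(profile, "MCProfile"))
  markers <- unique(profile$marker)
  rows <- list(); skipped <- list()
  for (i in seq_len(nrow(catalogue))) {
    lig <- catalogue$ligand[i]; rec <- catalogue$receptor[i]
    if (!(lig %in% markers) || !(rec %in% markers)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        ligand = lig, receptor = rec, reason = "marker not on panel")
      next
    }
    for (s in senders) for (r in receivers) {
      if (s == r) next
      # receiver expresses the receptor, sender carries the ligand - and
      # the reverse orientation (sender receptor vs receiver ligand)
      for (orient in 1:2) {
        sm <- if (orient == 1) lig else rec
        rm <- if (orient == 1) rec else lig
        x <- .profileVector(profile, s, sm)
        y <- .profileVector(profile, r, rm)
        res <- .screenPair(x, y, nPerm, seed, minSamples)
        if (is.null(res)) next
        rows[[length(rows) + 1L]] <- data.frame(
          sender = s, senderMarker = sm, receiver = r,
          receiverMarker = rm, axis = paste0(lig, "-", rec),
          n = res$n, dcor = res$dcor, pearson = res$pearson,
          signed = res$signed, p = res$p, method = res$method,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stop("no complete ligand-receptor pairs to screen")
  out <- do.call(rbind, rows)
  out$p_adj <- bhAdjust(out$p)
  out$significant <- out$p < alpha
  out <- out[order(out$p, -abs(out$signed)), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
                          else NULL
  out
}

#' Frequency-frequency communication screen
#'
#' Correlates the per-sample frequencies of populations of interest with
#' those of other populations, with the same transformation
#' (log + z-normalisation), signed distance correlation, permutation
#' p-values and Benjamini-Hochberg adjustment as [lrScreen()].
#' Self-pairings are excluded.
#'
#' @param freq Samples x populations frequency table (percentages), as
#'   from [mcFrequencies()], or any numeric data.frame with sample rows.
#' @param populations Populations of interest (columns of `freq`).
#' @param against Populations to correlate them with (default: all
#'   others).
#' @param alpha,nPerm,seed,minSamples As in [lrScreen()].
#' @return data.frame with columns `population`, `partner`, `n`, `dcor`,
#'   `pearson`, `signed`, `p`, `p_adj`, `method`, `significant`.
#' @export
frequencyScreen <- function(freq, populations,
                            against = setdiff(colnames(freq), populations),
                            alpha = 0.05, nPerm = 9999, seed = 1L,
                            minSamples = 4L) {
  rows <- list()
  for (s in populations) for (r in against) {
    if (s == r) next
    res <- .screenPair(stats::setNames(freq[[s]], rownames(freq)),
                       stats::setNames(freq[[r]], rownames(freq)),
                       nPerm, seed, minSamples)
    if (is.null(res)) next
    rows[[length(rows) + 1L]] <- data.frame(
      population = s, partner = r, n = res$n, dcor = res$dcor,
      pearson = res$pearson, signed = res$signed, p = res$p,
      method = res$method, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no complete population pairs to screen")
  out <- do.call(rbind, rows)
  out$p_adj <- bhAdjust(out$p)
  out$significant <- out$p < alpha
  out <- out[order(out$p, -abs(out$signed)), ]
  rownames(out) <- NULL
  out
}
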