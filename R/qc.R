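#' Remove anomalous acquisition segments
#'
#' Automatic removal of outlier events caused by abnormal flow behaviour
#' (clogs, pressure drops): events are taken in acquisition-time order
#' and partitioned into consecutive segments of `segmentSize` events;
#' per-segment per-channel means are robustly z-scored against all
#' segments (median and MAD across segments, so a burst of aberrant
#' segments cannot mask itself by inflating the scale); the segment
#' score is the sum of absolute z-scores over the monitored channels;
#' segments whose score exceeds `median + c * MAD` of the scores are
#' removed. The filter is iterated to a fixed point
#' (recomputing scores on the retained segments), which makes it exactly
#' idempotent on its own output.
#'
#' @param frame A [CytoFrame-class]; events must be sorted by the time
#'   channel.
#' @param segmentSize Events per segment (>= 50).
#' @param c Deviation threshold in MAD units (> 0). `Inf` removes
#'   nothing.
#' @param channels Channels to monitor (default: all except the time
#'   channel).
#' @return A list with `frame` (the filtered [CytoFrame-class]) and
#'   `report` (a list: `removedFraction`, `removedWindows` data.frame of
#'   removed time intervals, `nRemoved`, `iterations`).
#' @export
removeAnomalousSegments <- function(frame, segmentSize = 200, c = 7,
                                    channels = NULL) {
  stopifnot(is(frame, "CytoFrame"))
  if (segmentSize < 50) stop("segmentSize must be at least 50")
  if (!is.numeric(c) || c <= 0) stop("'c' must be positive")
  e <- exprs(frame)
  n0 <- nrow(e)
  if (n0 < segmentSize) stop("fewer events than one segment")
  tc <- frame@timeChannel
  if (is.na(tc)) stop("frame has no time channel")
  if (is.unsorted(e[, tc])) stop("events must be sorted by time")
  mon <- channels %||% setdiff(colnames(e), tc)
  if (!all(mon %in% colnames(e))) stop("unknown monitored channel")

  keep <- rep(TRUE, n0)
  seg <- pmin((seq_len(n0) - 1L) %/% segmentSize + 1L,
              n0 %/% segmentSize)      # last partial segment merged
  removedSegs <- integer(0)
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    live <- setdiff(unique(seg), removedSegs)
    if (length(live) < 3L) break       # too few segments to score
    segMeans <- vapply(live, function(s)
      colMeans(e[keep & seg == s, mon, drop = FALSE]), numeric(length(mon)))
    segMeans <- matrix(segMeans, nrow = length(mon))
    ctr <- apply(segMeans, 1, stats::median)
    scl <- pmax(apply(segMeans, 1, stats::mad), .Machine$double.eps)
    z <- (segMeans - ctr) / scl
    score <- colSums(abs(z))
    thr <- stats::median(score) + c * stats::mad(score)
    bad <- live[score > thr]
    if (!length(bad) || !is.finite(thr)) break
    removedSegs <- c(removedSegs, bad)
    keep[seg %in% bad] <- FALSE
    if (iterations >= 10L) break
  }
  windows <- if (length(removedSegs)) {
    do.call(rbind, lapply(sort(removedSegs), function(s) {
      tm <- e[seg == s, tc]
      data.frame(segment = s, start = min(tm), end = max(tm))
    }))
  } else data.frame(segment = integer(0), start = numeric(0),
                    end = numeric(0))
  out <- frame
  out@exprs <- e[keep, , drop = FALSE]
  if (nrow(frame@labels)) out@labels <- frame@labels[keep, , drop = FALSE]
  list(frame = out,
       report = list(removedFraction = 1 - sum(keep) / n0,
                     removedWindows = windows,
                     nRemoved = n0 - sum(keep),
                     iterations = iterations))
}

#' Downsample events per sample
#'
#' Uniform sampling without replacement to at most `n` events per
#' sample; samples with fewer events are kept whole. Deterministic under
#' `seed`.
#'
#' @param frames A named list of [CytoFrame-class] objects (or a single
#'   frame).
#' @param n Target events per sample (>= 1).
#' @param seed Integer seed.
#' @return The downsampled list (or single frame).
#' @export
downsampleEvents <- function(frames, n, seed = 1L) {
  if (n < 1) stop("n must be at least 1")
  single <- is(frames, "CytoFrame")
  if (single) frames <- list(frames)
  set.seed(seed)
  out <- lapply(frames, function(fr) {
    ne <- nEvents(fr)
    if (ne <= n) return(fr)
    idx <- sort(sample.int(ne, n))
    fr@exprs <- fr@exprs[idx, , drop = FALSE]
    if (nrow(fr@labels)) fr@labels <- fr@labels[idx, , drop = FALSE]
    fr
  })
  if (single) out[[1]] else out
}

#' Log-transform and z-scale a feature matrix
#'
#' Natural log followed by per-feature centering and unit-variance
#' scaling (features are rows). Features containing non-positive values
#' are first shifted by `1 - min(feature)` so the smallest value maps to
#' 1 before the log. Constant features map to all-zeros.
#'
#' @param m Numeric matrix, features x observations (a vector is treated
#'   as one feature).
#' @return Matrix of the same shape.
#' @export
logZScale <- function(m) {
  vec <- is.null(dim(m))
  if (vec) m <- matrix(m, nrow = 1)
  out <- t(apply(m, 1, function(r) {
    if (any(r <= 0)) r <- r + (1 - min(r))
    r <- log(r)
    s <- stats::sd(r)
    if (!is.finite(s) || s == 0) return(rep(0, length(r)))
    (r - mean(r)) / s
  }))
  dimnames(out) <- dimnames(m)
  if (vec) out[1, ] else out
}

#' Exclude low-count samples
#'
#' Drops samples whose cell count in the population of interest is below
#' `threshold` (strictly less than; a sample with exactly `threshold`
#' cells is retained), mirroring the practice of excluding samples with
#' fewer than 100 cells in the final gate. Errors when nothing remains.
#'
#' @param counts Named integer vector of per-sample cell counts.
#' @param threshold Minimum acceptable count (default 100).
#' @return A list with `retained` (sample names), `excluded` (data.frame
#'   `sample_id`, `count`, `reason`).
#' @export
excludeLowCountSamples <- function(counts, threshold = 100) {
  if (is.null(names(counts))) stop("counts must be named by sample")
  low <- counts < threshold
  if (all(low))
    stop("all samples fall below the minimum cell count (", threshold, ")")
  list(retained = names(counts)[!low],
       excluded = data.frame(
         sample_id = names(counts)[low],
         count = as.integer(counts[low]),
         reason = rep(sprintf("fewer than %d cells", threshold), sum(low)),
         stringsAsFactors = FALSE))
}
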