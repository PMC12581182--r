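#' Marker enrichment modelling (MEM) scores
#'
#' Signed per-marker enrichment of a population against a reference
#' (default in practice: all other cells). Per marker the raw magnitude
#' is `|median_pop - median_ref| + IQR_ref / IQR_pop - 1`, floored at 0,
#' carrying the sign of `median_pop - median_ref`; scores are then
#' rescaled so the largest magnitude across markers is 10 (unless all
#' scores are 0). Zero IQRs are floored at a small epsilon.
#'
#' @param pop Cells x markers matrix of the population.
#' @param ref Cells x markers matrix of the reference; same markers.
#' @param eps Floor applied to IQRs (default 1e-8).
#' @return Named numeric vector of scores in `[-10, 10]`, with
#'   attribute `reference` describing the comparison.
#' @export
memScores <- function(pop, ref, eps = 1e-8) {
  if (!nrow(pop) || !nrow(ref)) stop("both groups must be non-empty")
  if (!identical(colnames(pop), colnames(ref)))
    stop("population and reference must share the same markers")
  medP <- apply(pop, 2, stats::median)
  medR <- apply(ref, 2, stats::median)
  iqrP <- pmax(apply(pop, 2, stats::IQR), eps)
  iqrR <- pmax(apply(ref, 2, stats::IQR), eps)
  raw <- pmax(abs(medP - medR) + iqrR / iqrP - 1, 0)
  s <- sign(medP - medR) * raw
  mx <- max(abs(s))
  if (mx > 0) s <- 10 * s / mx
  structure(s, reference = sprintf(
    "population (n=%d) vs reference (n=%d)", nrow(pop), nrow(ref)))
}

.f1 <- function(sel, pos) {
  tp <- sum(sel & pos)
  fp <- sum(sel & !pos)
  fn <- sum(!sel & pos)
  if (2 * tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

.gateMembership <- function(x, lower, upper, skip = NULL) {
  sel <- rep(TRUE, nrow(x))
  for (m in names(lower)) {
    if (!is.null(skip) && m %in% skip) next
    if (is.finite(lower[[m]])) sel <- sel & x[, m] >= lower[[m]]
    if (is.finite(upper[[m]])) sel <- sel & x[, m] <= upper[[m]]
  }
  sel
}

#' Fit an axis-aligned gate to a target population
#'
#' Greedy coordinate ascent over candidate thresholds (per-marker
#' quantile grids): at each step the single (marker, bound) addition or
#' adjustment that maximally increases the F1 score
#' `2TP / (2TP + FP + FN)` of the gate against the target labelling is
#' applied; the search stops when the best improvement falls below
#' `tol` or `maxConstraints` bounds are in place. A final refinement
#' pass re-optimises each active bound over the exact data values
#' between its neighbouring grid candidates, so cleanly separable
#' populations reach F1 = 1. Deterministic (ties resolved in marker
#' order, then lower-before-upper, then smallest
#' threshold). Per-marker importance (F1 drop when the marker's bounds
#' are ignored, see [markerImportance()]) is computed on the fitted
#' gate.
#'
#' @param x Cells x markers numeric matrix.
#' @param target Logical vector (or 0/1): cells belonging to the
#'   population to reproduce. At least one positive cell is required;
#'   fewer than 10 positives triggers a warning.
#' @param nQuantiles Size of the per-marker candidate threshold grid
#'   (default 99: the 1%..99% percentiles).
#' @param tol Minimum F1 improvement to continue (default 1e-4).
#' @param maxConstraints Maximum number of finite bounds (default 20).
#' @param targetName Population name stored in the result.
#' @return A [GateSpec-class].
#' @export
fitGate <- function(x, target, nQuantiles = 99, tol = 1e-4,
                    maxConstraints = 20, targetName = "population") {
  pos <- as.logical(target)
  if (!any(pos)) stop("no positive cells in the target labelling")
  if (sum(pos) < 10) warning("fewer than 10 positive cells; the gate may overfit")
  if (is.null(colnames(x))) stop("x must have marker column names")
  markers <- colnames(x)
  cand <- lapply(markers, function(m)
    unique(stats::quantile(x[, m], probs = seq_len(nQuantiles) /
                             (nQuantiles + 1), names = FALSE)))
  names(cand) <- markers
  lower <- stats::setNames(rep(-Inf, length(markers)), markers)
  upper <- stats::setNames(rep(Inf, length(markers)), markers)
  order <- character(0)                 # markers in order of first use
  f1cur <- .f1(rep(TRUE, nrow(x)), pos)
  repeat {
    nConstr <- sum(is.finite(lower)) + sum(is.finite(upper))
    best <- list(gain = 0)
    for (m in markers) {
      others <- .gateMembership(x, lower, upper, skip = m)
      xm <- x[, m]
      for (q in cand[[m]]) {
        if (is.finite(upper[[m]]) || q != lower[[m]]) {
          selL <- others & xm >= q &
            (if (is.finite(upper[[m]])) xm <= upper[[m]] else TRUE)
          fL <- .f1(selL, pos)
          if (fL > f1cur + best$gain + 1e-15)
            best <- list(gain = fL - f1cur, marker = m, side = "lower",
                         value = q, f1 = fL)
        }
        selU <- others & xm <= q &
          (if (is.finite(lower[[m]])) xm >= lower[[m]] else TRUE)
        fU <- .f1(selU, pos)
        if (fU > f1cur + best$gain + 1e-15)
          best <- list(gain = fU - f1cur, marker = m, side = "upper",
                       value = q, f1 = fU)
      }
    }
    if (best$gain < tol) break
    isNew <- if (best$side == "lower") !is.finite(lower[[best$marker]])
             else !is.finite(upper[[best$marker]])
    if (isNew && nConstr >= maxConstraints) break
    if (best$side == "lower") lower[[best$marker]] <- best$value
    else upper[[best$marker]] <- best$value
    if (!(best$marker %in% order)) order <- c(order, best$marker)
    f1cur <- best$f1
  }
  # refinement: tune each active bound over exact data values between
  # its neighbouring grid candidates
  for (pass in 1:3) {
    changed <- FALSE
    for (m in markers) {
      for (side in c("lower", "upper")) {
        cur <- if (side == "lower") lower[[m]] else upper[[m]]
        if (!is.finite(cur)) next
        others <- .gateMembership(x, lower, upper, skip = m)
        xm <- x[, m]
        grid <- sort(c(cand[[m]], cur))
        i <- match(cur, grid)
        lo <- if (i > 1) grid[i - 1] else min(xm)
        hi <- if (i < length(grid)) grid[i + 1] else max(xm)
        vals <- unique(c(cur, xm[xm >= lo & xm <= hi]))
        f1s <- vapply(vals, function(q) {
          sel <- if (side == "lower")
            others & xm >= q &
              (if (is.finite(upper[[m]])) xm <= upper[[m]] else TRUE)
          else
            others & xm <= q &
              (if (is.finite(lower[[m]])) xm >= lower[[m]] else TRUE)
          .f1(sel, pos)
        }, numeric(1))
        bestq <- vals[which.max(f1s)]
        if (max(f1s) > f1cur + 1e-12) {
          if (side == "lower") lower[[m]] <- bestq else upper[[m]] <- bestq
          f1cur <- max(f1s)
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  used <- order
  constraints <- data.frame(marker = used,
                            lower = unname(lower[used]),
                            upper = unname(upper[used]),
                            stringsAsFactors = FALSE)
  gate <- new("GateSpec", constraints = constraints, f1 = f1cur,
              importance = numeric(0), target = targetName)
  gate@importance <- markerImportance(gate, x, pos)
  gate
}

#' Apply a gate to events
#'
#' @param gate A [GateSpec-class].
#' @param x Cells x markers matrix containing the gated markers.
#' @return Logical vector: cells inside the gate.
#' @export
applyGate <- function(gate, x) {
  stopifnot(is(gate, "GateSpec"))
  cs <- gate@constraints
  sel <- rep(TRUE, nrow(x))
  for (i in seq_len(nrow(cs))) {
    xm <- x[, cs$marker[i]]
    if (is.finite(cs$lower[i])) sel <- sel & xm >= cs$lower[i]
    if (is.finite(cs$upper[i])) sel <- sel & xm <= cs$upper[i]
  }
  sel
}

#' Per-marker gate importance
#'
#' For each gated marker, the decrease in F1 when that marker's
#' constraints are removed from the gate (without re-fitting, so a
#' large value means the marker is indispensable; near zero means its
#' constraints are redundant given the rest). Markers not in the gate
#' have importance 0 by definition. With `refit = TRUE` the remaining
#' gate is re-optimised after each removal instead (slower; importance
#' then measures irreplaceability rather than marginal contribution).
#'
#' @param gate A fitted [GateSpec-class].
#' @param x Cells x markers matrix compatible with the gate.
#' @param target Logical vector of target membership.
#' @param refit Re-fit the reduced gate before scoring (default FALSE).
#' @return Named numeric vector over the gated markers, sorted
#'   decreasing.
#' @export
markerImportance <- function(gate, x, target, refit = FALSE) {
  stopifnot(is(gate, "GateSpec"))
  pos <- as.logical(target)
  cs <- gate@constraints
  if (!nrow(cs)) return(stats::setNames(numeric(0), character(0)))
  fFull <- .f1(applyGate(gate, x), pos)
  imp <- vapply(cs$marker, function(m) {
    red <- gate
    red@constraints <- cs[cs$marker != m, , drop = FALSE]
    if (refit) {
      keep <- setdiff(colnames(x), m)
      red <- fitGate(x[, keep, drop = FALSE], pos,
                     targetName = gate@target)
    }
    fFull - .f1(applyGate(red, x), pos)
  }, numeric(1))
  sort(imp, decreasing = TRUE)
}
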