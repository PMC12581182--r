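#' PCA of population frequencies
#'
#' Principal component analysis of a samples x populations frequency
#' table: each population is centered and scaled to unit variance, the
#' decomposition is computed by SVD ([stats::prcomp()]), and the top
#' contributing populations are ranked by squared loading on the first
#' two components. Missing values are refused (no imputation); constant
#' populations are dropped with a warning.
#'
#' @param freq Samples x populations numeric data.frame or matrix.
#' @return A list of class `PCAResult`: `scores` (samples x components),
#'   `loadings` (populations x components), `explainedVar`
#'   (non-increasing fractions summing to <= 1), `topContributors`
#'   (data.frame: population, component, squaredLoading).
#' @export
pcaFrequencies <- function(freq) {
  m <- as.matrix(freq)
  if (nrow(m) < 3L) stop("need at least 3 samples for PCA")
  if (any(is.na(m)))
    stop("missing values in the frequency table; imputation is refused")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant population(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(2L, ncol(pc$rotation))
  contrib <- do.call(rbind, lapply(seq_len(k), function(j) {
    sq <- pc$rotation[, j]^2
    data.frame(population = names(sort(sq, decreasing = TRUE)),
               component = paste0("PC", j),
               squaredLoading = unname(sort(sq, decreasing = TRUE)),
               stringsAsFactors = FALSE)
  }))
  structure(list(scores = pc$x, loadings = pc$rotation,
                 explainedVar = ev, topContributors = contrib,
                 center = pc$center, scale = pc$scale),
            class = "PCAResult")
}

#' @export
print.PCAResult <- function(x, ...) {
  cat(sprintf("PCA of %d samples x %d populations\n",
              nrow(x$scores), nrow(x$loadings)))
  cat(" explained variance:",
      paste0(sprintf("%.1f%%", 100 * utils::head(x$explainedVar, 4)),
             collapse = ", "), "\n")
  invisible(x)
}

# midranks-based Mann-Whitney U of group A against B
.uStat <- function(ranks, isA, nA) sum(ranks[isA]) - nA * (nA + 1) / 2

#' Two-tailed Mann-Whitney U test
#'
#' For combined sample sizes up to `exactLimit` (default 12) the exact
#' two-tailed p-value is computed by full enumeration of all group
#' assignments (midranks, so ties are handled exactly): `p` is the
#' proportion of assignments whose U is at least as far from the null
#' mean `nA * nB / 2` as the observed U. Larger samples use the normal
#' approximation with tie correction (no continuity correction).
#'
#' @param a,b Numeric vectors, each non-empty.
#' @param exactLimit Largest combined n for enumeration.
#' @return A list: `U` (statistic of the first group), `p`, `method`.
#' @export
mannWhitney <- function(a, b, exactLimit = 12L) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  nA <- length(a); nB <- length(b); n <- nA + nB
  ranks <- rank(c(a, b))
  isA <- seq_len(n) <= nA
  U <- .uStat(ranks, isA, nA)
  mu <- nA * nB / 2
  if (n <= exactLimit) {
    sets <- utils::combn(n, nA)
    Us <- apply(sets, 2, function(idx)
      sum(ranks[idx]) - nA * (nA + 1) / 2)
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    list(U = U, p = p, method = "exact-enumeration")
  } else {
    ties <- table(ranks)
    sig2 <- nA * nB / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- if (sig2 > 0) (U - mu) / sqrt(sig2) else 0
    list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))),
         method = "normal-approximation")
  }
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Kruskal-Wallis H (tie-corrected, via [stats::kruskal.test()])
#' followed by Dunn's pairwise z tests on the pooled midranks, with
#' Benjamini-Hochberg adjustment across the pairwise family.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor or character vector of group labels (>= 3
#'   groups; groups with fewer than 2 values are flagged with a
#'   warning).
#' @return A list: `H`, `p` (the global test), `pairwise` (data.frame
#'   `groupA`, `groupB`, `z`, `p`, `p_adj`).
#' @export
kruskalWallisDunn <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 3L) stop("need at least 3 groups")
  sizes <- table(groups)
  if (any(sizes < 2L))
    warning("group(s) with fewer than 2 values: ",
            paste(names(sizes)[sizes < 2], collapse = ", "))
  kw <- stats::kruskal.test(values, groups)
  n <- length(values)
  ranks <- rank(values)
  ties <- table(ranks)
  tieTerm <- sum(ties^3 - ties)
  meanRank <- tapply(ranks, groups, mean)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    gi <- pairs[1, j]; gj <- pairs[2, j]
    se <- sqrt((n * (n + 1) / 12 - tieTerm / (12 * (n - 1))) *
               (1 / sizes[[gi]] + 1 / sizes[[gj]]))
    z <- (meanRank[[gi]] - meanRank[[gj]]) / se
    data.frame(groupA = gi, groupB = gj, z = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  }))
  pw$p_adj <- bhAdjust(pw$p)
  rownames(pw) <- NULL
  list(H = unname(kw$statistic), p = kw$p.value, pairwise = pw)
}

.sigTier <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "ns")))
}

#' Compare population frequencies between groups
#'
#' Applies a two-tailed Mann-Whitney U test (`design = "two-group"`) or
#' Kruskal-Wallis with Dunn's post hoc (`design = "multi-group"`) to
#' each population of a frequency table, adjusts the per-population
#' p-values by Benjamini-Hochberg across populations, and annotates
#' significance tiers (ns, * < 0.05, ** < 0.01, *** < 0.001) from the
#' adjusted p. Group summaries report both mean +/- sem and
#' median / IQR.
#'
#' @param freq Samples x populations frequency data.frame (row names =
#'   sample ids), e.g. from [mcFrequencies()].
#' @param sheet Sample sheet data.frame with `sample_id` and `group`.
#' @param design `"two-group"` or `"multi-group"`.
#' @return data.frame, one row per population: per-group `mean_*`,
#'   `sem_*`, `median_*`, `iqr_*` columns, `statistic`, `p`, `p_adj`,
#'   `tier`. For multi-group designs the Dunn tables are attached as
#'   attribute `pairwise` (a named list).
#' @export
comparePopulations <- function(freq, sheet,
                               design = c("two-group", "multi-group")) {
  design <- match.arg(design)
  grp <- sheet$group[match(rownames(freq), sheet$sample_id)]
  if (any(is.na(grp))) stop("samples in freq missing from the sample sheet")
  grp <- as.factor(grp)
  ng <- nlevels(grp)
  if (design == "two-group" && ng != 2L)
    stop("two-group design requires exactly 2 groups")
  if (design == "multi-group" && ng < 3L)
    stop("multi-group design requires at least 3 groups")
  pairwise <- list()
  rows <- lapply(colnames(freq), function(pp) {
    v <- freq[[pp]]
    sm <- unlist(lapply(levels(grp), function(g) {
      x <- v[grp == g]
      stats::setNames(
        c(mean(x), stats::sd(x) / sqrt(length(x)), stats::median(x),
          stats::IQR(x)),
        paste0(c("mean_", "sem_", "median_", "iqr_"), g))
    }))
    if (design == "two-group") {
      tt <- mannWhitney(v[grp == levels(grp)[1]], v[grp == levels(grp)[2]])
      stat <- tt$U; p <- tt$p
    } else {
      tt <- kruskalWallisDunn(v, grp)
      pairwise[[pp]] <<- tt$pairwise
      stat <- tt$H; p <- tt$p
    }
    data.frame(population = pp, t(sm), statistic = stat, p = p,
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bhAdjust(out$p)
  out$tier <- .sigTier(out$p_adj)
  rownames(out) <- NULL
  if (design == "multi-group") attr(out, "pairwise") <- pairwise
  out
}
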