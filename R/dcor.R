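#' @useDynLib flowSDC, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.checkPair <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) stop("x and y must be numeric")
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in input")
  invisible(TRUE)
}

#' Distance correlation
#'
#' Sample distance correlation (the V-statistic): pairwise
#' absolute-difference matrices are double-centered (row mean, column
#' mean and grand mean removed); the squared distance covariance is the
#' mean elementwise product of the two centered matrices, and the
#' distance correlation is dCov normalised by the geometric mean of the
#' two distance variances. Lies in `[0, 1]` and is zero (asymptotically)
#' only under independence, so it detects nonlinear as well as linear
#' association. Computed by a streaming O(n^2) kernel that never
#' materialises the n x n matrices.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, all finite.
#' @return A single value in `[0, 1]`; 0 when either distance variance
#'   vanishes (a constant argument).
#' @examples
#' x <- 1:5
#' distanceCorrelation(x, 3 * x - 2)   # affine dependence -> 1
#' @export
distanceCorrelation <- function(x, y) {
  .checkPair(x, y)
  s <- .dcovStats(as.numeric(x), as.numeric(y))
  v <- s[2] * s[3]
  if (v <= 0) return(0)
  r2 <- s[1] / sqrt(v)
  sqrt(max(r2, 0))
}

# centred distance matrices and dcor via the explicit matrix route;
# shared by the permutation engine (small n only)
.dcorCentered <- function(x, y) {
  ax <- as.matrix(stats::dist(x, method = "manhattan"))
  ay <- as.matrix(stats::dist(y, method = "manhattan"))
  A <- sweep(sweep(ax, 1, rowMeans(ax)), 2, colMeans(ax)) + mean(ax)
  B <- sweep(sweep(ay, 1, rowMeans(ay)), 2, colMeans(ay)) + mean(ay)
  dvx <- mean(A * A); dvy <- mean(B * B)
  dcov2 <- mean(A * B)
  dcor <- if (dvx * dvy <= 0) 0 else sqrt(max(dcov2 / sqrt(dvx * dvy), 0))
  list(A = A, B = B, dvx = dvx, dvy = dvy, dcor = dcor)
}

#' Signed distance correlation
#'
#' Distance correlation with the sign of the Pearson correlation of the
#' same pair, so the magnitude reflects (possibly nonlinear) dependence
#' strength while the sign orients the association. When the Pearson
#' correlation is exactly zero the sign is set to `+1` and flagged.
#'
#' @inheritParams distanceCorrelation
#' @return A single numeric value in `[-1, 1]` with attributes
#'   `pearson` (the Pearson coefficient) and `zeroSign` (`TRUE` when the
#'   sign convention at Pearson 0 was applied).
#' @examples
#' x <- 1:6
#' signedDcor(x, -x)    # -1
#' @export
signedDcor <- function(x, y) {
  .checkPair(x, y)
  d <- distanceCorrelation(x, y)
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) 0 else stats::cor(x, y)
  zero <- (r == 0)
  s <- if (zero) 1 else sign(r)
  structure(s * d, pearson = r, zeroSign = zero)
}

# all permutations of 1..n as an n x n! matrix (n <= 7 -> at most 5040),
# built by inserting n into every position of every (n-1)-permutation
.allPerms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .allPerms(n - 1L)
  out <- matrix(0L, n, n * ncol(sub))
  col <- 1L
  for (j in seq_len(ncol(sub))) {
    for (pos in seq_len(n)) {
      out[, col] <- append(sub[, j], n, after = pos - 1L)
      col <- col + 1L
    }
  }
  out
}

#' Permutation p-value for distance correlation
#'
#' Tests independence by permuting `y`. For small samples
#' (`n <= exactLimit`, default 7) all `n!` permutations are enumerated
#' and `p = #\{dcor_perm >= dcor_obs\} / n!` (the identity permutation is
#' included, so `p >= 1/n!`). Otherwise a Monte-Carlo estimate
#' `p = (1 + #\{>=\}) / (1 + nPerm)` is used. The distance variances are
#' permutation-invariant, so only the cross term is recomputed per
#' permutation (in C).
#'
#' @inheritParams distanceCorrelation
#' @param method `"auto"` (exact when `n <= exactLimit`), `"exact"` or
#'   `"montecarlo"`.
#' @param nPerm Number of Monte-Carlo permutations (default 9999).
#' @param seed Optional integer seed for the Monte-Carlo draw.
#' @param exactLimit Largest `n` for which `"auto"` enumerates.
#' @return The p-value, with attributes `method` (`"exact-permutation"`
#'   or `"monte-carlo"`) and `statistic` (the observed dcor).
#' @export
dcorPvalue <- function(x, y, method = c("auto", "exact", "montecarlo"),
                       nPerm = 9999, seed = NULL, exactLimit = 7L) {
  method <- match.arg(method)
  .checkPair(x, y)
  n <- length(x)
  if (method == "auto") method <- if (n <= exactLimit) "exact" else "montecarlo"
  cc <- .dcorCentered(x, y)
  obs <- cc$dcor
  denom <- sqrt(cc$dvx * cc$dvy)
  if (denom <= 0) {
    # a constant margin is independent of anything: all permutation
    # statistics are 0 == observed
    p <- 1
    return(structure(p, method = paste0(
      if (method == "exact") "exact-permutation" else "monte-carlo"),
      statistic = 0))
  }
  if (method == "exact") {
    if (n > 9L) stop("exact enumeration not feasible beyond n = 9")
    P <- .allPerms(n)
    dc2 <- .dcovPerm(cc$A, cc$B, P)
    stat <- sqrt(pmax(dc2 / denom, 0))
    p <- mean(stat >= obs - 1e-12)
    structure(p, method = "exact-permutation", statistic = obs)
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    P <- vapply(seq_len(nPerm), function(i) sample.int(n), integer(n))
    dc2 <- .dcovPerm(cc$A, cc$B, P)
    stat <- sqrt(pmax(dc2 / denom, 0))
    p <- (1 + sum(stat >= obs - 1e-12)) / (1 + nPerm)
    structure(p, method = "monte-carlo", statistic = obs)
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction with monotonicity enforcement,
#' returned in the input order. Thin validated wrapper around
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted p-values, elementwise `>=` the input.
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}
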