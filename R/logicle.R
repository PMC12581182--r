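#' Logicle transformation parameters
#'
#' Bundle and validate the four parameters of the logicle (biexponential)
#' scale used throughout the pipeline: linear near zero, logarithmic at
#' high intensity.
#'
#' @param w Linearisation width in decades. Must satisfy `0 <= w <= m/2`.
#' @param t Top of scale (raw intensity mapped to 1 on the transformed
#'   scale). Must be positive.
#' @param m Total display width in decades. Must be positive.
#' @param a Additional negative display decades. Must be non-negative.
#'
#' @return A list of class `logicleParams` with the user parameters and
#'   the derived biexponential coefficients.
#' @examples
#' p <- logicleParams()          # w = 0.5, t = 10000, m = 2, a = 0
#' logicleTransform(10000, p)    # 1 at the top of scale
#' @export
logicleParams <- function(w = 0.5, t = 10000, m = 2, a = 0) {
  stopifnot(is.numeric(w), is.numeric(t), is.numeric(m), is.numeric(a),
            length(w) == 1L, length(t) == 1L, length(m) == 1L,
            length(a) == 1L)
  if (!is.finite(t) || t <= 0) stop("'t' must be a positive finite number")
  if (!is.finite(m) || m <= 0) stop("'m' must be a positive finite number")
  if (!is.finite(w) || w < 0 || w > m / 2)
    stop("'w' must satisfy 0 <= w <= m/2")
  if (!is.finite(a) || a < 0) stop("'a' must be non-negative")

  # derived coefficients of the biexponential
  #   B(y) = alpha * exp(b*y) - gamma * exp(-d*y) - f
  # with B(1) = t and B(x1) = 0 (x1 is the transformed image of raw 0)
  b  <- (m + a) * log(10)
  wn <- w / (m + a)              # normalised linearisation width
  x2 <- a / (m + a)
  x1 <- x2 + wn
  x0 <- x2 + 2 * wn
  d  <- if (wn == 0) b else .logicleSolveD(wn, b)
  ca  <- exp(x0 * (b + d))
  fa  <- exp(b * x1) - ca * exp(-d * x1)
  alpha <- t / (exp(b) - ca * exp(-d) - fa)
  structure(
    list(w = w, t = t, m = m, a = a,
         b = b, d = d, x0 = x0, x1 = x1, x2 = x2,
         alpha = alpha, gamma = alpha * ca, f = alpha * fa),
    class = "logicleParams")
}

# root of 2*(log(d) - log(b)) + w*(d + b) = 0 on (0, b)
.logicleSolveD <- function(w, b) {
  fn <- function(d) 2 * (log(d) - log(b)) + w * (d + b)
  stats::uniroot(fn, lower = b * 1e-12, upper = b, tol = .Machine$double.eps^0.75)$root
}

.asLogicleParams <- function(p) {
  if (inherits(p, "logicleParams")) p else do.call(logicleParams, as.list(p))
}

#' @export
print.logicleParams <- function(x, ...) {
  cat(sprintf("logicle parameters: w = %g, t = %g, m = %g, a = %g\n",
              x$w, x$t, x$m, x$a))
  invisible(x)
}

# biexponential and its derivative, vectorised over y
.biexp <- function(y, p) p$alpha * exp(p$b * y) - p$gamma * exp(-p$d * y) - p$f
.biexpDeriv <- function(y, p) p$alpha * p$b * exp(p$b * y) + p$gamma * p$d * exp(-p$d * y)

#' Inverse logicle (biexponential) evaluation
#'
#' Maps transformed-scale values back to raw intensities by exact
#' evaluation of the biexponential. `logicleInverse(1, p)` equals `p$t`.
#'
#' @param y Numeric vector of transformed-scale values.
#' @param p A `logicleParams` object (default: the pipeline defaults).
#' @return Raw intensities, same length as `y`.
#' @export
logicleInverse <- function(y, p = logicleParams()) {
  p <- .asLogicleParams(p)
  if (any(!is.finite(y))) stop("non-finite input to logicleInverse()")
  .biexp(y, p)
}

#' Logicle transformation
#'
#' Forward logicle transform: the numerical inverse of the biexponential,
#' computed by Newton iteration from a monotone-spline initial guess.
#' Strictly increasing; `logicleTransform(p$t, p) == 1`; approximately
#' linear around raw 0 and logarithmic for large intensities.
#'
#' @param x Numeric vector of raw intensities.
#' @param p A `logicleParams` object.
#' @param tol Absolute tolerance on the transformed scale (default 1e-9,
#'   well below the 1e-8 contract).
#' @return Transformed values, same length as `x`.
#' @export
logicleTransform <- function(x, p = logicleParams(), tol = 1e-9) {
  p <- .asLogicleParams(p)
  if (any(!is.finite(x))) stop("non-finite input to logicleTransform()")
  if (!length(x)) return(numeric(0))
  # bracket in y covering the data range, then spline seed + Newton polish
  lo <- -0.5; hi <- 1.5
  while (.biexp(lo, p) > min(x)) lo <- lo - 0.5
  while (.biexp(hi, p) < max(x)) hi <- hi + 0.5
  grid <- seq(lo, hi, length.out = 512L)
  seed <- stats::splinefun(.biexp(grid, p), grid, method = "monoH.FC")
  y <- seed(x)
  for (i in 1:50) {
    resid <- .biexp(y, p) - x
    if (all(abs(resid) <= tol * pmax(1, abs(x)))) break
    y <- y - resid / .biexpDeriv(y, p)
  }
  y
}
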