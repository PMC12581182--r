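# Independent oracles used across the suite. These deliberately use
# naive, explicit computations (loops, bisection) so they share no code
# path with the package implementations they check.

# distance correlation by explicit double-centering of full matrices
oracleDcor <- function(x, y) {
  n <- length(x)
  a <- abs(outer(x, x, "-"))
  b <- abs(outer(y, y, "-"))
  A <- matrix(0, n, n); B <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    A[j, k] <- a[j, k] - mean(a[j, ]) - mean(a[, k]) + mean(a)
    B[j, k] <- b[j, k] - mean(b[j, ]) - mean(b[, k]) + mean(b)
  }
  dcov2 <- mean(A * B)
  dvx <- mean(A * A); dvy <- mean(B * B)
  if (dvx * dvy <= 0) return(0)
  sqrt(max(dcov2 / sqrt(dvx * dvy), 0))
}

# population distance correlation of a bivariate normal with correlation
# rho (Szekely's closed form, evaluated numerically)
bvnDcorPopulation <- function(rho) {
  num <- rho * asin(rho) + sqrt(1 - rho^2) - rho * asin(rho / 2) -
    sqrt(4 - rho^2) + 1
  den <- 1 + pi / 3 - sqrt(3)
  sqrt(num / den)
}

# forward logicle by pure bisection on an independently assembled
# biexponential (own coefficient derivation, no Newton, no splines)
oracleLogicle <- function(x, w = 0.5, t = 10000, m = 2, a = 0) {
  b <- (m + a) * log(10)
  wn <- w / (m + a)
  x2 <- a / (m + a); x1 <- x2 + wn; x0 <- x2 + 2 * wn
  d <- if (wn == 0) b else {
    lo <- b * 1e-12; hi <- b
    f <- function(dd) 2 * (log(dd) - log(b)) + wn * (dd + b)
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  ca <- exp(x0 * (b + d))
  fa <- exp(b * x1) - ca * exp(-d * x1)
  al <- t / (exp(b) - ca * exp(-d) - fa)
  bx <- function(y) al * (exp(b * y) - ca * exp(-d * y) - fa)
  vapply(x, function(xi) {
    lo <- -2; hi <- 3
    for (i in 1:100) {
      mid <- (lo + hi) / 2
      if (bx(mid) < xi) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

# brute-force best-matching unit with first-minimum tie rule
oracleBMU <- function(x, codebook) {
  vapply(seq_len(nrow(x)), function(i) {
    d2 <- vapply(seq_len(nrow(codebook)), function(j)
      sum((x[i, ] - codebook[j, ])^2), numeric(1))
    which.min(d2)
  }, integer(1))
}

# adjusted Rand index between two partitions (contingency formula)
ariIndex <- function(a, b) {
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  (sumij - expected) / ((ai + bj) / 2 - expected)
}

# small cohort spec used by several tests: two populations carrying a
# ligand/receptor pair plus filler markers
miniLRSpec <- function(nA = 10, nB = 10, cells = 400, couplings = list(),
                       seed = 1) {
  mcs <- list(
    metaclusterSpec("S", c(A = 0.5, B = 0.5),
                    mean = c(ICOS = 0.55), parent = "CD8"),
    metaclusterSpec("R", c(A = 0.5, B = 0.5),
                    mean = c(ICOSL = 0.55), parent = "TME"))
  cohortSpec(groups = data.frame(group = c("A", "B"), n = c(nA, nB)),
             cellsPerSample = cells,
             markers = c("ICOS", "ICOSL", "M1", "M2", "M3", "M4"),
             metaclusters = mcs, couplings = couplings, seed = seed)
}

# across-sample median of a marker within one truth population
popMedians <- function(cohort, population, marker, transform = TRUE) {
  p <- logicleParams()
  vapply(frames(cohort), function(fr) {
    sel <- truthLabels(fr)$population == population
    v <- exprs(fr)[sel, marker]
    if (transform) v <- logicleTransform(v, p)
    median(v)
  }, numeric(1))
}
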