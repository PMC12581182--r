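twoPopSpec <- function(cells = 1000, doubletFrac = 0, deadFrac = 0,
                       seed = 1) {
  mcs <- list(
    metaclusterSpec("P1", c(A = 1, B = 1),
                    mean = c(M1 = 0.6, M2 = 0.3), sd = c(M1 = 0.05)))
  cohortSpec(groups = data.frame(group = c("A", "B"), n = c(1, 1)),
             cellsPerSample = cells,
             markers = c("M1", "M2", "Viability"),
             metaclusters = mcs, doubletFrac = doubletFrac,
             deadFrac = deadFrac, seed = seed)
}

test_that("simulated marginals match the specified transformed means", {
  co <- simulateCohort(twoPopSpec(cells = 1000, seed = 5))
  p <- logicleParams()
  for (fr in frames(co)) {
    z <- apply(exprs(fr)[, c("M1", "M2")], 2, logicleTransform, p = p)
    expect_lt(abs(mean(z[, "M1"]) - 0.6), 3 * 0.05 / sqrt(1000))
    expect_lt(abs(mean(z[, "M2"]) - 0.3), 3 * 0.06 / sqrt(1000))
  }
})

test_that("equal seeds give bit-identical cohorts", {
  s <- defaultCohortSpec(nLN = 2, nDLBCL = 2, cellsPerSample = 300,
                         doubletFrac = 0.02, deadFrac = 0.02, seed = 42)
  c1 <- simulateCohort(s)
  c2 <- simulateCohort(s)
  expect_identical(lapply(frames(c1), exprs), lapply(frames(c2), exprs))
  expect_identical(truthTable(c1), truthTable(c2))
})

test_that("doublet and dead fractions are honoured", {
  co <- simulateCohort(twoPopSpec(cells = 10000, doubletFrac = 0.05,
                                  deadFrac = 0.03, seed = 8))
  tt <- truthTable(co)
  for (sid in unique(tt$sample_id)) {
    nd <- sum(tt$doublet[tt$sample_id == sid])
    expect_gte(nd, 400)   # binomial(10000, .05) 99% interval is ~[444, 556]
    expect_lte(nd, 600)
  }
  # dead cells carry a shifted viability signal
  fr <- frames(co)[[1]]
  lb <- truthLabels(fr)
  p <- logicleParams()
  v <- logicleTransform(exprs(fr)[, "Viability"], p)
  expect_gt(mean(v[lb$dead]) - mean(v[!lb$dead]), 0.25)
})

test_that("invalid cohort specifications are rejected", {
  mcs <- list(metaclusterSpec("P1", c(A = 0.6, B = 1)))
  expect_error(simulateCohort(
    cohortSpec(data.frame(group = c("A", "B"), n = c(1, 1)), 100,
               c("M1", "M2"), mcs)), "sum to 1")
  expect_error(cohortSpec(data.frame(group = c("A", "B"), n = c(1, 1)),
                          0, c("M1", "M2"), mcs), "positive")
})

test_that("linear coupling with large beta and small noise gives r -> 1", {
  cp <- lrCoupling("S", "ICOS", "R", "ICOSL", shape = "linear",
                   beta = 0.5, noiseSd = 1e-4)
  co <- simulateCohort(miniLRSpec(nA = 10, nB = 10, cells = 400,
                                  couplings = list(cp), seed = 2))
  x <- popMedians(co, "S", "ICOS")
  y <- popMedians(co, "R", "ICOSL")
  expect_gt(cor(x, y), 0.99)
})

test_that("shape = 'none' couplings are a no-op", {
  base <- miniLRSpec(seed = 6)
  co0 <- simulateCohort(base)
  cp <- lrCoupling("S", "ICOS", "R", "ICOSL", shape = "none")
  co1 <- injectLRCoupling(co0, cp, seed = 3)
  expect_identical(lapply(frames(co0), exprs), lapply(frames(co1), exprs))
})

test_that("quadratic coupling decouples Pearson from distance correlation", {
  cp <- lrCoupling("S", "ICOS", "R", "ICOSL", shape = "quadratic",
                   beta = 0.4, noiseSd = 0.005)
  co <- simulateCohort(miniLRSpec(nA = 20, nB = 20, cells = 400,
                                  couplings = list(cp), seed = 11))
  x <- popMedians(co, "S", "ICOS")
  y <- popMedians(co, "R", "ICOSL")
  expect_lt(abs(cor(x, y)), 0.2)
  expect_gt(distanceCorrelation(x, y), 0.5)
})

test_that("coupling honesty: uncoupled medians are independent across samples", {
  rej <- vapply(1:60, function(i) {
    co <- simulateCohort(miniLRSpec(nA = 5, nB = 5, cells = 150,
                                    seed = 1000 + i))
    x <- popMedians(co, "S", "ICOS")
    y <- popMedians(co, "R", "ICOSL")
    as.numeric(dcorPvalue(x, y, nPerm = 199, seed = i)) < 0.05
  }, logical(1))
  # binomial(60, .05): >= 9 rejections has probability < 1e-3
  expect_lte(sum(rej), 8)
})

test_that("time anomalies flag exactly the windowed events", {
  co <- simulateCohort(twoPopSpec(cells = 2000, seed = 9))
  fr <- frames(co)[[1]]
  tm <- exprs(fr)[, "Time"]
  win <- unname(quantile(tm, c(0.45, 0.55)))
  out <- injectTimeAnomaly(fr, win, c(M1 = 5000))
  hit <- truthLabels(out)$anomaly
  expect_identical(hit, tm >= win[1] & tm <= win[2])
  expect_equal(exprs(out)[hit, "M1"] - exprs(fr)[hit, "M1"],
               rep(5000, sum(hit)), tolerance = 1e-9)
  expect_identical(exprs(out)[!hit, ], exprs(fr)[!hit, ])
  # zero shift changes nothing but still flags
  z <- injectTimeAnomaly(fr, win, c(M1 = 0))
  expect_identical(exprs(z), exprs(fr))
  expect_error(injectTimeAnomaly(fr, c(5, 5), c(M1 = 1)), "empty")
  expect_error(injectTimeAnomaly(fr, c(2000, 3000), c(M1 = 1)), "range")
})
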