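cleanFrame <- function(cells = 10000, seed = 1) {
  spec <- defaultCohortSpec(nLN = 2, nDLBCL = 2, cellsPerSample = cells,
                            seed = seed)
  frames(simulateCohort(spec))[[1]]
}

test_that("QC keeps clean samples nearly intact and is idempotent", {
  fr <- cleanFrame(8000, seed = 31)
  res <- removeAnomalousSegments(fr)
  expect_lte(res$report$removedFraction, 0.05)
  res2 <- removeAnomalousSegments(res$frame)
  expect_identical(res2$report$nRemoved, 0L)
  expect_identical(exprs(res2$frame), exprs(res$frame))
})

test_that("QC recovers injected clog windows", {
  fr <- cleanFrame(10000, seed = 32)
  tm <- exprs(fr)[, "Time"]
  win <- unname(quantile(tm, c(0.40, 0.50)))   # ~10% of events
  shift <- setNames(rep(4000, 5), c("CXCR5", "PD1", "HLADR", "CD127",
                                    "CD45RA"))
  bad <- injectTimeAnomaly(fr, win, shift)
  res <- removeAnomalousSegments(bad)
  inWin <- truthLabels(bad)$anomaly
  removedTimes <- setdiff(tm, exprs(res$frame)[, "Time"])
  recovered <- mean(tm[inWin] %in% removedTimes)
  expect_gte(recovered, 0.9)
  # clean events mostly survive
  expect_lte(res$report$removedFraction, mean(inWin) + 0.06)
})

test_that("an infinite threshold removes nothing", {
  fr <- cleanFrame(5000, seed = 33)
  res <- removeAnomalousSegments(fr, c = 1e9)
  expect_identical(res$report$nRemoved, 0L)
  expect_error(removeAnomalousSegments(fr, segmentSize = 10), "50")
  expect_error(removeAnomalousSegments(fr, c = -1), "positive")
})

test_that("downsampling is uniform, capped and deterministic", {
  fr <- cleanFrame(2000, seed = 34)
  same <- downsampleEvents(fr, 5000, seed = 1)
  expect_identical(exprs(same), exprs(fr))
  d1 <- downsampleEvents(fr, 100, seed = 7)
  d2 <- downsampleEvents(fr, 100, seed = 7)
  expect_identical(nEvents(d1), 100L)
  expect_identical(exprs(d1), exprs(d2))
  expect_false(identical(exprs(downsampleEvents(fr, 100, seed = 8)),
                         exprs(d1)))
  expect_error(downsampleEvents(fr, 0), "at least 1")
})

test_that("downsampling preserves population proportions in expectation", {
  fr <- cleanFrame(4000, seed = 35)
  pop <- truthLabels(fr)$population
  base <- table(pop) / length(pop)
  ps <- vapply(1:100, function(i) {
    d <- downsampleEvents(fr, 400, seed = 100 + i)
    obs <- table(factor(truthLabels(d)$population, names(base)))
    suppressWarnings(chisq.test(obs, p = as.numeric(base))$p.value)
  }, numeric(1))
  # goodness-of-fit rejections should stay near the nominal 5% rate
  expect_lte(mean(ps < 0.05), 0.12)
})

test_that("logZScale centers, scales and applies the shift rule", {
  m <- rbind(a = c(5, 5, 5, 5), b = c(1, 2, 4, 8), c = c(-1, 0, 2, 6))
  z <- logZScale(m)
  expect_identical(z["a", ], setNames(rep(0, 4), colnames(m)))
  expect_lt(abs(mean(z["b", ])), 1e-12)
  expect_lt(abs(sd(z["b", ]) - 1), 1e-12)
  # row c is shifted by 1 - min = 2 before the log
  expect_equal(unname(z["c", ]),
               as.numeric(scale(log(c(-1, 0, 2, 6) + 2))),
               tolerance = 1e-12)
})

test_that("low-count samples are excluded by strict less-than", {
  counts <- c(s1 = 99, s2 = 100, s3 = 2500)
  res <- excludeLowCountSamples(counts)
  expect_identical(res$retained, c("s2", "s3"))
  expect_identical(res$excluded$sample_id, "s1")
  expect_match(res$excluded$reason, "fewer than 100")
  expect_error(excludeLowCountSamples(c(a = 5, b = 8)), "all samples")
})
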