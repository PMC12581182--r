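test_that("MEM scores vanish on self-reference and follow the sign rule", {
  set.seed(2)
  m <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("M", 1:4)))
  s <- memScores(m, m)
  expect_true(all(s == 0))
  pop <- m; pop[, "M1"] <- pop[, "M1"] + 5
  s1 <- memScores(pop, m)
  expect_gt(s1[["M1"]], 0)
  s2 <- memScores(m, pop)
  expect_equal(unname(s1), -unname(s2), tolerance = 1e-10)
  expect_error(memScores(m[, 1:3], m), "markers")
})

test_that("MEM scores reproduce a hand-evaluated toy", {
  # population marker A: median 2, IQR 1; reference: median 0.5, IQR 2
  #   raw_A = |2 - 0.5| + 2/1 - 1 = 2.5 (positive)
  # marker B: pop median 1, IQR 2; ref median 2, IQR 1
  #   raw_B = |1 - 2| + 1/2 - 1 = 0.5 (negative)
  # scaling: max |raw| = 2.5 -> A = +10, B = -2
  pop <- cbind(A = c(1.5, 1.75, 2, 2.25, 2.5),
               B = c(-1, 0, 1, 2, 3))
  ref <- cbind(A = c(-0.5, 0, 0.5, 1, 1.5),
               B = c(1, 1.5, 2, 2.5, 3))
  s <- memScores(pop, ref)
  expect_equal(unname(s[["A"]]), 10, tolerance = 1e-10)
  expect_equal(unname(s[["B"]]), -2, tolerance = 1e-10)
  # invariant to cell order
  expect_equal(memScores(pop[5:1, ], ref[c(3, 1, 5, 2, 4), ]), s)
  # scale-invariant when both groups share equal IQR structure
  popE <- cbind(A = c(0, 1, 2, 3, 4), B = c(0, 1, 2, 3, 4) + 3)
  refE <- cbind(A = c(1, 2, 3, 4, 5), B = c(0, 1, 2, 3, 4))
  expect_equal(memScores(2 * popE, 2 * refE), memScores(popE, refE),
               tolerance = 1e-10)
})

test_that("a separable population is gated by one constraint at F1 = 1", {
  set.seed(6)
  n <- 2000
  m <- cbind(M1 = runif(n), M2 = runif(n), M3 = runif(n))
  target <- m[, "M1"] > 0.7
  g <- fitGate(m, target)
  expect_equal(gateF1(g), 1, tolerance = 1e-9)
  cs <- gateConstraints(g)
  expect_identical(nrow(cs), 1L)
  expect_identical(cs$marker, "M1")
  expect_lt(abs(cs$lower - 0.7), 0.02)
  expect_identical(applyGate(g, m), target)
  # importance of the single perfect constraint is 1 - F1(empty gate)
  imp <- markerImportanceScores(g)
  expect_equal(unname(imp[["M1"]]), 1 - flowSDC:::.f1(rep(TRUE, n), target),
               tolerance = 1e-9)
})

test_that("an all-positive target yields the empty gate with F1 = 1", {
  m <- cbind(M1 = runif(100), M2 = runif(100))
  g <- fitGate(m, rep(TRUE, 100))
  expect_identical(nrow(gateConstraints(g)), 0L)
  expect_equal(gateF1(g), 1)
  expect_error(fitGate(m, rep(FALSE, 100)), "no positive")
  expect_warning(fitGate(m, c(rep(TRUE, 5), rep(FALSE, 95))), "fewer than 10")
})

test_that("redundant duplicated constraints each have near-zero importance", {
  set.seed(8)
  n <- 1000
  a <- runif(n)
  m <- cbind(A = a, B = a, C = runif(n))   # A and B duplicated
  target <- a > 0.6
  gate <- new("GateSpec",
              constraints = data.frame(marker = c("A", "B"),
                                       lower = c(0.6, 0.6),
                                       upper = c(Inf, Inf)),
              f1 = 1, importance = numeric(0), target = "dup")
  imp <- markerImportance(gate, m, target)
  expect_lt(max(abs(imp)), 1e-9)
  # ungated markers are absent (importance 0 by definition)
  expect_false("C" %in% names(imp))
})

test_that("the follicular-regulatory analogue is recovered by four markers", {
  spec <- defaultCohortSpec(nLN = 2, nDLBCL = 3, cellsPerSample = 2500,
                            seed = 51)
  co <- simulateCohort(spec)
  p <- logicleParams()
  mk <- clusteringMarkers()
  X <- do.call(rbind, lapply(frames(co), function(fr)
    apply(exprs(fr)[, mk], 2, logicleTransform, p = p)))
  target <- truthTable(co)$population == "MC09tfr"
  g <- fitGate(X, target, targetName = "MC09tfr")
  expect_gte(gateF1(g), 0.9)
  expect_lte(nrow(gateConstraints(g)), 5L)
  imp <- markerImportanceScores(g)
  top4 <- names(sort(imp, decreasing = TRUE))[1:4]
  expect_setequal(intersect(top4, c("CXCR5", "PD1", "HLADR", "CD127")),
                  top4)
})

test_that("greedy gating never decreases F1 below the empty gate", {
  set.seed(9)
  m <- matrix(runif(3000), 1000, 3, dimnames = list(NULL, c("A", "B", "C")))
  target <- m[, "A"] + m[, "B"] > 1.2
  g <- fitGate(m, target)
  emptyF1 <- flowSDC:::.f1(rep(TRUE, nrow(m)), target)
  expect_gte(gateF1(g), emptyF1)
  expect_true(all(markerImportanceScores(g) >= 0))
  expect_true(all(markerImportanceScores(g) <= 1))
})
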