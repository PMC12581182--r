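test_that("Mann-Whitney enumeration reproduces hand-counted cases", {
  r <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)       # 2 of the 20 arrangements are as extreme
  expect_identical(r$method, "exact-enumeration")
  same <- mannWhitney(c(3, 1, 2), c(2, 1, 3))
  expect_equal(same$p, 1)
  expect_error(mannWhitney(numeric(0), 1:3), "non-empty")
})

test_that("the exact branch agrees with an independent oracle (n <= 8)", {
  set.seed(70)
  for (nA in 1:7) for (nB in 1:(8 - nA)) {
    x <- rnorm(nA); y <- rnorm(nB)     # continuous: no ties
    ours <- mannWhitney(x, y)
    ref <- wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12,
                 label = sprintf("p at nA=%d nB=%d", nA, nB))
    expect_equal(ours$U, unname(ref$statistic), tolerance = 1e-12)
  }
})

test_that("the large-sample branch applies the tie-corrected normal", {
  set.seed(71)
  x <- round(rnorm(15), 1); y <- round(rnorm(12, 0.8), 1)
  ours <- mannWhitney(x, y)
  expect_identical(ours$method, "normal-approximation")
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
})

test_that("Kruskal-Wallis + Dunn orders shifted groups correctly", {
  vals <- c(1, 2, 3, 1.5, 2.5, 3.5, 10, 11, 12)
  grp <- rep(c("a", "b", "c"), each = 3)
  r <- kruskalWallisDunn(vals, grp)
  # independent H computation: H = 12/(N(N+1)) * sum(R_g^2/n_g) - 3(N+1)
  rk <- rank(vals)
  H <- 12 / (9 * 10) * sum(tapply(rk, grp, sum)^2 / 3) - 3 * 10
  expect_equal(r$H, H, tolerance = 1e-12)
  pw <- r$pairwise
  involved <- pw$groupA == "c" | pw$groupB == "c"
  expect_true(max(pw$p[involved]) < min(pw$p[!involved]))
  expect_true(all(pw$p_adj >= pw$p))
  # three identical groups: H = 0, pairwise p = 1
  same <- kruskalWallisDunn(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(same$H, 0, tolerance = 1e-12)
  expect_true(all(same$pairwise$p == 1))
  expect_error(kruskalWallisDunn(1:4, rep(c("a", "b"), 2)), "3 groups")
})

test_that("PCA of frequencies identifies the shifted population", {
  set.seed(72)
  n <- 10
  freq <- data.frame(P1 = rnorm(n, 20, 0.5), P2 = rnorm(n, 30, 0.5),
                     P3 = rnorm(n, 10, 0.5), P4 = rnorm(n, 40, 0.5))
  freq$P1[6:10] <- freq$P1[6:10] + 15          # pure group shift in P1
  r <- pcaFrequencies(freq)
  expect_identical(r$topContributors$population[1], "P1")
  L <- r$loadings
  expect_equal(crossprod(L), diag(ncol(L)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(r$explainedVar) <= 1e-12))
  expect_lte(sum(r$explainedVar), 1 + 1e-12)
  # reconstruction from all components returns the scaled input
  rec <- r$scores %*% t(L)
  expect_equal(rec, scale(as.matrix(freq)), tolerance = 1e-10,
               ignore_attr = TRUE)
  freq2 <- freq; freq2$P2 <- 30
  expect_warning(pcaFrequencies(freq2), "constant")
  freq3 <- freq; freq3$P1[1] <- NA
  expect_error(pcaFrequencies(freq3), "imputation is refused")
  expect_error(pcaFrequencies(freq[1:2, ]), "3 samples")
})

test_that("population comparisons flag a strong two-group enrichment", {
  set.seed(73)
  sheet <- data.frame(sample_id = paste0("s", 1:9),
                      group = rep(c("LN", "DLBCL"), c(4, 5)))
  freq <- data.frame(
    MC09 = c(rnorm(4, 1, 0.3), rnorm(5, 8, 1.5)),   # enriched
    MC01 = c(rnorm(4, 25, 3), rnorm(5, 24, 3)),
    MC05 = c(rnorm(4, 15, 2), rnorm(5, 16, 2)),
    row.names = sheet$sample_id)
  cmp <- comparePopulations(freq, sheet, design = "two-group")
  expect_identical(nrow(cmp), 3L)
  r9 <- cmp[cmp$population == "MC09", ]
  expect_lt(r9$p, 0.05)
  expect_true(r9$tier != "ns")
  expect_true(all(c("mean_DLBCL", "sem_LN", "median_DLBCL", "iqr_LN")
                  %in% names(cmp)))
  # tiers are a pure function of adjusted p
  expect_identical(cmp$tier, flowSDC:::.sigTier(cmp$p_adj))
})

test_that("permuted group labels keep the false-positive rate nominal", {
  set.seed(74)
  sheet <- data.frame(sample_id = paste0("s", 1:10),
                      group = rep(c("A", "B"), each = 5))
  hits <- vapply(1:60, function(i) {
    freq <- as.data.frame(matrix(rnorm(10 * 6, 10, 2), 10, 6,
                                 dimnames = list(sheet$sample_id,
                                                 paste0("P", 1:6))))
    sum(comparePopulations(freq, sheet, "two-group")$p < 0.05)
  }, numeric(1))
  # 360 null tests at alpha = .05: expect ~18 hits, bound generously
  expect_lte(sum(hits), 38)
})

test_that("report bundles are complete, stable and tolerant of gaps", {
  out <- file.path(tempdir(), "repA")
  tabs <- list(comparisons = data.frame(a = 1:3, b = c("x", "y", "z")),
               pca_scores = NULL,
               lr = data.frame(p = c(0.01, 0.2)))
  m1 <- buildReport(tabs, out, runInfo = list(seed = 7, k = 11))
  files <- list.files(out)
  expect_setequal(files, c("comparisons.csv", "lr.csv", "manifest.json",
                           "run.log"))
  present <- vapply(m1$tables, `[[`, logical(1), "present")
  expect_identical(present, c(TRUE, FALSE, TRUE))
  h1 <- tools::md5sum(file.path(out, files))
  buildReport(tabs, out, runInfo = list(seed = 7, k = 11))
  expect_identical(tools::md5sum(file.path(out, files)), h1)
})
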