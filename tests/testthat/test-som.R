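test_that("SOM training is deterministic and absorbs a degenerate input", {
  bl <- simulateBlobs(n = 200, k = 3, d = 4, seed = 3)
  s1 <- trainSOM(bl$data, grid = c(5, 5), seed = 9)
  s2 <- trainSOM(bl$data, grid = c(5, 5), seed = 9)
  expect_identical(codebook(s1), codebook(s2))
  expect_false(identical(codebook(trainSOM(bl$data, grid = c(5, 5),
                                           seed = 10)),
                         codebook(s1)))
  # a single replicated point pulls every node onto it
  one <- matrix(rep(c(0.3, 0.7), each = 40), 40, 2,
                dimnames = list(NULL, c("A", "B")))
  expect_warning(sp <- trainSOM(one, grid = c(3, 3), seed = 1),
                 "fewer than 5")
  expect_true(all(abs(sweep(codebook(sp), 2, c(0.3, 0.7))) < 1e-3))
  expect_error(trainSOM(bl$data[, 1, drop = FALSE], seed = 1), "2 markers")
  x <- bl$data; x[1, 1] <- NaN
  expect_error(trainSOM(x, seed = 1), "non-finite")
})

test_that("BMU assignment equals the brute-force oracle and breaks ties low", {
  bl <- simulateBlobs(n = 400, k = 3, d = 5, seed = 5)
  som <- trainSOM(bl$data, grid = c(6, 6), seed = 6)
  idx <- sample(nrow(bl$data), 1000, replace = TRUE)
  expect_identical(assignCells(som, bl$data[idx, ]),
                   oracleBMU(bl$data[idx, ], codebook(som)))
  # exact codebook vector maps to its own node
  expect_identical(assignCells(som, codebook(som)),
                   seq_len(nrow(codebook(som))))
  # exact equidistant tie resolves to the lower node index
  tie <- new("SOMModel",
             codebook = matrix(c(0, 1, 0, 0), 2, 2,
                               dimnames = list(NULL, c("A", "B"))),
             gridDim = c(1L, 2L), markers = c("A", "B"), meta = list())
  expect_identical(assignCells(tie, matrix(c(0.5, 0), 1, 2,
                                           dimnames = list(NULL, c("A", "B")))),
                   1L)
})

test_that("consensus metaclustering recovers separated blobs", {
  bl <- simulateBlobs(n = 1000, k = 3, d = 5, sep = 8, seed = 7)
  som <- trainSOM(bl$data, grid = c(10, 10), seed = 8)
  nodes <- assignCells(som, bl$data)
  mc <- metaclusterNodes(som, 3, seed = 9)
  expect_gte(ariIndex(mc[nodes], bl$labels), 0.9)
  # k = nodes is the identity map; B = 1 with a seed is reproducible
  expect_identical(metaclusterNodes(som, 100), 1:100)
  expect_identical(metaclusterNodes(som, 5, B = 1, seed = 4),
                   metaclusterNodes(som, 5, B = 1, seed = 4))
  expect_error(metaclusterNodes(som, 1), "range")
  expect_error(metaclusterNodes(som, 101), "range")
})

test_that("the elbow criterion finds k on separated data and falls back", {
  bl <- simulateBlobs(n = 1000, k = 3, d = 5, sep = 8, seed = 12)
  som <- trainSOM(bl$data, grid = c(10, 10), seed = 13)
  k <- selectKElbow(som, 2:8, seed = 14)
  expect_identical(as.integer(k), 3L)
  curve <- attr(k, "curve")
  expect_identical(nrow(curve), 7L)
  expect_identical(curve$k, 2:8)
  # featureless data: no elbow, smallest k with a warning
  set.seed(15)
  flat <- matrix(0.5 + rnorm(4000, 0, 1e-9), 1000, 4,
                 dimnames = list(NULL, paste0("M", 1:4)))
  somf <- trainSOM(flat, grid = c(6, 6), seed = 16)
  expect_warning(kf <- selectKElbow(somf, 2:8, seed = 17), "no elbow")
  expect_identical(as.integer(kf), 2L)
  expect_error(selectKElbow(som, 2:3), "at least 3")
})

test_that("metacluster recovery degrades gracefully with separation", {
  ari <- vapply(c(2, 5, 8), function(sep) {
    bl <- simulateBlobs(n = 600, k = 3, d = 5, sep = sep, seed = 20)
    som <- trainSOM(bl$data, grid = c(8, 8), seed = 21)
    ariIndex(metaclusterNodes(som, 3, seed = 22)[assignCells(som, bl$data)],
             bl$labels)
  }, numeric(1))
  expect_true(all(diff(ari) >= -0.02))   # monotone up to noise
  expect_gte(ari[3], 0.9)
})

test_that("metacluster frequencies are percentages of the parent", {
  pops <- c("A", "A", "A", "B", "B", "B", "B", "B", "B", "B",
            "A", "A", "A", "A", "A", "A", "A", "B", "B", "B")
  sids <- rep(c("s1", "s2"), each = 10)
  f <- mcFrequencies(pops, sids)
  expect_equal(f["s1", "A"], 30)
  expect_equal(f["s1", "B"], 70)
  expect_equal(f["s2", "A"], 70)
  expect_true(all(abs(rowSums(f) - 100) < 1e-9))
  # permutation invariance to cell order
  o <- sample(20)
  expect_equal(mcFrequencies(pops[o], sids[o]), f)
  # one population only
  expect_equal(mcFrequencies(rep("A", 5), rep("s", 5))[["A"]], 100)
  # zero parent count flagged, not divided
  expect_warning(fz <- mcFrequencies(pops, sids,
                                     parentCounts = c(s1 = 10, s2 = 0)),
                 "zero parent")
  expect_true(all(is.na(fz["s2", ])))
})
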