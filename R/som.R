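#' Train a self-organising map
#'
#' Online SOM training on a cells x markers matrix: cells are presented
#' one at a time (in seeded random order, `epochs` passes through the
#' data); the best-matching unit (BMU) is the node with smallest
#' Euclidean distance; all nodes are pulled towards the cell with a
#' Gaussian neighbourhood weight whose radius decays linearly from the
#' 0.67 quantile of the grid distances to 0, while the learning rate
#' decays linearly between `alpha[1]` and `alpha[2]`. The codebook is
#' initialised from a seeded random sample of cells. Deterministic under
#' `seed`.
#'
#' @param x Numeric matrix, cells x markers (transformed and scaled as
#'   desired), with column names.
#' @param grid Integer vector (rows, cols); default a 10 x 10 grid of
#'   100 nodes.
#' @param epochs Passes through the data (default 10).
#' @param alpha Length-2 numeric: initial and final learning rate.
#' @param seed Integer seed.
#' @return A [SOMModel-class].
#' @export
trainSOM <- function(x, grid = c(10, 10), epochs = 10,
                     alpha = c(0.05, 0.01), seed = 1L) {
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric matrix")
  if (any(!is.finite(x))) stop("non-finite values in the training matrix")
  if (ncol(x) < 2L) stop("need at least 2 markers")
  if (is.null(colnames(x))) stop("training matrix must have column names")
  grid <- as.integer(grid)
  nnodes <- prod(grid)
  if (nrow(x) < nnodes * 5L)
    warning("fewer than 5 cells per node; the map may be unstable")
  gridxy <- as.matrix(expand.grid(row = seq_len(grid[1]),
                                  col = seq_len(grid[2])))
  storage.mode(gridxy) <- "double"
  set.seed(seed)
  init <- x[sample.int(nrow(x), nnodes, replace = nrow(x) < nnodes), ,
            drop = FALSE]
  nupd <- as.integer(epochs) * nrow(x)
  order <- as.integer(unlist(lapply(seq_len(epochs), function(i)
    sample.int(nrow(x)))))
  r0 <- unname(stats::quantile(stats::dist(gridxy), 0.67))
  radii <- seq(r0, 0, length.out = nupd)
  alphas <- seq(alpha[1], alpha[2], length.out = nupd)
  cb <- .somTrain(x, init, gridxy, order, radii, alphas)
  colnames(cb) <- colnames(x)
  new("SOMModel", codebook = cb, gridDim = grid, markers = colnames(x),
      meta = list(epochs = epochs, alpha = alpha, radius0 = r0,
                  seed = seed))
}

#' Assign cells to SOM nodes
#'
#' Maps each cell to its best-matching unit (the node whose codebook
#' vector is nearest in Euclidean distance); exact ties are broken by
#' the lowest node index.
#'
#' @param som A [SOMModel-class].
#' @param x Cells x markers matrix with the same marker columns as used
#'   in training (matched by name).
#' @return Integer vector of 1-based node indices.
#' @export
assignCells <- function(som, x) {
  stopifnot(is(som, "SOMModel"))
  if (is.null(colnames(x)) || !all(som@markers %in% colnames(x)))
    stop("marker columns do not match the trained map")
  x <- x[, som@markers, drop = FALSE]
  if (any(!is.finite(x))) stop("non-finite values in input")
  .somAssign(x, som@codebook)
}

# seeded bootstrap dendrograms of the codebook, shared across k
.bootstrapTrees <- function(codebook, B, seed) {
  set.seed(seed)
  lapply(seq_len(B), function(b) {
    idx <- sort(unique(sample.int(nrow(codebook), replace = TRUE)))
    list(idx = idx,
         hc = stats::hclust(stats::dist(codebook[idx, , drop = FALSE]),
                            method = "average"))
  })
}

.consensusMatrix <- function(trees, nnodes, k) {
  hits <- matrix(0, nnodes, nnodes)
  both <- matrix(0, nnodes, nnodes)
  for (tr in trees) {
    idx <- tr$idx
    both[idx, idx] <- both[idx, idx] + 1
    cl <- stats::cutree(tr$hc, k = min(k, length(idx)))
    same <- outer(cl, cl, "==")
    hits[idx, idx] <- hits[idx, idx] + same
  }
  cons <- ifelse(both > 0, hits / both, 0)
  diag(cons) <- 1
  cons
}

#' Group SOM nodes into metaclusters
#'
#' Consensus metaclustering of the codebook: `B` bootstrap resamples of
#' the nodes are each clustered by average-linkage hierarchical
#' clustering and cut at `k`; the consensus matrix (fraction of
#' co-assignments among co-sampled node pairs) is then clustered by
#' average linkage on `1 - consensus` and cut at `k`. Metacluster labels
#' are renumbered in order of first appearance over the node index.
#'
#' @param som A [SOMModel-class].
#' @param k Number of metaclusters, `2 <= k <= nodes` (`k = nodes`
#'   returns the identity map).
#' @param B Bootstrap resamples (default 100).
#' @param seed Integer seed.
#' @return Integer vector: metacluster label per node.
#' @export
metaclusterNodes <- function(som, k, B = 100, seed = 1L) {
  stopifnot(is(som, "SOMModel"))
  nnodes <- nrow(som@codebook)
  if (k < 2 || k > nnodes) stop("k out of range [2, nodes]")
  if (k == nnodes) return(seq_len(nnodes))
  trees <- .bootstrapTrees(som@codebook, B, seed)
  cons <- .consensusMatrix(trees, nnodes, k)
  hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
  cl <- stats::cutree(hc, k = k)
  as.integer(factor(cl, levels = unique(cl)))
}

#' Elbow-guided choice of the metacluster number
#'
#' Computes the within-metacluster sum of squares (WSS) of the codebook
#' vectors for each candidate `k` (using the same consensus
#' metaclustering as [metaclusterNodes()]) and returns the `k`
#' maximising the discrete curvature (second difference) of the WSS
#' curve. When the curve shows no elbow (all curvatures non-positive or
#' negligible) the smallest `k` is returned with a warning. The choice
#' is advisory - pipelines may override it.
#'
#' @param som A [SOMModel-class].
#' @param kRange Candidate values of `k` (length >= 3, within
#'   `[2, nodes]`).
#' @param B,seed Passed to [metaclusterNodes()].
#' @return The selected `k`, with attribute `curve` (data.frame of `k`
#'   and `wss`).
#' @export
selectKElbow <- function(som, kRange = 2:12, B = 100, seed = 1L) {
  stopifnot(is(som, "SOMModel"))
  kRange <- sort(unique(as.integer(kRange)))
  if (length(kRange) < 3L) stop("kRange must contain at least 3 values")
  cb <- som@codebook
  wss <- vapply(kRange, function(k) {
    cl <- metaclusterNodes(som, k, B = B, seed = seed)
    sum(vapply(split(seq_len(nrow(cb)), cl), function(idx) {
      sum(scale(cb[idx, , drop = FALSE], scale = FALSE)^2)
    }, numeric(1)))
  }, numeric(1))
  curve <- data.frame(k = kRange, wss = wss)
  i <- seq(2, length(kRange) - 1L)
  curvature <- wss[i - 1] - 2 * wss[i] + wss[i + 1]
  if (all(curvature <= max(1e-10, 1e-8 * wss[1]))) {
    warning("no elbow detected; returning the smallest k")
    k <- kRange[1]
  } else {
    k <- kRange[i[which.max(curvature)]]
  }
  structure(k, curve = curve)
}

#' Per-sample metacluster frequencies
#'
#' Frequencies as percentage of the parent population:
#' `100 * (cells in metacluster and sample) / (parent cells in sample)`.
#' With the default parent counts (all assigned cells per sample) the
#' percentages sum to 100 within each sample.
#'
#' @param populations Per-cell population labels (metacluster ids or
#'   names).
#' @param sampleIds Per-cell sample identifiers (same length).
#' @param parentCounts Optional named per-sample parent counts; default
#'   is the number of assigned cells per sample. Samples with a zero
#'   parent count get `NA` frequencies and a warning, never a division
#'   by zero.
#' @return A data.frame, samples x populations, of percentages; row
#'   names are sample ids.
#' @export
mcFrequencies <- function(populations, sampleIds, parentCounts = NULL) {
  if (length(populations) != length(sampleIds))
    stop("populations and sampleIds must have equal length")
  tab <- table(sample_id = sampleIds, population = populations)
  counts <- matrix(as.numeric(tab), nrow(tab), ncol(tab),
                   dimnames = dimnames(tab))
  if (is.null(parentCounts)) parentCounts <- rowSums(counts)
  parentCounts <- parentCounts[rownames(counts)]
  zero <- !is.finite(parentCounts) | parentCounts == 0
  if (any(zero)) {
    warning("zero parent count for sample(s): ",
            paste(rownames(counts)[zero], collapse = ", "))
    parentCounts[zero] <- NA_real_
  }
  as.data.frame(100 * counts / parentCounts)
}
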