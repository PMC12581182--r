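#' Run the unsupervised TME analysis pipeline on a cohort
#'
#' End-to-end analysis mirroring the study workflow on a cohort with
#' per-cell compartment labels (for synthetic cohorts, the truth table
#' stands in for manual pre-gating):
#' \enumerate{
#'   \item anomaly QC per sample ([removeAnomalousSegments()]) and
#'     removal of labelled doublets/dead cells;
#'   \item optional per-sample downsampling;
#'   \item logicle transformation of the clustering markers and
#'     per-marker z-scaling (pooled over the clustered compartment);
#'   \item SOM training (default 10 x 10 grid) on the cells of the
#'     clustered compartment, consensus metaclustering into `k`
#'     metaclusters (elbow-guided when `k = NULL`), per-sample
#'     metacluster frequencies and low-count sample exclusion;
#'   \item two-group frequency comparison (Mann-Whitney,
#'     Benjamini-Hochberg across metaclusters);
#'   \item median-intensity profiles of metaclusters and of the other
#'     (non-clustered) populations, and the signed distance-correlation
#'     ligand-receptor and frequency screens, optionally restricted to
#'     one sample group.
#' }
#'
#' @param cohort A [CytoCohort-class] whose frames carry labels with
#'   `population` and `parent` columns.
#' @param clusterParent Compartment to cluster (default `"CD8"`).
#' @param markers Clustering markers (default [clusteringMarkers()]
#'   intersected with the panel).
#' @param grid SOM grid (default `c(10, 10)`).
#' @param k Number of metaclusters; `NULL` for elbow-guided selection.
#' @param nPerSample Downsampling target per sample (`NULL` = keep all).
#' @param qc Apply acquisition-anomaly QC (default TRUE).
#' @param removeArtefacts Drop labelled doublet/dead events (default
#'   TRUE).
#' @param minParentCells Low-count exclusion threshold on the clustered
#'   compartment per sample (default 100, strict less-than).
#' @param catalogue Ligand-receptor catalogue (default
#'   [defaultLRCatalogue()]).
#' @param screenGroup Restrict the communication screens to this sample
#'   group (e.g. `"DLBCL"`); `NULL` uses all samples.
#' @param sendersOfInterest Metacluster labels to screen as senders
#'   (default: all discovered metaclusters).
#' @param nPerm,alpha Permutation and significance settings for the
#'   screens.
#' @param seed Master seed for SOM training, metaclustering,
#'   downsampling and permutations.
#' @return A list with elements `som`, `nodeAssignments`, `metaclusters`
#'   (node map), `k`, `assignments` (per-cell data.frame with
#'   `sample_id`, `population`, `parent`), `frequencies`,
#'   `tmeFrequencies`, `comparisons`, `profile`, `lrTable`, `freqTable`,
#'   `qcReports`, `excluded`, `params`.
#' @export
runPipeline <- function(cohort, clusterParent = "CD8", markers = NULL,
                        grid = c(10, 10), k = 11, nPerSample = NULL,
                        qc = TRUE, removeArtefacts = TRUE,
                        minParentCells = 100,
                        catalogue = defaultLRCatalogue(),
                        screenGroup = NULL, sendersOfInterest = NULL,
                        nPerm = 9999, alpha = 0.05, seed = 1L) {
  stopifnot(is(cohort, "CytoCohort"))
  frames <- frames(cohort)
  ss <- sampleSheet(cohort)
  qcReports <- list()
  if (qc) {
    for (sid in names(frames)) {
      res <- removeAnomalousSegments(frames[[sid]])
      frames[[sid]] <- res$frame
      qcReports[[sid]] <- res$report
    }
  }
  if (removeArtefacts) {
    for (sid in names(frames)) {
      lb <- truthLabels(frames[[sid]])
      if (all(c("doublet", "dead") %in% names(lb))) {
        keep <- !(lb$doublet | lb$dead)
        frames[[sid]]@exprs <- frames[[sid]]@exprs[keep, , drop = FALSE]
        frames[[sid]]@labels <- lb[keep, , drop = FALSE]
      }
    }
  }
  if (!is.null(nPerSample))
    frames <- downsampleEvents(frames, nPerSample, seed = seed)

  labs <- lapply(frames, truthLabels)
  for (sid in names(labs))
    if (!all(c("population", "parent") %in% names(labs[[sid]])))
      stop("frames must carry 'population' and 'parent' labels")

  markers <- markers %||% intersect(clusteringMarkers(),
                                    channels(frames[[1]]))
  tp <- logicleParams()
  # transformed clustering matrix over the clustered compartment
  matList <- lapply(names(frames), function(sid) {
    sel <- labs[[sid]]$parent == clusterParent
    e <- exprs(frames[[sid]])[sel, markers, drop = FALSE]
    apply(e, 2, logicleTransform, p = tp)
  })
  X <- do.call(rbind, matList)
  cellSample <- rep(names(frames),
                    vapply(matList, nrow, integer(1)))
  Xs <- scale(X)
  som <- trainSOM(Xs, grid = grid, seed = seed)
  nodes <- assignCells(som, Xs)
  if (is.null(k)) k <- as.integer(selectKElbow(som, seed = seed))
  mcMap <- metaclusterNodes(som, k, seed = seed)
  mcLabels <- sprintf("MC%02d", mcMap[nodes])

  freq <- mcFrequencies(mcLabels, cellSample)
  parentCounts <- table(cellSample)[rownames(freq)]
  excl <- excludeLowCountSamples(
    stats::setNames(as.integer(parentCounts), rownames(freq)),
    threshold = minParentCells)
  freq <- freq[excl$retained, , drop = FALSE]
  comparisons <- comparePopulations(
    freq, ss[ss$sample_id %in% excl$retained, ],
    design = if (length(unique(ss$group)) == 2) "two-group"
             else "multi-group")

  # per-cell population labels: metacluster for the clustered
  # compartment, truth population elsewhere
  assignments <- do.call(rbind, lapply(names(frames), function(sid) {
    lb <- labs[[sid]]
    pop <- lb$population
    pop[lb$parent == clusterParent] <-
      mcLabels[cellSample == sid]
    data.frame(sample_id = sid, population = pop, parent = lb$parent,
               truthPopulation = lb$population, stringsAsFactors = FALSE)
  }))
  profile <- medianProfile(frames, assignments)

  tmePops <- sort(unique(assignments$population[
    assignments$parent != clusterParent]))
  tmeFreq <- if (length(tmePops)) {
    sel <- assignments$parent != clusterParent
    mcFrequencies(assignments$population[sel],
                  assignments$sample_id[sel])
  } else NULL

  screenSamples <- if (is.null(screenGroup)) ss$sample_id
                   else ss$sample_id[ss$group %in% screenGroup]
  screenSamples <- intersect(screenSamples, excl$retained)
  prof <- profile[profile$sample_id %in% screenSamples, ]
  class(prof) <- class(profile)
  attr(prof, "scale") <- attr(profile, "scale")
  senders <- sendersOfInterest %||% sort(unique(mcLabels))
  lrTable <- if (length(tmePops))
    lrScreen(prof, catalogue, senders = senders, receivers = tmePops,
             alpha = alpha, nPerm = nPerm, seed = seed)
  else NULL

  freqTable <- if (!is.null(tmeFreq)) {
    keep <- intersect(screenSamples, rownames(freq))
    comb <- cbind(freq[keep, , drop = FALSE],
                  tmeFreq[keep, , drop = FALSE])
    tryCatch(
      frequencyScreen(comb, populations = senders,
                      against = tmePops, alpha = alpha, nPerm = nPerm,
                      seed = seed),
      error = function(e) NULL)
  } else NULL

  list(som = som, nodeAssignments = nodes, metaclusters = mcMap, k = k,
       assignments = assignments, frequencies = freq,
       tmeFrequencies = tmeFreq, comparisons = comparisons,
       profile = profile, lrTable = lrTable, freqTable = freqTable,
       qcReports = qcReports, excluded = excl$excluded,
       params = list(grid = grid, k = k, markers = markers,
                     seed = seed, alpha = alpha, nPerm = nPerm,
                     screenGroup = screenGroup))
}
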