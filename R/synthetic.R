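#' Describe a synthetic metacluster
#'
#' One simulated cell population: its per-group mixing proportions and
#' its marker profile as Gaussian mean/sd on the transformed (logicle)
#' scale. Markers not listed fall back to the background level
#' (mean 0.25 - the logicle image of raw 0 under the default parameters -
#' sd 0.06).
#'
#' @param name Population name.
#' @param proportions Named numeric vector, one mixing proportion per
#'   group; proportions of all metaclusters must sum to 1 within each
#'   group.
#' @param mean,sd Named numeric vectors of per-marker transformed-scale
#'   means and standard deviations (partial; background applied to the
#'   rest).
#' @param parent Parent compartment label, e.g. `"CD8"` or `"TME"`; used
#'   by the pipeline to emulate pre-gating from ground truth.
#' @return A list understood by [cohortSpec()].
#' @export
metaclusterSpec <- function(name, proportions, mean = numeric(0),
                            sd = numeric(0), parent = "CD8") {
  stopifnot(is.character(name), length(name) == 1L,
            !is.null(names(proportions)))
  list(name = name, proportions = proportions, mean = mean, sd = sd,
       parent = parent)
}

#' Describe a ligand-receptor coupling to inject
#'
#' A latent per-sample factor `u_s ~ N(0, 1)` drives the ligand marker of
#' the sender population and the receptor marker of the receiver
#' population. With `shape = "linear"` both sides are shifted by
#' `beta * u_s`; with `shape = "quadratic"` the receiver side is shifted
#' by `beta * (u_s^2 - 1)` (centered, so the across-sample linear
#' correlation with the sender is near zero by construction);
#' `shape = "none"` is a no-op. Per-sample Gaussian noise with standard
#' deviation `noiseSd` is added to each side.
#'
#' @param sender,receiver Population names in the cohort's truth table.
#' @param ligand,receptor Marker names in the cohort's panel.
#' @param shape One of `"linear"`, `"quadratic"`, `"none"`.
#' @param beta Effect size, `>= 0`, on the transformed scale.
#' @param noiseSd Per-sample noise standard deviation, `>= 0`.
#' @return A list understood by [cohortSpec()] and [injectLRCoupling()].
#' @export
lrCoupling <- function(sender, ligand, receiver, receptor,
                       shape = c("linear", "quadratic", "none"),
                       beta = 0.3, noiseSd = 0.02) {
  shape <- match.arg(shape)
  stopifnot(beta >= 0, noiseSd >= 0)
  list(sender = sender, ligand = ligand, receiver = receiver,
       receptor = receptor, shape = shape, beta = beta, noiseSd = noiseSd)
}

#' Construct a cohort specification
#'
#' @param groups data.frame with columns `group` and `n` (samples per
#'   group), at least two groups.
#' @param cellsPerSample Events per sample.
#' @param markers Ordered unique marker names (a `Time` channel is added
#'   automatically at simulation).
#' @param metaclusters List of [metaclusterSpec()] entries.
#' @param couplings List of [lrCoupling()] entries applied at simulation.
#' @param doubletFrac,deadFrac Expected artefact fractions in `[0, 1]`.
#' @param anomalyWindows List of time-anomaly settings, each a list with
#'   `sample` (sample id), `window` (start/end acquisition time) and
#'   `shift` (named per-marker raw-intensity offset).
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return A validated [CohortSpec-class] object.
#' @export
cohortSpec <- function(groups, cellsPerSample, markers, metaclusters,
                       couplings = list(), doubletFrac = 0, deadFrac = 0,
                       anomalyWindows = list(), seed = 1L) {
  if (cellsPerSample < 1) stop("cellsPerSample must be positive")
  mcl <- stats::setNames(metaclusters,
                         vapply(metaclusters, `[[`, character(1), "name"))
  for (cp in couplings)
    if (!all(c(cp$ligand, cp$receptor) %in% markers))
      stop(sprintf("coupling markers '%s'/'%s' not in the marker list",
                   cp$ligand, cp$receptor))
  new("CohortSpec", groups = as.data.frame(groups),
      cellsPerSample = as.integer(cellsPerSample),
      markers = as.character(markers), metaclusters = mcl,
      couplings = couplings, doubletFrac = doubletFrac,
      deadFrac = deadFrac, anomalyWindows = anomalyWindows,
      seed = as.integer(seed))
}

# background transformed-scale level: logicle image of raw 0 with the
# default parameters
.BG_MEAN <- 0.25
.BG_SD <- 0.06

.mcProfile <- function(mc, markers) {
  mu <- rep(.BG_MEAN, length(markers)); names(mu) <- markers
  sg <- rep(.BG_SD, length(markers)); names(sg) <- markers
  mu[names(mc$mean)] <- mc$mean
  sg[names(mc$sd)] <- mc$sd
  list(mean = mu, sd = sg)
}

#' Default study-like cohort specification
#'
#' A synthetic stand-in for a spectral-cytometry lymphoma cohort: by
#' default 4 control lymph-node (LN) and 5 DLBCL samples, a merged
#' 31-marker panel (22 T-cell clustering markers, 8 ligand markers
#' carried by tumor-microenvironment populations, one viability
#' channel), and ten populations - seven CD8 metacluster analogues
#' (including rare DLBCL-enriched follicular regulatory subsets:
#' `MC09tfr` CXCR5+PD1+HLADR+CD127-, `MC10tfr` ...CD127+, `MC11tfr`
#' ...HLADR-) and three TME populations (lymphoma B cells, dendritic
#' cells, NK cells). Per-sample mixing proportions are the group
#' proportions jittered on the log scale (`propJitterSd`) and
#' renormalised, so population frequencies vary across samples.
#'
#' @param nLN,nDLBCL Samples per group.
#' @param cellsPerSample Events per sample (default 5000).
#' @param couplings,doubletFrac,deadFrac,anomalyWindows,seed Passed to
#'   [cohortSpec()].
#' @param propJitterSd Log-scale sd of the per-sample proportion jitter.
#' @return A [CohortSpec-class].
#' @export
defaultCohortSpec <- function(nLN = 4, nDLBCL = 5, cellsPerSample = 5000,
                              couplings = list(), doubletFrac = 0,
                              deadFrac = 0, anomalyWindows = list(),
                              propJitterSd = 0.25, seed = 1L) {
  hi <- 0.65; lo <- 0.22
  mcs <- list(
    metaclusterSpec("MC01naive", c(LN = .22, DLBCL = .08),
      mean = c(CD45RA = .70, CCR7 = .70, CD127 = .60, CD28 = .60)),
    metaclusterSpec("MC08cxcr3", c(LN = .12, DLBCL = .05),
      mean = c(CXCR3 = hi, CD127 = .60, CD28 = .60, CCR7 = .55)),
    metaclusterSpec("MCeff", c(LN = .08, DLBCL = .06),
      mean = c(CD45RA = hi, CD95 = .60, CXCR3 = .45)),
    metaclusterSpec("MCexh", c(LN = .04, DLBCL = .10),
      mean = c(PD1 = .68, TIM3 = .60, LAG3 = .60, HLADR = .65,
               CTLA4 = .62, CD69 = .60, CD95 = .60, CD127 = lo,
               CXCR5 = lo, ICOS = .55, CD25 = .50)),
    metaclusterSpec("MC09tfr", c(LN = .01, DLBCL = .08),
      mean = c(CXCR5 = .68, PD1 = .68, HLADR = .65, CD127 = lo,
               CTLA4 = .62, CD69 = .60, ICOS = .55, CD95 = .60,
               CD25 = .50, TIM3 = .35, LAG3 = .35)),
    metaclusterSpec("MC10tfr", c(LN = .01, DLBCL = .04),
      mean = c(CXCR5 = .68, PD1 = .68, HLADR = .65, CD127 = .60,
               CTLA4 = .62, CD69 = .60, ICOS = .55, CD95 = .60,
               CD25 = .50, TIM3 = .35, LAG3 = .35)),
    metaclusterSpec("MC11tfr", c(LN = .01, DLBCL = .06),
      mean = c(CXCR5 = .68, PD1 = .68, HLADR = lo, CD127 = lo,
               CTLA4 = .62, CD69 = .60, ICOS = .55, CD95 = .60,
               CD25 = .50, TIM3 = .35, LAG3 = .35)),
    metaclusterSpec("Bcell", c(LN = .30, DLBCL = .38), parent = "TME",
      mean = c(CXCR5 = .66, HLADR = .70, ICOSL = .60, CD80 = .50,
               CD86 = .60, PDL1 = .50, PDL2 = .50, CD40 = .65,
               ICOS = .45, CD69 = .50, CD25 = .45, CD95 = .55,
               CTLA4 = .40)),
    metaclusterSpec("DC", c(LN = .06, DLBCL = .06), parent = "TME",
      mean = c(HLADR = .72, CD80 = .60, CD86 = .65, ICOSL = .55,
               PDL1 = .55, CD40 = .60, GAL9 = .50, ICOS = .35)),
    metaclusterSpec("NK", c(LN = .15, DLBCL = .09), parent = "TME",
      mean = c(CD95 = .55, GAL9 = .45, PDL1 = .35)))
  markers <- c("CXCR5", "HLADR", "CD127", "TIGIT", "CD45RA", "CD28",
               "OX40", "CD137", "CCR7", "ICOS", "CD95", "CCR4", "CD25",
               "PD1", "CD69", "TIM3", "LAG3", "CXCR3", "BTLA", "CD40L",
               "CTLA4", "CCR6",
               "ICOSL", "CD80", "CD86", "PDL1", "PDL2", "OX40L", "CD40",
               "GAL9", "Viability")
  spec <- cohortSpec(
    groups = data.frame(group = c("LN", "DLBCL"), n = c(nLN, nDLBCL)),
    cellsPerSample = cellsPerSample, markers = markers,
    metaclusters = mcs, couplings = couplings,
    doubletFrac = doubletFrac, deadFrac = deadFrac,
    anomalyWindows = anomalyWindows, seed = seed)
  attr(spec, "propJitterSd") <- propJitterSd
  spec
}

#' The default T-cell clustering marker panel
#'
#' The 22 markers used for SOM clustering of the CD8 compartment.
#' @return Character vector of marker names.
#' @export
clusteringMarkers <- function() {
  c("CXCR5", "HLADR", "CD127", "TIGIT", "CD45RA", "CD28", "OX40",
    "CD137", "CCR7", "ICOS", "CD95", "CCR4", "CD25", "PD1", "CD69",
    "TIM3", "LAG3", "CXCR3", "BTLA", "CD40L", "CTLA4", "CCR6")
}

#' Simulate a cohort with known ground truth
#'
#' Draws each sample's cells i.i.d. Gaussian per metacluster on the
#' transformed (logicle) scale and maps them to raw intensities through
#' the inverse logicle, appends a sorted acquisition-time channel, then
#' applies (in order) ligand-receptor couplings, doublets (channel-wise
#' sums of two random cells on the raw scale), dead cells (a high
#' viability-channel shift) and acquisition-time anomalies. All
#' randomness derives from `spec@seed`; identical specs give
#' bit-identical cohorts.
#'
#' @param spec A [CohortSpec-class].
#' @param transform [logicleParams()] linking the transformed and raw
#'   scales.
#' @return A [CytoCohort-class] whose truth table records each cell's
#'   population and doublet/dead/anomaly flags, and whose `latent` slot
#'   records each sample's latent coupling factors.
#' @export
simulateCohort <- function(spec, transform = logicleParams()) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  set.seed(spec@seed)
  jsd <- attr(spec, "propJitterSd") %||% 0.25
  markers <- spec@markers
  mcNames <- names(spec@metaclusters)
  profiles <- lapply(spec@metaclusters, .mcProfile, markers = markers)

  sampleIds <- unlist(lapply(seq_len(nrow(spec@groups)), function(i)
    sprintf("%s_%d", spec@groups$group[i], seq_len(spec@groups$n[i]))))
  groupsOf <- rep(spec@groups$group, spec@groups$n)
  ss <- data.frame(sample_id = sampleIds, group = groupsOf,
                   stringsAsFactors = FALSE)

  framesT <- list()   # transformed-scale matrices, built first
  truthList <- list()
  n <- spec@cellsPerSample
  for (i in seq_along(sampleIds)) {
    sid <- sampleIds[i]
    base <- vapply(spec@metaclusters,
                   function(mc) unname(mc$proportions[[groupsOf[i]]]),
                   numeric(1))
    pr <- base * exp(stats::rnorm(length(base), 0, jsd))
    pr <- pr / sum(pr)
    pop <- sample(mcNames, n, replace = TRUE, prob = pr)
    Z <- matrix(0, n, length(markers), dimnames = list(NULL, markers))
    for (mc in mcNames) {
      idx <- which(pop == mc)
      if (!length(idx)) next
      pf <- profiles[[mc]]
      Z[idx, ] <- matrix(stats::rnorm(length(idx) * length(markers),
                                      mean = rep(pf$mean, each = length(idx)),
                                      sd = rep(pf$sd, each = length(idx))),
                         nrow = length(idx))
    }
    framesT[[sid]] <- Z
    parentOf <- vapply(spec@metaclusters, function(mc)
      mc$parent %||% "CD8", character(1))
    truthList[[sid]] <- data.frame(
      sample_id = sid, cell = seq_len(n), population = pop,
      parent = unname(parentOf[pop]), doublet = FALSE, dead = FALSE,
      anomaly = FALSE, stringsAsFactors = FALSE)
  }

  # latent coupling factors and shifts, on the transformed scale
  latent <- data.frame(sample_id = sampleIds, stringsAsFactors = FALSE)
  for (ci in seq_along(spec@couplings)) {
    cp <- spec@couplings[[ci]]
    if (cp$shape == "none") next
    u <- stats::rnorm(length(sampleIds))
    epsL <- stats::rnorm(length(sampleIds), 0, cp$noiseSd)
    epsR <- stats::rnorm(length(sampleIds), 0, cp$noiseSd)
    latent[[sprintf("u%d_%s_%s", ci, cp$ligand, cp$receptor)]] <- u
    for (i in seq_along(sampleIds)) {
      sid <- sampleIds[i]
      pop <- truthList[[sid]]$population
      sidx <- pop == cp$sender
      ridx <- pop == cp$receiver
      framesT[[sid]][sidx, cp$ligand] <-
        framesT[[sid]][sidx, cp$ligand] + cp$beta * u[i] + epsL[i]
      rshift <- if (cp$shape == "quadratic") cp$beta * (u[i]^2 - 1)
                else cp$beta * u[i]
      framesT[[sid]][ridx, cp$receptor] <-
        framesT[[sid]][ridx, cp$receptor] + rshift + epsR[i]
    }
  }

  # dead cells: high viability-dye signal
  if ("Viability" %in% markers && spec@deadFrac > 0) {
    for (sid in sampleIds) {
      dead <- stats::runif(n) < spec@deadFrac
      framesT[[sid]][dead, "Viability"] <-
        framesT[[sid]][dead, "Viability"] + 0.35
      truthList[[sid]]$dead <- dead
    }
  }

  # to raw scale; doublets are raw-scale channel-wise sums
  frames <- list()
  for (sid in sampleIds) {
    raw <- apply(framesT[[sid]], 2, logicleInverse, p = transform)
    if (spec@doubletFrac > 0) {
      nd <- stats::rbinom(1, n, spec@doubletFrac)
      di <- sample.int(n, nd)
      partner <- sample.int(n, nd, replace = TRUE)
      raw[di, ] <- raw[di, ] + raw[partner, ]
      truthList[[sid]]$doublet[di] <- TRUE
    }
    raw <- cbind(raw, Time = sort(stats::runif(n, 0, 1000)))
    frames[[sid]] <- CytoFrame(raw, sampleId = sid, timeChannel = "Time",
                               labels = truthList[[sid]])
  }

  cohort <- new("CytoCohort", frames = frames, sampleSheet = ss,
                truth = do.call(rbind, c(truthList, make.row.names = FALSE)),
                latent = latent)

  for (aw in spec@anomalyWindows) {
    sids <- aw$sample %||% sampleIds
    for (sid in sids)
      cohort <- .applyAnomaly(cohort, sid, aw$window, aw$shift)
  }
  cohort
}

.applyAnomaly <- function(cohort, sid, window, shift) {
  fr <- cohort@frames[[sid]]
  if (is.null(fr)) stop(sprintf("unknown sample '%s'", sid))
  cohort@frames[[sid]] <- injectTimeAnomaly(fr, window, shift)
  hit <- truthLabels(cohort@frames[[sid]])$anomaly
  sel <- cohort@truth$sample_id == sid
  cohort@truth$anomaly[sel] <- cohort@truth$anomaly[sel] | hit
  cohort
}

#' Inject a ligand-receptor coupling into an existing cohort
#'
#' Applies one [lrCoupling()] to a simulated cohort: a fresh latent
#' factor `u_s ~ N(0, 1)` is drawn per sample under `seed` and the
#' ligand/receptor markers of the sender/receiver populations are
#' shifted on the transformed scale (see [lrCoupling()] for the link
#' shapes). `shape = "none"` returns the cohort unchanged.
#'
#' @param cohort A [CytoCohort-class] with a truth table.
#' @param coupling An [lrCoupling()].
#' @param seed Integer seed for the latent draw.
#' @param transform [logicleParams()] linking the scales.
#' @return The modified cohort; the latent factor is appended to the
#'   `latent` slot.
#' @export
injectLRCoupling <- function(cohort, coupling, seed = 1L,
                             transform = logicleParams()) {
  stopifnot(is(cohort, "CytoCohort"))
  cp <- coupling
  if (cp$shape == "none") return(cohort)
  pops <- unique(cohort@truth$population)
  if (!all(c(cp$sender, cp$receiver) %in% pops))
    stop("sender/receiver population not present in the truth table")
  ex <- channels(cohort@frames[[1]])
  if (!all(c(cp$ligand, cp$receptor) %in% ex))
    stop("ligand/receptor marker not present on the panel")
  sids <- names(cohort@frames)
  set.seed(seed)
  u <- stats::rnorm(length(sids))
  epsL <- stats::rnorm(length(sids), 0, cp$noiseSd)
  epsR <- stats::rnorm(length(sids), 0, cp$noiseSd)
  for (i in seq_along(sids)) {
    fr <- cohort@frames[[sids[i]]]
    pop <- truthLabels(fr)$population
    e <- exprs(fr)
    sidx <- pop == cp$sender
    ridx <- pop == cp$receiver
    rshift <- if (cp$shape == "quadratic") cp$beta * (u[i]^2 - 1)
              else cp$beta * u[i]
    e[sidx, cp$ligand] <- logicleInverse(
      logicleTransform(e[sidx, cp$ligand], transform) +
        cp$beta * u[i] + epsL[i], transform)
    e[ridx, cp$receptor] <- logicleInverse(
      logicleTransform(e[ridx, cp$receptor], transform) +
        rshift + epsR[i], transform)
    fr@exprs <- e
    cohort@frames[[sids[i]]] <- fr
  }
  cohort@latent[[sprintf("u_%s_%s", cp$ligand, cp$receptor)]] <- u
  cohort
}

#' Inject an acquisition-time anomaly
#'
#' Shifts the raw intensities of all events whose acquisition time falls
#' inside `window` by a per-marker offset, emulating a clog or other
#' transient flow disturbance, and flags those events in the frame's
#' labels (`anomaly` column).
#'
#' @param frame A [CytoFrame-class] with a time channel.
#' @param window Numeric length-2: start and end acquisition time;
#'   must overlap the frame's time range and have positive length.
#' @param shift Named numeric vector of raw-intensity offsets (markers
#'   not named are untouched). A zero shift still flags the window.
#' @return The modified [CytoFrame-class].
#' @export
injectTimeAnomaly <- function(frame, window, shift) {
  stopifnot(is(frame, "CytoFrame"))
  tc <- frame@timeChannel
  if (is.na(tc)) stop("frame has no time channel")
  if (length(window) != 2L || window[2] <= window[1])
    stop("empty anomaly window")
  tm <- exprs(frame)[, tc]
  if (window[1] > max(tm) || window[2] < min(tm))
    stop("anomaly window outside the acquisition-time range")
  hit <- tm >= window[1] & tm <= window[2]
  e <- exprs(frame)
  bad <- setdiff(names(shift), colnames(e))
  if (length(bad)) stop("unknown markers in shift: ",
                        paste(bad, collapse = ", "))
  for (m in names(shift)) e[hit, m] <- e[hit, m] + shift[[m]]
  frame@exprs <- e
  lb <- frame@labels
  if (!nrow(lb)) lb <- data.frame(row.names = seq_len(nrow(e)))
  lb$anomaly <- (lb$anomaly %||% rep(FALSE, nrow(e))) | hit
  frame@labels <- lb
  frame
}

#' Simulate well-separated Gaussian blobs
#'
#' A minimal clustering benchmark: `k` spherical Gaussian clusters with
#' means placed at distance `sep` along orthogonal-ish directions in
#' `d` dimensions, unit-free transformed-scale units.
#'
#' @param n Cells per blob.
#' @param k Number of blobs.
#' @param d Number of markers.
#' @param sep Distance between blob centres, in sd units (`sd = 1`).
#' @param seed Integer seed.
#' @return A list with `data` (matrix, `n * k` rows, marker columns
#'   `M1..Md`) and `labels` (integer blob membership).
#' @export
simulateBlobs <- function(n = 1000, k = 3, d = 5, sep = 8, seed = 1L) {
  set.seed(seed)
  centres <- matrix(0, k, d)
  for (j in seq_len(k)) centres[j, ((j - 1) %% d) + 1] <- (j - 1) * sep / 2
  if (k > 1) centres[, 1] <- centres[, 1] + seq(0, sep * (k - 1), length.out = k)
  lab <- rep(seq_len(k), each = n)
  X <- centres[lab, , drop = FALSE] +
    matrix(stats::rnorm(n * k * d), n * k, d)
  colnames(X) <- paste0("M", seq_len(d))
  list(data = X, labels = lab)
}
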