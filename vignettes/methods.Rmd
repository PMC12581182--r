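---
title: "Methods: unsupervised cytometry phenotyping and signed distance-correlation communication inference"
author: "flowSDC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unsupervised cytometry phenotyping and signed distance-correlation communication inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

flowSDC implements an analysis pipeline for high-dimensional (spectral)
flow cytometry of tumor microenvironments: event-level preprocessing,
self-organising-map (SOM) metaclustering, marker-enrichment annotation
and transparent auto-gating, nonparametric frequency statistics, and
inference of ligand-receptor (LR) communication between cell
populations by signed distance correlation across samples. This
vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic validation
cohort does and does not establish.

## Logicle transformation

Fluorescence intensities are displayed and analysed on the logicle
(biexponential) scale: linear around zero (so cells spread below zero
by background subtraction remain visible) and logarithmic at high
intensity. The scale is parameterised by the linearisation width `w`
(decades), the top of scale `t`, the total width `m` (decades) and the
additional negative range `a` (decades); the pipeline default is
`w = 0.5, t = 10000, m = 2, a = 0`. The inverse (transformed to raw)
map is the exact biexponential

  B(y) = alpha * exp(b y) - gamma * exp(-d y) - f,

with coefficients derived so that `B(1) = t` and `B((a + w)/(m + a)) = 0`;
the forward transform inverts `B` numerically (monotone-spline seed
followed by Newton iteration, absolute tolerance 1e-9 on the
transformed scale, verified to round-trip at 1e-6 relative tolerance in
the tests). The decay-rate coefficient `d` solves
`2 (log d - log b) + w_n (d + b) = 0` on `(0, b)` and is found by
`uniroot` at near machine precision.

## Acquisition-anomaly QC

Transient flow disturbances (clogs, pressure drops) produce bursts of
events with aberrant intensities. The filter partitions time-sorted
events into consecutive segments (default `segmentSize = 200` events),
computes per-segment per-channel means, and z-scores them robustly
across segments using the median and MAD - the robust location/scale is
essential because an anomalous burst would otherwise inflate the plain
standard deviation and mask itself. The segment score is the sum of
|z| over the monitored channels, and segments scoring above
`median + c * MAD` (default `c = 7` MAD units) are removed. The filter
iterates to a fixed point, which makes it exactly idempotent on its own
output. On clean simulated samples the default settings remove
essentially nothing (well under 5%), while injected high-shift windows
covering 10% of a sample are recovered at over 90%; both behaviours are
asserted in the test suite. This is a deliberately simple
segment-deviation filter: it targets sustained multi-channel shifts,
not single-event outliers or slow drifts.

## SOM metaclustering

Clustering follows the two-stage FlowSOM strategy: an online SOM
(default 10 x 10 grid, 100 nodes) quantises the cells, and the node
codebook is then grouped into `k` metaclusters. Training uses Euclidean
distance, a Gaussian neighbourhood whose radius decays linearly from
the 0.67 quantile of the grid distances to zero, a learning rate
decaying linearly from 0.05 to 0.01, and 10 passes through the data in
seeded random order; the codebook is initialised from a seeded random
sample of cells, so training is fully deterministic given the seed.
Cells are assigned to their best-matching unit (BMU), with exact ties
broken by the lowest node index; the BMU search is verified against a
brute-force scan in the tests.

Metaclustering is a consensus procedure: `B = 100` bootstrap resamples
of the nodes are each clustered by average-linkage hierarchical
clustering of the codebook and cut at `k`; the consensus matrix (the
fraction of co-assignments among co-sampled node pairs) is then itself
clustered by average linkage on `1 - consensus` and cut at `k`. The
number of metaclusters is guided by the elbow of the within-metacluster
sum-of-squares curve of the codebook - the `k` maximising the discrete
second difference - but is deliberately user-overridable: cluster
granularity is ultimately a biological judgement, and the default
pipeline configuration accepts an explicit `k` (the study-mirroring
end-to-end runs use `k = 11`). On data without an elbow (curvature
nowhere positive) the smallest candidate `k` is returned with a
warning. Whether to z-scale the transformed markers before clustering
is exposed as a choice; the pipeline scales by default (pooled
mean/sd over the clustered compartment), since markers differ in
dynamic range.

## MEM annotation and F1 auto-gating

Metaclusters are annotated by marker enrichment modelling (MEM)
against the remaining cells: per marker the signed magnitude is
`|median_pop - median_ref| + IQR_ref / IQR_pop - 1`, floored at zero,
signed by the median difference and rescaled so the largest magnitude
is 10. IQRs are floored at 1e-8 to keep degenerate populations finite.
Note that the score is not invariant under a common affine rescaling of
both groups in general (the IQR-ratio term is scale-free but the
median-difference term is not); it is invariant on the equal-IQR
subfamily, which is what the tests assert.

Each metacluster is also reproduced by a transparent axis-aligned gate
fitted by greedy coordinate ascent on the F1 score
`2TP / (2TP + FP + FN)`: candidate thresholds are the 1%-99% percentile
grid per marker (99 candidates), the single best (marker, bound)
addition or adjustment is applied per step, and the search stops below
a 1e-4 improvement or at 20 bounds. A final refinement pass
re-optimises each active bound over the exact data values between its
neighbouring grid candidates, so cleanly separable populations reach
F1 = 1 rather than stalling at the grid resolution. Marker importance
is the F1 drop when a marker's bounds are ignored, computed without
re-fitting (a redundant marker therefore scores near zero; re-fitting
after removal is available behind the `refit` flag for an
irreplaceability reading instead).

## Signed distance correlation and the communication screens

Dependence between two per-sample summary vectors is measured by the
sample distance correlation: double-center the two pairwise
absolute-difference matrices, take the mean elementwise product as the
squared distance covariance, and normalise by the geometric mean of the
distance variances. The statistic lies in [0, 1] and vanishes
(asymptotically) only under independence, so nonlinear couplings are
detectable - the package's power analysis shows the dcor screen
dominating a Pearson screen on quadratic couplings. The sign is taken
from the Pearson correlation of the same pair; at exactly zero Pearson
correlation the sign is set positive and flagged, since no orientation
is defined there. The implementation is a streaming O(n^2) kernel (the
centred matrices are never materialised) and is checked against an
independent double-centering oracle at 1e-12.

Significance uses permutation of one margin. For `n <= 7` samples all
`n!` permutations are enumerated and the p-value is the proportion of
permutation statistics at least as large as the observed one (identity
included, so `p >= 1/n!` - at the study's 4-5 samples per group this
granularity, e.g. 1/120 at n = 5, is the honest resolution limit).
Larger designs use Monte-Carlo sampling with
`p = (1 + #exceedances) / (1 + nPerm)`, default `nPerm = 9999`. Outputs
carry a method tag. Type-I calibration at alpha = 0.05 is asserted over
1000 null replicates.

The LR screen takes per-sample, per-population median fluorescence
intensities (MFIs; medians of raw intensities by default, configurable
to the transformed scale), log-transforms and z-normalises each vector
across samples, and computes the signed dcor and permutation p for
every catalogue axis and (sender, receiver) combination in both
orientations. Population entries backed by fewer than `minCells`
(default 10) cells are missing, never zero, and each pair is computed
over its pairwise-complete samples with `n` reported. Rows with
`p < alpha` (default 0.05) are flagged significant; Benjamini-Hochberg
adjusted p-values over the whole screen are always reported as an
additional column, with the LR screen and the frequency screen treated
as separate families. The log step uses natural logarithms (the base
cancels in the z-normalisation) and shifts any non-positive feature by
`1 - min` first; because that shift is data-dependent and compresses
the high end when a value is far below zero, the synthetic generator
keeps coupling shifts inside the dye's dynamic range (see below). The
frequency screen applies the same machinery to per-sample population
frequencies, excluding self-pairings.

The shipped LR catalogue covers the co-stimulatory and co-inhibitory
axes resolvable on typical T-cell and TME spectral panels
(ICOS-ICOSL, CTLA4-CD80/CD86, PD1-PDL1/PDL2, OX40-OX40L, CD137-CD137L,
TIGIT-PVR, CD95-CD95L, BTLA-HVEM, TIM3-GAL9, CD40L-CD40, CD28-CD80/86)
and is a plain CSV the user can replace. Screened correlations are
associations across samples, not demonstrations of physical contact or
causal signalling.

## Frequency statistics

Metacluster frequencies are percentages of the parent population per
sample and sum to 100 within a sample. Samples with fewer than 100
parent-compartment cells are excluded (strictly fewer - a sample with
exactly 100 cells is retained). Two-group comparisons use a two-tailed
Mann-Whitney U test: exact by full enumeration of group assignments
(midranks, so ties are exact) up to combined n = 12, normal
approximation with tie correction (without continuity correction)
beyond. Multi-group comparisons use Kruskal-Wallis with Dunn's post hoc
z tests on pooled midranks, Benjamini-Hochberg adjusted within the
pairwise family. Across populations, p-values are BH-adjusted within
each comparison family, and significance tiers (ns, * < 0.05,
** < 0.01, *** < 0.001) are a pure function of the adjusted p. PCA of
frequency tables centers and unit-scales each population and refuses
missing values rather than imputing; constant populations are dropped
with a warning. Group summaries report both mean +/- sem and
median/IQR.

## The synthetic cohort generator

Because event-level patient data of this kind are typically not
deposited, every stage is validated on synthetic cohorts with known
ground truth. Cells are drawn i.i.d. Gaussian per metacluster on the
transformed scale - the standard working assumption behind clustering
transformed cytometry data - and mapped to raw intensities through the
inverse logicle. The default cohort mirrors a lymphoma study design:
4 control lymph-node and 5 DLBCL samples, 5000 cells per sample, and a
merged 31-marker panel (the 22 T-cell clustering markers, 8 TME ligand
markers and a viability channel - a deliberate merge of what would be
two stained panels in practice, so one simulated tube exercises both
the clustering and the LR screen). Ten populations are simulated: seven
CD8 metacluster analogues - naive (CD45RA+CCR7+), CXCR3+ memory,
effector, exhausted (PD1+TIM3+LAG3+CXCR5-), and three rare
DLBCL-enriched follicular regulatory subsets (CXCR5+PD1+ with
HLADR+CD127-, HLADR+CD127+ and HLADR-CD127- variants, at 1% each in
control vs 4-8% in DLBCL) - plus lymphoma B cells, dendritic cells and
NK cells carrying the ligand markers. Population levels are set so that
each of CXCR5, PD1, HLADR and CD127 is individually necessary to gate
the HLADR+CD127- follicular subset (the exhausted population matches it
except for CXCR5; B cells match its activation profile except for PD1;
the sibling subsets differ only in CD127 or HLADR), which is what makes
the auto-gate recovery check meaningful.

Per-sample mixing proportions are the group proportions jittered on the
log scale (sd 0.25) and renormalised, giving realistic across-sample
frequency variation. Doublets (default 0, study runs 2%) are
channel-wise sums of two random cells on the raw scale; dead cells are
a +0.35 transformed-scale shift of the viability channel; time
anomalies add per-channel raw offsets inside an acquisition-time
window. All flags are recorded in the truth table, which stands in for
the manual pre-gating a human operator would do.

LR couplings are driven by a latent per-sample factor `u_s ~ N(0, 1)`:
the sender population's ligand marker shifts by `beta * u_s` and the
receiver's receptor marker by `beta * u_s` (linear) or
`beta * (u_s^2 - 1)` (quadratic - centered, so the linear correlation
is near zero by construction while the dependence remains detectable).
Shifts act on the transformed scale; the study-condition effect size is
`beta = 0.15` with per-sample noise sd 0.01, chosen so that shifted
medians stay within the dye's dynamic range (a shift that drives a
population's median below the logicle zero point would make the
log-normalisation of the screen meaningless - as it would in a real
experiment, where an MFI cannot fall below background). Validation runs
that need correlation power use 20-40 samples, since 4-5 samples per
group cannot separate power properties from noise.

What the simulations do not emulate: spectral unmixing and spillover,
autofluorescence, batch effects, non-Gaussian population shapes, and
marker correlations within a population beyond the coupling-driven
shifts. Passing tests therefore demonstrate algorithmic correctness and
calibration under the stated model, not robustness to every artefact of
real acquisitions.

## Problem sizes and numerical conventions

The validation suite uses cohorts of 2500-10000 cells per sample,
SOM training sets of 9000-25000 cells, 200-replicate power runs at 40
samples and a 1000-replicate null calibration - sizes chosen to make
the statistical assertions sharp while keeping a full run in a few
minutes on one core. Degenerate inputs follow explicit rules: constant
features z-scale to zeros, a constant margin gives dcor 0 and
permutation p 1, zero parent counts flag a sample rather than divide,
and an all-positive gate target yields the empty gate at F1 = 1. All
stochastic steps (simulation, SOM, bootstrap consensus, permutations,
downsampling) are governed by explicit seeds, and equal seeds reproduce
results bit-identically.
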