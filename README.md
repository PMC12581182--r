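# flowSDC

Unsupervised analysis of tumor-microenvironment (TME) spectral
cytometry with signed distance-correlation inference of cell-cell
communication.

High-dimensional flow cytometry of lymphoma biopsies can resolve rare
tumor-infiltrating T-cell subsets, but two questions then follow: which
subsets are enriched in disease, and which other TME cells do they talk
to? flowSDC implements the full chain for both, aimed at
cytometrists and computational immunologists:

- **Preprocessing** - logicle (biexponential) transformation with the
  standard `(w, t, m, a)` parameterisation, automatic removal of
  acquisition anomalies (clogs) by robust segment scoring, per-sample
  downsampling, low-count sample exclusion.
- **Phenotyping** - FlowSOM-style clustering: an online self-organising
  map (default 10 x 10 grid) followed by bootstrap consensus
  metaclustering with elbow-guided choice of `k`; marker enrichment
  modelling (MEM) scores for annotation; transparent axis-aligned gates
  fitted by greedy F1 maximisation, with per-marker importance measured
  as the F1 drop when a marker is omitted.
- **Statistics** - per-sample metacluster frequencies, two-tailed
  Mann-Whitney U (exact by enumeration for small cohorts),
  Kruskal-Wallis with Dunn's post hoc, Benjamini-Hochberg correction,
  and PCA of frequency profiles.
- **Communication inference** - for each ligand-receptor axis and each
  (sender, receiver) population pair, the median fluorescence
  intensities across samples are log-transformed, z-normalised and
  scored by **signed distance correlation**: Szekely's distance
  correlation `dcor in [0, 1]` (sensitive to nonlinear dependence),
  signed by the Pearson correlation of the same pair, with permutation
  p-values (exact for `n <= 7` samples, Monte-Carlo otherwise) and BH
  adjustment. Pairs with `p < 0.05` are flagged.
- **Synthetic cohorts** - a first-class generator with known ground
  truth (group-dependent metacluster abundances including rare
  disease-enriched follicular subsets, latent linear/quadratic
  ligand-receptor couplings, doublets, dead cells, time-window
  anomalies) so that every stage has a measurable recovery target, plus
  FCS 3.0 / CSV input-output.

The central statistic: for sample vectors `x, y` (one value per
sample), the pairwise distance matrices are double-centered, the
squared distance covariance is the mean elementwise product, and

    dcor(x, y) = dCov(x, y) / sqrt(dVar(x) dVar(y)),
    signed value = sign(pearson(x, y)) * dcor(x, y).

`dcor = 0` only under independence (asymptotically), so quadratic and
other non-monotone couplings that Pearson screening misses are
detectable; the sign restores the orientation that practitioners read
from correlograms.

## Worked example

Simulate a study-like cohort - 4 control lymph-node (LN) and 5 DLBCL
samples, 5000 cells each, a 31-marker panel, a DLBCL-enriched
CXCR5+PD1+HLADR+CD127- follicular regulatory CD8 analogue (`MC09tfr`),
and one injected ICOS -> ICOSL coupling between it and lymphoma B
cells - then run the full pipeline:

```r
library(flowSDC)

cp   <- lrCoupling("MC09tfr", "ICOS", "Bcell", "ICOSL",
                   shape = "linear", beta = 0.15, noiseSd = 0.01)
spec <- defaultCohortSpec(couplings = list(cp), doubletFrac = 0.02,
                          deadFrac = 0.02, seed = 1)
cohort <- simulateCohort(spec)
cohort
#> CytoCohort: 9 samples (DLBCL n=5, LN n=4)
#>  events per sample: 5000-5000
#>  ground truth available

res <- runPipeline(cohort, k = 11, nPerm = 4999, seed = 1)

head(res$comparisons[order(res$comparisons$p),
     c("population", "mean_LN", "mean_DLBCL", "p", "p_adj", "tier")], 4)
#>   population   mean_LN mean_DLBCL          p      p_adj tier
#> 1       MC01  2.240671  12.322348 0.01587302 0.02040816    *
#> 2       MC02  3.899180  23.120595 0.01587302 0.02040816    *
#> 3       MC03  9.082584  26.424881 0.01587302 0.02040816    *
#> 5       MC07 17.746347   6.774383 0.01587302 0.02040816    *

res$lrTable[1:3, c("sender", "senderMarker", "receiver",
                   "receiverMarker", "n", "signed", "p", "method")]
#>   sender senderMarker receiver receiverMarker n    signed      p      method
#> 1   MC02         ICOS    Bcell          ICOSL 9 0.9714294 0.0002 monte-carlo
#> 2   MC11         ICOS       DC          ICOSL 9 0.8168260 0.0026 monte-carlo
#> 3   MC01         ICOS    Bcell          ICOSL 9 0.8215633 0.0066 monte-carlo
```

Reading the output: several metaclusters differ between the groups at
the resolution an exact Mann-Whitney test allows with 4 vs 5 samples
(the smallest achievable two-tailed p is 2/126 ~ 0.0159; `tier` is
derived from the BH-adjusted p). In the ligand-receptor table, the top
row is the injected communication axis: metacluster `MC02` is the
discovered analogue of the simulated `MC09tfr` population, and its ICOS
median across samples tracks the ICOSL median of lymphoma B cells with
signed distance correlation 0.97 at permutation p = 2e-4. The
`frequencyScreen()` counterpart, MEM labels (`memScores()`), automatic
gates (`fitGate()`, `markerImportance()`) and report export
(`buildReport()`) follow the same pattern; see the methods vignette
(`vignettes/methods.Rmd`) for the underlying models and defaults.

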