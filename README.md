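# manifoldFC

Manifold learning for time-varying functional connectivity (tvFC) in R.

Whole-brain functional connectivity measured with fMRI fluctuates within a
scan. The sliding-window description of those fluctuations — a matrix with
one row per unique ROI pair and one column per temporal window, each column
the Fisher-z Pearson correlations of the windowed ROI timeseries — has
thousands of rows (`N_cons = N(N-1)/2`; 12,246 for a 157-region
parcellation) but occupies a manifold of far lower dimension. This package
is for researchers who want to construct, inspect and embed such tvFC
matrices: it implements sliding-window tvFC construction and normalization,
three manifold learners written from their defining equations — Laplacian
Eigenmaps (generalized eigenproblem `Lf = λDf` on a weighted k-NN graph),
T-SNE (perplexity-calibrated Gaussian affinities, Student-t low-dimensional
kernel, exact KL-divergence gradient descent with early exaggeration) and
UMAP (per-node `(ρ, σ)` calibration to `log2(k)`, fuzzy-union
symmetrization `C = B + Bᵀ − B∘Bᵀ`, cross-entropy layout by negative-
sampling SGD) — plus global/local intrinsic-dimension estimators (twoNN,
local PCA), two surrogate-data null models (connectivity randomization and
phase randomization), silhouette and L1-logistic-regression evaluation
frameworks, two group-level aggregation strategies ("Concatenate + Embed"
and "Embed + Procrustes"), and a seeded synthetic multi-task fMRI generator
whose data carry task-specific covariance states, slow state wandering,
temporal autocorrelation and subject connectome fingerprints.

The tvFC matrix is a `SummarizedExperiment` subclass (`TvfcMatrix`), so row
(connection) and column (window) metadata travel with the values; the
optimization loops of T-SNE and UMAP are compiled (Rcpp/RcppArmadillo) and
consume R's RNG, so every result is reproducible under `set.seed()`.

## Worked example

```r
library(manifoldFC)

cfg  <- syntheticConfig(nSubjects = 1, seed = 7)   # 30 ROIs, 4 tasks x 2 blocks
scan <- generateDataset(cfg)[[1]]
scan$ts
#> RoiTimeseries: 30 ROIs x 1024 acquisitions (TR = 1.5 s, subject sub01)

tv <- computeTvfc(scan$ts, WindowSpec(wDuration = 30, wStep = 5),
                  schedule = scan$schedule)
tv
#> TvfcMatrix: 435 connections x 199 windows (Fisher-z, as-is; w = 30, step = 5)
#>   window labels: attention(36) math(36) memory(37) mixed(54) rest(36)

emb <- embedTvfc(tv, leParams(k = 40, m = 3), metric = "correlation")
emb
#> LE embedding: 199 samples x 3 dimensions
#>   hyper-parameters: k=40, metric=correlation, m=3

silhouetteIndex(emb, "task")
#> SI_task = 0.9623 (n = 145 windows, 54 excluded)

estimateId(tv, "twoNN")
#> IdEstimate (twoNN, global): 4.02 [n = 199]
```

The 30-ROI scan yields `countConnections(30) = 435` connections and
`countWindows(1024, WindowSpec(30, 5)) = 199` windows. Windows fully inside
one task block keep that task's label; windows touching an instruction
period or two tasks are `"mixed"` and are excluded from task silhouettes.
The task silhouette of 0.96 says the embedding cleanly groups windows by
task; the twoNN estimate says those 435-dimensional window vectors locally
occupy only about four dimensions.

Group-level analyses follow the same grammar: `concatEmbed(tvfcs, ...)`
(optionally `normalize = TRUE` to z-score rows per scan first, which removes
subject fingerprints), `embedProcrustes(embeddings, alignDims = 20)`,
`classifyWindows(group, mUsed, scheme = "split_half")`,
`stabilityStudy(tv, umapParams(...), nReps = 20)`,
`randomizeConnectivity(tv)` / `phaseRandomize(ts)` for the null models, and
`runPipeline(pipelineConfig(...))` to drive simulate → tvfc → null → id →
embed → evaluate sweeps with provenance sidecars.

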