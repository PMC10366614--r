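---
title: "Manifold learning for time-varying functional connectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Manifold learning for time-varying functional connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Whole-brain functional connectivity measured with fMRI evolves within a
scan. The standard sliding-window description turns an ROI-by-time signal
matrix into a *tvFC matrix*: one row per unique ROI pair (for N regions,
`N (N - 1) / 2` connections — 12,246 for a 157-region parcellation) and one
column per temporal window (`floor((N_acq - (w - step)) / step)` windows —
988 for a 1,017-acquisition scan with 30-sample windows advanced one sample
at a time). Each column is the Fisher-z transformed Pearson correlation of
the windowed ROI timeseries, vectorized over the upper triangle. The
resulting cloud of window vectors lives in an ambient space of thousands of
dimensions, but the generative constraints on brain connectivity (network
structure, anatomy, limited task-driven reconfiguration) confine it to a
low-dimensional manifold. This package implements, from their defining
equations, the machinery to construct that cloud, estimate the dimension of
the manifold it occupies, embed it with three manifold learners, and
evaluate the embeddings.

## The three learners

All three methods start from a windows-by-windows dissimilarity matrix
(`pairwiseDissimilarity()`: Euclidean, correlation `1 - r`, or cosine) and
a neighborhood notion.

**Laplacian Eigenmaps** (`leAffinity()`, `leEmbed()`). The k-NN graph uses
the weighted affinity: 1 for mutual neighbors, 0.5 for one-directional
ones (a binary union variant is exposed via `weighted = FALSE`; both
appear in the literature and the weighted form matches the common library
implementation). The embedding solves the generalized eigenproblem
`L f = lambda D f` with `L = D - W`. Numerically we work with the
symmetric normalized form `D^{-1/2} L D^{-1/2}` (degrees are strictly
positive by the graph invariant), recover the generalized eigenvectors as
`D^{-1/2} u`, and fix signs so each eigenvector's largest-magnitude entry
is positive — this makes results platform-reproducible. The constant
eigenvector of eigenvalue 0 is dropped; because all eigenpairs come from
one decomposition, the first `m'` columns of an `m`-dimensional solution
equal the `m'`-dimensional solution. Disconnected graphs are embedded
jointly with a warning (the zero eigenvalue's multiplicity then equals the
component count, recorded in the diagnostics); this matches the observed
behavior of group-level graphs at very low k, which separate subjects
rather than failing.

**T-SNE** (`calibrateSigmas()`, `jointP()`, `lowDimQ()`, `tsneEmbed()`).
Per-sample Gaussian kernel widths are calibrated by bisection on
`log(sigma)` so the perplexity `2^H` of each conditional distribution hits
the target (if all neighbors are equidistant the entropy is flat in sigma
and the bracket midpoint is returned). The joint affinity is
`P = (p_{i|j} + p_{j|i}) / (2n)`, the standard joint formulation with the
`1/n` factor, so P is a probability distribution. The low-dimensional
affinity uses the Student-t kernel; the layout minimizes `KL(P || Q)` with
the exact O(n^2) gradient (no Barnes–Hut: scan-level problems here have at
most ~1,000 windows), momentum 0.5 switching to 0.8 at iteration 250, and
early exaggeration: P is multiplied by 4 (not renormalized — the inflated
mass is the point) for the first 100 iterations, producing the
characteristic sharp cost drop when the factor is removed. PCA
(classical-scaling) initialization is the default because it injects
global structure and makes the method deterministic; random initialization
is seeded.

**UMAP** (`rhoSigma()`, `fuzzyGraph()`, `fitAb()`, `umapEmbed()`). Per
node, `rho` is the nearest-neighbor distance and `sigma` solves
`sum_j exp(-max(0, d_ij - rho_i) / sigma_i) = log2(k)` by bisection
(tolerance 1e-5, at most 64 iterations, bracket `[1e-8, 1e3] * max(d)`;
the degenerate all-equidistant case returns the lower bracket end with a
warning). This guarantees every node one unit-weight edge. The directed
membership matrix is symmetrized by the fuzzy union
`C = B + B' - B o B'`. The `min_dist` parameter (default 0.8) is mapped to
the smooth kernel `1 / (1 + a d^{2b})` by least squares against the
piecewise target curve over `d` in [0, 3]. The layout minimizes the
edge-wise cross-entropy by per-edge SGD: edges are sampled in proportion
to their weight (an edge of relative weight below `1/n_epochs` is never
sampled), each attractive update is paired with 5 uniform negative
samples, gradient components are clipped to [-4, 4], and the learning rate
decays linearly to zero. The attractive term uses the symmetrized weight
`w_c`. Spectral (LE) initialization is the default, falling back to seeded
random for disconnected graphs. Per-epoch mean displacement is recorded:
with a small learning rate (0.01) the trace settles after the early
epochs, while at 1.0 the layout keeps jumping — the mechanism behind the
learning-rate recommendation below.

## Intrinsic dimension

`twonnId()` uses the two-nearest-neighbor ratio estimator: under its
model, `log(mu_i) = log(r2_i / r1_i)` is exponential with rate d. The
largest 10% of ratios (boundary and outlier pairs) enter the likelihood as
right-censored observations; simply discarding them, a tempting reading of
the usual "discard 10%" recipe, inflates d by roughly 20%, which the
censored maximum-likelihood form avoids. The estimate depends only on
distance ratios and is therefore exactly scale invariant. `lpcaId()`
reports the number of principal components needed to reach 95% cumulative
explained variance (the threshold is exposed; no consensus value exists),
either globally or per sample over a k-NN neighborhood. On tvFC window
clouds, local estimates sit at or below their global counterparts and rise
with neighborhood size.

A practical caveat that the synthetic experiments make explicit: with
step-1 sliding windows, consecutive windows share 29 of 30 samples, so the
2-NN scale of every window is its temporal neighbors and TwoNN largely
measures the autocorrelation curve rather than the FC-state family.
Condition-level comparisons (below) therefore use non-overlapping windows.

## The synthetic multi-task dataset

`generateDataset()` emulates the statistical structure of a continuous
multi-task fMRI session: four tasks (rest, memory, math, attention), each
occupying two temporally separated 180-s blocks preceded by 12-s
instruction periods, arranged so no task repeats back-to-back, at
TR = 1.5 s. The schedule arithmetic yields 1,024 acquisitions; scan length
is derived from the schedule rather than fixed, since block arithmetic and
a nominal volume count cannot both be honored exactly. Within a block,
ROI signals are latent factors mixed through a task-specific loading
matrix (drawn once per dataset, shared across subjects), giving recurrent
task-specific covariance states; a per-task count of latent factors
controls how rich each state family is. The defaults give rest 8 factors
and each externally driven task 3, encoding the observation that FC
traverses more configurations at rest.

Three mechanisms make the data more than a sequence of static covariance
draws:

- **Amplitude envelopes** (`factorModulation = 0.6`, AR coefficient 0.95):
  each factor's amplitude follows a slow log-normal process normalized so
  the expected covariance is unchanged. The windowed covariance therefore
  wanders over an `n_factors`-parameter family — genuinely time-varying
  connectivity, and the substrate of the rest-vs-task intrinsic-dimension
  contrast.
- **Connectome fingerprints**: per-ROI signal gains (sd 0.25 around 1) and
  a subject-specific shared component (loading sd 0.7) shift the mean and
  standard deviation of each subject's connection traces. The scale was
  calibrated once so that, as with real data, group embeddings of
  unnormalized concatenated scans separate subjects while row z-scoring
  removes the effect; the ambient-space subject silhouette (~0.2 at 435
  connections) is small compared to the embedded one.
- **Individual topography** (`subjectTopographySd = 0.25`): per-subject
  perturbations of the loading matrices, so scan-level embeddings share a
  common geometry without being identical — the mechanism that makes
  low-dimensional Procrustes alignment imperfect and alignment with more
  dimensions worthwhile.

Signals get i.i.d. observation noise (sd 0.5) and an AR(1) filter
(coefficient 0.3). All randomness flows from the config seed (a separate
fingerprint seed lets task structure and fingerprints vary independently);
fixed seeds give bit-identical data. What the generator deliberately does
not model: hemodynamic convolution, physiological noise, head motion, and
voxel-level spatial structure. Passing tests on this data therefore shows
the algorithms reproduce the targeted statistical phenomena, not that they
are robust to fMRI artifacts.

## Null models

`randomizeConnectivity()` permutes row order independently per column,
destroying the row-to-connection correspondence while preserving each
column's value multiset exactly; embeddings of such surrogates carry no
task structure. `phaseRandomize()` replaces each ROI's Fourier phases
(independently per ROI) with uniform draws while keeping magnitudes, with
Hermitian symmetry enforced (DC and Nyquist real), so surrogates retain
each ROI's amplitude spectrum and autocorrelation but destroy timing.
Because phase randomization precedes the sliding window, window overlap
reintroduces temporal autocorrelation and such surrogates still embed as
time-contiguous "spaghetti", without bringing the two blocks of a task
together — a caution about interpreting temporally contiguous structure.

## Evaluation framework

`silhouetteIndex()` scores cluster structure by task or subject
(Euclidean distance, task-homogeneous windows only); it is invariant under
similarity transforms of the embedding, so Procrustes alignment never
changes a within-scan score. Group embeddings come from two strategies:
`concatEmbed()` (concatenate tvFC matrices, embed once; sensitive to
fingerprints unless rows are z-scored per scan) and `embedProcrustes()`
(embed scans separately, align with similarity transforms using the
leading `alignDims` dimensions, window index as correspondence). For the
alignment study, separability is evaluated in the first three dimensions
of the aligned embedding while `alignDims` varies; evaluating in the full
`alignDims`-dimensional space would confound the alignment gain with the
dimension-dilution of the silhouette statistic. `classifyWindows()` is an
L1-penalized multinomial logistic regression (glmnet, fixed penalty
`1/n_train`) under split-half or leave-one-subject-out cross-validation,
reporting macro F1 and per-dimension coefficient magnitudes.
`stabilityStudy()` re-embeds a scan across seeds; T-SNE uses its random
initialization there, since with the deterministic PCA initialization
there would be no seed-to-seed variability to measure. UMAP's stability is
assessed at its best-performing learning rate (0.01); the optimal T-SNE
settings are perplexity 65, correlation distance, learning rate 10.

## Problem sizes and numerical choices

The test suite and the acceptance script run on a scaled-down version of
the study conditions, chosen as the package's default experimental sizes:
30 ROIs (435 connections), 5 subjects, the full 1,024-acquisition
schedule; scan-level analyses use step-1 windows (995 windows per scan),
group-level concatenation uses step-5 windows, stability studies use 20
seeded repetitions, the Procrustes alignment contrast is averaged over
three generated dataset replicates (the low-dimensional alignment quality
fluctuates between realizations), and intrinsic-dimension validation uses
n = 2,000 manifold samples and 3,600-s single-condition scans with
non-overlapping windows. Correlations are clamped to `±(1 - 1e-7)` before the Fisher
transform so degenerate windows stay finite; row z-scoring uses the
population (1/N) standard deviation so the unit-variance invariant holds
exactly; k-NN ties break by ascending sample index; eigenvector signs are
fixed as described above. These choices are documented rather than
hidden because each one is a place where two implementations of the same
equations can legitimately differ.

## Known limitations

Scan-level problems are dense-matrix O(n^2); the exact T-SNE gradient and
dense eigendecompositions are intended for up to a few thousand windows,
not voxel-scale data. The Fisher-separability ID estimator, tapered
windows, partial-correlation FC, Barnes–Hut/parametric variants of the
learners, and formal statistical testing across hyper-parameter grids are
out of scope. The synthetic generator's fingerprints are low-rank and its
noise is white; real between-subject variability is richer, so group-level
results on this data are mechanism demonstrations, not effect-size
predictions for real cohorts.
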