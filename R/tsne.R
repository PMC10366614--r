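#' T-SNE hyper-parameters
#'
#' @param perplexity effective neighborhood size `PP` (must be < n).
#' @param m output dimensions (2 or 3 in practice).
#' @param learningRate gradient-descent step `alpha` (default 10, the value
#'   that behaves best on tvFC data; larger values trade stability for
#'   speed).
#' @param nIter gradient-descent iterations (default 1000).
#' @param earlyExaggerationFactor multiplier applied to P during the early
#'   phase (default 4).
#' @param earlyExaggerationIters length of the early-exaggeration phase
#'   (default 100).
#' @param init "pca" (classical-scaling initialization, deterministic;
#'   introduces global structure) or "random" (seeded Gaussian).
#' @param seed RNG seed (used by random initialization).
#' @return A validated list of class `"TsneParams"`.
#' @export
tsneParams <- function(perplexity = 30, m = 2L, learningRate = 10,
                       nIter = 1000L, earlyExaggerationFactor = 4,
                       earlyExaggerationIters = 100L,
                       init = c("pca", "random"), seed = 1L) {
  init <- match.arg(init)
  stopifnot(perplexity > 1, learningRate > 0, m >= 1L, nIter >= 1L,
            earlyExaggerationFactor >= 1, earlyExaggerationIters >= 0L)
  structure(list(perplexity = perplexity, m = as.integer(m),
                 learningRate = learningRate, nIter = as.integer(nIter),
                 earlyExaggerationFactor = earlyExaggerationFactor,
                 earlyExaggerationIters = as.integer(earlyExaggerationIters),
                 init = init, seed = as.integer(seed)),
            class = "TsneParams")
}

# entropy (bits) and conditional row p_{.|i} for squared distances d2 and
# kernel width sigma
condRow <- function(d2, sigma) {
  e <- -d2 / (2 * sigma^2)
  e <- e - max(e)
  w <- exp(e)
  w / sum(w)
}

entropyBits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Calibrate per-sample Gaussian kernel widths to a target perplexity
#'
#' For each sample i finds `sigma_i` such that the perplexity
#' `2^H(p_.|i)` of its conditional neighbor distribution (Gaussian kernel
#' over squared dissimilarities, Shannon entropy H in bits) equals the
#' requested value, by bisection on `log(sigma)`. If the entropy is
#' insensitive to sigma across the whole bracket (all neighbors
#' equidistant) the bracket midpoint is returned.
#'
#' @param ds symmetric dissimilarity matrix.
#' @param perplexity target perplexity, `1 < PP < n`.
#' @param tol convergence tolerance on `log2(perplexity)` (default 1e-6).
#' @param maxIter maximum bisection iterations per sample (default 200).
#' @return numeric vector of kernel widths with attribute
#'   `"achievedPerplexity"`.
#' @export
calibrateSigmas <- function(ds, perplexity, tol = 1e-6, maxIter = 200L) {
  n <- nrow(ds)
  if (perplexity <= 1 || perplexity >= n)
    stop("'perplexity' must satisfy 1 < PP < n")
  target <- log2(perplexity)
  sigmas <- numeric(n)
  achieved <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- ds[i, -i]^2
    hOf <- function(ls) entropyBits(condRow(d2, exp(ls)))
    lo <- log(sqrt(max(d2)) + 1e-12) - 30
    hi <- log(sqrt(max(d2)) + 1e-12) + 30
    hLo <- hOf(lo); hHi <- hOf(hi)
    if (abs(hHi - hLo) < tol) {           # equidistant neighbors: any sigma
      sigmas[i] <- exp((lo + hi) / 2)
      achieved[i] <- 2^hHi
      next
    }
    ok <- FALSE
    for (it in seq_len(maxIter)) {
      mid <- (lo + hi) / 2
      hMid <- hOf(mid)
      if (abs(hMid - target) < tol) { ok <- TRUE; break }
      if (hMid > target) hi <- mid else lo <- mid
    }
    if (!ok && abs(hOf((lo + hi) / 2) - target) > 1e-3)
      stop("perplexity calibration failed to converge for sample ", i)
    sigmas[i] <- exp((lo + hi) / 2)
    achieved[i] <- 2^hOf((lo + hi) / 2)
  }
  attr(sigmas, "achievedPerplexity") <- achieved
  sigmas
}

#' Joint T-SNE affinity matrix P
#'
#' Symmetrizes the perplexity-calibrated conditional distributions:
#' `P_ij = (p_i|j + p_j|i) / (2n)`, normalized so the entries sum to one
#' (standard joint formulation).
#'
#' @inheritParams calibrateSigmas
#' @param sigmas optional pre-calibrated kernel widths.
#' @return symmetric affinity matrix with zero diagonal, entries >= 0,
#'   summing to 1.
#' @export
jointP <- function(ds, perplexity, sigmas = NULL) {
  n <- nrow(ds)
  if (is.null(sigmas)) sigmas <- calibrateSigmas(ds, perplexity)
  Pc <- matrix(0, n, n)
  for (i in seq_len(n))
    Pc[i, -i] <- condRow(ds[i, -i]^2, sigmas[i])
  P <- (Pc + t(Pc)) / (2 * n)
  P / sum(P)
}

#' Low-dimensional Student-t affinity matrix Q
#'
#' `Q_ij = (1 + d_ij^2)^-1 / sum_{k != l} (1 + d_kl^2)^-1` with Euclidean
#' distances in embedding space; the heavy Student-t tail gives distant
#' points higher affinity than a Gaussian would, letting the layout push
#' dissimilar points apart.
#'
#' @param coords numeric matrix, samples x m embedding coordinates.
#' @return symmetric affinity matrix, entries summing to 1 over ordered
#'   pairs.
#' @export
lowDimQ <- function(coords) {
  d2 <- as.matrix(dist(coords))^2
  W <- 1 / (1 + d2)
  diag(W) <- 0
  W / sum(W)
}

#' Kullback-Leibler divergence between affinity matrices
#'
#' @param P,Q affinity matrices (nonnegative, summing to 1); zero entries
#'   of P contribute nothing.
#' @return `sum(P * log(P / Q))`.
#' @export
klDivergence <- function(P, Q) {
  idx <- P > 0
  sum(P[idx] * log(P[idx] / pmax(Q[idx], 1e-300)))
}

#' T-SNE embedding
#'
#' Minimizes `KL(P || Q)` by gradient descent with momentum (0.5 switching
#' to 0.8 at iteration 250) and early exaggeration (P multiplied by the
#' exaggeration factor during the initial iterations). The gradient is the
#' exact O(n^2) form; the per-iteration cost trace (computed against the P
#' in effect, so the drop at the end of the exaggeration phase is visible)
#' is stored in `diagnostics()$cost`.
#'
#' @param ds symmetric dissimilarity matrix.
#' @param params a [tsneParams()] list.
#' @param windowData optional per-sample metadata carried into the result.
#' @return An [Embedding-class].
#' @export
tsneEmbed <- function(ds, params = tsneParams(), windowData = NULL) {
  stopifnot(inherits(params, "TsneParams"))
  n <- nrow(ds)
  P <- jointP(ds, params$perplexity)
  set.seed(params$seed)
  Y0 <- if (params$init == "pca") {
    Y <- cmdscale(ds, k = params$m)
    if (ncol(Y) < params$m)
      Y <- cbind(Y, matrix(0, n, params$m - ncol(Y)))
    Y <- fixSigns(Y)
    Y / sd(Y[, 1L]) * 1e-4
  } else {
    matrix(rnorm(n * params$m, sd = 1e-4), n, params$m)
  }
  res <- tsne_gd_cpp(P, Y0, params$nIter, params$learningRate,
                     params$earlyExaggerationFactor,
                     params$earlyExaggerationIters, 250L, 0.5, 0.8)
  if (!all(is.finite(res$Y)))
    stop("numerical overflow in T-SNE gradient descent at iteration ",
         res$bad_iter)
  coords <- res$Y
  colnames(coords) <- sprintf("dim_%d", seq_len(ncol(coords)))
  if (is.null(windowData)) windowData <- data.frame(label = rep(NA_character_, n))
  new("Embedding", coords = coords, method = "TSNE",
      hyperparams = unclass(params),
      windowData = windowData,
      diagnostics = list(cost = as.numeric(res$cost),
                         exaggerationEndCost =
                           if (params$earlyExaggerationIters > 0)
                             res$cost[params$earlyExaggerationIters]
                           else NA_real_))
}
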