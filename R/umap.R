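#' UMAP hyper-parameters
#'
#' @param k neighborhood size (>= 2).
#' @param m output dimensions.
#' @param minDist minimum separation between closest samples in the
#'   embedding (default 0.8); mapped to the smooth kernel parameters
#'   `(a, b)` by [fitAb()].
#' @param learningRate initial SGD step (default 0.01; decays linearly to
#'   0 across epochs).
#' @param nEpochs optimization epochs (default 500).
#' @param negativeSampleRate negative samples per attractive update
#'   (default 5).
#' @param init "spectral" (Laplacian Eigenmaps of the fuzzy graph; falls
#'   back to seeded random when the graph is disconnected) or "random".
#' @param seed RNG seed (drives edge sampling and negative sampling).
#' @return A validated list of class `"UmapParams"`.
#' @export
umapParams <- function(k = 70L, m = 3L, minDist = 0.8, learningRate = 0.01,
                       nEpochs = 500L, negativeSampleRate = 5L,
                       init = c("spectral", "random"), seed = 1L) {
  init <- match.arg(init)
  stopifnot(k >= 2L, m >= 1L, minDist > 0, minDist < 2,
            learningRate > 0, nEpochs >= 1L, negativeSampleRate >= 1L)
  structure(list(k = as.integer(k), m = as.integer(m), minDist = minDist,
                 learningRate = learningRate, nEpochs = as.integer(nEpochs),
                 negativeSampleRate = as.integer(negativeSampleRate),
                 init = init, seed = as.integer(seed)),
            class = "UmapParams")
}

#' Per-node UMAP normalization factors rho and sigma
#'
#' `rho_i` is the distance from node i to its nearest neighbor (smallest
#' positive neighbor distance). `sigma_i` solves
#' `sum_j exp(-max(0, d_ij - rho_i) / sigma_i) = log2(k)` over the k
#' nearest neighbors, by bisection (tolerance 1e-5, at most 64 iterations,
#' bracket `[1e-8, 1e3] * max(d)`). When all k neighbors sit at distance
#' `rho_i` the left side equals k for every sigma and no root exists; the
#' lower bracket end is returned with a warning.
#'
#' @param ds symmetric dissimilarity matrix.
#' @param k neighborhood size, `2 <= k <= n - 1`.
#' @return list with numeric vectors `rho` and `sigma` and the neighbor
#'   index matrix `nn`.
#' @export
rhoSigma <- function(ds, k) {
  n <- nrow(ds)
  k <- as.integer(k)
  if (k < 2L || k > n - 1L) stop("'k' must satisfy 2 <= k <= n - 1")
  nb <- knnSets(ds, k)
  target <- log2(k)
  rho <- sigma <- numeric(n)
  degenerate <- FALSE
  for (i in seq_len(n)) {
    d <- ds[i, nb[i, ]]
    pos <- d[d > 0]
    rho[i] <- if (length(pos)) min(pos) else 0
    g <- function(s) sum(exp(-pmax(0, d - rho[i]) / s))
    dmax <- max(d, 1e-12)
    lo <- 1e-8 * dmax; hi <- 1e3 * dmax
    if (g(lo) >= target) {                # degenerate: all neighbors at rho
      sigma[i] <- lo
      degenerate <- TRUE
      next
    }
    for (it in seq_len(64L)) {
      mid <- (lo + hi) / 2
      if (g(mid) > target) hi <- mid else lo <- mid
      if (hi - lo < 1e-5 * dmax) break
    }
    sigma[i] <- (lo + hi) / 2
    if (abs(g(sigma[i]) - target) > 1e-3)
      stop("sigma calibration failed to converge for node ", i)
  }
  if (degenerate)
    warning("equidistant neighborhood(s): sigma set to the lower bracket end")
  list(rho = rho, sigma = sigma, nn = nb)
}

#' UMAP fuzzy neighborhood graph
#'
#' Builds the directed membership matrix `B` over the k-NN edge set,
#' `B[i, j] = exp(-max(0, d_ij - rho_i) / sigma_i)` for j among the k
#' nearest neighbors of i (so every node's nearest-neighbor edge has
#' weight 1), and its fuzzy-union symmetrization
#' `C = B + t(B) - B * t(B)`.
#'
#' @inheritParams rhoSigma
#' @return A [FuzzyGraph-class].
#' @export
fuzzyGraph <- function(ds, k) {
  rs <- rhoSigma(ds, k)
  n <- nrow(ds)
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- ds[i, rs$nn[i, ]]
    B[i, rs$nn[i, ]] <- exp(-pmax(0, d - rs$rho[i]) / rs$sigma[i])
  }
  C <- B + t(B) - B * t(B)
  new("FuzzyGraph", B = B, Csym = C, rho = rs$rho, sigma = rs$sigma,
      k = as.integer(k))
}

#' Fit the smooth low-dimensional kernel parameters (a, b)
#'
#' Least-squares fit of `1 / (1 + a * d^(2b))` to the piecewise target
#' curve (1 for `d <= minDist`, `exp(-(d - minDist))` beyond) over a fixed
#' grid `d` in \[0, 3\]. This is the standard construction giving
#' `minDist` its meaning as the minimum separation between closest
#' embedded samples.
#'
#' @param minDist minimum-distance parameter in (0, 2).
#' @return named numeric vector `c(a = , b = )` with attribute
#'   `"rmsResidual"`.
#' @export
fitAb <- function(minDist) {
  if (minDist <= 0 || minDist >= 2) stop("'minDist' must be in (0, 2)")
  d <- seq(0, 3, length.out = 300L)
  target <- ifelse(d <= minDist, 1, exp(-(d - minDist)))
  rss <- function(par) {
    f <- 1 / (1 + par[1L] * d^(2 * par[2L]))
    sum((f - target)^2)
  }
  fit <- optim(c(1, 1), rss, method = "L-BFGS-B",
               lower = c(1e-3, 1e-3), upper = c(100, 10))
  if (fit$convergence != 0)
    stop("kernel parameter fit failed (optim code ", fit$convergence, ")")
  out <- c(a = fit$par[1L], b = fit$par[2L])
  attr(out, "rmsResidual") <- sqrt(fit$value / length(d))
  out
}

#' UMAP layout optimization
#'
#' Minimizes the edge-wise cross-entropy between the fuzzy graph and the
#' layout graph by per-edge stochastic gradient descent: attractive
#' updates along edges sampled proportionally to their `C` weight (edges
#' below `max(w) / nEpochs` of the maximum weight are never sampled),
#' repulsive updates via uniform negative sampling, gradient components
#' clipped to \[-4, 4\], learning rate decaying linearly to 0. The mean
#' per-epoch coordinate displacement is recorded in
#' `diagnostics()$displacement` as a stability trace.
#'
#' @param graph a [FuzzyGraph-class].
#' @param params a [umapParams()] list.
#' @param windowData optional per-sample metadata carried into the result.
#' @return An [Embedding-class].
#' @export
umapEmbed <- function(graph, params = umapParams(), windowData = NULL) {
  stopifnot(is(graph, "FuzzyGraph"), inherits(params, "UmapParams"))
  C <- fuzzyC(graph)
  n <- nrow(C)
  ab <- fitAb(params$minDist)
  set.seed(params$seed)

  # undirected edge list (i < j), weight-thresholded per the sampling scheme
  idx <- which(upper.tri(C) & C > 0, arr.ind = TRUE)
  w <- C[idx]
  keep <- w >= max(w) / params$nEpochs
  idx <- idx[keep, , drop = FALSE]
  w <- w[keep]
  epochsPerSample <- max(w) / w

  Y <- if (params$init == "spectral") {
    ncomp <- countComponents(C)
    if (ncomp > 1L) {
      matrix(runif(n * params$m, -10, 10), n, params$m)
    } else {
      g <- new("NeighborGraph", weights = C, k = graph@k,
               metric = "fuzzy", nComponents = 1L)
      sp <- embeddingCoords(leEmbed(g, params$m))
      sp <- sp / max(abs(sp)) * 10
      sp + matrix(rnorm(n * params$m, sd = 1e-3), n, params$m)
    }
  } else {
    matrix(runif(n * params$m, -10, 10), n, params$m)
  }

  res <- umap_sgd_cpp(Y, idx[, 1L] - 1L, idx[, 2L] - 1L, epochsPerSample,
                      params$nEpochs, params$learningRate,
                      ab[["a"]], ab[["b"]], params$negativeSampleRate)
  if (!all(is.finite(res$Y)))
    stop("non-finite coordinates in UMAP SGD at epoch ", res$bad_epoch)
  coords <- res$Y
  colnames(coords) <- sprintf("dim_%d", seq_len(ncol(coords)))
  if (is.null(windowData)) windowData <- data.frame(label = rep(NA_character_, n))
  new("Embedding", coords = coords, method = "UMAP",
      hyperparams = c(unclass(params), list(a = ab[["a"]], b = ab[["b"]])),
      windowData = windowData,
      diagnostics = list(displacement = as.numeric(res$displacement),
                         nEdges = nrow(idx)))
}
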