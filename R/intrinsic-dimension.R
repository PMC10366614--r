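#' TwoNN intrinsic-dimension estimate
#'
#' Maximum-likelihood estimate of the global intrinsic dimension from the
#' ratios `mu_i = r2_i / r1_i` of each point's second- to first-nearest
#' Euclidean neighbor distance: under the estimator's model, `log(mu)` is
#' exponential with rate d. Duplicated points (`r1 = 0`) are dropped with
#' a warning; the 10% largest ratios — the estimator's usual guard against
#' boundary/outlier ratios — enter as right-censored observations (simply
#' discarding them would bias d upward). The estimate depends on distances
#' only through the ratios, so it is exactly invariant to global
#' rescaling.
#'
#' @param x numeric matrix, samples x features (n >= 20).
#' @return numeric intrinsic-dimension estimate.
#' @export
twonnId <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 20L) stop("twoNN needs at least 20 samples")
  ds <- as.matrix(dist(x))
  # per row: the two smallest distances excluding self
  r12 <- t(vapply(seq_len(n), function(i) {
    d <- ds[i, -i]
    sort(d, partial = 1:2)[1:2]
  }, numeric(2)))
  dup <- r12[, 1L] == 0
  if (all(dup)) stop("all points are duplicated; twoNN is degenerate")
  if (any(dup)) {
    warning(sum(dup), " duplicated point(s) dropped from twoNN estimate")
    r12 <- r12[!dup, , drop = FALSE]
  }
  mu <- sort(r12[, 2L] / r12[, 1L])
  nUse <- length(mu)
  r <- max(2L, floor(0.9 * nUse))         # top 10% treated as censored
  x <- log(mu)
  # censored-exponential MLE: log(mu) ~ Exp(d) with the largest 10% of
  # ratios censored at the cutoff rather than simply dropped
  r / (sum(x[seq_len(r)]) + (nUse - r) * x[r])
}

# neighborhood PCA dimension: smallest number of principal components whose
# cumulative explained variance reaches the threshold
pcaDim <- function(x, threshold) {
  ev <- eigen(cov(x), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  if (sum(ev) == 0) return(1L)
  cum <- cumsum(ev) / sum(ev)
  as.integer(which(cum >= threshold - 1e-12)[1L])
}

#' Local-PCA intrinsic-dimension estimate
#'
#' Eigen-decomposes the sample (or k-NN neighborhood) covariance and
#' reports the smallest number of components whose cumulative explained
#' variance reaches `threshold` (default 0.95). `scope = "local"` returns
#' one estimate per sample over its `k` Euclidean nearest neighbors (self
#' included) plus the across-sample mean.
#'
#' @param x numeric matrix, samples x features.
#' @param scope "global" or "local".
#' @param k neighborhood size for local scope (>= 5).
#' @param threshold cumulative explained-variance threshold in (0, 1\].
#' @return An [IdEstimate-class].
#' @export
lpcaId <- function(x, scope = c("global", "local"), k = 50L,
                   threshold = 0.95) {
  scope <- match.arg(scope)
  x <- as.matrix(x)
  n <- nrow(x)
  if (scope == "global") {
    d <- pcaDim(x, threshold)
    return(new("IdEstimate", estimator = "lPCA", scope = "global",
               value = as.numeric(d), localValues = numeric(0),
               k = NA_integer_, nSamples = as.integer(n)))
  }
  k <- as.integer(k)
  if (k < 5L) stop("local scope needs k >= 5")
  if (k > n - 1L) stop("'k' must be <= n - 1")
  nb <- knnSets(as.matrix(dist(x)), k)
  vals <- vapply(seq_len(n), function(i)
    as.numeric(pcaDim(x[c(i, nb[i, ]), , drop = FALSE], threshold)),
    numeric(1))
  new("IdEstimate", estimator = "lPCA", scope = "local",
      value = mean(vals), localValues = vals, k = k,
      nSamples = as.integer(n))
}

#' Intrinsic dimension of a tvFC window cloud
#'
#' Applies an estimator to the selected window columns of a tvFC matrix
#' (windows as points in the ambient connection space).
#'
#' @param tvfc a [TvfcMatrix-class].
#' @param estimator "twoNN" or "lPCA".
#' @param scope "global" or "local" (lPCA only for local neighborhoods).
#' @param k neighborhood size for local scope.
#' @param windowSubset optional task label (or vector of labels): restrict
#'   to task-homogeneous windows with those labels.
#' @param threshold cumulative-variance threshold for lPCA.
#' @return An [IdEstimate-class].
#' @export
estimateId <- function(tvfc, estimator = c("twoNN", "lPCA"),
                       scope = c("global", "local"), k = 50L,
                       windowSubset = NULL, threshold = 0.95) {
  estimator <- match.arg(estimator)
  scope <- match.arg(scope)
  stopifnot(is(tvfc, "TvfcMatrix"))
  if (!is.null(windowSubset)) {
    keep <- windowLabels(tvfc) %in% windowSubset
    tvfc <- tvfc[, keep]
  }
  x <- t(tvfcValues(tvfc))
  if (nrow(x) < 20L)
    stop("window subset has only ", nrow(x), " windows; need >= 20")
  if (estimator == "twoNN") {
    if (scope == "local") stop("local scope is supported for lPCA only")
    val <- twonnId(x)
    return(new("IdEstimate", estimator = "twoNN", scope = "global",
               value = val, localValues = numeric(0), k = NA_integer_,
               nSamples = nrow(x)))
  }
  lpcaId(x, scope = scope, k = k, threshold = threshold)
}
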