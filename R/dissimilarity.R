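#' Pairwise dissimilarity between samples
#'
#' Computes the dissimilarity matrix that seeds all three manifold
#' learners. Samples are rows of `x`; for a tvFC matrix pass
#' `t(tvfcValues(tvfc))` (windows as samples, connections as features) or
#' use [tvfcDissimilarity()].
#'
#' Metrics: `euclidean` (L2), `correlation` (1 - Pearson r between sample
#' vectors, range \[0, 2\]), `cosine` (1 - cosine similarity).
#'
#' @param x numeric matrix, samples x features.
#' @param metric one of "euclidean", "correlation", "cosine".
#' @return symmetric numeric matrix with zero diagonal and a `"metric"`
#'   attribute.
#' @examples
#' pairwiseDissimilarity(rbind(c(0, 0), c(3, 4)))[1, 2]  # 5
#' @export
pairwiseDissimilarity <- function(x,
    metric = c("euclidean", "correlation", "cosine")) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 samples")
  ds <- switch(metric,
    euclidean = as.matrix(dist(x, method = "euclidean")),
    correlation = {
      sds <- apply(x, 1L, sd)
      if (any(sds == 0))
        stop("zero-variance sample ", which(sds == 0)[1L],
             " is degenerate under the correlation metric")
      1 - cor(t(x))
    },
    cosine = {
      nrm <- sqrt(rowSums(x^2))
      if (any(nrm == 0))
        stop("zero-norm sample ", which(nrm == 0)[1L],
             " is degenerate under the cosine metric")
      1 - tcrossprod(x / nrm)
    })
  ds <- (ds + t(ds)) / 2
  ds[ds < 0] <- 0
  diag(ds) <- 0
  dimnames(ds) <- NULL
  attr(ds, "metric") <- metric
  ds
}

#' Dissimilarity between tvFC windows
#'
#' Convenience wrapper: columns of the tvFC matrix (windows) are the
#' samples.
#'
#' @param tvfc a [TvfcMatrix-class].
#' @inheritParams pairwiseDissimilarity
#' @return symmetric windows x windows dissimilarity matrix.
#' @export
tvfcDissimilarity <- function(tvfc,
    metric = c("euclidean", "correlation", "cosine")) {
  stopifnot(is(tvfc, "TvfcMatrix"))
  pairwiseDissimilarity(t(tvfcValues(tvfc)), match.arg(metric))
}

#' k-nearest neighbors from a dissimilarity matrix
#'
#' For each sample, the indices of its `k` smallest-dissimilarity neighbors
#' (self excluded), ascending by dissimilarity; ties broken by ascending
#' sample index for determinism.
#'
#' @param ds symmetric dissimilarity matrix.
#' @param k neighborhood size, `1 <= k <= n - 1`.
#' @return integer matrix, n x k; row i holds the neighbors of sample i.
#' @export
knnSets <- function(ds, k) {
  n <- nrow(ds)
  k <- as.integer(k)
  if (k < 1L || k > n - 1L)
    stop("'k' must satisfy 1 <= k <= n - 1 (n = ", n, ")")
  out <- matrix(NA_integer_, n, k)
  for (i in seq_len(n)) {
    d <- ds[i, ]
    ord <- order(d, seq_len(n))        # ties -> lower index first
    ord <- ord[ord != i]
    out[i, ] <- ord[seq_len(k)]
  }
  out
}
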