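#' Weighted k-NN affinity graph for Laplacian Eigenmaps
#'
#' Builds the neighbor graph the spectral embedding operates on. In the
#' weighted scheme (default, matching the library implementation the
#' method is usually run with) `W[i,j]` is 1 when i and j are mutually in
#' each other's k-NN sets, 0.5 when the relation holds in exactly one
#' direction, and 0 otherwise. The binary variant sets `W[i,j] = 1`
#' whenever the relation holds in at least one direction.
#'
#' @param ds symmetric dissimilarity matrix (see
#'   [pairwiseDissimilarity()]).
#' @param k neighborhood size, `1 <= k <= n - 1`.
#' @param weighted use the mutual/one-directional 1 / 0.5 weighting
#'   (default) rather than the binary union graph.
#' @return A [NeighborGraph-class]; its `nComponents` slot records the
#'   number of connected components.
#' @export
leAffinity <- function(ds, k, weighted = TRUE) {
  n <- nrow(ds)
  nb <- knnSets(ds, k)
  A <- matrix(0, n, n)                      # directed: A[i,j] = 1 iff j in kNN(i)
  A[cbind(rep(seq_len(n), each = ncol(nb)), as.vector(t(nb)))] <- 1
  W <- if (weighted) (A + t(A)) / 2 else pmax(A, t(A))
  diag(W) <- 0
  metric <- attr(ds, "metric")
  new("NeighborGraph", weights = W, k = as.integer(k),
      metric = if (is.null(metric)) "unknown" else metric,
      nComponents = countComponents(W))
}

# connected components of a symmetric adjacency by breadth-first search
countComponents <- function(W) {
  n <- nrow(W)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nbrs <- which(W[v, ] > 0 & comp == 0L)
      comp[nbrs] <- cur
      queue <- c(queue, nbrs)
    }
  }
  cur
}

# deterministic sign: each vector's largest-magnitude entry is positive
fixSigns <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Laplacian Eigenmaps embedding of a neighbor graph
#'
#' Solves the generalized eigenproblem `L f = lambda D f` with
#' `L = D - W` (D the diagonal degree matrix) through its symmetric
#' normalized form `D^{-1/2} L D^{-1/2}`, and returns the eigenvectors of
#' the `m` smallest nonzero eigenvalues (the constant eigenvector `f_0`,
#' whose eigenvalue is 0, is dropped). Because all eigenpairs are computed
#' jointly, the first `m'` columns of an m-dimensional solution equal the
#' m'-dimensional solution (up to the deterministic sign convention:
#' largest-magnitude entry positive).
#'
#' A disconnected graph is embedded jointly (with a warning); the zero
#' eigenvalue then has multiplicity equal to the component count, recorded
#' in `diagnostics()$nComponents`.
#'
#' @param graph a [NeighborGraph-class] from [leAffinity()].
#' @param m number of embedding dimensions (`m <= n - 2`).
#' @param windowData optional per-sample metadata data.frame carried into
#'   the result.
#' @return An [Embedding-class] with `diagnostics()$eigenvalues` holding
#'   the full ascending spectrum of the generalized problem.
#' @export
leEmbed <- function(graph, m, windowData = NULL) {
  stopifnot(is(graph, "NeighborGraph"))
  W <- graphWeights(graph)
  n <- nrow(W)
  m <- as.integer(m)
  if (m > n - 2L) stop("'m' must be <= n - 2")
  if (nComponents(graph) > 1L)
    warning("graph has ", nComponents(graph),
            " connected components; embedding them jointly")
  deg <- rowSums(W)
  dis <- 1 / sqrt(deg)
  Lsym <- diag(n) - (dis * W) * rep(dis, each = n)   # D^-1/2 (D - W) D^-1/2
  Lsym <- (Lsym + t(Lsym)) / 2
  es <- eigen(Lsym, symmetric = TRUE)
  ord <- seq(n, 1L)                                  # ascending eigenvalues
  lambda <- es$values[ord]
  U <- es$vectors[, ord, drop = FALSE]
  Fv <- dis * U                                      # generalized eigenvectors
  # unit-norm columns, deterministic sign
  Fv <- fixSigns(Fv / rep(sqrt(colSums(Fv^2)), each = n))
  coords <- Fv[, 2L:(m + 1L), drop = FALSE]          # drop constant f_0
  colnames(coords) <- sprintf("dim_%d", seq_len(m))
  if (is.null(windowData)) windowData <- data.frame(label = rep(NA_character_, n))
  new("Embedding", coords = coords, method = "LE",
      hyperparams = list(k = graph@k, metric = graph@metric, m = m),
      windowData = windowData,
      diagnostics = list(eigenvalues = lambda,
                         nComponents = nComponents(graph)))
}
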