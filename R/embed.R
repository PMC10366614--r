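#' Laplacian Eigenmaps hyper-parameters
#'
#' @param k neighborhood size (default 75, in the regime where the graph
#'   bridges temporally separated blocks of the same task).
#' @param m embedding dimensions (default 3).
#' @param weighted use the mutual/one-directional 1 / 0.5 affinity
#'   weighting (default) rather than the binary union graph.
#' @return A list of class `"LeParams"`.
#' @export
leParams <- function(k = 75L, m = 3L, weighted = TRUE) {
  stopifnot(k >= 1L, m >= 1L)
  structure(list(k = as.integer(k), m = as.integer(m), weighted = weighted),
            class = "LeParams")
}

# dispatch an embedding method on a precomputed dissimilarity matrix
embedDs <- function(ds, params, windowData = NULL) {
  if (inherits(params, "LeParams")) {
    g <- leAffinity(ds, params$k, weighted = params$weighted)
    if (nComponents(g) > 1L)
      return(suppressWarnings(leEmbed(g, params$m, windowData = windowData)))
    leEmbed(g, params$m, windowData = windowData)
  } else if (inherits(params, "TsneParams")) {
    tsneEmbed(ds, params, windowData = windowData)
  } else if (inherits(params, "UmapParams")) {
    umapEmbed(fuzzyGraph(ds, params$k), params, windowData = windowData)
  } else {
    stop("'params' must come from leParams(), tsneParams() or umapParams()")
  }
}

#' Embed a tvFC matrix
#'
#' One-call scan-level embedding: computes the window dissimilarity matrix
#' under the chosen metric and runs the manifold learner selected by the
#' class of `params` ([leParams()], [tsneParams()] or [umapParams()]).
#' Window metadata (start, task label, subject) is carried into the
#' result.
#'
#' @param tvfc a [TvfcMatrix-class].
#' @param params method hyper-parameters; their class selects the method.
#' @param metric dissimilarity metric (see [pairwiseDissimilarity()]).
#' @return An [Embedding-class].
#' @examples
#' \dontrun{
#' emb <- embedTvfc(tvfc, leParams(k = 75, m = 3), metric = "correlation")
#' }
#' @export
embedTvfc <- function(tvfc, params = leParams(),
                      metric = c("euclidean", "correlation", "cosine")) {
  stopifnot(is(tvfc, "TvfcMatrix"))
  metric <- match.arg(metric)
  ds <- tvfcDissimilarity(tvfc, metric)
  wd <- data.frame(window_start = windowStarts(tvfc),
                   label = windowLabels(tvfc),
                   subject = rep(subjectId(tvfc), ncol(tvfc)))
  embedDs(ds, params, windowData = wd)
}
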