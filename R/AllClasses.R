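#' @import methods
#' @importFrom stats cor sd dist fft rnorm runif quantile median optim
#'   cmdscale setNames cov predict coef
#' @importFrom utils head read.table write.table combn packageVersion
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames rowData colData
#' @importFrom S4Vectors metadata DataFrame
#' @useDynLib manifoldFC, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' ROI timeseries container
#'
#' Holds a regions-of-interest (ROI) by acquisitions signal matrix for one
#' scan, together with its sampling interval (TR, seconds) and a subject tag.
#' This is the input object for sliding-window connectivity
#' ([computeTvfc()]) and for phase randomization ([phaseRandomize()]).
#'
#' @slot data numeric matrix, ROIs in rows, acquisitions in columns.
#' @slot tr sampling interval in seconds.
#' @slot subjectId character scalar identifying the subject.
#'
#' @seealso [RoiTimeseries()], [computeTvfc()], [generateDataset()]
#' @export
setClass("RoiTimeseries",
  representation(data = "matrix", tr = "numeric", subjectId = "character"))

setValidity("RoiTimeseries", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) msg <- c(msg, "'data' must be numeric")
  if (anyNA(object@data)) msg <- c(msg, "'data' contains missing values")
  if (nrow(object@data) < 2L) msg <- c(msg, "need at least 2 ROIs")
  if (ncol(object@data) < 2L) msg <- c(msg, "need at least 2 acquisitions")
  if (length(object@tr) != 1L || object@tr <= 0)
    msg <- c(msg, "'tr' must be a positive scalar (seconds)")
  if (length(object@subjectId) != 1L) msg <- c(msg, "'subjectId' must be scalar")
  if (is.null(rownames(object@data))) msg <- c(msg, "'data' must have ROI names")
  if (length(msg)) msg else TRUE
})

#' Construct a RoiTimeseries
#'
#' @param data numeric matrix, ROIs x acquisitions. Row names are taken as
#'   ROI names; default names `ROI001...` are added if absent.
#' @param tr repetition time in seconds.
#' @param subjectId subject label.
#' @return A [RoiTimeseries-class] object.
#' @examples
#' ts <- RoiTimeseries(matrix(rnorm(40), 4, 10), tr = 1.5, subjectId = "sub01")
#' nRois(ts)
#' @export
RoiTimeseries <- function(data, tr = 1.5, subjectId = "sub01") {
  data <- as.matrix(data)
  if (is.null(rownames(data)))
    rownames(data) <- sprintf("ROI%03d", seq_len(nrow(data)))
  new("RoiTimeseries", data = data, tr = tr, subjectId = as.character(subjectId))
}

#' Task schedule
#'
#' An ordered, non-overlapping set of events partitioning a scan into task
#' and instruction intervals. Onsets and durations are expressed in
#' acquisitions (0-based onsets), the unit in which windows are defined.
#'
#' @slot events data.frame with columns `onset_acq`, `duration_acq`, `label`.
#' @slot nAcq total number of acquisitions covered.
#' @export
setClass("TaskSchedule",
  representation(events = "data.frame", nAcq = "integer"))

setValidity("TaskSchedule", function(object) {
  ev <- object@events
  need <- c("onset_acq", "duration_acq", "label")
  if (!all(need %in% names(ev))) return("events needs onset_acq, duration_acq, label")
  if (nrow(ev) == 0L) return("empty schedule")
  if (is.unsorted(ev$onset_acq, strictly = TRUE)) return("events must be sorted by onset")
  ends <- ev$onset_acq + ev$duration_acq
  if (any(ev$onset_acq[-1L] != ends[-nrow(ev)]))
    return("events must tile the scan without gaps or overlaps")
  if (ev$onset_acq[1L] != 0L) return("first event must start at acquisition 0")
  if (ends[nrow(ev)] != object@nAcq) return("events must cover exactly nAcq acquisitions")
  TRUE
})

#' Construct a TaskSchedule
#'
#' @param events data.frame with 0-based `onset_acq`, `duration_acq` (counts)
#'   and `label` ("instruction" or a task name). Events must tile the scan.
#' @param nAcq total acquisitions; defaults to the end of the last event.
#' @return A [TaskSchedule-class] object.
#' @export
TaskSchedule <- function(events, nAcq = NULL) {
  events$onset_acq <- as.integer(events$onset_acq)
  events$duration_acq <- as.integer(events$duration_acq)
  events$label <- as.character(events$label)
  if (is.null(nAcq))
    nAcq <- events$onset_acq[nrow(events)] + events$duration_acq[nrow(events)]
  new("TaskSchedule", events = events, nAcq = as.integer(nAcq))
}

#' Sliding-window specification
#'
#' Rectangular sliding windows of `wDuration` acquisitions advanced by
#' `wStep` acquisitions; windows are half-open 0-based intervals
#' `[start, start + wDuration)`.
#'
#' @slot wDuration window length in acquisitions (default 30, i.e. 45 s at
#'   TR = 1.5 s).
#' @slot wStep window step in acquisitions (default 1).
#' @export
setClass("WindowSpec", representation(wDuration = "integer", wStep = "integer"))

setValidity("WindowSpec", function(object) {
  if (length(object@wDuration) != 1L || object@wDuration < 1L) return("bad wDuration")
  if (length(object@wStep) != 1L || object@wStep < 1L) return("bad wStep")
  if (object@wStep > object@wDuration) return("wStep must be <= wDuration")
  TRUE
})

#' @rdname WindowSpec-class
#' @param wDuration,wStep window length and step in acquisitions.
#' @return A [WindowSpec-class] object.
#' @export
WindowSpec <- function(wDuration = 30L, wStep = 1L) {
  new("WindowSpec", wDuration = as.integer(wDuration), wStep = as.integer(wStep))
}

#' Time-varying functional connectivity matrix
#'
#' The central data object of the package: a connections x windows matrix of
#' Fisher-z transformed windowed Pearson correlations, stored as a
#' [SummarizedExperiment::SummarizedExperiment] whose single assay `"z"` has
#' one row per unique ROI pair (i < j) and one column per sliding window.
#' Row metadata carries the connection index (`roi_i`, `roi_j`); column
#' metadata carries `window_start` (0-based acquisition index) and `label`
#' (task name or `"mixed"`). The window specification, normalization flag,
#' TR and subject tag live in `metadata()`.
#'
#' @seealso [computeTvfc()], [zscoreRows()], [connectionIndex()],
#'   [windowStarts()], [windowLabels()]
#' @export
setClass("TvfcMatrix", contains = "SummarizedExperiment")

setValidity("TvfcMatrix", function(object) {
  if (!"z" %in% SummarizedExperiment::assayNames(object)) return("assay 'z' missing")
  rd <- SummarizedExperiment::rowData(object)
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("roi_i", "roi_j") %in% names(rd))) return("rowData needs roi_i, roi_j")
  if (!all(c("window_start", "label") %in% names(cd)))
    return("colData needs window_start, label")
  if (any(rd$roi_i >= rd$roi_j)) return("connection index must satisfy i < j")
  md <- S4Vectors::metadata(object)
  if (!is(md$spec, "WindowSpec")) return("metadata$spec must be a WindowSpec")
  if (!is.logical(md$normalized)) return("metadata$normalized must be a flag")
  n <- (1 + sqrt(1 + 8 * nrow(object))) / 2
  if (abs(n - round(n)) > 1e-9) return("row count is not N*(N-1)/2 for integer N")
  TRUE
})

#' Low-dimensional embedding
#'
#' Coordinates of tvFC windows (or other samples) in an m-dimensional space,
#' produced by one of the three manifold learning methods. Window metadata
#' (start, task label, subject, scan) is carried along so that evaluation
#' functions can score the embedding without referring back to the input.
#'
#' @slot coords numeric matrix, samples x dimensions.
#' @slot method one of "LE", "TSNE", "UMAP".
#' @slot hyperparams named list of the hyper-parameters used.
#' @slot windowData data.frame of per-sample metadata (at least `label`).
#' @slot diagnostics named list: eigenvalues (LE), cost trace (T-SNE),
#'   per-epoch displacement (UMAP), component counts, seeds.
#' @export
setClass("Embedding",
  representation(coords = "matrix", method = "character",
                 hyperparams = "list", windowData = "data.frame",
                 diagnostics = "list"))

setValidity("Embedding", function(object) {
  if (!all(is.finite(object@coords))) return("coordinates must be finite")
  if (nrow(object@windowData) != nrow(object@coords))
    return("windowData rows must match sample count")
  if (!object@method %in% c("LE", "TSNE", "UMAP")) return("unknown method")
  TRUE
})

#' Group-level embedding
#'
#' An [Embedding-class] whose samples pool windows from several scans,
#' produced either by "Concatenate + Embed" ([concatEmbed()]) or by
#' "Embed + Procrustes" ([embedProcrustes()]). `windowData` additionally
#' carries `subject` and `scan` columns.
#'
#' @slot strategy "concat_embed" or "embed_procrustes".
#' @slot alignDims dimensions used by the Procrustes alignment (0 for
#'   concatenation).
#' @export
setClass("GroupEmbedding", contains = "Embedding",
  representation(strategy = "character", alignDims = "integer"))

#' Weighted k-nearest-neighbor graph
#'
#' Shared substrate of the Laplacian Eigenmaps pipeline: a symmetric
#' affinity matrix over samples whose entries are 1 for mutual neighbors,
#' 0.5 for one-directional neighbors and 0 otherwise (or 1/0 in the binary
#' variant).
#'
#' @slot weights symmetric numeric matrix with zero diagonal.
#' @slot k neighborhood size used.
#' @slot metric distance name the dissimilarities were computed with.
#' @slot nComponents number of connected components of the graph.
#' @export
setClass("NeighborGraph",
  representation(weights = "matrix", k = "integer", metric = "character",
                 nComponents = "integer"))

setValidity("NeighborGraph", function(object) {
  W <- object@weights
  if (nrow(W) != ncol(W)) return("weights must be square")
  if (max(abs(W - t(W))) > 1e-12) return("weights must be symmetric")
  if (any(diag(W) != 0)) return("diagonal must be zero")
  if (any(rowSums(W) == 0)) return("every node needs at least one edge")
  TRUE
})

#' UMAP fuzzy neighborhood graph
#'
#' Output of the UMAP graph-construction phase: the directed membership
#' matrix `B` (exponential weights over the k-NN edge set), its fuzzy-union
#' symmetrization `C = B + t(B) - B * t(B)`, and the per-node normalization
#' factors `rho` (distance to nearest neighbor) and `sigma` (calibrated
#' scale).
#'
#' @slot B directed weight matrix, entries in \[0, 1\].
#' @slot C symmetric weight matrix, entries in \[0, 1\].
#' @slot rho,sigma per-node normalization factors.
#' @slot k neighborhood size used.
#' @export
setClass("FuzzyGraph",
  representation(B = "matrix", Csym = "matrix", rho = "numeric",
                 sigma = "numeric", k = "integer"))

setValidity("FuzzyGraph", function(object) {
  if (min(object@B) < 0 || max(object@B) > 1 + 1e-12)
    return("B entries must lie in [0,1]")
  if (max(abs(object@Csym - t(object@Csym))) > 1e-12) return("C must be symmetric")
  if (min(object@Csym) < 0 || max(object@Csym) > 1 + 1e-12)
    return("C entries must lie in [0,1]")
  TRUE
})

#' Intrinsic-dimension estimate
#'
#' @slot estimator "twoNN" or "lPCA".
#' @slot scope "global" (one estimate from all samples) or "local"
#'   (one estimate per sample over its k-NN neighborhood).
#' @slot value the global estimate, or the across-sample mean of the local
#'   estimates.
#' @slot localValues per-sample estimates (local scope only).
#' @slot k neighborhood size (local scope only, `NA` otherwise).
#' @slot nSamples number of samples used.
#' @export
setClass("IdEstimate",
  representation(estimator = "character", scope = "character",
                 value = "numeric", localValues = "numeric",
                 k = "integer", nSamples = "integer"))
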