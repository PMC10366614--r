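# Accessor and show methods. Slot access stays inside this file (and the
# constructors); everything else goes through these.

#' @rdname accessors
#' @export
setMethod("nRois", "RoiTimeseries", function(object) nrow(object@data))
#' @rdname accessors
#' @export
setMethod("nAcquisitions", "RoiTimeseries", function(object) ncol(object@data))
#' @rdname accessors
#' @export
setMethod("trSeconds", "RoiTimeseries", function(object) object@tr)
#' @rdname accessors
#' @export
setMethod("subjectId", "RoiTimeseries", function(object) object@subjectId)
#' @rdname accessors
#' @export
setMethod("roiNames", "RoiTimeseries", function(object) rownames(object@data))

#' Extract the ROI x acquisitions matrix
#' @param object a [RoiTimeseries-class].
#' @return numeric matrix, ROIs in rows.
#' @export
tsData <- function(object) {
  stopifnot(is(object, "RoiTimeseries"))
  object@data
}

#' @rdname accessors
#' @export
setMethod("scheduleEvents", "TaskSchedule", function(object) object@events)
#' @rdname accessors
#' @export
setMethod("nAcquisitions", "TaskSchedule", function(object) object@nAcq)

#' Window length and step of a WindowSpec
#' @param object a [WindowSpec-class].
#' @return integer scalar.
#' @export
wDuration <- function(object) object@wDuration
#' @rdname wDuration
#' @export
wStep <- function(object) object@wStep

#' @rdname accessors
#' @export
setMethod("tvfcValues", "TvfcMatrix",
  function(object) SummarizedExperiment::assay(object, "z"))
#' @rdname accessors
#' @export
setMethod("connectionIndex", "TvfcMatrix",
  function(object) as.data.frame(SummarizedExperiment::rowData(object)))
#' @rdname accessors
#' @export
setMethod("windowStarts", "TvfcMatrix",
  function(object) SummarizedExperiment::colData(object)$window_start)
#' @rdname accessors
#' @export
setMethod("windowLabels", "TvfcMatrix",
  function(object) SummarizedExperiment::colData(object)$label)
#' @rdname accessors
#' @export
setMethod("windowSpec", "TvfcMatrix",
  function(object) S4Vectors::metadata(object)$spec)
#' @rdname accessors
#' @export
setMethod("isNormalized", "TvfcMatrix",
  function(object) S4Vectors::metadata(object)$normalized)
#' @rdname accessors
#' @export
setMethod("subjectId", "TvfcMatrix",
  function(object) S4Vectors::metadata(object)$subject_id)

#' @rdname accessors
#' @export
setMethod("embeddingCoords", "Embedding", function(object) object@coords)
#' @rdname accessors
#' @export
setMethod("embeddingMethod", "Embedding", function(object) object@method)
#' @rdname accessors
#' @export
setMethod("windowData", "Embedding", function(object) object@windowData)
#' @rdname accessors
#' @export
setMethod("diagnostics", "Embedding", function(object) object@diagnostics)

#' Hyper-parameters of an Embedding
#' @param object an [Embedding-class].
#' @return named list.
#' @export
hyperParams <- function(object) object@hyperparams

#' @rdname accessors
#' @export
setMethod("graphWeights", "NeighborGraph", function(object) object@weights)
#' @rdname accessors
#' @export
setMethod("nComponents", "NeighborGraph", function(object) object@nComponents)

#' Fuzzy graph components
#' @param object a [FuzzyGraph-class].
#' @return The requested matrix or vector.
#' @export
fuzzyB <- function(object) object@B
#' @rdname fuzzyB
#' @export
fuzzyC <- function(object) object@Csym
#' @rdname fuzzyB
#' @export
fuzzyRho <- function(object) object@rho
#' @rdname fuzzyB
#' @export
fuzzySigma <- function(object) object@sigma

#' @rdname accessors
#' @export
setMethod("idValue", "IdEstimate", function(object) object@value)
#' @rdname accessors
#' @export
setMethod("localIdValues", "IdEstimate", function(object) object@localValues)

setMethod("show", "RoiTimeseries", function(object) {
  cat(sprintf("RoiTimeseries: %d ROIs x %d acquisitions (TR = %g s, subject %s)\n",
              nRois(object), nAcquisitions(object), trSeconds(object),
              subjectId(object)))
})

setMethod("show", "TaskSchedule", function(object) {
  ev <- scheduleEvents(object)
  tasks <- setdiff(unique(ev$label), "instruction")
  cat(sprintf("TaskSchedule: %d events over %d acquisitions; tasks: %s\n",
              nrow(ev), nAcquisitions(object), paste(tasks, collapse = ", ")))
})

setMethod("show", "WindowSpec", function(object) {
  cat(sprintf("WindowSpec: duration %d, step %d (acquisitions)\n",
              wDuration(object), wStep(object)))
})

setMethod("show", "TvfcMatrix", function(object) {
  cat(sprintf("TvfcMatrix: %d connections x %d windows (%s; w = %d, step = %d)\n",
              nrow(object), ncol(object),
              if (isNormalized(object)) "row z-scored" else "Fisher-z, as-is",
              wDuration(windowSpec(object)), wStep(windowSpec(object))))
  lab <- windowLabels(object)
  cat("  window labels:",
      paste(sprintf("%s(%d)", names(table(lab)), table(lab)), collapse = " "),
      "\n")
})

setMethod("show", "Embedding", function(object) {
  cat(sprintf("%s embedding: %d samples x %d dimensions\n",
              embeddingMethod(object), nrow(embeddingCoords(object)),
              ncol(embeddingCoords(object))))
  hp <- hyperParams(object)
  if (length(hp))
    cat("  hyper-parameters:",
        paste(names(hp), vapply(hp, function(x) paste(format(x), collapse = "/"),
                                character(1)), sep = "=", collapse = ", "), "\n")
})

setMethod("show", "GroupEmbedding", function(object) {
  callNextMethod()
  cat(sprintf("  group strategy: %s (%d scans)\n", object@strategy,
              length(unique(windowData(object)$scan))))
})

setMethod("show", "NeighborGraph", function(object) {
  cat(sprintf("NeighborGraph: %d nodes, k = %d, metric = %s, %d component(s)\n",
              nrow(graphWeights(object)), object@k, object@metric,
              nComponents(object)))
})

setMethod("show", "FuzzyGraph", function(object) {
  cat(sprintf("FuzzyGraph: %d nodes, k = %d; median sigma = %.4g\n",
              nrow(fuzzyB(object)), object@k, median(fuzzySigma(object))))
})

setMethod("show", "IdEstimate", function(object) {
  cat(sprintf("IdEstimate (%s, %s): %.2f [n = %d%s]\n",
              object@estimator, object@scope, idValue(object), object@nSamples,
              if (!is.na(object@k)) sprintf(", k = %d", object@k) else ""))
})
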