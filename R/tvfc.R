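#' Number of unique pairwise connections
#'
#' For `n` regions, the number of unique unordered ROI pairs is
#' `n * (n - 1) / 2` — the row dimension of a tvFC matrix.
#'
#' @param nRois number of regions (>= 2).
#' @return integer count of connections.
#' @examples
#' countConnections(157)  # 12246 for the 157-ROI parcellation
#' @export
countConnections <- function(nRois) {
  nRois <- as.integer(nRois)
  if (length(nRois) != 1L || is.na(nRois) || nRois < 2L)
    stop("'nRois' must be a single integer >= 2")
  as.integer(nRois * (nRois - 1L) / 2L)
}

#' Number of sliding windows that fit a scan
#'
#' Windows of `wDuration` acquisitions advanced by `wStep` until a full
#' window no longer fits: `floor((nAcq - (wDuration - wStep)) / wStep)`.
#'
#' @param nAcq number of acquisitions in the scan.
#' @param spec a [WindowSpec-class].
#' @return integer window count.
#' @examples
#' countWindows(1017, WindowSpec(30, 1))  # 988
#' @export
countWindows <- function(nAcq, spec = WindowSpec()) {
  nAcq <- as.integer(nAcq)
  if (wDuration(spec) > nAcq)
    stop("window duration (", wDuration(spec), ") exceeds scan length (", nAcq, ")")
  as.integer((nAcq - (wDuration(spec) - wStep(spec))) %/% wStep(spec))
}

# 0-based window start indices for a scan
windowStartIndices <- function(nAcq, spec) {
  n <- countWindows(nAcq, spec)
  as.integer(seq(0L, by = wStep(spec), length.out = n))
}

# connection index in column-major upper-triangle order:
# (1,2),(1,3),(2,3),(1,4),... matching upper.tri() vectorization
connectionPairs <- function(nRois) {
  j <- rep(seq_len(nRois), seq_len(nRois) - 1L)
  i <- sequence(seq_len(nRois) - 1L)
  data.frame(roi_i = i, roi_j = j)
}

# clamp correlations away from +-1 before arctanh so degenerate windows
# stay finite
FISHER_CLIP <- 1 - 1e-7

fisherZ <- function(r) atanh(pmin(pmax(r, -FISHER_CLIP), FISHER_CLIP))

#' Sliding-window time-varying functional connectivity
#'
#' For each rectangular half-open window `[start, start + wDuration)` the
#' Pearson correlation between all ROI pairs is computed, Fisher-z
#' transformed (`atanh`, with correlations clamped to +-(1 - 1e-7)) and
#' vectorized in upper-triangle order, one column per window.
#'
#' @param ts a [RoiTimeseries-class].
#' @param spec a [WindowSpec-class] (default 30-acquisition windows, step 1).
#' @param schedule optional [TaskSchedule-class]; when supplied, windows are
#'   labeled with [labelWindows()], otherwise all labels are `NA`.
#' @return A [TvfcMatrix-class] of size
#'   `countConnections(nRois(ts)) x countWindows(nAcquisitions(ts), spec)`.
#' @examples
#' ts <- RoiTimeseries(matrix(rnorm(3 * 40), 3, 40), tr = 1.5)
#' computeTvfc(ts, WindowSpec(30, 5))  # 3 connections x 3 windows
#' @export
computeTvfc <- function(ts, spec = WindowSpec(), schedule = NULL) {
  stopifnot(is(ts, "RoiTimeseries"), is(spec, "WindowSpec"))
  X <- tsData(ts)
  nAcq <- ncol(X)
  starts <- windowStartIndices(nAcq, spec)
  w <- wDuration(spec)
  pairs <- connectionPairs(nrow(X))
  ut <- upper.tri(matrix(0, nrow(X), nrow(X)))
  Z <- matrix(NA_real_, nrow(pairs), length(starts))
  for (c in seq_along(starts)) {
    seg <- t(X[, (starts[c] + 1L):(starts[c] + w), drop = FALSE])
    sds <- apply(seg, 2L, sd)
    if (any(sds == 0))
      stop(sprintf("zero-variance ROI '%s' in window %d (start %d)",
                   rownames(X)[which(sds == 0)[1L]], c, starts[c]))
    Z[, c] <- fisherZ(cor(seg)[ut])
  }
  labels <- if (is.null(schedule)) rep(NA_character_, length(starts))
            else labelWindows(schedule, nAcq, spec)
  newTvfc(Z, pairs, starts, spec, labels, normalized = FALSE,
          tr = trSeconds(ts), subject = subjectId(ts),
          roiNames = roiNames(ts))
}

# internal TvfcMatrix constructor
newTvfc <- function(values, pairs, starts, spec, labels, normalized,
                    tr = NA_real_, subject = NA_character_, roiNames = NULL,
                    extra = list()) {
  rd <- S4Vectors::DataFrame(pairs)
  if (!is.null(roiNames)) {
    rd$name_i <- roiNames[pairs$roi_i]
    rd$name_j <- roiNames[pairs$roi_j]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(z = values),
    rowData = rd,
    colData = S4Vectors::DataFrame(window_start = as.integer(starts),
                                   label = labels),
    metadata = c(list(spec = spec, normalized = normalized, tr = tr,
                      subject_id = subject), extra))
  new("TvfcMatrix", se)
}

#' Row-wise z-scoring of a tvFC matrix
#'
#' Forces every connection's trace to mean 0 and standard deviation 1
#' across the window axis (population, 1/N, convention so the unit-variance
#' invariant holds exactly). This is the "normalized" variant of the tvFC
#' matrix; it removes the per-connection mean/std offsets that drive
#' connectome fingerprinting.
#'
#' @param tvfc a [TvfcMatrix-class].
#' @return A [TvfcMatrix-class] with the `normalized` flag set.
#' @export
zscoreRows <- function(tvfc) {
  stopifnot(is(tvfc, "TvfcMatrix"))
  Z <- tvfcValues(tvfc)
  mu <- rowMeans(Z)
  sdp <- sqrt(rowMeans((Z - mu)^2))
  if (any(sdp == 0))
    stop("constant row: connection ", which(sdp == 0)[1L],
         " has zero variance across windows")
  Zn <- (Z - mu) / sdp
  out <- tvfc
  SummarizedExperiment::assay(out, "z") <- Zn
  S4Vectors::metadata(out)$normalized <- TRUE
  out
}

# per-acquisition label vector ("instruction" / task name) from a schedule
acquisitionLabels <- function(schedule) {
  ev <- scheduleEvents(schedule)
  rep(ev$label, ev$duration_acq)
}

#' Label sliding windows by task
#'
#' A window is task-homogeneous — and receives that task's label — iff all
#' of its acquisitions carry one single task label and none fall in an
#' instruction period. Every other window is `"mixed"`.
#'
#' @param schedule a [TaskSchedule-class] covering the scan.
#' @param nAcq scan length in acquisitions.
#' @param spec a [WindowSpec-class].
#' @return character vector of length `countWindows(nAcq, spec)`.
#' @export
labelWindows <- function(schedule, nAcq, spec = WindowSpec()) {
  stopifnot(is(schedule, "TaskSchedule"))
  if (nAcquisitions(schedule) < nAcq)
    stop("schedule covers ", nAcquisitions(schedule),
         " acquisitions but the scan has ", nAcq)
  acqLab <- acquisitionLabels(schedule)
  starts <- windowStartIndices(nAcq, spec)
  w <- wDuration(spec)
  vapply(starts, function(s) {
    lab <- unique(acqLab[(s + 1L):(s + w)])
    if (length(lab) == 1L && lab != "instruction") lab else "mixed"
  }, character(1))
}

#' Select task-homogeneous windows
#'
#' @param tvfc a [TvfcMatrix-class] with window labels.
#' @return A [TvfcMatrix-class] restricted to windows whose label is a task
#'   name (drops `"mixed"` windows).
#' @export
homogeneousWindows <- function(tvfc) {
  keep <- !is.na(windowLabels(tvfc)) & windowLabels(tvfc) != "mixed"
  tvfc[, keep]
}
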