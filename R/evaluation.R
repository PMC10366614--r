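#' Silhouette index of an embedding or of ambient tvFC data
#'
#' Standard silhouette score (cluster cohesion vs. separation, in
#' \[-1, 1\]) over Euclidean distance, grouped by task or by subject.
#' For task scoring, windows labeled `"mixed"` (or unlabeled) are
#' excluded. Passing a [TvfcMatrix-class] scores the raw windows in
#' ambient connection space (columns as samples).
#'
#' @param x an [Embedding-class], [GroupEmbedding-class] or
#'   [TvfcMatrix-class].
#' @param labelType "task" or "subject".
#' @param dims optionally restrict to the first `dims` embedding
#'   dimensions.
#' @return list of class `"SilhouetteReport"` with elements `labelType`,
#'   `value`, `nUsed`, `excluded`.
#' @export
silhouetteIndex <- function(x, labelType = c("task", "subject"), dims = NULL) {
  labelType <- match.arg(labelType)
  if (is(x, "TvfcMatrix")) {
    coords <- t(tvfcValues(x))
    labels <- if (labelType == "task") windowLabels(x)
              else rep(subjectId(x), ncol(x))
  } else {
    stopifnot(is(x, "Embedding"))
    coords <- embeddingCoords(x)
    wd <- windowData(x)
    labels <- if (labelType == "task") wd$label else wd$subject
    if (is.null(labels)) stop("no '", labelType, "' labels available")
  }
  if (!is.null(dims)) coords <- coords[, seq_len(dims), drop = FALSE]
  keep <- if (labelType == "task") !is.na(labels) & labels != "mixed"
          else !is.na(labels)
  excluded <- sum(!keep)
  coords <- coords[keep, , drop = FALSE]
  labels <- labels[keep]
  if (length(unique(labels)) < 2L)
    stop("silhouette undefined: fewer than 2 distinct labels")
  sil <- cluster::silhouette(as.integer(factor(labels)), dist(coords))
  structure(list(labelType = labelType,
                 value = mean(sil[, "sil_width"]),
                 nUsed = nrow(coords), excluded = excluded),
            class = "SilhouetteReport")
}

#' @export
print.SilhouetteReport <- function(x, ...) {
  cat(sprintf("SI_%s = %.4f (n = %d windows, %d excluded)\n",
              x$labelType, x$value, x$nUsed, x$excluded))
  invisible(x)
}

#' Group embedding by "Concatenate + Embed"
#'
#' Concatenates scan-level tvFC matrices column-wise into one large matrix
#' for the whole dataset (optionally row z-scoring each scan first) and
#' computes a single embedding on the result. Without normalization the
#' per-connection mean/std fingerprints remain in the data and the group
#' embedding separates subjects; z-scoring removes them.
#'
#' @param tvfcs list of [TvfcMatrix-class] with identical connection
#'   indices.
#' @param params embedding hyper-parameters ([leParams()], [tsneParams()]
#'   or [umapParams()]).
#' @param metric dissimilarity metric.
#' @param normalize z-score each scan's rows before concatenation.
#' @return A [GroupEmbedding-class].
#' @export
concatEmbed <- function(tvfcs, params = leParams(),
                        metric = c("euclidean", "correlation", "cosine"),
                        normalize = FALSE) {
  metric <- match.arg(metric)
  stopifnot(length(tvfcs) >= 1L, all(vapply(tvfcs, is, TRUE, "TvfcMatrix")))
  ci <- lapply(tvfcs, function(t) connectionIndex(t)[, c("roi_i", "roi_j")])
  if (!all(vapply(ci, identical, TRUE, ci[[1L]])))
    stop("scans have mismatched connection indices")
  if (normalize) tvfcs <- lapply(tvfcs, zscoreRows)
  X <- do.call(cbind, lapply(tvfcs, tvfcValues))
  wd <- do.call(rbind, lapply(seq_along(tvfcs), function(s)
    data.frame(window_start = windowStarts(tvfcs[[s]]),
               label = windowLabels(tvfcs[[s]]),
               subject = rep(subjectId(tvfcs[[s]]), ncol(tvfcs[[s]])),
               scan = s)))
  ds <- pairwiseDissimilarity(t(X), metric)
  emb <- embedDs(ds, params, windowData = wd)
  new("GroupEmbedding", coords = embeddingCoords(emb),
      method = embeddingMethod(emb), hyperparams = hyperParams(emb),
      windowData = windowData(emb), diagnostics = diagnostics(emb),
      strategy = "concat_embed", alignDims = 0L)
}

#' Least-squares similarity (Procrustes) fit
#'
#' Finds the translation, rotation/reflection and uniform scale that best
#' map `source` onto `target` in the least-squares sense, via the SVD of
#' the cross-covariance of the centered configurations. The disparity is
#' the residual sum of squares normalized by the total variance of the
#' centered target (0 for an exact match).
#'
#' @param source,target numeric matrices of equal dimensions (n x m,
#'   `n >= m + 1`), rows in correspondence.
#' @return list of class `"ProcrustesFit"`: `rotation` (m x m orthogonal),
#'   `scale`, `translation` (length m), `disparity`.
#' @export
procrustesFit <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (!identical(dim(source), dim(target)))
    stop("'source' and 'target' must have equal dimensions")
  if (nrow(source) < ncol(source) + 1L)
    stop("need at least m + 1 points for an m-dimensional fit")
  muS <- colMeans(source); muT <- colMeans(target)
  Xc <- sweep(source, 2L, muS); Yc <- sweep(target, 2L, muT)
  nX <- sum(Xc^2); nY <- sum(Yc^2)
  if (nX == 0 || nY == 0)
    stop("degenerate (zero-variance) configuration")
  sv <- svd(crossprod(Xc, Yc))
  R <- sv$u %*% t(sv$v)
  s <- sum(sv$d) / nX
  translation <- muT - s * drop(muS %*% R)
  disparity <- max(0, 1 - sum(sv$d)^2 / (nX * nY))
  structure(list(rotation = R, scale = s, translation = translation,
                 disparity = disparity),
            class = "ProcrustesFit")
}

#' Apply a Procrustes fit to coordinates
#'
#' @param fit a `"ProcrustesFit"` from [procrustesFit()].
#' @param x numeric matrix of coordinates.
#' @return transformed coordinates `s * x * R + t`.
#' @export
applyProcrustes <- function(fit, x) {
  stopifnot(inherits(fit, "ProcrustesFit"))
  sweep(fit$scale * (as.matrix(x) %*% fit$rotation), 2L, fit$translation, "+")
}

#' Group embedding by "Embed + Procrustes"
#'
#' Aligns independently computed scan-level embeddings into a common space
#' with similarity (Procrustes) transforms, using the first `alignDims`
#' dimensions of each, and stacks the aligned coordinates. Scans must have
#' equal window counts with matched schedules: the window index provides
#' the point correspondence. More alignment dimensions (toward the data's
#' intrinsic dimension) give better task alignment; the similarity
#' transform leaves within-scan distance ratios untouched.
#'
#' @param embeddings list of [Embedding-class] with at least `alignDims`
#'   dimensions and equal sample counts.
#' @param alignDims number of leading dimensions used for the alignment.
#' @param reference index of the reference scan (default 1), or
#'   `"generalized"` for an iterative align-to-evolving-mean fit
#'   (5 passes).
#' @return A [GroupEmbedding-class] in `alignDims` dimensions.
#' @export
embedProcrustes <- function(embeddings, alignDims, reference = 1L) {
  stopifnot(length(embeddings) >= 1L,
            all(vapply(embeddings, is, TRUE, "Embedding")))
  ns <- vapply(embeddings, function(e) nrow(embeddingCoords(e)), integer(1))
  if (length(unique(ns)) != 1L)
    stop("scans have mismatched window counts; no correspondence")
  alignDims <- as.integer(alignDims)
  if (any(vapply(embeddings, function(e) ncol(embeddingCoords(e)), integer(1))
          < alignDims))
    stop("every embedding needs at least 'alignDims' dimensions")
  coordsList <- lapply(embeddings, function(e)
    embeddingCoords(e)[, seq_len(alignDims), drop = FALSE])
  if (identical(reference, "generalized")) {
    aligned <- coordsList
    ref <- aligned[[1L]]
    for (pass in 1:5) {
      aligned <- lapply(coordsList, function(x)
        applyProcrustes(procrustesFit(x, ref), x))
      ref <- Reduce(`+`, aligned) / length(aligned)
    }
  } else {
    ref <- coordsList[[as.integer(reference)]]
    aligned <- lapply(coordsList, function(x)
      applyProcrustes(procrustesFit(x, ref), x))
  }
  coords <- do.call(rbind, aligned)
  wd <- do.call(rbind, lapply(seq_along(embeddings), function(s) {
    w <- windowData(embeddings[[s]])
    if (is.null(w$subject)) w$subject <- sprintf("scan%02d", s)
    w$scan <- s
    w
  }))
  colnames(coords) <- sprintf("dim_%d", seq_len(ncol(coords)))
  new("GroupEmbedding", coords = coords,
      method = embeddingMethod(embeddings[[1L]]),
      hyperparams = hyperParams(embeddings[[1L]]),
      windowData = wd,
      diagnostics = list(alignDims = alignDims),
      strategy = "embed_procrustes", alignDims = alignDims)
}

# macro and per-class F1 from predicted/true label vectors
f1Scores <- function(truth, pred, levels) {
  perClass <- vapply(levels, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  list(perClass = perClass, macro = mean(perClass))
}

#' Task classification from a group embedding
#'
#' Multiclass logistic regression with an L1 penalty (glmnet, fixed
#' penalty `lambda = strength / n_train`) predicting the task label of
#' task-homogeneous windows from the first `mUsed` embedding dimensions.
#' `split_half` trains on the first half of every scan's windows and tests
#' on the second, then swaps and averages; `leave_one_subject_out` makes
#' one fold per subject.
#'
#' @param group a [GroupEmbedding-class].
#' @param mUsed number of leading dimensions used as features.
#' @param scheme "split_half" or "leave_one_subject_out".
#' @param strength L1 regularization strength (default 1).
#' @return list of class `"ClassificationReport"`: `f1PerClass`,
#'   `f1Average` (macro), `mUsed`, `folds`, `scheme`, and per-dimension
#'   mean absolute coefficients in `coefMagnitude`.
#' @export
classifyWindows <- function(group, mUsed,
    scheme = c("split_half", "leave_one_subject_out"), strength = 1) {
  scheme <- match.arg(scheme)
  stopifnot(is(group, "GroupEmbedding"))
  wd <- windowData(group)
  coords <- embeddingCoords(group)
  if (mUsed > ncol(coords)) stop("'mUsed' exceeds embedding dimensions")
  keep <- !is.na(wd$label) & wd$label != "mixed"
  X <- coords[keep, seq_len(mUsed), drop = FALSE]
  y <- factor(wd$label[keep])
  scan <- wd$scan[keep]
  subject <- wd$subject[keep]
  lv <- levels(y)

  folds <- if (scheme == "split_half") {
    firstHalf <- unlist(lapply(unique(scan), function(s) {
      i <- which(scan == s)
      seq_along(i) <= length(i) / 2
    }))
    list(which(firstHalf), which(!firstHalf))
  } else {
    lapply(unique(subject), function(s) which(subject != s))
  }

  fitFold <- function(trainIdx) {
    testIdx <- setdiff(seq_along(y), trainIdx)
    if (length(unique(y[trainIdx])) < length(lv))
      stop("a class is absent from a training fold")
    fit <- glmnet::glmnet(X[trainIdx, , drop = FALSE], y[trainIdx],
                          family = "multinomial", alpha = 1,
                          lambda = strength / length(trainIdx))
    pred <- drop(predict(fit, X[testIdx, , drop = FALSE], type = "class"))
    co <- stats::coef(fit)
    mag <- rowMeans(vapply(co, function(b) abs(as.numeric(b)[-1L]),
                           numeric(mUsed)))
    list(f1 = f1Scores(y[testIdx], pred, lv), coefMag = mag)
  }
  res <- lapply(folds, fitFold)
  perClass <- rowMeans(vapply(res, function(r) r$f1$perClass, numeric(length(lv))))
  coefMag <- rowMeans(vapply(res, function(r) r$coefMag, numeric(mUsed)))
  names(coefMag) <- sprintf("dim_%d", seq_len(mUsed))
  structure(list(scheme = scheme, f1PerClass = perClass,
                 f1Average = mean(perClass), mUsed = as.integer(mUsed),
                 folds = length(folds), coefMagnitude = coefMag),
            class = "ClassificationReport")
}

#' @export
print.ClassificationReport <- function(x, ...) {
  cat(sprintf("Classification (%s, m = %d, %d folds): macro F1 = %.3f\n",
              x$scheme, x$mUsed, x$folds, x$f1Average))
  invisible(x)
}

#' Stability of stochastic embeddings
#'
#' Repeats a scan-level embedding `nReps` times with distinct seeds and
#' reports the distribution of silhouette indices. For T-SNE the random
#' (seeded) initialization is used so that seed-to-seed variability is
#' observable; LE is deterministic and yields a zero-width distribution.
#' Failed repetitions are recorded, not fatal.
#'
#' @param tvfc a [TvfcMatrix-class].
#' @param params embedding hyper-parameters; the per-repetition seed
#'   overrides `params$seed`.
#' @param metric dissimilarity metric.
#' @param nReps number of seeded repetitions (>= 2).
#' @param seed base seed; repetition r uses `seed + r`.
#' @param labelType label for the silhouette (default "task").
#' @return list of class `"StabilityReport"`: `values`, `median`, `iqr`,
#'   `nOutliers` (1.5 IQR rule), `errors`.
#' @export
stabilityStudy <- function(tvfc, params, metric = "euclidean", nReps = 20L,
                           seed = 1L, labelType = "task") {
  stopifnot(is(tvfc, "TvfcMatrix"), nReps >= 2L)
  ds <- tvfcDissimilarity(tvfc, metric)
  wd <- data.frame(window_start = windowStarts(tvfc),
                   label = windowLabels(tvfc),
                   subject = rep(subjectId(tvfc), ncol(tvfc)))
  values <- rep(NA_real_, nReps)
  errors <- character(0)
  for (r in seq_len(nReps)) {
    p <- params
    if (inherits(p, "TsneParams")) p$init <- "random"
    if (!is.null(p$seed)) p$seed <- as.integer(seed + r)
    values[r] <- tryCatch(
      silhouetteIndex(embedDs(ds, p, windowData = wd), labelType)$value,
      error = function(e) { errors <<- c(errors, conditionMessage(e)); NA_real_ })
  }
  ok <- values[!is.na(values)]
  q <- quantile(ok, c(0.25, 0.75))
  iqr <- unname(q[2L] - q[1L])
  out <- sum(ok < q[1L] - 1.5 * iqr | ok > q[2L] + 1.5 * iqr)
  structure(list(values = values, median = median(ok), iqr = iqr,
                 nOutliers = out, errors = errors),
            class = "StabilityReport")
}

#' @export
print.StabilityReport <- function(x, ...) {
  cat(sprintf("Stability over %d reps: median SI = %.3f, IQR = %.4f, %d outlier(s)\n",
              length(x$values), x$median, x$iqr, x$nOutliers))
  invisible(x)
}
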