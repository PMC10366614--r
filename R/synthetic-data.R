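#' Configuration for the synthetic multi-task dataset
#'
#' Defines the statistical structure the generator emulates: a continuous
#' multi-task scan in which each task occupies `blocksPerTask` temporally
#' separated blocks of `blockLength` seconds, each preceded by an
#' `instructionLength`-second instruction period; ROI signals within a task
#' block are drawn from a task-specific covariance (latent-factor mixing),
#' AR(1)-smoothed, and carry per-subject "fingerprints" (per-ROI signal
#' gains plus a subject-specific shared component) that propagate to
#' per-connection mean/std differences in the tvFC matrix.
#'
#' `nLatentFactors` may be a single count or a named per-task vector; the
#' default gives rest more latent factors (8) than the three externally
#' driven tasks (3 each), so that rest explores a richer set of FC
#' configurations and has a higher intrinsic dimension.
#'
#' @param nSubjects number of subjects (default 5).
#' @param nRois number of regions (default 30; 157 supported).
#' @param tr repetition time, seconds (default 1.5).
#' @param taskNames task labels (default rest, memory, math, attention).
#' @param blockLength task block length, seconds (default 180).
#' @param instructionLength instruction period, seconds (default 12).
#' @param blocksPerTask temporally separated blocks per task (default 2).
#' @param nLatentFactors latent factors per task (scalar or named vector).
#' @param noiseSd sd of i.i.d. observation noise, signal units (default 0.5).
#' @param autocorrStrength AR(1) coefficient in \[0, 1) (default 0.3).
#' @param factorModulation depth of the slow log-normal amplitude envelope
#'   on each latent factor (default 0.6; 0 disables). The envelope makes
#'   the windowed covariance wander over an `nLatentFactors`-parameter
#'   family of states, so a condition with more factors genuinely explores
#'   more FC configurations (higher intrinsic dimension); envelopes are
#'   normalized so the expected covariance stays the task covariance.
#' @param modulationAr AR(1) coefficient of the envelope process
#'   (default 0.95, i.e. slow relative to the window length).
#' @param subjectTopographySd per-subject perturbation of the task loading
#'   matrices (default 0.25): individual differences in FC topography, so
#'   scan-level embeddings share a common geometry without being
#'   identical across subjects.
#' @param subjectOffsetSd scale of the subject-specific shared-component
#'   loadings (additive connectivity fingerprint; default 0.7).
#' @param subjectGainSd sd of per-ROI signal gains around 1 (multiplicative
#'   fingerprint; default 0.25).
#' @param maxCovSimilarity ceiling on the pairwise correlation between
#'   task covariance matrices (default 0.9).
#' @param seed master seed for the dataset.
#' @param fingerprintSeed separate seed for the subject fingerprints
#'   (default `seed + 1000`), so task structure and fingerprints can be
#'   varied independently.
#' @return A validated list of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(nSubjects = 5L, nRois = 30L, tr = 1.5,
    taskNames = c("rest", "memory", "math", "attention"),
    blockLength = 180, instructionLength = 12, blocksPerTask = 2L,
    nLatentFactors = c(rest = 8L, memory = 3L, math = 3L, attention = 3L),
    noiseSd = 0.5, autocorrStrength = 0.3,
    factorModulation = 0.6, modulationAr = 0.95,
    subjectTopographySd = 0.25,
    subjectOffsetSd = 0.7, subjectGainSd = 0.25,
    maxCovSimilarity = 0.9, seed = 1L, fingerprintSeed = seed + 1000L) {
  if (length(nLatentFactors) == 1L && is.null(names(nLatentFactors)))
    nLatentFactors <- setNames(rep(as.integer(nLatentFactors),
                                   length(taskNames)), taskNames)
  cfg <- list(nSubjects = as.integer(nSubjects), nRois = as.integer(nRois),
              tr = tr, taskNames = taskNames, blockLength = blockLength,
              instructionLength = instructionLength,
              blocksPerTask = as.integer(blocksPerTask),
              nLatentFactors = nLatentFactors, noiseSd = noiseSd,
              autocorrStrength = autocorrStrength,
              factorModulation = factorModulation,
              modulationAr = modulationAr,
              subjectTopographySd = subjectTopographySd,
              subjectOffsetSd = subjectOffsetSd,
              subjectGainSd = subjectGainSd,
              maxCovSimilarity = maxCovSimilarity,
              seed = as.integer(seed),
              fingerprintSeed = as.integer(fingerprintSeed))
  validateSyntheticConfig(cfg)
  class(cfg) <- "SyntheticConfig"
  cfg
}

validateSyntheticConfig <- function(cfg) {
  stopifnot(cfg$nSubjects >= 1L, cfg$nRois >= 2L, cfg$tr > 0,
            length(cfg$taskNames) >= 1L, cfg$blockLength > 0,
            cfg$instructionLength >= 0, cfg$blocksPerTask >= 1L,
            cfg$noiseSd >= 0, cfg$autocorrStrength >= 0,
            cfg$autocorrStrength < 1, cfg$subjectOffsetSd >= 0,
            cfg$subjectGainSd >= 0, cfg$factorModulation >= 0,
            cfg$modulationAr >= 0, cfg$modulationAr < 1,
            cfg$subjectTopographySd >= 0)
  if (!all(cfg$taskNames %in% names(cfg$nLatentFactors)))
    stop("'nLatentFactors' must name every task")
  if (any(cfg$nLatentFactors[cfg$taskNames] < 1L))
    stop("every task needs at least one latent factor")
  blk <- cfg$blockLength / cfg$tr
  ins <- cfg$instructionLength / cfg$tr
  if (abs(blk - round(blk)) > 1e-9 || abs(ins - round(ins)) > 1e-9)
    stop("block and instruction lengths must be whole numbers of acquisitions")
  invisible(TRUE)
}

# interleaved block order with no task repeated back-to-back; deterministic
# given the RNG state. Sequential random construction with feasibility check
# (place the most-frequent remaining task when it would otherwise be forced).
scheduleOrder <- function(taskNames, blocksPerTask) {
  nTasks <- length(taskNames)
  total <- nTasks * blocksPerTask
  if (nTasks == 1L && blocksPerTask > 1L)
    stop("infeasible schedule: a single task cannot avoid immediate repetition")
  remaining <- setNames(rep(blocksPerTask, nTasks), taskNames)
  out <- character(total)
  prev <- ""
  for (b in seq_len(total)) {
    avail <- names(remaining)[remaining > 0L & names(remaining) != prev]
    if (!length(avail)) stop("infeasible schedule: cannot avoid immediate task repetition")
    slotsLeft <- total - b + 1L
    mx <- max(remaining[avail])
    # a task holding more than half the remaining slots must be placed now
    forced <- avail[remaining[avail] * 2L > slotsLeft]
    pick <- if (length(forced)) forced[1L]
            else avail[sample.int(length(avail), 1L)]
    out[b] <- pick
    remaining[pick] <- remaining[pick] - 1L
    prev <- pick
  }
  out
}

#' Generate the task schedule for one scan
#'
#' Interleaves `blocksPerTask` blocks of every task (no task repeated
#' back-to-back), each preceded by an instruction period. Onsets/durations
#' are in acquisitions; total scan length is derived from the schedule.
#'
#' @param config a [syntheticConfig()] object.
#' @return A [TaskSchedule-class].
#' @export
generateSchedule <- function(config) {
  validateSyntheticConfig(config)
  set.seed(config$seed)
  ord <- scheduleOrder(config$taskNames, config$blocksPerTask)
  blkAcq <- as.integer(round(config$blockLength / config$tr))
  insAcq <- as.integer(round(config$instructionLength / config$tr))
  labels <- as.vector(rbind(rep("instruction", length(ord)), ord))
  durs <- as.vector(rbind(rep(insAcq, length(ord)), rep(blkAcq, length(ord))))
  keep <- durs > 0L
  labels <- labels[keep]; durs <- durs[keep]
  onsets <- cumsum(c(0L, durs[-length(durs)]))
  TaskSchedule(data.frame(onset_acq = onsets, duration_acq = durs,
                          label = labels))
}

# AR(1) recursive smoothing per row, variance-preserving
arSmooth <- function(X, phi) {
  if (phi == 0) return(X)
  sm <- t(apply(X, 1L, function(x)
    as.numeric(stats::filter(x, phi, method = "recursive"))))
  sm * sqrt(1 - phi^2)
}

#' Generate the synthetic multi-subject multi-task dataset
#'
#' One scan per subject. Within each task block, ROI signals are latent
#' factors mixed through a task-specific loading matrix (drawn once per
#' dataset seed, shared across subjects), giving recurrent task-specific
#' covariance states; instruction periods use their own shared loading
#' matrix. The mixed signal receives the subject's per-ROI gain, a
#' subject-specific shared component, i.i.d. noise, and an AR(1) recursive
#' filter. Fixed seeds give bit-identical output.
#'
#' @param config a [syntheticConfig()] object.
#' @return A list with one element per subject, each a list with components
#'   `ts` ([RoiTimeseries-class]), `schedule` ([TaskSchedule-class], shared
#'   across subjects) and `groundTruth` (task covariances, per-ROI subject
#'   gains and subject-component loadings, schedule, seeds).
#' @examples
#' ds <- generateDataset(syntheticConfig(nSubjects = 1, nRois = 10, seed = 7))
#' ds[[1]]$ts
#' @export
generateDataset <- function(config) {
  validateSyntheticConfig(config)
  schedule <- generateSchedule(config)   # seeds RNG with config$seed
  ev <- scheduleEvents(schedule)
  nAcq <- nAcquisitions(schedule)
  p <- config$nRois

  # task + instruction loading matrices, redrawn until covariance states are
  # sufficiently distinct
  drawLoadings <- function(nf) matrix(rnorm(p * nf), p, nf) / sqrt(nf)
  for (try in 1:50) {
    L <- lapply(config$taskNames,
                function(tk) drawLoadings(config$nLatentFactors[[tk]]))
    names(L) <- config$taskNames
    covs <- lapply(L, tcrossprod)
    if (length(covs) < 2L) break
    ut <- upper.tri(covs[[1L]])
    cc <- combn(length(covs), 2L, function(ij)
      cor(covs[[ij[1L]]][ut], covs[[ij[2L]]][ut]))
    if (max(abs(cc)) < config$maxCovSimilarity) break
    if (try == 50L) stop("could not draw sufficiently distinct task covariances")
  }
  Lins <- drawLoadings(max(2L, min(config$nLatentFactors)))

  # slow positive amplitude envelope, E[env^2] = 1 so the expected
  # covariance stays the task covariance
  envelope <- function(nf, len) {
    tau <- config$factorModulation
    if (tau == 0) return(matrix(1, nf, len))
    g <- t(vapply(seq_len(nf), function(f)
      as.numeric(stats::filter(rnorm(len), config$modulationAr,
                               method = "recursive")) *
        sqrt(1 - config$modulationAr^2), numeric(len)))
    exp(tau * g - tau^2)
  }

  lapply(seq_len(config$nSubjects), function(s) {
    set.seed(config$fingerprintSeed + s)
    gains <- 1 + rnorm(p, sd = config$subjectGainSd)
    gains <- pmax(gains, 0.1)
    offsets <- rnorm(p, sd = config$subjectOffsetSd)
    # individual FC topography: per-subject perturbation of the loadings
    perturb <- function(Lt) Lt + config$subjectTopographySd *
      matrix(rnorm(length(Lt)), nrow(Lt)) / sqrt(ncol(Lt))
    Ls <- lapply(L, perturb)
    LinsS <- perturb(Lins)

    set.seed(config$seed + 104729L * s)
    X <- matrix(0, p, nAcq)
    for (e in seq_len(nrow(ev))) {
      idx <- (ev$onset_acq[e] + 1L):(ev$onset_acq[e] + ev$duration_acq[e])
      Le <- if (ev$label[e] == "instruction") LinsS else Ls[[ev$label[e]]]
      F <- envelope(ncol(Le), length(idx)) *
        matrix(rnorm(ncol(Le) * length(idx)), ncol(Le), length(idx))
      X[, idx] <- Le %*% F
    }
    subjFactor <- rnorm(nAcq)
    X <- gains * X + outer(offsets, subjFactor) +
      matrix(rnorm(p * nAcq, sd = config$noiseSd), p, nAcq)
    X <- arSmooth(X, config$autocorrStrength)
    rownames(X) <- sprintf("ROI%03d", seq_len(p))
    list(ts = RoiTimeseries(X, tr = config$tr,
                            subjectId = sprintf("sub%02d", s)),
         schedule = schedule,
         groundTruth = list(taskCovariances = covs,
                            subjectGains = gains,
                            subjectOffsets = offsets,
                            schedule = schedule,
                            seed = config$seed,
                            fingerprintSeed = config$fingerprintSeed))
  })
}

#' Sample points from a manifold of known intrinsic dimension
#'
#' Validation fixtures for the intrinsic-dimension estimators: latent
#' points of the requested dimension are embedded in ambient space by a
#' random orthonormal linear map.
#'
#' @param intrinsicDim latent dimension (<= `ambientDim`).
#' @param ambientDim embedding dimension.
#' @param nPoints number of points (>= 10).
#' @param kind latent distribution: `uniform-cube` (Uniform\[0,1\]^d),
#'   `gaussian` (standard normal), or `linear-subspace` (standard normal;
#'   points lie exactly on a d-dimensional linear subspace).
#' @param seed RNG seed.
#' @param noiseSd optional isotropic ambient noise (default 0, exact
#'   manifold).
#' @return numeric matrix, `nPoints` x `ambientDim`.
#' @export
generateManifoldSample <- function(intrinsicDim, ambientDim, nPoints,
    kind = c("uniform-cube", "gaussian", "linear-subspace"),
    seed = 1L, noiseSd = 0) {
  kind <- match.arg(kind)
  if (intrinsicDim > ambientDim)
    stop("'intrinsicDim' (", intrinsicDim, ") exceeds 'ambientDim' (",
         ambientDim, ")")
  if (nPoints < 10L) stop("need at least 10 points")
  set.seed(seed)
  Z <- switch(kind,
    `uniform-cube` = matrix(runif(nPoints * intrinsicDim), nPoints),
    gaussian = ,
    `linear-subspace` = matrix(rnorm(nPoints * intrinsicDim), nPoints))
  Q <- qr.Q(qr(matrix(rnorm(ambientDim * intrinsicDim), ambientDim)))
  X <- Z %*% t(Q[, seq_len(intrinsicDim), drop = FALSE])
  if (noiseSd > 0) X <- X + matrix(rnorm(length(X), sd = noiseSd), nrow(X))
  X
}
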