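test_that("default schedule has 8 blocks of 120 acquisitions, no task repeated", {
  cfg <- syntheticConfig(nSubjects = 1L, nRois = 12L, seed = 9L)
  sched <- generateSchedule(cfg)
  ev <- scheduleEvents(sched)
  blocks <- ev[ev$label != "instruction", ]
  expect_identical(nrow(blocks), 8L)
  expect_true(all(blocks$duration_acq == 120L))
  expect_true(all(ev$duration_acq[ev$label == "instruction"] == 8L))
  expect_true(all(table(blocks$label) == 2L))
  expect_false(any(blocks$label[-1L] == blocks$label[-8L]))
  # labels partition the scan with no gaps; acquisitions = total seconds / tr
  expect_identical(nAcquisitions(sched),
                   as.integer(8 * (180 + 12) / 1.5))
  expect_identical(length(manifoldFC:::acquisitionLabels(sched)),
                   nAcquisitions(sched))
})

test_that("infeasible schedules error", {
  cfg <- syntheticConfig(nSubjects = 1L, nRois = 12L,
                         taskNames = "only",
                         nLatentFactors = c(only = 3L), seed = 1L)
  expect_error(generateSchedule(cfg), "infeasible")
})

test_that("fixed seed gives bit-identical datasets", {
  cfg <- syntheticConfig(nSubjects = 2L, nRois = 10L, seed = 77L)
  d1 <- generateDataset(cfg)
  d2 <- generateDataset(cfg)
  expect_identical(tsData(d1[[1L]]$ts), tsData(d2[[1L]]$ts))
  expect_identical(tsData(d1[[2L]]$ts), tsData(d2[[2L]]$ts))
})

test_that("noise-free single-task signals converge to the task covariance", {
  cfg <- syntheticConfig(nSubjects = 1L, nRois = 8L, taskNames = c("a", "b"),
                         nLatentFactors = c(a = 3L, b = 3L),
                         blockLength = 3000, instructionLength = 0,
                         blocksPerTask = 1L, noiseSd = 0,
                         autocorrStrength = 0, factorModulation = 0,
                         subjectOffsetSd = 0, subjectGainSd = 0,
                         subjectTopographySd = 0, seed = 5L)
  d <- generateDataset(cfg)[[1L]]
  ev <- scheduleEvents(d$schedule)
  idx <- (ev$onset_acq[1L] + 1L):(ev$onset_acq[1L] + ev$duration_acq[1L])
  emp <- cov(t(tsData(d$ts)[, idx]))
  truth <- d$groundTruth$taskCovariances[[ev$label[1L]]]
  # 2000 samples: elementwise convergence to the mixing covariance
  expect_lt(max(abs(emp - truth)), 0.15)
  expect_gt(cor(emp[upper.tri(emp)], truth[upper.tri(truth)]), 0.98)
})

test_that("task covariance states are distinct, symmetric and PSD", {
  d <- smallDataset()[[1L]]
  covs <- d$groundTruth$taskCovariances
  for (cv in covs) {
    expect_equal(cv, t(cv))
    expect_gte(min(eigen(cv, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
  ut <- upper.tri(covs[[1L]])
  cc <- combn(length(covs), 2, function(ij)
    cor(covs[[ij[1]]][ut], covs[[ij[2]]][ut]))
  expect_lt(max(abs(cc)), 0.9)
})

test_that("fingerprints shift tvFC row means; z-scoring removes the shift", {
  base <- list(nSubjects = 2L, nRois = 10L, seed = 31L)
  # same task structure, different fingerprints across subjects
  d <- generateDataset(syntheticConfig(nSubjects = 2L, nRois = 10L, seed = 31L))
  tvA <- computeTvfc(d[[1L]]$ts, WindowSpec(30, 10), d[[1L]]$schedule)
  tvB <- computeTvfc(d[[2L]]$ts, WindowSpec(30, 10), d[[2L]]$schedule)
  shift <- mean(abs(rowMeans(tvfcValues(tvA)) - rowMeans(tvfcValues(tvB))))
  expect_gt(shift, 0.05)
  zA <- rowMeans(tvfcValues(zscoreRows(tvA)))
  zB <- rowMeans(tvfcValues(zscoreRows(tvB)))
  expect_lt(max(abs(zA - zB)), 1e-10)

  # fingerprints disabled: row-mean distributions indistinguishable
  cfg0 <- syntheticConfig(nSubjects = 2L, nRois = 10L, seed = 31L,
                          subjectOffsetSd = 0, subjectGainSd = 0,
                          subjectTopographySd = 0)
  d0 <- generateDataset(cfg0)
  m1 <- rowMeans(tvfcValues(computeTvfc(d0[[1L]]$ts, WindowSpec(30, 10),
                                        d0[[1L]]$schedule)))
  m2 <- rowMeans(tvfcValues(computeTvfc(d0[[2L]]$ts, WindowSpec(30, 10),
                                        d0[[2L]]$schedule)))
  expect_gt(ks.test(m1, m2)$p.value, 0.01)
})

test_that("manifold samples have the requested structure", {
  # exact linear subspace: rank d
  X <- generateManifoldSample(3, 12, 100, "linear-subspace", seed = 2)
  expect_identical(dim(X), c(100L, 12L))
  sv <- svd(scale(X, scale = FALSE))$d
  expect_lt(sv[4] / sv[1], 1e-10)
  # identity-dimension gaussian: ambient equals intrinsic
  G <- generateManifoldSample(2, 2, 100, "gaussian", seed = 3)
  expect_identical(idValue(lpcaId(G, "global")), 2)
  # orthonormal embedding preserves latent distances (cube in [0,1]^d)
  U <- generateManifoldSample(2, 9, 50, "uniform-cube", seed = 4)
  expect_lte(max(dist(U)), sqrt(2) + 1e-9)
  expect_error(generateManifoldSample(5, 3, 100), "exceeds")
  expect_error(generateManifoldSample(2, 5, 5), "10")
})

test_that("timeseries and events tables round-trip through text files", {
  d <- smallDataset()[[1L]]
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "ts.tsv")
  writeRoiTimeseries(d$ts, p1)
  ts2 <- readRoiTimeseries(p1, tr = 1.5, subjectId = subjectId(d$ts))
  expect_equal(tsData(ts2), tsData(d$ts), tolerance = 1e-6)
  p2 <- file.path(dir, "events.tsv")
  writeEvents(d$schedule, p2, tr = 1.5)
  s2 <- readEvents(p2, tr = 1.5)
  expect_identical(scheduleEvents(s2), scheduleEvents(d$schedule))
  p3 <- file.path(dir, "truth.json")
  writeGroundTruth(d$groundTruth, p3)
  expect_true(jsonlite::validate(paste(readLines(p3), collapse = "")))
})
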