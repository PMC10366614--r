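test_that("connection and window counts follow the dimensional identities", {
  # derived by enumerating unordered pairs / start indices
  expect_identical(countConnections(2L), 1L)
  expect_identical(countConnections(10L), 45L)
  nPairs <- function(n) nrow(t(combn(n, 2)))
  for (n in c(3L, 7L, 23L)) expect_identical(countConnections(n), nPairs(n))
  expect_error(countConnections(1), "2")

  expect_identical(countWindows(30L, WindowSpec(30, 1)), 1L)
  expect_identical(countWindows(30L, WindowSpec(30, 30)), 1L)
  # enumeration oracle: starts 0, step, ... while start + w <= n
  nWins <- function(nAcq, w, st) length(seq(0L, nAcq - w, by = st))
  expect_identical(countWindows(100L, WindowSpec(20, 5)), 17L)
  expect_identical(nWins(100, 20, 5), 17L)
  for (p in list(c(57, 10, 3), c(200, 30, 7), c(31, 30, 1)))
    expect_identical(countWindows(p[1], WindowSpec(p[2], p[3])),
                     as.integer(nWins(p[1], p[2], p[3])))
  expect_error(countWindows(20L, WindowSpec(30, 1)), "exceeds")
})

test_that("compute_tvfc matches per-window Pearson correlations", {
  set.seed(1)
  X <- matrix(rnorm(3 * 40), 3, 40, dimnames = list(paste0("r", 1:3), NULL))
  ts <- RoiTimeseries(X, tr = 1.5)
  tv <- computeTvfc(ts, WindowSpec(30, 5))
  expect_identical(dim(tv), c(3L, 3L))
  expect_identical(windowStarts(tv), c(0L, 5L, 10L))
  # oracle: direct per-window correlation, upper-triangle order
  for (w in 1:3) {
    s <- windowStarts(tv)[w]
    r <- cor(t(X[, (s + 1):(s + 30)]))
    expect_equal(tvfcValues(tv)[, w],
                 atanh(r[upper.tri(r)]), tolerance = 1e-12)
  }
  ci <- connectionIndex(tv)
  expect_identical(ci$roi_i, c(1L, 1L, 2L))
  expect_identical(ci$roi_j, c(2L, 3L, 3L))
})

test_that("identical ROIs give the clipped Fisher-z ceiling", {
  x <- rnorm(50)
  ts <- RoiTimeseries(rbind(a = x, b = x, c = rnorm(50)), tr = 1)
  tv <- computeTvfc(ts, WindowSpec(20, 10))
  expect_equal(unname(tvfcValues(tv)[1, ]),
               rep(atanh(1 - 1e-7), ncol(tv)), tolerance = 1e-10)
})

test_that("zero-variance ROI in a window is a named error", {
  X <- rbind(a = rnorm(40), b = c(rep(1, 25), rnorm(15)))
  expect_error(computeTvfc(RoiTimeseries(X, 1), WindowSpec(20, 5)),
               "zero-variance ROI 'b'")
})

test_that("independent white-noise ROIs give correlations near zero", {
  set.seed(7)
  ts <- RoiTimeseries(matrix(rnorm(4 * 600), 4, 600), tr = 1)
  tv <- computeTvfc(ts, WindowSpec(200, 100))
  # r under independence: sd ~ 1/sqrt(200) ~ 0.07
  expect_lt(max(abs(tvfcValues(tv))), 0.35)
  expect_lt(abs(mean(tvfcValues(tv))), 0.1)
})

test_that("Fisher z is monotone: per-column rank order preserved", {
  tv <- smallTvfc()
  Z <- tvfcValues(tv)
  set.seed(2)
  for (c in sample(ncol(Z), 5)) {
    r <- tanh(Z[, c])
    expect_identical(order(r), order(Z[, c]))
  }
})

test_that("row z-scoring gives exact population moments and is idempotent", {
  expect_equal(manifoldFC:::fisherZ(0), 0)
  tv <- smallTvfc()
  tz <- zscoreRows(tv)
  Z <- tvfcValues(tz)
  expect_true(isNormalized(tz))
  expect_lt(max(abs(rowMeans(Z))), 1e-12)
  expect_lt(max(abs(sqrt(rowMeans(Z^2)) - 1)), 1e-9)
  # hand case with the population-sd convention
  expect_equal((c(1, 2, 3) - 2) / sqrt(2 / 3),
               c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  # idempotence
  expect_equal(tvfcValues(zscoreRows(tz)), Z, tolerance = 1e-12)
})

test_that("window labels are task-homogeneous or mixed", {
  sched <- TaskSchedule(data.frame(
    onset_acq = c(0L, 8L, 128L, 136L),
    duration_acq = c(8L, 120L, 8L, 120L),
    label = c("instruction", "math", "instruction", "rest")))
  labs <- labelWindows(sched, 256L, WindowSpec(30, 1))
  # 120-acquisition block, w = 30 -> 91 homogeneous windows per block
  expect_identical(sum(labs == "math"), 91L)
  expect_identical(sum(labs == "rest"), 91L)
  # windows overlapping instruction periods are mixed
  expect_identical(labs[1], "mixed")            # starts inside instruction
  expect_identical(labs[9], "math")             # first fully-math window
  expect_identical(labs[100], "mixed")          # spans math + instruction
  expect_error(labelWindows(sched, 500L, WindowSpec(30, 1)), "covers")
})

test_that("default schedule yields 2 x 91 homogeneous windows per task", {
  d <- smallDataset()[[1L]]
  labs <- labelWindows(d$schedule, nAcquisitions(d$schedule), WindowSpec(30, 1))
  counts <- table(labs[labs != "mixed"])
  expect_setequal(names(counts), c("rest", "memory", "math", "attention"))
  expect_true(all(counts == 182L))
})

test_that("dissimilarity metrics match their definitions", {
  expect_equal(pairwiseDissimilarity(rbind(c(0, 0), c(3, 4)))[1, 2], 5)
  x <- rnorm(10)
  dsC <- pairwiseDissimilarity(rbind(x, -x, x + 5), "correlation")
  expect_equal(dsC[1, 2], 2)          # perfect anticorrelation
  expect_equal(dsC[1, 3], 0)          # shift-invariant
  same <- rbind(x, x)
  for (m in c("euclidean", "correlation", "cosine"))
    expect_equal(pairwiseDissimilarity(same, m)[1, 2], 0, tolerance = 1e-12)
  dsK <- pairwiseDissimilarity(rbind(c(1, 0), c(0, 1), c(1, 1)), "cosine")
  expect_equal(dsK[1, 2], 1)
  expect_equal(dsK[1, 3], 1 - 1 / sqrt(2), tolerance = 1e-12)
  expect_error(pairwiseDissimilarity(rbind(c(1, 1), c(2, 2)), "correlation"),
               "zero-variance")
  expect_error(pairwiseDissimilarity(rbind(c(0, 0), c(2, 2)), "cosine"),
               "zero-norm")
})

test_that("knn sets agree with a brute-force oracle and break ties by index", {
  # 3 collinear points at 0, 1, 3
  ds <- as.matrix(dist(c(0, 1, 3)))
  expect_identical(as.vector(knnSets(ds, 1)), c(2L, 1L, 2L))
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(20:120, 1)
    ds <- pairwiseDissimilarity(matrix(rnorm(n * 4), n))
    k <- sample(n - 1L, 1)
    expect_identical(knnSets(ds, k), knnOracle(ds, k))
  }
  # k = n-1 lists every other sample
  ds <- pairwiseDissimilarity(matrix(rnorm(30), 10))
  expect_identical(sort(knnSets(ds, 9)[1, ]), 2:10)
  # ties: duplicated points, lower index wins
  dsT <- as.matrix(dist(c(0, 5, 5, 5)))
  expect_identical(knnSets(dsT, 2)[1, ], c(2L, 3L))
  expect_error(knnSets(ds, 10), "k")
})

test_that("tvFC round-trips through the text container", {
  tv <- smallTvfc()
  pre <- file.path(withr::local_tempdir(), "tv")
  writeTvfc(tv, pre)
  tv2 <- readTvfc(pre)
  expect_equal(tvfcValues(tv2), unname(tvfcValues(tv)), tolerance = 1e-6)
  expect_identical(windowLabels(tv2), windowLabels(tv))
  expect_identical(windowStarts(tv2), windowStarts(tv))
})
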