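test_that("silhouette matches hand evaluation and behaves at chance", {
  # 1-D clusters {0, 0.1 | A} and {10, 10.1 | B}
  emb <- new("Embedding", coords = matrix(c(0, 0.1, 10, 10.1), 4),
             method = "LE", hyperparams = list(),
             windowData = data.frame(label = c("A", "A", "B", "B")),
             diagnostics = list())
  si <- silhouetteIndex(emb, "task")
  expect_equal(si$value, 0.99, tolerance = 1e-3)
  expect_identical(si$nUsed, 4L)
  # random labels in one tight cluster: |SI| < 0.1
  set.seed(30)
  rnd <- new("Embedding", coords = matrix(rnorm(400), 200),
             method = "LE", hyperparams = list(),
             windowData = data.frame(label = sample(c("A", "B"), 200, TRUE)),
             diagnostics = list())
  expect_lt(abs(silhouetteIndex(rnd, "task")$value), 0.1)
  # bounded in [-1, 1]; mixed windows excluded; single label errors
  tv <- smallTvfc()
  amb <- silhouetteIndex(tv, "task")
  expect_gte(amb$value, -1); expect_lte(amb$value, 1)
  expect_identical(amb$excluded, sum(windowLabels(tv) == "mixed"))
  one <- new("Embedding", coords = matrix(rnorm(10), 5), method = "LE",
             hyperparams = list(),
             windowData = data.frame(label = rep("A", 5)),
             diagnostics = list())
  expect_error(silhouetteIndex(one, "task"), "2 distinct")
})

test_that("silhouette agrees with a direct formula oracle", {
  set.seed(31)
  Y <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 3), 20))
  lab <- rep(c("p", "q"), each = 20)
  emb <- new("Embedding", coords = Y, method = "LE", hyperparams = list(),
             windowData = data.frame(label = lab), diagnostics = list())
  D <- as.matrix(dist(Y))
  sOracle <- mean(vapply(1:40, function(i) {
    own <- lab == lab[i]
    a <- mean(D[i, own & seq_len(40) != i])
    b <- mean(D[i, !own])
    (b - a) / max(a, b)
  }, numeric(1)))
  expect_equal(silhouetteIndex(emb, "task")$value, sOracle, tolerance = 1e-12)
})

test_that("silhouette is invariant under similarity transforms", {
  tv <- smallTvfc()
  emb <- embedTvfc(tv, leParams(k = 40, m = 3), "correlation")
  base <- silhouetteIndex(emb, "task")$value
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- new("Embedding",
               coords = sweep(2.5 * embeddingCoords(emb) %*% R, 2, c(3, -1, 7), "+"),
               method = "LE", hyperparams = list(),
               windowData = windowData(emb), diagnostics = list())
  expect_equal(silhouetteIndex(moved, "task")$value, base, tolerance = 1e-9)
})

test_that("procrustes recovers similarity transforms exactly", {
  set.seed(32)
  X <- matrix(rnorm(60), 20)
  th <- 0.9
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Y <- sweep(1.7 * X %*% R, 2, c(2, -3, 0.5), "+")
  fit <- procrustesFit(X, Y)
  expect_lt(fit$disparity, 1e-10)
  expect_equal(fit$scale, 1.7, tolerance = 1e-9)
  expect_equal(fit$rotation, R, tolerance = 1e-9)
  expect_equal(applyProcrustes(fit, X), Y, tolerance = 1e-9)
  # identity case
  fid <- procrustesFit(X, X)
  expect_equal(fid$disparity, 0, tolerance = 1e-12)
  expect_equal(fid$scale, 1, tolerance = 1e-12)
  expect_error(procrustesFit(matrix(0, 10, 2), matrix(rnorm(20), 10)),
               "degenerate")
})

test_that("procrustes disparity matches the vegan oracle", {
  skip_if_not_installed("vegan")
  set.seed(33)
  X <- matrix(rnorm(50), 25); Y <- matrix(rnorm(50), 25)
  fit <- procrustesFit(X, Y)
  vg <- vegan::procrustes(Y, X, symmetric = FALSE, scale = TRUE)
  # same aligned configuration and residual sum of squares
  expect_equal(applyProcrustes(fit, X), unname(unclass(fitted(vg))), tolerance = 1e-8)
  expect_equal(sum((applyProcrustes(fit, X) - Y)^2), sum(residuals(vg)^2),
               tolerance = 1e-8)
})

test_that("concatenation identity: a single scan embeds unchanged", {
  tv <- smallTvfc()
  g <- concatEmbed(list(tv), leParams(k = 40, m = 3), "correlation")
  e <- embedTvfc(tv, leParams(k = 40, m = 3), "correlation")
  expect_equal(embeddingCoords(g), embeddingCoords(e), tolerance = 1e-12)
  expect_identical(g@strategy, "concat_embed")
})

test_that("procrustes group aligns a scan to itself unchanged", {
  tv <- smallTvfc()
  e <- embedTvfc(tv, leParams(k = 40, m = 5), "correlation")
  g <- embedProcrustes(list(e, e), alignDims = 5)
  expect_equal(embeddingCoords(g)[seq_len(ncol(tv)), ],
               embeddingCoords(e)[, 1:5], tolerance = 1e-10)
  # alignment is a similarity: within-scan distance ratios preserved
  g2 <- embedProcrustes(list(e, embedTvfc(smallTvfc2(),
                                          leParams(k = 40, m = 5),
                                          "correlation")), alignDims = 5)
  n <- ncol(tv)
  d0 <- as.vector(dist(embeddingCoords(embedTvfc(smallTvfc2(),
                                                 leParams(k = 40, m = 5),
                                                 "correlation"))[, 1:5]))
  d1 <- as.vector(dist(embeddingCoords(g2)[(n + 1):(2 * n), ]))
  s <- median(d1 / d0)
  expect_lt(max(abs(d1 - s * d0)), 1e-8 * max(d0))
  expect_error(embedProcrustes(list(e), alignDims = 9), "alignDims")
})

test_that("classification scores separable and shuffled fixtures correctly", {
  set.seed(34)
  n <- 80
  centers <- matrix(c(0, 0, 6, 0, 0, 6, 6, 6), 4, 2, byrow = TRUE)
  lab <- rep(c("w", "x", "y", "z"), each = n / 4)
  coords <- centers[rep(1:4, each = n / 4), ] + matrix(rnorm(2 * n, 0, 0.4), n)
  coords <- cbind(coords, matrix(rnorm(3 * n), n))   # noise dims
  wd <- data.frame(label = lab, subject = rep(sprintf("s%d", 1:4), n / 4),
                   scan = rep(1:4, n / 4))
  g <- new("GroupEmbedding", coords = coords, method = "LE",
           hyperparams = list(), windowData = wd, diagnostics = list(),
           strategy = "concat_embed", alignDims = 0L)
  rep1 <- classifyWindows(g, mUsed = 2, scheme = "split_half")
  expect_gt(rep1$f1Average, 0.95)
  expect_identical(rep1$folds, 2L)
  rep2 <- classifyWindows(g, mUsed = 5, scheme = "leave_one_subject_out")
  expect_gt(rep2$f1Average, 0.95)
  expect_identical(rep2$folds, 4L)
  # informative dimensions dominate the coefficient magnitudes
  expect_gt(mean(rep1$coefMagnitude[1:2]), mean(rep2$coefMagnitude[3:5]))
  # shuffled labels: macro F1 near chance for 4 balanced classes
  wdS <- wd; set.seed(35); wdS$label <- sample(wdS$label)
  gS <- new("GroupEmbedding", coords = coords, method = "LE",
            hyperparams = list(), windowData = wdS, diagnostics = list(),
            strategy = "concat_embed", alignDims = 0L)
  f1S <- classifyWindows(gS, mUsed = 5, scheme = "split_half")$f1Average
  expect_lt(abs(f1S - 0.25), 0.15)
  expect_error(classifyWindows(g, mUsed = 99), "exceeds")
})

test_that("stability study: deterministic LE has zero IQR, seeds reproduce", {
  tv <- smallTvfc()
  st <- stabilityStudy(tv, leParams(k = 40, m = 3), "correlation",
                       nReps = 3, seed = 1)
  expect_equal(st$iqr, 0, tolerance = 1e-15)
  expect_length(st$values, 3)
  st2 <- stabilityStudy(tv, umapParams(k = 30, m = 2, nEpochs = 150),
                        "euclidean", nReps = 3, seed = 9)
  st3 <- stabilityStudy(tv, umapParams(k = 30, m = 2, nEpochs = 150),
                        "euclidean", nReps = 3, seed = 9)
  expect_identical(st2$values, st3$values)
  expect_gt(st2$iqr, 0)
})
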