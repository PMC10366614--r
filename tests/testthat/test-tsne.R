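test_that("sigma calibration achieves the requested perplexity", {
  set.seed(10)
  ds <- pairwiseDissimilarity(matrix(rnorm(100 * 8), 100))
  sig <- calibrateSigmas(ds, perplexity = 30)
  # recompute the entropy from the returned sigmas (independent check)
  for (i in c(1, 17, 100)) {
    p <- exp(-ds[i, -i]^2 / (2 * sig[i]^2))
    p <- p / sum(p)
    expect_equal(2^(-sum(p * log2(p))), 30, tolerance = 1e-3)
  }
  expect_equal(unname(attr(sig, "achievedPerplexity")), rep(30, 100),
               tolerance = 1e-3)
})

test_that("calibration matches a brute-force 1-D root finder", {
  # one point with neighbors at distances 1 and 10, target PP = 1.5
  ds <- matrix(c(0, 1, 10, 1, 0, 9, 10, 9, 0), 3)
  sig <- calibrateSigmas(ds, perplexity = 1.5)
  hOf <- function(s) {
    p <- exp(-c(1, 10)^2 / (2 * s^2)); p <- p / sum(p)
    -sum(p[p > 0] * log2(p[p > 0]))
  }
  grid <- exp(seq(log(1e-3), log(1e3), length.out = 200000))
  oracle <- grid[which.min(abs(vapply(grid, hOf, 1) - log2(1.5)))]
  expect_equal(hOf(sig[1]), log2(1.5), tolerance = 1e-5)
  expect_equal(sig[1], oracle, tolerance = 1e-3)
})

test_that("equidistant neighborhoods return an admissible midpoint sigma", {
  # regular simplex: all pairwise distances equal, perplexity locked at n-1
  x <- diag(4) * sqrt(2) / 2
  ds <- pairwiseDissimilarity(x)
  sig <- calibrateSigmas(ds, perplexity = 2)
  expect_true(all(is.finite(sig) & sig > 0))
  expect_equal(unname(attr(sig, "achievedPerplexity")), rep(3, 4),
               tolerance = 1e-6)
})

test_that("joint P is a symmetric probability distribution", {
  set.seed(11)
  ds <- pairwiseDissimilarity(matrix(rnorm(60 * 4), 60))
  P <- jointP(ds, perplexity = 12)
  expect_equal(sum(P), 1, tolerance = 1e-12)
  expect_identical(P, t(P))
  expect_true(all(P >= 0))
  expect_true(all(diag(P) == 0))
  # 3-point hand evaluation of the conditional/joint construction
  ds3 <- matrix(c(0, 1, 2, 1, 0, 1.5, 2, 1.5, 0), 3)
  sig <- calibrateSigmas(ds3, perplexity = 1.8)
  Pc <- matrix(0, 3, 3)
  for (i in 1:3) {
    w <- exp(-ds3[i, -i]^2 / (2 * sig[i]^2))
    Pc[i, -i] <- w / sum(w)
  }
  expect_equal(jointP(ds3, 1.8), (Pc + t(Pc)) / 6, tolerance = 1e-9)
})

test_that("low-dimensional Q follows the Student-t kernel", {
  expect_equal(lowDimQ(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))[1, 2], 0.5)
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(unique(round(lowDimQ(tri)[upper.tri(diag(3))], 12)), 1 / 6)
  set.seed(12)
  Y <- matrix(rnorm(8), 4)
  Q <- lowDimQ(Y)
  W <- 1 / (1 + as.matrix(dist(Y))^2); diag(W) <- 0
  expect_equal(Q, W / sum(W), tolerance = 1e-12)
  expect_equal(sum(Q), 1, tolerance = 1e-12)
})

test_that("KL divergence is zero iff P equals Q", {
  set.seed(13)
  Y <- matrix(rnorm(20), 10)
  Q <- lowDimQ(Y)
  expect_equal(klDivergence(Q, Q), 0, tolerance = 1e-12)
  P <- jointP(pairwiseDissimilarity(matrix(rnorm(50), 10)), 3)
  expect_gt(klDivergence(P, Q), 0)
})

test_that("gradient descent reduces the cost and drops at de-exaggeration", {
  set.seed(14)
  x <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 6), 30))
  ds <- pairwiseDissimilarity(x)
  emb <- tsneEmbed(ds, tsneParams(perplexity = 15, m = 2, nIter = 400,
                                  learningRate = 10, seed = 1),
                   windowData = data.frame(label = rep(c("a", "b"), each = 30)))
  cost <- diagnostics(emb)$cost
  expect_true(all(is.finite(cost)))
  expect_lt(cost[400], cost[1])
  # the exaggerated cost is inflated; removing the factor drops it sharply
  expect_lt(cost[101], cost[100])
  expect_lt(cost[400], diagnostics(emb)$exaggerationEndCost)
  # two well-separated clusters embed separably
  expect_gt(silhouetteIndex(emb, "task")$value, 0.5)
})

test_that("t-SNE is deterministic given seed and init", {
  set.seed(15)
  ds <- pairwiseDissimilarity(matrix(rnorm(40 * 3), 40))
  p <- tsneParams(perplexity = 10, nIter = 120, seed = 7, init = "random")
  e1 <- tsneEmbed(ds, p); e2 <- tsneEmbed(ds, p)
  expect_identical(embeddingCoords(e1), embeddingCoords(e2))
  # PCA init is deterministic without a seed contribution
  pp <- tsneParams(perplexity = 10, nIter = 60, seed = 1)
  pp2 <- tsneParams(perplexity = 10, nIter = 60, seed = 99)
  expect_identical(embeddingCoords(tsneEmbed(ds, pp)),
                   embeddingCoords(tsneEmbed(ds, pp2)))
})
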