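# Shared fixtures, generated once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, expr, envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

# small multi-task dataset: 12 ROIs, 2 subjects, full default schedule
smallDataset <- function() {
  cached("smallDataset",
         generateDataset(syntheticConfig(nSubjects = 2L, nRois = 12L, seed = 42L)))
}

# tvFC of subject 1 at step 5 (199 windows) — cheap, labeled
smallTvfc <- function() {
  cached("smallTvfc", {
    d <- smallDataset()[[1L]]
    computeTvfc(d$ts, WindowSpec(30L, 5L), d$schedule)
  })
}

smallTvfc2 <- function() {
  cached("smallTvfc2", {
    d <- smallDataset()[[2L]]
    computeTvfc(d$ts, WindowSpec(30L, 5L), d$schedule)
  })
}

# hand-built neighbor graph from an explicit weight matrix
graphFromW <- function(W, k = 1L, metric = "euclidean") {
  new("NeighborGraph", weights = W, k = as.integer(k), metric = metric,
      nComponents = manifoldFC:::countComponents(W))
}

# two 5-cliques joined by a single edge
twoCliquesW <- function() {
  W <- matrix(0, 10, 10)
  W[1:5, 1:5] <- 1; W[6:10, 6:10] <- 1
  diag(W) <- 0
  W[5, 6] <- W[6, 5] <- 1
  W
}

# path graph on n nodes
pathW <- function(n) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) W[i, i + 1L] <- W[i + 1L, i] <- 1
  W
}

# brute-force k-NN oracle: full sort per row, ties by index
knnOracle <- function(ds, k) {
  n <- nrow(ds)
  t(vapply(seq_len(n), function(i) {
    ord <- order(ds[i, ], seq_len(n))
    ord <- ord[ord != i]
    ord[seq_len(k)]
  }, integer(k)))
}
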