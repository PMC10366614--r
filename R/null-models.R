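#' Connectivity-randomization null model
#'
#' Destroys the row-to-connection relationship of a tvFC matrix by
#' independently permuting the row order of every column. Each column's
#' value multiset (hence its sum) is preserved exactly; dimensions and
#' window metadata are unchanged.
#'
#' @param tvfc a [TvfcMatrix-class].
#' @param seed RNG seed (recorded in the output metadata).
#' @return A [TvfcMatrix-class] with per-column randomized rows.
#' @export
randomizeConnectivity <- function(tvfc, seed = 1L) {
  stopifnot(is(tvfc, "TvfcMatrix"))
  Z <- tvfcValues(tvfc)
  set.seed(seed)
  for (c in seq_len(ncol(Z))) Z[, c] <- Z[sample.int(nrow(Z)), c]
  out <- tvfc
  SummarizedExperiment::assay(out, "z") <- Z
  S4Vectors::metadata(out)$null_model <- list(model = "connectivity",
                                              seed = as.integer(seed))
  out
}

#' Phase-randomization null model
#'
#' Surrogate ROI timeseries that keep each ROI's Fourier amplitude
#' spectrum — hence its autocorrelation function — while destroying the
#' timing of signal fluctuations. Per ROI: discrete Fourier transform;
#' magnitudes retained; phases of the positive frequencies replaced by
#' i.i.d. Uniform(0, 2*pi) draws, phases drawn independently per ROI;
#' Hermitian symmetry enforced (DC and, for even length, Nyquist components
#' kept real) so the inverse transform is real-valued.
#'
#' @param ts a [RoiTimeseries-class].
#' @param seed RNG seed.
#' @return A [RoiTimeseries-class] of surrogate timeseries.
#' @export
phaseRandomize <- function(ts, seed = 1L) {
  stopifnot(is(ts, "RoiTimeseries"))
  X <- tsData(ts)
  n <- ncol(X)
  half <- (n - 1L) %/% 2L                 # positive non-Nyquist frequencies
  set.seed(seed)
  out <- X
  for (r in seq_len(nrow(X))) {
    sp <- fft(X[r, ])
    phi <- runif(half, 0, 2 * pi)
    idx <- seq_len(half) + 1L
    sp[idx] <- Mod(sp[idx]) * exp(1i * phi)
    sp[n + 2L - idx] <- Conj(sp[idx])     # Hermitian mirror
    if (n %% 2L == 0L) {                  # Nyquist stays real, keep magnitude
      ny <- n / 2L + 1L
      sp[ny] <- Mod(sp[ny]) * sign(Re(sp[ny]) + (Re(sp[ny]) == 0))
    }
    y <- fft(sp, inverse = TRUE) / n
    if (max(abs(Im(y))) > 1e-8)
      stop("phase randomization produced a non-negligible imaginary part")
    out[r, ] <- Re(y)
  }
  RoiTimeseries(out, tr = trSeconds(ts), subjectId = subjectId(ts))
}
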