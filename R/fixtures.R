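#' Controlled synthetic spike rasters
#'
#' Generates samples-by-neurons matrices with known synchrony structure so
#' the SVD synchrony metric can be exercised without the simulator:
#' \describe{
#'   \item{synchronized}{one master Poisson spike train copied into every
#'     column — fully synchronized activity, M = 1.}
#'   \item{jittered}{the master train with independent Gaussian time
#'     jitter per neuron; synchrony degrades as the jitter grows.}
#'   \item{independent_poisson}{independent homogeneous Poisson trains;
#'     with P much larger than N the index approaches 0.}
#' }
#' Deterministic under the seed.
#'
#' @param kind fixture kind (above).
#' @param n_neurons N >= 2.
#' @param n_samples P >= N (1-ms bins).
#' @param rate_hz spike rate of each (or the master) train.
#' @param jitter_sd_ms Gaussian jitter standard deviation (ms).
#' @param seed integer seed.
#' @return a [rasterMatrix()] with 1-ms bins.
#' @export
makeRasterFixture <- function(kind = c("synchronized", "jittered",
                                       "independent_poisson"),
                              n_neurons = 50, n_samples = 10000,
                              rate_hz = 10, jitter_sd_ms = 2, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(n_neurons >= 2, n_samples >= n_neurons, rate_hz > 0)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  p_bin <- rate_hz / 1000  # 1-ms bins
  m <- matrix(0L, n_samples, n_neurons)
  if (kind == "independent_poisson") {
    m[] <- as.integer(stats::runif(n_samples * n_neurons) < p_bin)
  } else {
    master <- which(stats::runif(n_samples) < p_bin)
    if (kind == "synchronized") {
      m[master, ] <- 1L
    } else {
      for (j in seq_len(n_neurons)) {
        t <- round(master + stats::rnorm(length(master), 0, jitter_sd_ms))
        t <- t[t >= 1 & t <= n_samples]
        m[t, j] <- 1L
      }
    }
  }
  rasterMatrix(m, sample_ms = 1)
}

#' Controlled test signals for the spectral stack
#'
#' Sum of sinusoidal tones plus optional white Gaussian noise;
#' deterministic under the seed. Used to validate PSD estimation, band
#' power and harmonic-comb detection against closed forms.
#'
#' @param freqs_hz tone frequencies (must be below Nyquist).
#' @param amps tone amplitudes (recycled).
#' @param fs sampling rate (Hz).
#' @param duration_s length (s).
#' @param noise_sd white-noise standard deviation.
#' @param seed integer seed.
#' @return numeric time series of length \code{fs * duration_s}.
#' @export
makeSignalFixture <- function(freqs_hz = 20, amps = 1, fs = 1000,
                              duration_s = 10, noise_sd = 0, seed = 1) {
  if (any(freqs_hz >= fs / 2)) stop("tone frequency above Nyquist")
  amps <- rep_len(amps, length(freqs_hz))
  t <- seq_len(round(fs * duration_s)) / fs
  x <- numeric(length(t))
  for (k in seq_along(freqs_hz))
    x <- x + amps[k] * sin(2 * pi * freqs_hz[k] * t)
  if (noise_sd > 0) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    x <- x + stats::rnorm(length(t), 0, noise_sd)
  }
  x
}
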