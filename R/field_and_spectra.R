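#' Estimate the cortical local field potential
#'
#' First-order point-source approximation: the LFP is the sum of all
#' excitatory postsynaptic currents generated in the deep cortical layer
#' (D) and all inhibitory postsynaptic currents generated by the cortical
#' interneurons (CI), scaled by \eqn{1 / (4 \pi \sigma r)} with gray
#' matter conductivity \eqn{\sigma \approx 0.27} S/m and electrode
#' distance \eqn{r = 100} \eqn{\mu}m.
#'
#' @param result a [simulateTcm()] result (or any list with a
#'   \code{psc_pop} matrix holding per-population summed PSC traces).
#' @param sigma conductivity (S/m), > 0.
#' @param r electrode distance (m), > 0.
#' @return numeric LFP time series (one value per simulation step).
#' @export
estimateLfp <- function(result, sigma = 0.27, r = 1e-4) {
  stopifnot(sigma > 0, r > 0)
  psc <- result$psc_pop
  if (is.null(psc) || !all(c("D", "CI") %in% colnames(psc)))
    stop("result lacks D and CI population PSC traces")
  (psc[, "D"] + psc[, "CI"]) / (4 * pi * sigma * r)
}

#' Welch power spectral density
#'
#' Averaged periodogram over Hann-tapered segments with overlap. The
#' one-sided density is normalized so that the integral over frequency
#' recovers the signal variance (window power is compensated).
#'
#' @param x numeric time series.
#' @param fs sampling rate (Hz).
#' @param window_s segment length (s); default 1 s.
#' @param overlap fractional overlap between segments; default 0.5.
#' @param detrend remove the segment mean before tapering (default TRUE).
#' @return object of class \code{psd_result} with \code{freq} (Hz),
#'   \code{power} (units^2/Hz) and the estimation metadata.
#' @export
computePsd <- function(x, fs, window_s = 1, overlap = 0.5, detrend = TRUE) {
  nw <- round(window_s * fs)
  if (nw < 8) stop("window too short")
  if (length(x) < nw) stop("window longer than the signal")
  step <- max(1, round(nw * (1 - overlap)))
  starts <- seq(1, length(x) - nw + 1, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / nw)  # periodic Hann
  wpow <- sum(win^2)
  nf <- nw %/% 2 + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nw - 1)]
    if (detrend) seg <- seg - mean(seg)
    X <- stats::fft(seg * win)[seq_len(nf)]
    acc <- acc + (Mod(X)^2) / (fs * wpow)
  }
  p <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nw is even)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nw %% 2 == 0) dbl[nf] <- 1
  structure(list(freq = (seq_len(nf) - 1) * fs / nw, power = p * dbl,
                 fs = fs, window_s = window_s, overlap = overlap,
                 n_segments = length(starts)),
            class = "psd_result")
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf("<psd_result> %d bins to %g Hz (%g-s windows, %d segments)\n",
              length(x$freq), max(x$freq), x$window_s, x$n_segments))
  invisible(x)
}

#' Band power
#'
#' Trapezoidal integral of the PSD over [low, high] Hz. The beta band of
#' interest is 13-30 Hz.
#'
#' @param psd a [computePsd()] result.
#' @param low,high band edges (Hz), low < high, within the grid.
#' @export
bandPower <- function(psd, low = 13, high = 30) {
  if (low >= high) stop("inverted band")
  if (low < min(psd$freq) - 1e-9 || high > max(psd$freq) + 1e-9)
    stop("band outside the frequency grid")
  f <- psd$freq; p <- psd$power
  keep <- f >= low & f <= high
  ff <- f[keep]; pp <- p[keep]
  if (length(ff) < 2) stop("band contains fewer than two frequency bins")
  sum(diff(ff) * (pp[-1] + pp[-length(pp)]) / 2)
}

#' Beta power attenuation
#'
#' Difference of band power between the off-stimulation and the
#' on-stimulation spectra, \code{bandPower(off) - bandPower(on)};
#' positive values mean the stimulation suppressed beta activity.
#'
#' @param psd_off,psd_on [computePsd()] results on identical grids.
#' @param low,high band edges (Hz).
#' @export
betaAttenuation <- function(psd_off, psd_on, low = 13, high = 30) {
  if (!isTRUE(all.equal(psd_off$freq, psd_on$freq)))
    stop("frequency grids differ")
  bandPower(psd_off, low, high) - bandPower(psd_on, low, high)
}

#' Detect a harmonic comb in a spectrum
#'
#' For each integer multiple of the fundamental, reports whether a local
#' PSD maximum exists within the tolerance and how prominent it is
#' (peak power over the local median level). Low-frequency periodic
#' stimulation drives such combs (e.g. 20 Hz pulsing producing peaks at
#' 20, 40, 60 ... Hz).
#'
#' @param psd a [computePsd()] result.
#' @param fundamental comb fundamental (Hz).
#' @param n_harmonics number of multiples to test; all must sit below the
#'   Nyquist frequency.
#' @param tolerance_hz half-width of the search window around each
#'   multiple (Hz).
#' @param min_prominence minimum ratio of peak power to the local median
#'   background for a detection (default 2; with Welch-averaged spectra
#'   this keeps the false-positive rate on featureless noise low).
#' @return data frame: harmonic, target_hz, detected, peak_hz, prominence.
#' @export
findHarmonicComb <- function(psd, fundamental, n_harmonics = 3,
                             tolerance_hz = 2, min_prominence = 2) {
  if (n_harmonics * fundamental > max(psd$freq))
    stop("harmonics exceed the frequency grid")
  f <- psd$freq; p <- psd$power
  out <- data.frame(harmonic = seq_len(n_harmonics),
                    target_hz = fundamental * seq_len(n_harmonics),
                    detected = FALSE, peak_hz = NA_real_,
                    prominence = NA_real_)
  for (k in seq_len(n_harmonics)) {
    f0 <- k * fundamental
    near <- which(abs(f - f0) <= tolerance_hz)
    if (!length(near)) next
    i <- near[which.max(p[near])]
    is_peak <- (i > 1 && i < length(p) && p[i] >= p[i - 1] && p[i] >= p[i + 1])
    # local background: median over a window 5 tolerances wide, comb bins excluded
    bg_idx <- which(abs(f - f0) <= 5 * tolerance_hz & abs(f - f0) > tolerance_hz)
    bg <- if (length(bg_idx)) stats::median(p[bg_idx]) else NA_real_
    prom <- if (is.na(bg) || bg <= 0) Inf else p[i] / bg
    out$detected[k] <- is_peak && prom >= min_prominence
    out$peak_hz[k] <- f[i]
    out$prominence[k] <- prom
  }
  out
}
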