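#' Pulse train container
#'
#' The single representation for every stimulation protocol: an ordered
#' set of Dirac event times with a common amplitude. Event times live in
#' the half-open window [onset, total_time) — the endpoint is excluded so
#' concatenated windows never double-count a pulse.
#'
#' @param event_times strictly increasing event times (s).
#' @param amplitude Dirac weight A of each pulse (model current units x ms).
#' @param onset stimulation start (s).
#' @param total_time end of the delivery window (s).
#' @export
pulseTrain <- function(event_times, amplitude, onset, total_time) {
  event_times <- as.numeric(event_times)
  if (length(event_times) && is.unsorted(event_times, strictly = TRUE))
    stop("event times must be strictly increasing")
  if (length(event_times) &&
      (min(event_times) < onset || max(event_times) >= total_time))
    stop("event times must lie in [onset, total_time)")
  structure(list(event_times = event_times, amplitude = amplitude,
                 onset = onset, total_time = total_time),
            class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("<pulse_train> %d events in [%g, %g) s, amplitude %g\n",
              length(x$event_times), x$onset, x$total_time, x$amplitude))
  invisible(x)
}

#' Conventional DBS: continuous periodic pulses
#'
#' Events at \code{onset + k / f_dbs}, k = 0, 1, ..., while strictly below
#' \code{total_time}.
#'
#' @param f_dbs stimulation frequency (Hz), > 0.
#' @param onset stimulation onset (s).
#' @param total_time end of the window (s).
#' @param amplitude pulse Dirac weight.
#' @export
cdbsTrain <- function(f_dbs, onset = 6, total_time = 12, amplitude = 1) {
  if (f_dbs <= 0) stop("f_dbs must be positive")
  if (onset >= total_time) stop("onset must precede total_time")
  k <- 0:ceiling((total_time - onset) * f_dbs)
  ev <- onset + k / f_dbs
  pulseTrain(ev[ev < total_time], amplitude, onset, total_time)
}

#' A-DBS: onset burst followed by slightly slower tonic pulsing
#'
#' An initial burst of \code{burst_pulses} pulses at \code{burst_hz}
#' at the DBS onset, followed by tonic stimulation at \code{tonic_hz};
#' the first tonic pulse falls one tonic period after the last burst pulse.
#' Defaults follow the published pattern: 20 pulses at 130 Hz, then 95 Hz.
#'
#' @inheritParams cdbsTrain
#' @param burst_pulses pulses in the onset burst.
#' @param burst_hz intra-burst rate (Hz).
#' @param tonic_hz tonic rate after the burst (Hz).
#' @export
adbsTrain <- function(onset = 6, total_time = 12, amplitude = 1,
                      burst_pulses = 20, burst_hz = 130, tonic_hz = 95) {
  if (onset >= total_time) stop("onset must precede total_time")
  burst <- onset + (seq_len(burst_pulses) - 1) / burst_hz
  if (burst[burst_pulses] >= total_time)
    stop("window too short to contain the initial burst")
  t0 <- burst[burst_pulses] + 1 / tonic_hz
  tonic <- numeric(0)
  if (t0 < total_time) {
    k <- 0:ceiling((total_time - t0) * tonic_hz)
    tonic <- t0 + k / tonic_hz
    tonic <- tonic[tonic < total_time]
  }
  pulseTrain(c(burst, tonic), amplitude, onset, total_time)
}

#' B-DBS: onset burst followed by repeating 4-pulse packs
#'
#' An initial burst of \code{burst_pulses} pulses at \code{pack_hz}, then
#' repeated packs of \code{pack_pulses} pulses at \code{pack_hz}. With the
#' default \code{pause_mode = "gap"} the 37 ms pause is measured from the
#' last pulse of one pack to the first pulse of the next, giving a
#' pack-onset period of 3/130 s + 37 ms (about 16.6 packs per second, the
#' reading consistent with the ~16 Hz harmonic structure such trains
#' drive); \code{"period"} instead interprets the pause value as the
#' pack-onset period itself.
#'
#' @inheritParams adbsTrain
#' @param pack_pulses pulses per steady-state pack.
#' @param pack_hz intra-pack (and onset-burst) rate (Hz).
#' @param pause_ms inter-pack pause (ms); see \code{pause_mode}.
#' @param pause_mode \code{"gap"} (default) or \code{"period"}.
#' @export
bdbsTrain <- function(onset = 6, total_time = 12, amplitude = 1,
                      burst_pulses = 20, pack_pulses = 4, pack_hz = 130,
                      pause_ms = 37, pause_mode = c("gap", "period")) {
  pause_mode <- match.arg(pause_mode)
  if (onset >= total_time) stop("onset must precede total_time")
  burst <- onset + (seq_len(burst_pulses) - 1) / pack_hz
  if (burst[burst_pulses] >= total_time)
    stop("window too short to contain the initial burst")
  intra <- 1 / pack_hz
  pack_span <- (pack_pulses - 1) * intra
  period <- if (pause_mode == "gap") pack_span + pause_ms / 1000
            else pause_ms / 1000
  if (period <= pack_span) stop("pack period shorter than the pack itself")
  ev <- burst
  start <- burst[burst_pulses] + pause_ms / 1000  # gap after the burst too
  if (pause_mode == "period") start <- burst[burst_pulses] - pack_span + period
  while (start < total_time) {
    pack <- start + (seq_len(pack_pulses) - 1) * intra
    ev <- c(ev, pack[pack < total_time])
    start <- start + period
  }
  pulseTrain(ev, amplitude, onset, total_time)
}

#' Rescale the pulse amplitude
#' @param train a [pulseTrain()].
#' @param factor positive multiplier applied to the amplitude.
#' @export
scaleAmplitude <- function(train, factor) {
  if (!is.finite(factor) || factor <= 0) stop("factor must be positive")
  train$amplitude <- train$amplitude * factor
  train
}

#' Select the stimulated subset of a population
#'
#' Reproducible pseudo-random subset of \code{round(fraction * n)} neuron
#' indices; the published protocol delivers DBS current to 50% of the
#' deep-layer neurons.
#'
#' @param n population size (>= 1).
#' @param fraction fraction in (0, 1].
#' @param seed integer seed.
#' @return sorted integer indices (1-based).
#' @export
selectTargets <- function(n, fraction = 0.5, seed = 1) {
  stopifnot(n >= 1, fraction > 0, fraction <= 1)
  k <- round(fraction * n)
  if (k < 1) stop("selection is empty")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  sort(sample.int(n, k))
}

#' Discretize a pulse train onto the simulation grid
#'
#' Each Dirac event of weight A becomes a rectangular current of width
#' \code{width_ms} and height \code{A / width_ms} starting at the nearest
#' grid point, so its time integral always equals the Dirac weight. The
#' default width is one grid step (the literal Dirac realization); the
#' network simulator uses a finite clinical pulse width instead (see
#' [simulateTcm()]), which is what lets the pulse intensity act as a
#' graded quantity — a strong pulse can re-depolarize the neuron after
#' its first spike within the same pulse, an effect a one-step impulse
#' cannot produce. Events are grid-free until this point: pattern
#' generation never depends on dt.
#'
#' @param train a [pulseTrain()].
#' @param dt step (ms).
#' @param n_steps grid length; defaults to cover \code{total_time}.
#' @param width_ms rectangular pulse width (ms); default one step.
#' @return numeric waveform of length \code{n_steps} (current units).
#' @export
injectTrain <- function(train, dt, n_steps = NULL, width_ms = dt) {
  if (dt <= 0) stop("dt must be positive")
  if (width_ms < dt - 1e-12) stop("width_ms must be at least one step")
  if (is.null(n_steps)) n_steps <- round(train$total_time * 1000 / dt)
  wave <- numeric(n_steps)
  if (length(train$event_times) == 0 || train$amplitude == 0) return(wave)
  k <- max(1L, round(width_ms / dt))
  idx <- round(train$event_times * 1000 / dt) + 1
  if (any(idx < 1 | idx > n_steps))
    stop("pulse events fall outside the simulation window")
  height <- train$amplitude / (k * dt)
  for (off in 0:(k - 1)) {
    j <- idx + off
    j <- j[j <= n_steps]
    wave[j] <- wave[j] + height
  }
  wave
}

#' Write a pulse train as two-column CSV (time_s, amplitude)
#' @param train a [pulseTrain()].
#' @param path output file.
#' @export
writePulseTrain <- function(train, path) {
  utils::write.csv(data.frame(time_s = train$event_times,
                              amplitude = train$amplitude),
                   path, row.names = FALSE)
  invisible(path)
}
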