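#' Default population layout of the thalamocortical microcircuit
#'
#' Six populations: three excitatory motor-cortex layers (S surface,
#' M middle, D deep), the shared cortical interneurons (CI), the thalamic
#' reticular nucleus (TRN) and the thalamocortical relay nucleus (TCR).
#' Default sizes 100/100/100/100/40/100 give the 540-neuron circuit.
#' Setting a size to 0 deactivates that population. The cell-category
#' mixtures and bias currents are documented reconstructions (the original
#' per-population tables are published elsewhere) and can be overridden.
#'
#' @param scale multiplier applied to every size (rounded), for reduced
#'   desk-scale runs; weights are normalized by source-population size so
#'   the operating point is approximately preserved.
#' @return data frame with columns name, size, categories (list of
#'   category proportions), I_bias, excitatory.
#' @export
defaultPopulations <- function(scale = 1) {
  pops <- data.frame(
    name = c("S", "M", "D", "CI", "TRN", "TCR"),
    size = round(scale * c(100, 100, 100, 100, 40, 100)),
    I_bias = c(3.7, 3.7, 3.9, 2.2, 0.4, 0.4),
    excitatory = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  pops$categories <- list(
    c(RS = 0.5, IB = 0.5),   # S
    c(RS = 1.0),             # M
    c(RS = 0.7, IB = 0.3),   # D
    c(FS = 0.5, LTS = 0.5),  # CI
    c(RE = 1.0),             # TRN
    c(TC = 1.0)              # TCR
  )
  pops
}

#' Default connectivity of the microcircuit
#'
#' All-to-all random connectivity: per-projection mean coupling strengths
#' \code{w} (rows = target population, cols = source), transmission delays
#' \code{delay_ms} (synaptic + axonal), a relative weight dispersion and a
#' connection probability. Per-connection weights are drawn as
#' \code{|Normal(mean, cv * mean)| / N_source}; signs live in the synapse
#' response A of the source population, so \code{w} holds magnitudes.
#' The values are a reconstruction tuned so the intact loop — deep-layer
#' cortex driving the thalamus, relay cells re-exciting cortex, with
#' reticular and cortical-interneuron inhibition — resonates in the beta
#' band, reproducing the Parkinsonian baseline.
#'
#' @param loop_gain multiplier on the cortico-thalamo-cortical loop
#'   projections; 1 is the pathological (beta-resonant) default, smaller
#'   values weaken the resonance.
#' @return list with matrices \code{w}, \code{delay_ms}, scalar
#'   \code{weight_cv}, \code{p_connect}.
#' @export
defaultConnectivity <- function(loop_gain = 1) {
  pops <- c("S", "M", "D", "CI", "TRN", "TCR")
  w <- matrix(0, 6, 6, dimnames = list(pops, pops))
  # cortico-thalamo-cortical loop (source in columns)
  w["TCR", "D"] <- 150 * loop_gain
  w["D", "TCR"] <- 225 * loop_gain
  w["TRN", "D"] <- 75
  w["TRN", "TCR"] <- 45
  w["TCR", "TRN"] <- 225
  # deep-layer recurrence and cortical inhibition
  w["D", "D"] <- 150 * loop_gain
  w["D", "CI"] <- 120
  w["CI", "D"] <- 90
  w["CI", "TCR"] <- 45
  # superficial/middle cortex
  w["S", "D"] <- 45; w["M", "D"] <- 45
  w["S", "TCR"] <- 75; w["M", "TCR"] <- 75
  w["D", "S"] <- 30; w["D", "M"] <- 30
  w["S", "S"] <- 10; w["M", "M"] <- 10
  w["S", "CI"] <- 120; w["M", "CI"] <- 120
  w["CI", "S"] <- 22.5; w["CI", "M"] <- 22.5
  w["CI", "CI"] <- 10

  delay_ms <- matrix(1, 6, 6, dimnames = list(pops, pops))
  delay_ms[c("TRN", "TCR"), c("S", "M", "D", "CI")] <- 22  # cortex -> thalamus
  delay_ms[c("S", "M", "D", "CI"), c("TRN", "TCR")] <- 22  # thalamus -> cortex
  delay_ms[c("TRN", "TCR"), c("TRN", "TCR")] <- 2

  list(w = w, delay_ms = delay_ms, weight_cv = 0.25, p_connect = 1)
}

#' Noise configuration
#'
#' White Gaussian membrane noise (added to the voltage equation as a
#' current) with mean 0 and standard deviation 0.5, and Gaussian spike
#' threshold noise with mean 0 and standard deviation 0.1 mV. A Poissonian
#' background input field exists in the data model but is disabled: the
#' simulations neglect it.
#'
#' @param membrane_sd standard deviation of the membrane noise current.
#' @param threshold_sd standard deviation of the threshold noise (mV).
#' @param poisson_background must remain FALSE (not implemented).
#' @export
noiseConfig <- function(membrane_sd = 0.5, threshold_sd = 0.1,
                        poisson_background = FALSE) {
  stopifnot(membrane_sd >= 0, threshold_sd >= 0)
  if (isTRUE(poisson_background))
    stop("Poissonian background noise is part of the data model but disabled")
  list(membrane_sd = membrane_sd, threshold_sd = threshold_sd,
       poisson_background = FALSE)
}

#' Default synapse classes per source population
#'
#' Each presynaptic neuron owns one short-term-plasticity channel: its
#' outgoing PSC. Excitatory sources are depressing AMPA-like channels
#' (the depletion of these channels under high-frequency drive is the
#' synaptic-suppression mechanism the stimulation patterns exploit);
#' inhibitory sources are slower GABA-like depressing channels with
#' negative response.
#'
#' @export
defaultSynapses <- function() {
  exc <- synapseClass("depressing", tau_s = 3, A = 1)
  inh <- synapseParams(U = 0.25, tau_f = 21, tau_d = 706, tau_s = 12, A = -1)
  list(S = exc, M = exc, D = exc, CI = inh, TRN = inh, TCR = exc)
}

#' Assemble the thalamocortical network
#'
#' Realizes heterogeneous neuron parameters, per-source-neuron synapse
#' channels and the all-to-all random weight matrix from the population,
#' connectivity and noise configurations. Deterministic under the seed.
#'
#' @param populations a [defaultPopulations()]-shaped data frame.
#' @param connectivity a [defaultConnectivity()]-shaped list.
#' @param synapses named list of per-source-population [synapseParams()].
#' @param noise a [noiseConfig()].
#' @param seed integer seed for heterogeneity and weight draws.
#' @return object of class \code{tcm_network}.
#' @export
tcmNetwork <- function(populations = defaultPopulations(),
                       connectivity = defaultConnectivity(),
                       synapses = defaultSynapses(),
                       noise = noiseConfig(),
                       seed = 1) {
  stopifnot(identical(populations$name, c("S", "M", "D", "CI", "TRN", "TCR")))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  sizes <- populations$size
  n <- sum(sizes)
  offset <- cumsum(c(0, sizes))[1:6]

  par <- vector("list", 6)
  syn <- vector("list", 6)
  for (j in 1:6) {
    if (sizes[j] == 0) { par[[j]] <- NULL; next }
    mix <- populations$categories[[j]]
    counts <- round(mix * sizes[j])
    counts[length(counts)] <- sizes[j] - sum(counts[-length(counts)])
    rows <- do.call(rbind, lapply(seq_along(mix), function(k) {
      if (counts[k] == 0) return(NULL)
      makeHeterogeneousParams(names(mix)[k], counts[k],
                              I_bias = populations$I_bias[j])
    }))
    par[[j]] <- rows
    sp <- synapses[[populations$name[j]]]
    if (is.null(sp)) stop("missing synapse parameters for ",
                          populations$name[j])
    syn[[j]] <- as.data.frame(sp[c("U", "tau_f", "tau_d", "tau_s", "A")])[
      rep(1, sizes[j]), ]
  }
  par <- do.call(rbind, par)
  syn <- do.call(rbind, syn)

  # all-to-all random weights, normalized by source size
  W <- matrix(0, n, n)
  for (j in 1:6) for (jp in 1:6) {
    if (sizes[j] == 0 || sizes[jp] == 0) next
    m <- connectivity$w[j, jp]
    if (m == 0) next
    blk <- abs(stats::rnorm(sizes[j] * sizes[jp], mean = m,
                            sd = connectivity$weight_cv * m)) / sizes[jp]
    if (connectivity$p_connect < 1)
      blk <- blk * (stats::runif(length(blk)) < connectivity$p_connect)
    W[offset[j] + seq_len(sizes[j]), offset[jp] + seq_len(sizes[jp])] <- blk
  }

  structure(list(
    n = n, sizes = sizes, offset = offset,
    names = populations$name,
    neuron = par, synapse = syn,
    W = W, delay_ms = connectivity$delay_ms,
    noise = noise, seed = seed,
    populations = populations, connectivity = connectivity
  ), class = "tcm_network")
}

#' @export
print.tcm_network <- function(x, ...) {
  cat(sprintf("<tcm_network> %d neurons (%s), seed %d\n", x$n,
              paste(sprintf("%s=%d", x$names, x$sizes), collapse = ", "),
              x$seed))
  invisible(x)
}

#' Neuron ids of a population (1-based, global)
#' @param network a [tcmNetwork()].
#' @param name population name.
#' @export
populationIds <- function(network, name) {
  j <- match(name, network$names)
  if (is.na(j)) stop("unknown population: ", name)
  if (network$sizes[j] == 0) return(integer(0))
  network$offset[j] + seq_len(network$sizes[j])
}

#' Simulate the network
#'
#' Time-stepped co-integration of all neurons and synapses with delayed
#' spike delivery; the DBS waveform is added only to the selected subset
#' of deep-layer (D) neurons. Bitwise reproducible under fixed seed, dt
#' and configuration.
#'
#' @param network a [tcmNetwork()].
#' @param train optional [pulseTrain()]; NULL for the off-stimulation run.
#' @param duration total simulated time (s). Default 12 s.
#' @param dt integration step (ms). Default 0.1 ms forward Euler.
#' @param seed integer seed driving membrane/threshold noise.
#' @param dbs_fraction fraction of D neurons that receive the stimulation
#'   current directly (default 0.5).
#' @param dbs_seed seed of the target-subset draw (fixed per run and
#'   recorded in the result).
#' @param record_v global neuron ids whose voltage traces to keep, or
#'   \code{"all"}.
#' @param record_stride keep every k-th voltage sample (1 = every step);
#'   1-ms sampling (stride \code{1/dt}) is ample for the synchrony matrix.
#' @param pulse_width_ms width of the delivered rectangular stimulation
#'   pulse (ms); default 0.3 ms, a clinically typical pulse duration.
#'   The charge of each pulse equals the train's amplitude regardless of
#'   width.
#' @return object of class \code{tcm_simulation}: \code{spikes} (data
#'   frame time_ms, neuron_id, population), \code{psc_pop} (steps x 6
#'   summed PSC per population), \code{time_s}, \code{dbs_targets},
#'   \code{v} (optional traces), and the run metadata.
#' @export
simulateTcm <- function(network, train = NULL, duration = 12, dt = 0.1,
                        seed = 1, dbs_fraction = 0.5, dbs_seed = seed,
                        record_v = integer(0), record_stride = 1,
                        pulse_width_ms = 0.3) {
  stopifnot(inherits(network, "tcm_network"), duration > 0, dt > 0)
  if (identical(record_v, "all")) record_v <- seq_len(network$n)
  n_steps <- round(duration * 1000 / dt)

  targets <- integer(0)
  wave <- numeric(n_steps)
  if (!is.null(train)) {
    if (train$total_time > duration + 1e-9)
      stop("pulse train window exceeds the simulation window")
    wave <- injectTrain(train, dt, n_steps,
                        width_ms = max(pulse_width_ms, dt))
    d_ids <- populationIds(network, "D")
    if (length(d_ids))
      targets <- d_ids[selectTargets(length(d_ids), dbs_fraction, dbs_seed)]
  }
  mask <- integer(network$n)
  mask[targets] <- 1L

  delay_steps <- matrix(pmax(1L, as.integer(round(network$delay_ms / dt))),
                        6, 6)

  # start every neuron at its subthreshold rest state (fall back to the
  # reset voltage when the bias admits none)
  disc <- (5 - network$neuron$b)^2 - 0.16 * (140 + network$neuron$I_bias)
  v0 <- ifelse(disc >= 0,
               (-(5 - network$neuron$b) - sqrt(pmax(disc, 0))) / 0.08,
               network$neuron$c)
  u0 <- network$neuron$b * v0

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  res <- .tcm_simulate_cpp(
    network$neuron$a, network$neuron$b, network$neuron$c, network$neuron$d,
    network$neuron$v_peak, network$neuron$I_bias,
    network$synapse$U, network$synapse$tau_f, network$synapse$tau_d,
    network$synapse$tau_s, network$synapse$A,
    network$W, delay_steps, as.integer(network$offset),
    as.integer(network$sizes),
    network$noise$membrane_sd, network$noise$threshold_sd,
    dt, as.integer(n_steps), wave, mask,
    as.integer(record_v) - 1L, as.integer(record_stride), v0, u0)

  pop_of <- rep(network$names, network$sizes)
  ids <- res$spike_id + 1L
  spikes <- data.frame(time_ms = res$spike_step * dt,
                       neuron_id = ids,
                       population = pop_of[ids],
                       stringsAsFactors = FALSE)
  psc <- res$psc_pop
  colnames(psc) <- network$names
  v <- NULL
  if (length(record_v)) {
    v <- res$v_rec
    colnames(v) <- as.character(record_v)
  }
  structure(list(
    spikes = spikes, psc_pop = psc, v = v,
    v_sample_ms = dt * record_stride,
    dt = dt, duration = duration, n_steps = n_steps,
    sizes = network$sizes, names = network$names, offset = network$offset,
    n = network$n, seed = seed, network_seed = network$seed,
    dbs_targets = targets,
    train = train
  ), class = "tcm_simulation")
}

#' @export
print.tcm_simulation <- function(x, ...) {
  cat(sprintf(
    "<tcm_simulation> %g s at dt=%g ms, %d neurons, %d spikes, %s\n",
    x$duration, x$dt, x$n, nrow(x$spikes),
    if (is.null(x$train)) "no stimulation"
    else sprintf("%d DBS pulses on %d D neurons",
                 length(x$train$event_times), length(x$dbs_targets))))
  invisible(x)
}

#' Convert a simulation to a samples-by-neurons activity matrix
#'
#' Builds the matrix consumed by the synchrony metric: rows are time
#' samples (P), columns neurons (N), ordered by population then neuron
#' index. \code{"spikes"} gives a 0/1 raster binned at \code{bin} ms;
#' \code{"voltage"} uses recorded membrane traces (only neurons passed to
#' \code{record_v} are available). A warning is issued when P is not much
#' larger than N, where the metric loses validity.
#'
#' @param result a [simulateTcm()] result.
#' @param window c(start, end) in seconds.
#' @param signal \code{"spikes"} or \code{"voltage"}.
#' @param bin bin width (ms) for spike mode.
#' @param min_ratio warn when P/N falls below this (default 10).
#' @return a [rasterMatrix()].
#' @export
rasterToMatrix <- function(result, window = c(0, result$duration),
                           signal = c("spikes", "voltage"), bin = 1,
                           min_ratio = 10) {
  signal <- match.arg(signal)
  stopifnot(window[1] < window[2], window[1] >= 0,
            window[2] <= result$duration + 1e-9)
  if (signal == "spikes") {
    nb <- floor((window[2] - window[1]) * 1000 / bin)
    if (nb < 1) stop("empty window")
    m <- matrix(0L, nb, result$n)
    sp <- result$spikes
    keep <- sp$time_ms >= window[1] * 1000 & sp$time_ms < window[1] * 1000 + nb * bin
    if (any(keep)) {
      bi <- floor((sp$time_ms[keep] - window[1] * 1000) / bin) + 1
      m[cbind(bi, sp$neuron_id[keep])] <- 1L
    }
    out <- rasterMatrix(m, sample_ms = bin,
                        labels = paste0(rep(result$names, result$sizes), "_",
                                        sequence(result$sizes)))
  } else {
    if (is.null(result$v)) stop("no voltage traces were recorded")
    sm <- result$v_sample_ms
    i0 <- floor(window[1] * 1000 / sm) + 1
    i1 <- min(floor(window[2] * 1000 / sm), nrow(result$v))
    out <- rasterMatrix(result$v[i0:i1, , drop = FALSE],
                        sample_ms = sm, labels = colnames(result$v))
  }
  if (nrow(out$values) < min_ratio * ncol(out$values))
    warning("sample count is not much larger than neuron count; ",
            "the synchrony metric may be unreliable")
  out
}

#' Write the spike raster as CSV (time_ms, neuron_id, population)
#' @param result a [simulateTcm()] result.
#' @param path output file.
#' @export
writeSpikes <- function(result, path) {
  utils::write.csv(result$spikes, path, row.names = FALSE)
  invisible(path)
}
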