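#' Write a network/run configuration file
#'
#' Serializes the complete run configuration — population sizes, bias
#' currents, connectivity weights and delays, synapse classes, noise
#' levels, stimulation protocol and seeds — as a single YAML document.
#'
#' @param path output file.
#' @param populations a [defaultPopulations()]-shaped data frame.
#' @param connectivity a [defaultConnectivity()]-shaped list.
#' @param synapses named list of per-population synapse parameters.
#' @param noise a [noiseConfig()].
#' @param protocol protocol name (see [protocolTrain()]).
#' @param amplitude base pulse amplitude.
#' @param duration,dbs_onset simulation window (s).
#' @param dt integration step (ms).
#' @param seed master seed.
#' @export
writeTcmConfig <- function(path,
                           populations = defaultPopulations(),
                           connectivity = defaultConnectivity(),
                           synapses = defaultSynapses(),
                           noise = noiseConfig(),
                           protocol = "cdbs130", amplitude = 1,
                           duration = 12, dbs_onset = 6, dt = 0.1,
                           seed = 1) {
  cfg <- list(
    populations = lapply(seq_len(nrow(populations)), function(j) {
      list(name = populations$name[j], size = populations$size[j],
           I_bias = populations$I_bias[j],
           categories = as.list(populations$categories[[j]]))
    }),
    connectivity = list(
      w = apply(connectivity$w, 1, as.list, simplify = FALSE),
      delay_ms = apply(connectivity$delay_ms, 1, as.list, simplify = FALSE),
      weight_cv = connectivity$weight_cv,
      p_connect = connectivity$p_connect),
    synapses = lapply(synapses, function(s)
      s[c("U", "tau_f", "tau_d", "tau_s", "A")]),
    noise = noise,
    protocol = list(name = protocol, amplitude = amplitude,
                    duration = duration, dbs_onset = dbs_onset),
    dt = dt, seed = seed)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a configuration file
#'
#' @param path a YAML file written by [writeTcmConfig()] (or hand-edited).
#' @return list with the parsed configuration; matrices restored.
#' @export
readTcmConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  pops <- do.call(rbind, lapply(cfg$populations, function(p)
    data.frame(name = p$name, size = p$size, I_bias = p$I_bias,
               stringsAsFactors = FALSE)))
  pops$excitatory <- pops$name %in% c("S", "M", "D", "TCR")
  pops$categories <- lapply(cfg$populations, function(p) unlist(p$categories))
  nm <- pops$name
  unmat <- function(x) {
    m <- do.call(rbind, lapply(x, function(row) unlist(row)))
    dimnames(m) <- list(nm, nm)
    m
  }
  cfg$populations <- pops
  cfg$connectivity <- list(w = unmat(cfg$connectivity$w),
                           delay_ms = unmat(cfg$connectivity$delay_ms),
                           weight_cv = cfg$connectivity$weight_cv,
                           p_connect = cfg$connectivity$p_connect)
  cfg$synapses <- lapply(cfg$synapses, function(s)
    synapseParams(s$U, s$tau_f, s$tau_d, s$tau_s, s$A))
  cfg$noise <- noiseConfig(cfg$noise$membrane_sd, cfg$noise$threshold_sd)
  cfg
}

#' Build a network from a parsed configuration
#' @param cfg a [readTcmConfig()] result.
#' @export
networkFromConfig <- function(cfg) {
  tcmNetwork(populations = cfg$populations,
             connectivity = cfg$connectivity,
             synapses = cfg$synapses,
             noise = cfg$noise,
             seed = cfg$seed)
}

#' Run-metadata record
#'
#' JSON-ready metadata of one simulation: seeds, a hash of the weight
#' matrix, and the identities of the directly stimulated neurons.
#'
#' @param res a [simulateTcm()] result.
#' @param network the network it was run on.
#' @export
runMetadata <- function(res, network) {
  list(seed = res$seed, network_seed = res$network_seed,
       dt = res$dt, duration = res$duration,
       n_neurons = res$n,
       weight_checksum = sum(network$W),
       dbs_targets = res$dbs_targets,
       n_spikes = nrow(res$spikes))
}

#' Write a JSON record (metadata, synchrony or comparison reports)
#' @param x a list or data frame.
#' @param path output file.
#' @export
writeJsonReport <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
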