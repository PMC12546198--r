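# Shared desk-scale network for the simulation tests: half-size
# populations (270 neurons) keep 12-s runs fast while preserving the
# operating point (weights are normalized by source-population size).
# Built lazily and cached for the whole test run.

.test_cache <- new.env(parent = emptyenv())

desk_network <- function(seed = 1) {
  key <- paste0("net", seed)
  if (is.null(.test_cache[[key]]))
    .test_cache[[key]] <- tcmNetwork(populations = defaultPopulations(0.5),
                                     seed = seed)
  .test_cache[[key]]
}

desk_amplitude <- function() {
  if (is.null(.test_cache$amp))
    .test_cache$amp <- calibrateAmplitude(desk_network())
  .test_cache$amp
}

# tiny network for cheap structural/determinism checks
tiny_network <- function(seed = 1) {
  if (is.null(.test_cache$tiny))
    .test_cache$tiny <- tcmNetwork(populations = defaultPopulations(0.2),
                                   seed = seed)
  .test_cache$tiny
}

random_spike_train <- function(n, rate_hz, t_max_ms, seed) {
  set.seed(seed)
  sort(runif(n, 0, t_max_ms))
}
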