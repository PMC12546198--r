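test_that("the default circuit has 540 neurons with the published layout", {
  net <- tcmNetwork(seed = 1)
  expect_equal(net$n, 540)
  expect_equal(net$sizes, c(100, 100, 100, 100, 40, 100))
  expect_equal(net$names, c("S", "M", "D", "CI", "TRN", "TCR"))
  expect_length(populationIds(net, "TRN"), 40)
  # inhibitory sources carry negative synaptic response
  ci <- populationIds(net, "CI")
  expect_true(all(net$synapse$A[ci] < 0))
  expect_true(all(net$synapse$A[populationIds(net, "D")] > 0))
})

test_that("a population sized to zero is deactivated from the circuit", {
  pops <- defaultPopulations()
  pops$size[pops$name == "M"] <- 0
  net <- tcmNetwork(populations = pops, seed = 1)
  expect_equal(net$n, 440)
  expect_length(populationIds(net, "M"), 0)
  res <- simulateTcm(net, NULL, duration = 0.5, dt = 0.1, seed = 1)
  expect_true(all(res$psc_pop[, "M"] == 0))
})

test_that("a drive-free noiseless network stays silent", {
  pops <- defaultPopulations(0.2)
  pops$I_bias[] <- 0.3   # below rheobase for every cell category
  conn <- defaultConnectivity()
  conn$w[] <- 0
  net <- tcmNetwork(populations = pops, connectivity = conn,
                    noise = noiseConfig(0, 0), seed = 1)
  res <- simulateTcm(net, NULL, duration = 0.5, dt = 0.1, seed = 1)
  expect_equal(nrow(res$spikes), 0)
  expect_true(all(res$psc_pop == 0))
})

test_that("simulations are bitwise reproducible under a fixed seed", {
  net <- tiny_network()
  tr <- cdbsTrain(130, 0.2, 0.5, amplitude = 50)
  r1 <- simulateTcm(net, tr, duration = 0.5, dt = 0.1, seed = 42)
  r2 <- simulateTcm(net, tr, duration = 0.5, dt = 0.1, seed = 42)
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$psc_pop, r2$psc_pop)
  expect_identical(r1$dbs_targets, r2$dbs_targets)
  r3 <- simulateTcm(net, tr, duration = 0.5, dt = 0.1, seed = 43)
  expect_false(identical(r1$spikes, r3$spikes))
})

test_that("stimulation current reaches exactly half of the deep layer", {
  net <- tiny_network()
  tr <- cdbsTrain(130, 0, 0.3, amplitude = 50)
  res <- simulateTcm(net, tr, duration = 0.3, dt = 0.1, seed = 1)
  d_ids <- populationIds(net, "D")
  expect_length(res$dbs_targets, round(0.5 * length(d_ids)))
  expect_true(all(res$dbs_targets %in% d_ids))
})

test_that("the activity matrix has the documented shape and content", {
  net <- tiny_network()
  res <- simulateTcm(net, NULL, duration = 1.5, dt = 0.1, seed = 3,
                     record_v = "all", record_stride = 10)
  rm <- suppressWarnings(rasterToMatrix(res, c(0, 1.5), bin = 1))
  expect_equal(dim(rm$values), c(1500, net$n))
  expect_true(all(rm$values %in% c(0L, 1L)))
  # one marked bin per occupied (1-ms bin, neuron) pair of the raster
  occupied <- unique(data.frame(bin = floor(res$spikes$time_ms),
                                id = res$spikes$neuron_id))
  expect_equal(sum(rm$values), nrow(occupied))
  # voltage mode uses the recorded traces at the recorded sampling
  vm <- suppressWarnings(rasterToMatrix(res, c(0, 1), signal = "voltage"))
  expect_equal(dim(vm$values), c(1000, net$n))
  expect_error(rasterToMatrix(res, c(1, 1)), "window")
  # a much-too-short window warns about P vs N
  expect_warning(rasterToMatrix(res, c(0, 0.05)), "much larger")
})

test_that("a silent network's voltage columns sit at their fixed points", {
  pops <- defaultPopulations(0.2)
  pops$I_bias[] <- 0.3
  conn <- defaultConnectivity(); conn$w[] <- 0
  net <- tcmNetwork(populations = pops, connectivity = conn,
                    noise = noiseConfig(0, 0), seed = 1)
  res <- simulateTcm(net, NULL, duration = 0.3, dt = 0.1, seed = 1,
                     record_v = "all", record_stride = 10)
  vm <- suppressWarnings(rasterToMatrix(res, c(0.2, 0.3), signal = "voltage"))
  drift <- apply(vm$values, 2, function(col) diff(range(col)))
  expect_lt(max(drift), 0.5)  # every column settled near its rest state
})

test_that("the off-stimulation circuit oscillates in the beta band", {
  net <- desk_network()
  res <- simulateTcm(net, NULL, duration = 4, dt = 0.1, seed = 2)
  lfp <- estimateLfp(res)
  psd <- computePsd(lfp[10001:length(lfp)], 1000 / res$dt)
  sel <- psd$freq >= 3 & psd$freq <= 100
  peak <- psd$freq[sel][which.max(psd$power[sel])]
  expect_gte(peak, 13); expect_lte(peak, 30)
  # against a weight-shuffled control of equal synaptic mass (loop
  # structure and delay timing destroyed): the control still
  # synchronizes, but its dominant rhythm falls out of the beta band
  shuf <- net
  set.seed(9)
  shuf$W <- matrix(sample(net$W), nrow(net$W))
  shuf$delay_ms[] <- 1
  res_s <- simulateTcm(shuf, NULL, duration = 4, dt = 0.1, seed = 2)
  psd_s <- computePsd(estimateLfp(res_s)[10001:(4e4)], 1000 / res$dt)
  peak_s <- psd_s$freq[sel][which.max(psd_s$power[sel])]
  expect_lt(peak_s, 13)
  # and the structured circuit concentrates a larger share of its
  # slow-band power in beta than the control does
  conc <- bandPower(psd) / bandPower(psd, 3, 45)
  conc_s <- bandPower(psd_s) / bandPower(psd_s, 3, 45)
  expect_gt(conc, conc_s)
})

test_that("halving the step leaves the off-period beta power within 15%", {
  net <- desk_network()
  rel <- sapply(1:5, function(s) {
    b <- sapply(c(0.1, 0.05), function(dt) {
      res <- simulateTcm(net, NULL, duration = 3, dt = dt, seed = s)
      psd <- computePsd(estimateLfp(res)[-(1:round(1000 / dt))], 1000 / dt)
      bandPower(psd)
    })
    (b[2] - b[1]) / b[1]
  })
  expect_lt(abs(median(rel)), 0.15)
})
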