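test_that("conventional DBS places events at onset + k/f within the window", {
  tr <- cdbsTrain(130, onset = 6, total_time = 12, amplitude = 1)
  expect_equal(tr$event_times[1:3], 6 + (0:2) / 130)
  expect_true(all(tr$event_times >= 6 & tr$event_times < 12))
  # enumeration: k/20 < 1 has exactly 20 solutions
  expect_length(cdbsTrain(20, 0, 1)$event_times, 20)
  # zero amplitude is a valid train whose injection is a no-op
  z <- cdbsTrain(130, 0, 1, amplitude = 0)
  expect_true(all(injectTrain(z, 0.1) == 0))
  expect_error(cdbsTrain(-5, 0, 1), "positive")
})

test_that("the burst-then-tonic pattern has 20 fast pulses then 95 Hz pulsing", {
  tr <- adbsTrain(onset = 0, total_time = 2)
  iv <- diff(tr$event_times)
  expect_equal(iv[1:19], rep(1 / 130, 19), tolerance = 1e-12)
  expect_equal(iv[20:(length(iv))], rep(1 / 95, length(iv) - 19),
               tolerance = 1e-12)
  # burst length counted as pulses before the first non-burst interval
  expect_equal(which(abs(iv - 1 / 130) > 1e-9)[1], 20)
  # brute-force enumeration of the two segments
  burst <- (0:19) / 130
  tonic <- seq(burst[20] + 1 / 95, 2, by = 1 / 95)
  tonic <- tonic[tonic < 2]
  expect_equal(tr$event_times, c(burst, tonic), tolerance = 1e-12)
  expect_error(adbsTrain(0, 0.1), "too short")
})

test_that("the burst-pack pattern delivers 4-pulse packs with 37 ms pauses", {
  tr <- bdbsTrain(onset = 0, total_time = 6)
  ev <- tr$event_times
  # drop the 20-pulse onset burst, cluster the rest by >15 ms gaps
  packs <- split(ev[-(1:20)], cumsum(c(1, diff(ev[-(1:20)]) > 0.015)))
  sizes <- lengths(packs)
  full <- sizes[-length(sizes)]        # last pack may be truncated
  expect_true(all(full == 4))
  # intra-pack spacing is the 130 Hz period
  for (p in packs[1:10])
    expect_equal(diff(p), rep(1 / 130, length(p) - 1), tolerance = 1e-12)
  # pause between packs: 37 ms from last pulse to next first pulse
  gap <- vapply(seq_len(length(packs) - 1), function(i)
    packs[[i + 1]][1] - packs[[i]][length(packs[[i]])], numeric(1))
  expect_equal(gap, rep(0.037, length(gap)), tolerance = 1e-12)
  # pack-onset rate ~ 16-17 per second in steady state
  onsets <- vapply(packs, `[`, numeric(1), 1)
  rate <- (length(onsets) - 1) / (onsets[length(onsets)] - onsets[1])
  expect_gt(rate, 16); expect_lt(rate, 17)
  # both patterns share the identical 20-pulse initial segment
  expect_equal(ev[1:20], adbsTrain(0, 6)$event_times[1:20])
})

test_that("amplitude scaling is multiplicative and leaves times unchanged", {
  tr <- cdbsTrain(130, 0, 1, amplitude = 2)
  expect_identical(scaleAmplitude(tr, 1), tr)
  s5 <- scaleAmplitude(tr, 5)
  expect_equal(s5$amplitude, 10)
  expect_identical(s5$event_times, tr$event_times)
  expect_equal(scaleAmplitude(scaleAmplitude(tr, 2), 2.5)$amplitude,
               scaleAmplitude(tr, 5)$amplitude)
  expect_error(scaleAmplitude(tr, 0), "positive")
})

test_that("target selection is a reproducible subset of the requested size", {
  expect_length(selectTargets(100, 0.5, seed = 3), 50)
  expect_equal(selectTargets(100, 1.0, seed = 3), 1:100)
  expect_identical(selectTargets(100, 0.5, seed = 9),
                   selectTargets(100, 0.5, seed = 9))
  expect_false(identical(selectTargets(100, 0.5, seed = 1),
                         selectTargets(100, 0.5, seed = 2)))
  expect_error(selectTargets(10, 0.01), "empty")
})

test_that("injection preserves pulse charge on the simulation grid", {
  tr <- pulseTrain(0.5, amplitude = 3, onset = 0, total_time = 1)
  w <- injectTrain(tr, dt = 0.1)
  expect_equal(sum(w) * 0.1, 3)          # integral equals the Dirac weight
  expect_equal(sum(w != 0), 1)
  # finite width spreads the same charge over several steps
  w3 <- injectTrain(tr, dt = 0.1, width_ms = 0.3)
  expect_equal(sum(w3) * 0.1, 3, tolerance = 1e-12)
  expect_equal(sum(w3 != 0), 3)
  # empty train -> all-zero waveform
  e <- pulseTrain(numeric(0), 1, 0, 1)
  expect_true(all(injectTrain(e, 0.1) == 0))
  # one nonzero sample per event for a 130 Hz train
  tr130 <- cdbsTrain(130, 0, 1)
  expect_equal(sum(injectTrain(tr130, 0.1) != 0),
               length(tr130$event_times))
  expect_error(injectTrain(pulseTrain(0.5, 1, 0, 1), dt = 0.1, n_steps = 10),
               "outside")
})

test_that("generators emit strictly increasing events independent of dt", {
  for (tr in list(cdbsTrain(130, 6, 12), adbsTrain(6, 12), bdbsTrain(6, 12))) {
    expect_true(all(diff(tr$event_times) > 0))
    expect_true(all(tr$event_times >= tr$onset &
                    tr$event_times < tr$total_time))
    # discretization never changes the event count
    expect_equal(sum(injectTrain(tr, 0.1) != 0), length(tr$event_times))
    expect_equal(sum(injectTrain(tr, 0.05) != 0), length(tr$event_times))
  }
})

test_that("pulse trains round-trip through the CSV export", {
  tr <- adbsTrain(0, 1, amplitude = 2.5)
  f <- withr::local_tempfile(fileext = ".csv")
  writePulseTrain(tr, f)
  got <- read.csv(f)
  expect_equal(got$time_s, tr$event_times)
  expect_true(all(got$amplitude == 2.5))
})
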