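test_that("spike-free dynamics decay to the (u=0, x=1, I=0) fixed point", {
  p <- synapseParams(U = 0.3, tau_f = 10, tau_d = 100, tau_s = 5)
  st <- synapseState(u = 0.5, x = 0.5, I = 2)
  # exact mode: closed-form exponentials
  for (k in 1:20000) st <- tmDecayStep(st, p, 1, "exact")
  expect_equal(st$u, 0, tolerance = 1e-12)
  expect_equal(st$x, 1, tolerance = 1e-12)
  expect_equal(st$I, 0, tolerance = 1e-12)
  # u(t) = u0 exp(-t/tau_f) after a finite horizon
  st <- synapseState(u = 0.8, x = 0.3, I = 2)
  out <- tmDecayStep(st, p, 25, "exact")
  expect_equal(out$u, 0.8 * exp(-25 / 10), tolerance = 1e-12)
  expect_equal(out$x, 1 - 0.7 * exp(-25 / 100), tolerance = 1e-12)
})

test_that("Euler decay converges to the exact exponentials at first order", {
  p <- synapseParams(U = 0.3, tau_f = 10, tau_d = 100, tau_s = 5)
  err_u <- function(dt) {
    st <- synapseState(u = 0.8, x = 0.3, I = 2)
    for (k in seq_len(round(100 / dt))) st <- tmDecayStep(st, p, dt, "euler")
    abs(st$u - 0.8 * exp(-10)) / (0.8 * exp(-10))
  }
  e1 <- err_u(0.1); e2 <- err_u(0.05)
  expect_lt(e1, 0.06)          # ~ (T/tau)(dt/tau)/2 = 5% at dt = 0.1
  expect_lt(e2, 0.6 * e1)      # halving dt roughly halves the error
  # the slowly decaying x variable is already sub-0.1% at dt = 0.1
  st <- synapseState(u = 0.8, x = 0.3, I = 2)
  for (k in 1:1000) st <- tmDecayStep(st, p, 0.1, "euler")
  expect_lt(abs(st$x - (1 - 0.7 * exp(-1))) / (1 - 0.7 * exp(-1)), 1e-3)
})

test_that("the presynaptic jump follows the u-first ordering", {
  p <- synapseParams(U = 0.5, tau_f = 10, tau_d = 100, tau_s = 5, A = 1)
  out <- tmOnSpike(synapseState(u = 0, x = 1), p)
  expect_equal(out$state$u, 0.5)
  expect_equal(out$state$x, 0.5)
  expect_equal(out$dI, 0.5)
  # no resources -> no response, whatever U
  out0 <- tmOnSpike(synapseState(u = 0, x = 0), p)
  expect_equal(out0$dI, 0)
  # inhibitory channels produce signed increments
  pn <- synapseParams(U = 0.5, tau_f = 10, tau_d = 100, tau_s = 5, A = -2)
  expect_equal(tmOnSpike(synapseState(), pn)$dI, -1)
})

test_that("event-driven increments match closed forms on canonical trains", {
  p <- synapseParams(U = 0.5, tau_f = 10, tau_d = 500, tau_s = 5, A = 2)
  # single spike from a fresh state
  expect_equal(eventDrivenPsc(p, 0), 2 * 0.5)
  # two spikes far beyond both time constants recover fully
  dI <- eventDrivenPsc(p, c(0, 50000))
  expect_equal(dI[2], dI[1], tolerance = 1e-6)
  # depressing 130 Hz train: non-increasing, strictly so before the
  # sequence settles onto the fixed point
  ts <- seq(0, 1000, by = 1000 / 130)
  dI <- eventDrivenPsc(p, ts)
  expect_true(all(diff(dI) <= 1e-12))
  expect_true(all(diff(dI[1:20]) < 0))
  ss <- tmSteadyState(p, 130)
  expect_equal(dI[length(dI)], ss$dI, tolerance = 1e-3)
  # geometric convergence: the gap to the fixed point shrinks by a
  # constant factor per period
  gaps <- abs(dI - ss$dI)
  ratio <- gaps[-1] / gaps[-length(gaps)]
  expect_lt(max(ratio[5:20]), 1)
  expect_lt(diff(range(ratio[5:20])), 0.05)
  expect_error(eventDrivenPsc(p, c(3, 2, 1)), "strictly increasing")
})

test_that("stepped integration reproduces the event-driven oracle within 1%", {
  # spike trains produced by the simulator live on the integration grid,
  # so the oracle is compared on grid-aligned jittered 130 Hz trains
  p <- synapseParams(U = 0.5, tau_f = 17, tau_d = 671, tau_s = 3, A = 1)
  dt <- 0.1
  step_train <- function(ts, mode) {
    st <- synapseState()
    got <- numeric(length(ts))
    idx <- round(ts / dt)
    k <- 0
    for (step in 0:max(idx)) {
      st <- tmDecayStep(st, p, dt, mode)
      while (k < length(ts) && idx[k + 1] == step) {
        k <- k + 1
        out <- tmOnSpike(st, p)
        st <- out$state
        got[k] <- out$dI
      }
    }
    got
  }
  for (seed in 1:5) {
    set.seed(seed)
    ts <- cumsum(1000 / 130 + runif(60, -2, 2))
    ts <- round(ts[ts < 500] / dt) * dt
    oracle <- eventDrivenPsc(p, ts)
    # exact inter-spike decay: machine-precision agreement
    expect_lt(max(abs(step_train(ts, "exact") - oracle) / oracle), 1e-9)
    # Euler decay at dt = 0.1 ms: within 1%
    expect_lt(max(abs(step_train(ts, "euler") - oracle) / oracle), 0.01)
  }
})

test_that("u and x stay in [0, 1] for arbitrary spike trains", {
  set.seed(42)
  for (rep in 1:20) {
    p <- synapseParams(U = runif(1), tau_f = runif(1, 1, 500),
                       tau_d = runif(1, 1, 800), tau_s = runif(1, 1, 20))
    st <- synapseState()
    gaps <- stats::rexp(200, rate = 1 / runif(1, 1, 50))
    for (g in gaps) {
      st <- tmDecayStep(st, p, g, "exact")
      st <- tmOnSpike(st, p)$state
      expect_true(st$u >= 0 && st$u <= 1)
      expect_true(st$x >= 0 && st$x <= 1)
    }
  }
})

test_that("steady-state transmission is non-increasing in drive frequency", {
  # synaptic suppression: the depressing channel transmits less per spike
  # as the drive rate grows
  p <- synapseParams(U = 0.5, tau_f = 17, tau_d = 671, tau_s = 3, A = 1)
  f <- 1:200
  dI <- vapply(f, function(fr) tmSteadyState(p, fr)$dI, numeric(1))
  expect_true(all(diff(dI) <= 1e-12))
})
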