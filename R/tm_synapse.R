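#' Tsodyks-Markram synapse parameters
#'
#' Short-term plasticity parameters of one synaptic channel. \code{A} is
#' the absolute synaptic response and carries the sign of the channel
#' (negative for inhibitory).
#'
#' @param U utilization increment per spike, in [0, 1].
#' @param tau_f facilitation decay constant (ms).
#' @param tau_d depression recovery constant (ms).
#' @param tau_s postsynaptic-current decay constant (ms).
#' @param A absolute synaptic response (signed, model current units).
#' @return list of class \code{tm_params}.
#' @export
synapseParams <- function(U, tau_f, tau_d, tau_s, A = 1) {
  stopifnot(U >= 0, U <= 1, tau_f > 0, tau_d > 0, tau_s > 0)
  structure(list(U = U, tau_f = tau_f, tau_d = tau_d, tau_s = tau_s, A = A),
            class = "tm_params")
}

#' Stock short-term-plasticity classes
#'
#' Facilitating, depressing and pseudo-linear parameter sets of the
#' standard cortical short-term plasticity taxonomy, used as defaults for
#' the network projections (the per-projection tables of the circuit are
#' published elsewhere and not reproduced; these are documented
#' reconstructions, overridable via the configuration).
#'
#' @param kind \code{"facilitating"}, \code{"depressing"} or
#'   \code{"pseudo_linear"}.
#' @param tau_s PSC decay constant (ms); 3 ms is AMPA-like, ~11 ms GABAA-like.
#' @param A absolute synaptic response (signed).
#' @export
synapseClass <- function(kind = c("depressing", "facilitating",
                                  "pseudo_linear"),
                         tau_s = 3, A = 1) {
  kind <- match.arg(kind)
  switch(kind,
    facilitating  = synapseParams(U = 0.09, tau_f = 670, tau_d = 138,
                                  tau_s = tau_s, A = A),
    depressing    = synapseParams(U = 0.50, tau_f = 17,  tau_d = 671,
                                  tau_s = tau_s, A = A),
    pseudo_linear = synapseParams(U = 0.29, tau_f = 326, tau_d = 329,
                                  tau_s = tau_s, A = A))
}

#' Fresh synapse state
#' @param u initial utilization (0 by convention).
#' @param x initial available resources (1 by convention).
#' @param I initial postsynaptic current.
#' @export
synapseState <- function(u = 0, x = 1, I = 0) list(u = u, x = x, I = I)

#' Spike-free decay of the synapse state
#'
#' Between presynaptic spikes \code{u} decays to 0 with \code{tau_f},
#' \code{x} recovers to 1 with \code{tau_d} and the PSC \code{I} decays to
#' 0 with \code{tau_s}. Both the exact exponential update (default, used
#' by the network core) and plain forward Euler are available.
#'
#' @param state a [synapseState()].
#' @param params a [synapseParams()].
#' @param dt time step (ms), > 0.
#' @param method \code{"exact"} or \code{"euler"}.
#' @export
tmDecayStep <- function(state, params, dt, method = c("exact", "euler")) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  method <- match.arg(method)
  if (method == "exact") {
    list(u = state$u * exp(-dt / params$tau_f),
         x = 1 - (1 - state$x) * exp(-dt / params$tau_d),
         I = state$I * exp(-dt / params$tau_s))
  } else {
    list(u = state$u - dt * state$u / params$tau_f,
         x = state$x + dt * (1 - state$x) / params$tau_d,
         I = state$I - dt * state$I / params$tau_s)
  }
}

#' Presynaptic spike arrival
#'
#' Applies the jump rules in the standard order: first
#' \eqn{u^+ = u^- + U (1 - u^-)}, then the resource consumption and PSC
#' increment both use the updated \code{u} and the pre-jump \code{x}:
#' \eqn{\Delta x = -u^+ x^-}, \eqn{\Delta I = A u^+ x^-}.
#'
#' @inheritParams tmDecayStep
#' @return list with \code{state} (updated) and \code{dI} (PSC increment).
#' @export
tmOnSpike <- function(state, params) {
  u_plus <- state$u + params$U * (1 - state$u)
  dI <- params$A * u_plus * state$x
  list(state = list(u = u_plus,
                    x = state$x - u_plus * state$x,
                    I = state$I + dI),
       dI = dI)
}

#' Event-driven closed-form PSC increment sequence
#'
#' Exact per-spike PSC increments for an arbitrary spike train, obtained by
#' composing the closed-form inter-spike exponential decays with the jump
#' rules. Serves as the independent oracle for the time-stepped
#' integration.
#'
#' @param params a [synapseParams()].
#' @param spike_times strictly increasing spike times (ms).
#' @return numeric vector of PSC increments, one per spike.
#' @export
eventDrivenPsc <- function(params, spike_times) {
  if (length(spike_times) == 0) return(numeric(0))
  if (is.unsorted(spike_times, strictly = TRUE))
    stop("spike_times must be strictly increasing")
  u <- 0; x <- 1
  t_prev <- -Inf
  dI <- numeric(length(spike_times))
  for (k in seq_along(spike_times)) {
    gap <- spike_times[k] - t_prev
    if (is.finite(gap)) {
      u <- u * exp(-gap / params$tau_f)
      x <- 1 - (1 - x) * exp(-gap / params$tau_d)
    }
    u <- u + params$U * (1 - u)
    dI[k] <- params$A * u * x
    x <- x - u * x
    t_prev <- spike_times[k]
  }
  dI
}

#' Periodic steady state of the per-spike map
#'
#' Fixed point (u*, x*) of the one-period return map for a periodic train
#' at rate \code{f_hz}, and the corresponding steady-state PSC increment.
#' The per-period map on u and x is affine, so the fixed point is solved in
#' closed form.
#'
#' @param params a [synapseParams()].
#' @param f_hz drive frequency (Hz), > 0.
#' @return list with \code{u}, \code{x} (post-decay, pre-jump values) and
#'   \code{dI}, the steady-state per-spike PSC increment.
#' @export
tmSteadyState <- function(params, f_hz) {
  stopifnot(f_hz > 0)
  Tms <- 1000 / f_hz
  Ef <- exp(-Tms / params$tau_f)
  Ed <- exp(-Tms / params$tau_d)
  # u_{n+1} = (u_n + U (1 - u_n)) Ef
  u_star <- params$U * Ef / (1 - (1 - params$U) * Ef)
  u_plus <- u_star + params$U * (1 - u_star)
  # x_{n+1} = 1 - (1 - x_n (1 - u_plus)) Ed
  x_star <- (1 - Ed) / (1 - (1 - u_plus) * Ed)
  list(u = u_star, x = x_star, dI = params$A * u_plus * x_star)
}
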