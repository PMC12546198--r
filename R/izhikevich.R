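#' Canonical Izhikevich cell categories
#'
#' Base parameter sets (a, b, c, d) of the two-variable quadratic
#' integrate-and-fire model, one per electrophysiological cell class, plus
#' the nominal spike cutoff \code{v_peak} and a default bias current.
#' These are the canonical published values for each class; the
#' per-population tables of the thalamocortical microcircuit are not
#' reproduced here, so these defaults are a documented reconstruction and
#' every field can be overridden through the network configuration.
#'
#' @format A data frame with one row per category:
#'   \describe{
#'     \item{a}{recovery rate (1/ms)}
#'     \item{b}{recovery sensitivity (dimensionless)}
#'     \item{c}{reset voltage (mV)}
#'     \item{d}{post-spike recovery increment}
#'     \item{v_peak}{nominal spike cutoff (mV)}
#'     \item{excitatory}{logical; selects the heterogeneity rule}
#'   }
#' @export
izhikevichCategories <- function() {
  data.frame(
    category = c("RS", "IB", "CH", "FS", "LTS", "TC", "RE"),
    a = c(0.02, 0.02, 0.02, 0.10, 0.02, 0.02, 0.02),
    b = c(0.20, 0.20, 0.20, 0.20, 0.25, 0.25, 0.25),
    c = c(-65, -55, -50, -65, -65, -65, -65),
    d = c(8, 4, 2, 2, 2, 0.05, 2.05),
    v_peak = 30,
    excitatory = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Single Izhikevich parameter record
#'
#' @param category one of \code{"RS"}, \code{"IB"}, \code{"CH"},
#'   \code{"FS"}, \code{"LTS"}, \code{"TC"}, \code{"RE"}.
#' @param I_bias constant bias current (model current units).
#' @return a list with fields \code{a, b, c, d, v_peak, I_bias, excitatory}.
#' @export
neuronParams <- function(category = "RS", I_bias = 0) {
  tab <- izhikevichCategories()
  row <- tab[tab$category == category, ]
  if (nrow(row) != 1L) stop("unknown neuron category: ", category)
  p <- list(a = row$a, b = row$b, c = row$c, d = row$d,
            v_peak = row$v_peak, I_bias = I_bias, excitatory = row$excitatory)
  stopifnot(p$a > 0, p$v_peak > p$c)
  p
}

#' Heterogeneous parameter draws for a cell category
#'
#' Implements the standard Izhikevich network randomization that makes
#' neurons of a class non-identical: for excitatory classes
#' \code{c = c0 + 15 r^2}, \code{d = d0 (1 - 0.75 r^2)}; for inhibitory
#' classes \code{a = a0 + 0.08 r}, \code{b = b0 - 0.05 r}, with \code{r}
#' uniform on [0, 1] per neuron. For the regular-spiking base
#' (\code{d0 = 8}) the d rule reduces to the canonical \code{d0 - 6 r^2};
#' the proportional form extends it to low-adaptation excitatory classes
#' (thalamocortical relay cells, \code{d0 = 0.05}) without driving the
#' recovery increment negative. With \code{r = 0} the canonical base
#' parameters are returned unchanged.
#'
#' @param category cell category label (see [izhikevichCategories()]).
#' @param n number of neurons (>= 1).
#' @param seed integer seed; identical seeds give identical draws.
#' @param r optional vector of randomization draws in [0, 1] overriding
#'   the uniform sampling (recycled to length \code{n}).
#' @param I_bias bias current copied into every record.
#' @return data frame with \code{n} rows: a, b, c, d, v_peak, I_bias.
#' @export
makeHeterogeneousParams <- function(category, n, seed = NULL, r = NULL,
                                    I_bias = 0) {
  if (n < 1) stop("n must be >= 1")
  base <- neuronParams(category, I_bias = I_bias)
  if (is.null(r)) {
    if (!is.null(seed)) {
      old <- .save_rng(); on.exit(.restore_rng(old))
      set.seed(seed)
    }
    r <- stats::runif(n)
  } else {
    r <- rep_len(r, n)
  }
  out <- data.frame(a = rep(base$a, n), b = rep(base$b, n),
                    c = rep(base$c, n), d = rep(base$d, n),
                    v_peak = rep(base$v_peak, n),
                    I_bias = rep(I_bias, n))
  if (base$excitatory) {
    out$c <- out$c + 15 * r^2
    out$d <- out$d * (1 - 0.75 * r^2)
  } else {
    out$a <- out$a + 0.08 * r
    out$b <- out$b - 0.05 * r
  }
  out
}

#' One forward-Euler step of a single Izhikevich neuron
#'
#' Reference (pure R) implementation of the membrane update used by the
#' network core: \eqn{\dot v = 0.04 v^2 + 5 v + 140 - u + I} and
#' \eqn{\dot u = a (b v - u)}, followed by the noisy-threshold reset: when
#' the freshly integrated \code{v} reaches \code{v_peak + threshold_noise},
#' \code{v} is set to the reset value \code{c} and \code{u} incremented
#' by \code{d}.
#'
#' @param state list with \code{v} (mV) and \code{u}.
#' @param params a [neuronParams()] record.
#' @param total_input total input current (bias + synaptic + noise + DBS).
#' @param dt time step (ms), > 0.
#' @param threshold_noise additive threshold perturbation (mV) for this step.
#' @return list with \code{state} (updated) and \code{spike} (logical).
#' @export
stepNeuron <- function(state, params, total_input = 0, dt = 0.1,
                       threshold_noise = 0) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  if (!all(is.finite(c(state$v, state$u, total_input))))
    stop("non-finite neuron state or input")
  v <- state$v; u <- state$u
  v_new <- v + dt * (0.04 * v^2 + 5 * v + 140 - u + total_input)
  u_new <- u + dt * params$a * (params$b * v - u)
  spike <- v_new >= params$v_peak + threshold_noise
  if (spike) {
    v_new <- params$c
    u_new <- u_new + params$d
  }
  list(state = list(v = v_new, u = u_new), spike = spike)
}

#' Resting fixed point of the quadratic nullcline system
#'
#' Solves \code{0.04 v^2 + 5 v + 140 + I - u = 0} with \code{u = b v}
#' for the stable (more hyperpolarized) root; returns \code{NULL} when the
#' bias exceeds rheobase and no rest state exists.
#'
#' @param params a [neuronParams()] record.
#' @param I total constant input.
#' @return list with \code{v} and \code{u}, or \code{NULL}.
#' @export
restingState <- function(params, I = 0) {
  disc <- (5 - params$b)^2 - 4 * 0.04 * (140 + I)
  if (disc < 0) return(NULL)
  v <- (-(5 - params$b) - sqrt(disc)) / (2 * 0.04)
  list(v = v, u = params$b * v)
}

# preserve/restore the caller's RNG state around internally seeded draws
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
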