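#' One forward-Euler step of the LIF membrane equation
#'
#' Advances the membrane potentials of one homogeneous population by `dt`
#' under leak, excitatory and inhibitory conductances, with additive Gaussian
#' voltage noise of standard deviation `sigma * sqrt(dt)`.  Neurons at or
#' above threshold emit a spike, are reset, and enter the absolute refractory
#' period; refractory neurons are clamped at the reset potential and do not
#' integrate.
#'
#' This is the reference single-step implementation; long simulations run the
#' identical update inside the compiled engine.
#'
#' @param state list with numeric vectors `v` (mV), `s` (synaptic activation),
#'   `refractory_remaining` (ms) and `r` (Hz), as returned by
#'   [population_state()].
#' @param gE,gI per-neuron excitatory and inhibitory conductances (nS).
#' @param params a [neuron_params()] object.
#' @param dt integration step (ms).
#'
#' @return The updated state with a logical `spiked` vector attached.
#' @export
step_membrane <- function(state, gE, gI, params, dt) {
  stopifnot(dt > 0, all(gE >= 0), all(gI >= 0),
            length(gE) == length(state$v), length(gI) == length(state$v))
  p <- params
  v <- state$v
  refr <- state$refractory_remaining
  active <- refr <= 0
  noise <- if (p$sigma > 0) {
    p$sigma * sqrt(dt) * stats::rnorm(length(v))
  } else {
    0
  }
  dv <- (dt / p$C) * (p$gL * (p$EL - v) + gE * (p$EE - v) + gI * (p$EI - v))
  v[active] <- v[active] + dv[active] + if (length(noise) > 1) noise[active] else noise
  if (any(!is.finite(v))) {
    stop("non-finite membrane potential in neuron(s) ",
         paste(which(!is.finite(v)), collapse = ", "))
  }
  refr[!active] <- refr[!active] - dt
  v[!active] <- p$vreset
  spiked <- active & v >= p$vth
  v[spiked] <- p$vreset
  refr[spiked] <- p$tref
  state$v <- v
  state$refractory_remaining <- refr
  state$spiked <- spiked
  state
}

#' Synaptic-activation update
#'
#' Decays activations by `exp(-dt / tau_s)` and then applies the per-spike
#' increment `rho_syn * (1 - s)`, which keeps activations in `[0, 1]` for any
#' spike pattern (the increment vanishes at saturation).
#'
#' @param s activations in `[0, 1]`.
#' @param spiked logical spike flags.
#' @param tau_s decay time constant (ms).
#' @param rho_syn per-spike increment fraction.
#' @param dt step (ms).
#'
#' @return Updated activations.
#' @export
update_synaptic_activation <- function(s, spiked, tau_s, rho_syn, dt) {
  stopifnot(length(s) == length(spiked), all(s >= 0 & s <= 1))
  s <- s * exp(-dt / tau_s)
  s[spiked] <- s[spiked] + rho_syn * (1 - s[spiked])
  s
}

#' Conductances from presynaptic activations
#'
#' Computes per-postsynaptic-neuron excitatory and inhibitory conductances as
#' the weight blocks times the presynaptic activations.  Weight entries are
#' non-negative; the sign of the interaction is carried by the excitatory
#' versus inhibitory classification of the block.
#'
#' @param weights_exc,weights_inh non-negative weight matrices
#'   (`n_post x n_pre`); either may be `NULL`.
#' @param s_pre presynaptic activations.
#'
#' @return List with vectors `gE` and `gI`.
#' @export
conductances <- function(weights_exc, weights_inh, s_pre) {
  block <- function(W) {
    if (is.null(W)) return(0)
    if (any(W < 0)) stop("negative entries in a conductance weight block")
    as.numeric(W %*% s_pre)
  }
  list(gE = block(weights_exc), gI = block(weights_inh))
}

#' Online firing-rate estimate
#'
#' Exponential filter of the spike train: the estimate decays by
#' `exp(-dt / tau_r)` and each spike adds `1000 / tau_r` so that a train at
#' `f` Hz averages to `f` Hz.
#'
#' @param r current estimates (Hz).
#' @param spiked logical spike flags.
#' @param tau_r filter time constant (ms).
#' @param dt step (ms).
#'
#' @return Updated rate estimates.
#' @export
estimate_rates <- function(r, spiked, tau_r, dt) {
  stopifnot(all(r >= 0))
  r <- r * exp(-dt / tau_r)
  r[spiked] <- r[spiked] + 1000 / tau_r
  r
}

#' Initial state of one spiking population
#'
#' @param n number of neurons.
#' @param params a [neuron_params()] object.
#' @param v0 optional initial membrane potentials (defaults to `EL`).
#'
#' @return A list with `v`, `s`, `refractory_remaining` and `r`.
#' @export
population_state <- function(n, params, v0 = NULL) {
  list(v = if (is.null(v0)) rep(params$EL, n) else rep_len(v0, n),
       s = numeric(n), refractory_remaining = numeric(n), r = numeric(n))
}
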