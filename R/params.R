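#' Neuron parameters for the conductance-based LIF backend
#'
#' Bundles the single-neuron constants of the spiking model: membrane
#' capacitance and leak, reversal potentials, threshold/reset, refractory
#' period, the voltage-noise amplitude, the synaptic-activation kinetics and
#' the time constant of the online rate estimator.
#'
#' @param C membrane capacitance (pF).
#' @param gL leak conductance (nS); the membrane time constant is `C/gL` ms.
#' @param EL,EE,EI leak, excitatory and inhibitory reversal potentials (mV).
#' @param vth spike threshold (mV); must exceed `EL`.
#' @param vreset reset potential after a spike (mV). The reset value is a
#'   convention of this implementation (the leak reversal by default).
#' @param tref absolute refractory period (ms).
#' @param sigma amplitude of the additive Gaussian voltage noise; the
#'   per-step standard deviation is `sigma * sqrt(dt)` so the voltage
#'   diffusion is independent of the integration step.
#' @param tau_s synaptic-activation decay time constant (ms); 80 ms for
#'   excitatory populations and 10 ms for inhibitory populations by default.
#' @param rho_syn per-spike synaptic-activation increment fraction in (0, 1];
#'   a spike moves the activation by `rho_syn * (1 - s)`.
#' @param tau_r time constant (ms) of the exponential spike filter that
#'   yields the per-neuron firing-rate estimate.
#' @param tau_s_in decay time constant (ms) of the input-layer synapses.
#'
#' @return A validated list of class `"neuron_params"`.
#' @export
neuron_params <- function(C = 200, gL = 10, EL = -70, EE = 0, EI = -75,
                          vth = -54, vreset = EL, tref = 2, sigma = 0.8,
                          tau_s = 80, rho_syn = 0.05, tau_r = 50,
                          tau_s_in = 80) {
  p <- list(C = C, gL = gL, EL = EL, EE = EE, EI = EI, vth = vth,
            vreset = vreset, tref = tref, sigma = sigma, tau_s = tau_s,
            rho_syn = rho_syn, tau_r = tau_r, tau_s_in = tau_s_in)
  stopifnot(
    "all time constants must be positive" =
      all(c(C, gL, tau_s, tau_r, tau_s_in) > 0) && tref >= 0,
    "vth must exceed EL" = vth > EL,
    "rho_syn must lie in (0, 1]" = rho_syn > 0 && rho_syn <= 1,
    "sigma must be non-negative" = sigma >= 0
  )
  class(p) <- "neuron_params"
  p
}

#' Parameters of the piecewise non-linear rate transfer function
#'
#' The rate backend maps unit activation `u` to a firing rate through a
#' transfer function that is zero below a threshold, quadratic between the
#' threshold and a critical activity level, and square-root shaped above it
#' (see [transfer()]).
#'
#' @param tau_u unit time constant (ms). May be overridden per unit when
#'   building a network (inhibitory units are faster).
#' @param theta lower threshold of the transfer function.
#' @param u_c critical activity level where the quadratic branch hands over
#'   to the square-root branch; must exceed `theta`.
#' @param v_scale scaling parameter; the transfer equals `v_scale` at `u_c`.
#'
#' @return A validated list of class `"rate_params"`.
#' @export
rate_params <- function(tau_u = 80, theta = 1, u_c = 10, v_scale = 20) {
  stopifnot(
    "u_c must exceed theta" = u_c > theta,
    "v_scale must be positive" = v_scale > 0,
    "tau_u must be positive" = tau_u > 0
  )
  structure(list(tau_u = tau_u, theta = theta, u_c = u_c, v_scale = v_scale),
            class = "rate_params")
}

#' Two-trace eligibility learning parameters
#'
#' Parameters of one plastic synapse class under the two-trace rule: each
#' synapse carries an LTP trace and an LTD trace, activated by thresholded
#' Hebbian activity, decaying with their own time constants and saturating at
#' their own ceilings.  At every neuromodulator event the weight moves by
#' `eta_lr * (T_p - T_d)` and both traces are consumed.
#'
#' Feed-forward synapse classes must have dominant LTP in the rising phase
#' (`eta_p > eta_d`) and dominant LTD in the falling phase (`tau_d > tau_p`);
#' this ordering is validated when `role = "feedforward"`.
#'
#' @param tau_p,tau_d decay time constants (ms) of the LTP and LTD traces.
#' @param eta_p,eta_d Hebbian activation constants (1/Hz^2).
#' @param tmax_p,tmax_d trace saturation levels.
#' @param r_th Hebbian rate threshold (Hz): the Hebbian term is the product
#'   of pre- and postsynaptic rates only when both exceed this threshold,
#'   which makes the traces blind to noise-driven rate overlaps.
#' @param eta_lr learning rate converting the trace difference into a weight
#'   change at a neuromodulator event.
#' @param trace_refractory lockout (ms) of trace activation after an event.
#' @param w_min,w_max weight bounds; excitatory weights never change sign.
#' @param role `"recurrent"` or `"feedforward"`; selects which structural
#'   constraints are enforced.
#'
#' @return A validated list of class `"trace_params"`.
#' @export
trace_params <- function(tau_p, tau_d, eta_p, eta_d, tmax_p = 1, tmax_d = 1,
                         r_th = 5, eta_lr = 0.01, trace_refractory = 25,
                         w_min = 0, w_max = 1,
                         role = c("recurrent", "feedforward")) {
  role <- match.arg(role)
  stopifnot(
    "trace time constants must be positive" = tau_p > 0 && tau_d > 0,
    "saturation levels must be positive" = tmax_p > 0 && tmax_d > 0,
    "activation constants must be non-negative" = eta_p >= 0 && eta_d >= 0,
    "w_max must exceed w_min" = w_max > w_min
  )
  if (role == "feedforward" && !(eta_p > eta_d && tau_d > tau_p)) {
    stop("feed-forward trace parameters require eta_p > eta_d ",
         "(dominant LTP while rising) and tau_d > tau_p ",
         "(dominant LTD while falling)")
  }
  structure(list(tau_p = tau_p, tau_d = tau_d, eta_p = eta_p, eta_d = eta_d,
                 tmax_p = tmax_p, tmax_d = tmax_d, r_th = r_th,
                 eta_lr = eta_lr, trace_refractory = trace_refractory,
                 w_min = w_min, w_max = w_max, role = role),
            class = "trace_params")
}
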