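#' Thresholded Hebbian term
#'
#' The Hebbian activity at a synapse is the product of the pre- and
#' postsynaptic rate estimates, gated to zero unless both rates exceed the
#' rate threshold.  The gate exists so that traces ignore random, noise-driven
#' rate overlaps between populations that are not co-active by design.
#'
#' @param r_pre,r_post rates (Hz); vectors are combined as an outer product
#'   (`n_post x n_pre`).
#' @param r_threshold gating threshold (Hz).
#'
#' @return Hebbian value(s) in Hz^2.
#' @export
hebbian_term <- function(r_pre, r_post, r_threshold) {
  stopifnot(all(r_pre >= 0), all(r_post >= 0))
  gp <- ifelse(r_pre > r_threshold, r_pre, 0)
  gq <- ifelse(r_post > r_threshold, r_post, 0)
  if (length(gp) == 1L && length(gq) == 1L) gq * gp else outer(gq, gp)
}

#' Euler update of the two eligibility traces
#'
#' Each trace follows `tau_a dT/dt = -T + eta_a H (Tmax_a - T)` for
#' `a in {p, d}`; traces saturate at `Tmax_a` and stay non-negative.  While a
#' trace group is inside its post-reward refractory window, its Hebbian input
#' is forced to zero and the traces simply decay.
#'
#' @param state list with matrices (or scalars) `T_p`, `T_d` and the scalar
#'   `refractory_remaining` (ms).
#' @param H Hebbian values, same shape as the traces.
#' @param params a [trace_params()] object.
#' @param dt step (ms).
#'
#' @return The updated trace state.
#' @export
update_traces <- function(state, H, params, dt) {
  if (state$refractory_remaining > 0) {
    H <- H * 0
    state$refractory_remaining <- state$refractory_remaining - dt
  }
  p <- params
  Tp <- state$T_p + (dt / p$tau_p) * (-state$T_p + p$eta_p * H * (p$tmax_p - state$T_p))
  Td <- state$T_d + (dt / p$tau_d) * (-state$T_d + p$eta_d * H * (p$tmax_d - state$T_d))
  state$T_p <- pmin(pmax(Tp, 0), p$tmax_p)
  state$T_d <- pmin(pmax(Td, 0), p$tmax_d)
  state
}

#' Neuromodulator event schedule for a stimulus protocol
#'
#' A global novelty signal is released each time a stimulus starts or ends.
#' For contiguous elements the shared boundary is a single event, so a
#' protocol of k contiguous elements yields k + 1 events: the sequence onset,
#' every interior transition, and the final offset.
#'
#' @param protocol a [stimulus_protocol()] object (or anything with a
#'   `duration` column).
#'
#' @return Numeric vector of strictly increasing event times (ms), relative
#'   to the first element's onset.
#' @export
reward_schedule <- function(protocol) {
  d <- protocol$duration
  if (length(d) == 0) return(numeric(0))
  unique(c(0, cumsum(d)))
}

#' Convert eligibility traces into weight changes at a reward event
#'
#' Applies `W <- clip(W + eta_lr * (T_p - T_d), w_min, w_max)`, zeroes both
#' traces (they are consumed), and starts the trace-activation refractory
#' window.  The neuromodulator is treated as a unit delta at the event time.
#'
#' @param weights weight matrix (or scalar).
#' @param state trace state as in [update_traces()].
#' @param params a [trace_params()] object.
#'
#' @return List with the updated `weights` and `state`.
#' @export
apply_reward <- function(weights, state, params) {
  w <- weights + params$eta_lr * (state$T_p - state$T_d)
  w <- pmin(pmax(w, params$w_min), params$w_max)
  state$T_p <- state$T_p * 0
  state$T_d <- state$T_d * 0
  state$refractory_remaining <- params$trace_refractory
  list(weights = w, state = state)
}

#' Effective trace saturation levels and time constants at constant Hebbian drive
#'
#' Under constant `H`, the trace ODE `tau_a dT/dt = -T + eta_a H (Tmax_a - T)`
#' relaxes exponentially toward a steady state.  The exact values are
#' `T~_a = eta_a H Tmax_a / (1 + eta_a H)` and
#' `tau~_a = tau_a / (1 + eta_a H)`.  As `H` grows, `T~_a` approaches the
#' saturation level `Tmax_a` and the effective time constant shrinks.
#'
#' @param H constant Hebbian level (Hz^2).
#' @param params a [trace_params()] object.
#'
#' @return List with `T_tilde_p`, `T_tilde_d`, `tau_tilde_p`, `tau_tilde_d`.
#' @export
effective_trace_params <- function(H, params) {
  stopifnot(H >= 0)
  p <- params
  list(T_tilde_p = p$eta_p * H * p$tmax_p / (1 + p$eta_p * H),
       T_tilde_d = p$eta_d * H * p$tmax_d / (1 + p$eta_d * H),
       tau_tilde_p = p$tau_p / (1 + p$eta_p * H),
       tau_tilde_d = p$tau_d / (1 + p$eta_d * H))
}

#' Falling-phase fixed point of the two-trace rule
#'
#' After Hebbian activity crosses below threshold at `t_th`, both traces
#' decay freely from their effective saturation levels.  The reward delay
#' `D = t_reward - t_th` at which the decaying LTP and LTD exponentials
#' intersect (so the weight update vanishes) is
#' `D = log(T~_p / T~_d) / (1/tau_p - 1/tau_d)`.  Recurrent learning drives
#' the gap between the end of Timer firing and the next reward toward this
#' value.
#'
#' @param params a [trace_params()] object (`tau_p != tau_d` required).
#' @param T_tilde_p,T_tilde_d positive effective saturation levels, e.g. from
#'   [effective_trace_params()].
#'
#' @return The crossing delay D (ms).  If the trace ordering admits no
#'   non-negative crossing the value is negative; callers treat that as "no
#'   positive crossing".
#' @export
falling_fixed_point_D <- function(params, T_tilde_p, T_tilde_d) {
  stopifnot(T_tilde_p > 0, T_tilde_d > 0)
  if (params$tau_p == params$tau_d) {
    stop("tau_p == tau_d: the falling-phase crossing is singular")
  }
  log(T_tilde_p / T_tilde_d) / (1 / params$tau_p - 1 / params$tau_d)
}

#' Rising-phase fixed point of the feed-forward rule
#'
#' During the rising phase the traces approach their effective saturations
#' with their effective time constants.  The Hebbian level `H*` at which the
#' two rising exponentials agree at the reward time,
#' `T~_p(H) (1 - exp(-t_reward / tau~_p(H))) =
#'  T~_d(H) (1 - exp(-t_reward / tau~_d(H)))`,
#' is the feed-forward fixed point: learning moves the feed-forward weight
#' until the Hebbian product at reward time equals `H*`.
#'
#' @param t_reward time from trace activation to the reward (ms).
#' @param params a [trace_params()] object with feed-forward ordering
#'   (`eta_p > eta_d`, `tau_d > tau_p`).
#' @param bracket search interval for `H`.
#' @param tol relative residual tolerance.
#'
#' @return List with `H_star` and the `residual` of the balance equation.
#' @export
rising_fixed_point_H <- function(t_reward, params, bracket = c(1e-8, 1e8),
                                 tol = 1e-12) {
  stopifnot(t_reward > 0)
  if (!(params$eta_p > params$eta_d && params$tau_d > params$tau_p)) {
    stop("rising fixed point requires feed-forward parameter ordering ",
         "(eta_p > eta_d, tau_d > tau_p)")
  }
  bal <- function(H) {
    e <- effective_trace_params(H, params)
    e$T_tilde_p * (1 - exp(-t_reward / e$tau_tilde_p)) -
      e$T_tilde_d * (1 - exp(-t_reward / e$tau_tilde_d))
  }
  lo <- bal(bracket[1]); hi <- bal(bracket[2])
  if (sign(lo) == sign(hi)) {
    stop("no sign change of the rising-phase balance on the bracket [",
         bracket[1], ", ", bracket[2], "]")
  }
  root <- stats::uniroot(bal, interval = bracket, tol = tol)
  e <- effective_trace_params(root$root, params)
  scale <- max(abs(e$T_tilde_p), abs(e$T_tilde_d), .Machine$double.eps)
  list(H_star = root$root, residual = abs(bal(root$root)) / scale)
}
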