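#' Piecewise non-linear rate transfer function
#'
#' Maps unit activation to firing rate: zero at or below the threshold
#' `theta`, a quadratic branch `v * ((u - theta)/(u_c - theta))^2` between
#' `theta` and the critical level `u_c`, and a square-root branch
#' `2 v * sqrt((u - theta)/(u_c - theta) - 3/4)` above `u_c`.  Both branches
#' evaluate to `v` at `u_c`, so the function is continuous and non-decreasing
#' everywhere.  The square-root branch is what lets recurrent units hover
#' near a saddle and produce long, graded transients whose duration grows
#' with the recurrent weight.
#'
#' The two branch expressions are constructed so that they agree exactly at
#' `u_c` (this is the unique continuous arrangement of a quadratic onset and
#' a square-root continuation), and they are isolated here so an alternative
#' form is a one-line change.
#'
#' @param u activation (scalar or vector).
#' @param params a [rate_params()] object.
#'
#' @return Firing rate(s), same shape as `u`.
#' @export
transfer <- function(u, params) {
  th <- params$theta
  x <- (u - th) / (params$u_c - th)
  out <- numeric(length(u))
  quad <- u > th & u < params$u_c
  root <- u >= params$u_c
  out[quad] <- params$v_scale * x[quad]^2
  out[root] <- 2 * params$v_scale * sqrt(x[root] - 0.75)
  out
}

#' One Euler step of the rate-unit dynamics
#'
#' Advances `tau_u * du/dt = -u + sum_alpha W^alpha xi(u) + I_ext` by `dt`
#' and refreshes the rates `r = xi(u)`.  Inhibition enters through
#' negative-signed weight entries.
#'
#' @param state list with vectors `u` and `r`.
#' @param weights signed dense weight matrix (`n x n`).
#' @param params a [rate_params()] object; `tau_u` may be a vector giving a
#'   per-unit time constant.
#' @param dt step (ms); must be well below `tau_u`.
#' @param input optional external input vector.
#'
#' @return The updated state.
#' @export
step_rate_units <- function(state, weights, params, dt, input = 0) {
  r <- transfer(state$u, params)
  drive <- as.numeric(weights %*% r) + input
  u <- state$u + (dt / params$tau_u) * (-state$u + drive)
  if (any(!is.finite(u))) {
    stop("non-finite activation in unit(s) ",
         paste(which(!is.finite(u)), collapse = ", "))
  }
  list(u = u, r = transfer(u, params))
}
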