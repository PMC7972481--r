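#' Build a fixed recurrent reservoir
#'
#' The reservoir is a non-learning, recurrently connected rate network that
#' receives the columnar network's Messenger activity and whose state
#' therefore encodes the recent history of the main network.  The binary
#' projection `J` is block-structured: the first `K/n` reservoir units
#' receive the first column's Messengers, the next `K/n` the second
#' column's, and so on (remainder rows are distributed round-robin).
#' Recurrent weights are drawn from a zero-mean normal with standard
#' deviation `g / sqrt(K)` — the standard gain-scaled convention for random
#' recurrent networks, under which the recurrent input variance is `g^2`
#' independent of `K`.
#'
#' @param K number of reservoir units (must be at least `n_columns`).
#' @param n_columns number of columns feeding the reservoir.
#' @param g reservoir gain; below 1 the autonomous dynamics are contracting,
#'   so the state is a fading memory of the input history.
#' @param tau_net reservoir time constant (ms).
#' @param theta_m Messenger input threshold (Hz): reservoir drive is the
#'   threshold-linear function of `r - theta_m`.
#' @param seed RNG seed (same seed, same matrices).
#' @param j_scale input scale of the binary projection (entries are
#'   `j_scale` rather than 1), keeping the reservoir within the graded range
#'   of its saturating nonlinearity.
#'
#' @return A `reservoir_spec` with `J` (`K x n_columns`), `W_res` (`K x K`),
#'   and the scalars.
#' @export
build_reservoir <- function(K, n_columns, g = 0.95, tau_net = 150,
                            theta_m = 1, seed = 1, j_scale = 1) {
  if (K < n_columns) stop("K must be at least the number of columns")
  set.seed(seed)
  # contiguous blocks of size K %/% n, remainder distributed round-robin
  sizes <- rep(K %/% n_columns, n_columns) +
    (seq_len(n_columns) <= K %% n_columns)
  col_of <- rep(seq_len(n_columns), sizes)
  J <- matrix(0, K, n_columns)
  J[cbind(seq_len(K), col_of)] <- j_scale
  W_res <- matrix(stats::rnorm(K * K, 0, g / sqrt(K)), K, K)
  structure(list(J = J, W_res = W_res, K = K, n_columns = n_columns, g = g,
                 tau_net = tau_net, theta_m = theta_m, j_scale = j_scale),
            class = "reservoir_spec")
}

#' Build the sparse pattern network
#'
#' A high-dimensional thresholded projection of the reservoir: `M` binary
#' units, each reading the reservoir through a sparse random matrix `O` with
#' fraction `rho_sparse` of entries non-zero (drawn from a zero-mean normal
#' with standard deviation `g / sqrt(M)`).  Distinct reservoir states map to
#' nearly non-overlapping binary patterns, so a pattern at time t uniquely
#' tags the input history up to t.
#'
#' @param M number of sparse units.
#' @param K number of reservoir units.
#' @param rho_sparse fraction of non-zero entries in `O`.
#' @param g gain of the projection.
#' @param theta_o sparse-unit threshold.
#' @param q_max ceiling of the learned feedback weights.
#' @param seed RNG seed.
#'
#' @return A `sparse_pattern_spec` with `O` (`M x K`) and the scalars.
#' @export
build_sparse_pattern <- function(M, K, rho_sparse = 0.04, g = 0.95,
                                 theta_o = 1, q_max = 2, seed = 1) {
  stopifnot(rho_sparse > 0, rho_sparse < 1)
  set.seed(seed)
  O <- matrix(0, M, K)
  nz <- which(stats::runif(M * K) < rho_sparse)
  O[nz] <- stats::rnorm(length(nz), 0, g / sqrt(M))
  structure(list(O = O, M = M, K = K, rho_sparse = rho_sparse, g = g,
                 theta_o = theta_o, q_max = q_max),
            class = "sparse_pattern_spec")
}

#' One Euler step of the reservoir dynamics
#'
#' `tau_net du/dt = -u + J psi(r - theta_m) + W_res tanh(u)`, with `psi` the
#' threshold-linear function.  Reference implementation; long runs use the
#' compiled engine.
#'
#' @param u reservoir state.
#' @param messenger_rates per-column Messenger rates (Hz).
#' @param spec a `reservoir_spec`.
#' @param dt step (ms).
#' @return The updated state.
#' @export
step_reservoir <- function(u, messenger_rates, spec, dt) {
  psi <- pmax(messenger_rates - spec$theta_m, 0)
  u2 <- u + (dt / spec$tau_net) *
    (-u + as.numeric(spec$J %*% psi) + as.numeric(spec$W_res %*% tanh(u)))
  if (any(!is.finite(u2))) stop("non-finite reservoir state")
  u2
}

#' Binary sparse pattern for a reservoir state
#'
#' `nu_m = [any messenger rate exceeds theta_m] * H(sum_i O_mi tanh(u_i) -
#' theta_o)`: patterns fire only while Messengers are active, so a pattern
#' marks a transition together with the history that led to it.  The global
#' any-Messenger gate is an interpretation choice (the gating factor's index
#' is not tied to a specific unit).
#'
#' @param u reservoir state.
#' @param messenger_rates per-column Messenger rates (Hz).
#' @param spec a `sparse_pattern_spec`.
#' @param theta_m Messenger gate threshold (Hz).
#' @return Binary vector of length `M`.
#' @export
sparse_pattern <- function(u, messenger_rates, spec, theta_m) {
  gate <- any(messenger_rates > theta_m)
  as.numeric(gate & (as.numeric(spec$O %*% tanh(u)) > spec$theta_o))
}

#' Hebbian update of the sparse-to-Timer feedback weights
#'
#' `Q <- clip(Q + r_j nu_m dt, 0, q_max)` with rates in Hz and `dt` in ms
#' (so a 10 Hz Timer paired with an active pattern unit for 1 ms adds 0.01).
#' The temporal pairing between a pattern and the Timer cells active just
#' after it arises from simultaneous simulation; there is no explicit lag.
#'
#' @param Q feedback weights (`n_timer x M`).
#' @param timer_rates Timer unit rates (Hz).
#' @param nu binary sparse pattern.
#' @param dt step (ms).
#' @param q_max weight ceiling.
#' @param r_threshold optional Timer rate gate (Hz); zero gives the plain
#'   Hebbian form, a positive value keeps the decaying tail of the ending
#'   element from wiring itself to its own transition pattern.
#' @return The updated `Q`.
#' @export
update_Q <- function(Q, timer_rates, nu, dt, q_max, r_threshold = 0) {
  r <- ifelse(timer_rates > r_threshold, timer_rates, 0)
  Q <- Q + (dt * 1e-3) * outer(r, nu)
  pmin(pmax(Q, 0), q_max)
}

#' Attach the three-stage extension to a rate-backend network
#'
#' Installs the reservoir, the sparse pattern net, and zero-initialised
#' feedback weights `Q` onto a `nonmarkov`-variant network.  During training
#' the sparse patterns that accompany each transition connect, by plain
#' Hebbian learning, to the Timer units active just after; during recall that
#' feedback path replaces the direct Messenger-to-Timer route and makes
#' transitions history-dependent.
#'
#' @param net a rate-backend `ttl_network` built with
#'   `variant = "nonmarkov"`.
#' @param config configuration (uses the `nonmarkov` section).
#' @param seed RNG seed for the random matrices.
#'
#' @return The network with `three_stage` attached.
#' @export
attach_three_stage <- function(net, config = net$config, seed = 1) {
  if (net$backend != "rate") {
    stop("the three-stage extension runs on the rate backend")
  }
  if (net$variant != "nonmarkov") {
    stop("build the network with variant = 'nonmarkov' first ",
         "(the direct Messenger-to-Timer path must be removed)")
  }
  nm <- config$nonmarkov
  res <- build_reservoir(nm$K, net$n_columns, g = nm$g, tau_net = nm$tau_net,
                         theta_m = nm$theta_m, seed = seed,
                         j_scale = nm$j_scale %||% 1)
  sp <- build_sparse_pattern(nm$M, nm$K, rho_sparse = nm$rho_sparse,
                             g = nm$g, theta_o = nm$theta_o,
                             q_max = nm$q_max, seed = seed + 1)
  net$three_stage <- list(reservoir = res, sparse = sp,
                          Q = matrix(0, net$n_columns, nm$M))
  net
}

#' Pairwise overlap of binary patterns
#'
#' Jaccard overlap (intersection over union) between binary pattern vectors;
#' used to verify that the sparse patterns tagging different histories are
#' nearly non-overlapping.
#'
#' @param a,b binary vectors.
#' @return Overlap in `[0, 1]` (0 when both are empty).
#' @export
pattern_overlap <- function(a, b) {
  u <- sum(a > 0 | b > 0)
  if (u == 0) return(0)
  sum(a > 0 & b > 0) / u
}

#' Sparse pattern active at a given time in a record
#'
#' @param record a `ttl_record` from a three-stage run with pattern
#'   recording enabled.
#' @param t time (ms); the nearest recorded sample is returned.
#' @return Binary vector of length `M`.
#' @export
pattern_at <- function(record, t) {
  if (is.null(record$nu)) stop("record has no sparse-pattern trace")
  i <- which.min(abs(record$time - t))
  as.numeric(record$nu[, i])
}
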