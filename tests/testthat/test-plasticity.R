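test_that("Hebbian term is the gated product of rates", {
  expect_equal(hebbian_term(0, 50, 5), 0)
  expect_equal(hebbian_term(20, 10, 5), 200)
  expect_equal(hebbian_term(20, 3, 5), 0)   # one rate below threshold
  expect_equal(hebbian_term(3, 20, 5), 0)
  H <- hebbian_term(c(20, 2), c(10, 30), 5)
  expect_equal(dim(H), c(2, 2))
  expect_equal(H[1, 1], 200)
  expect_equal(H[, 2], c(0, 0))  # presynaptic rate below threshold
})

test_that("traces decay exponentially without Hebbian drive", {
  tp <- trace_params(tau_p = 1000, tau_d = 300, eta_p = 0.05, eta_d = 0.05)
  st <- list(T_p = 0.8, T_d = 0.8, refractory_remaining = 0)
  for (i in 1:300) st <- update_traces(st, 0, tp, 1)
  expect_equal(st$T_p, 0.8 * (1 - 1 / 1000)^300, tolerance = 1e-9)
  expect_equal(st$T_d, 0.8 * (1 - 1 / 300)^300, tolerance = 1e-9)
})

test_that("constant Hebbian drive converges to the exact ODE steady state", {
  tp <- trace_params(tau_p = 800, tau_d = 267, eta_p = 0.05, eta_d = 0.02,
                     tmax_p = 1, tmax_d = 1.3)
  H <- 900
  st <- list(T_p = 0, T_d = 0, refractory_remaining = 0)
  for (i in 1:40000) st <- update_traces(st, H, tp, 0.25)
  eff <- effective_trace_params(H, tp)
  expect_equal(st$T_p, eff$T_tilde_p, tolerance = 1e-3)
  expect_equal(st$T_d, eff$T_tilde_d, tolerance = 1e-3)
})

test_that("traces never exceed their saturation levels", {
  tp <- trace_params(tau_p = 100, tau_d = 50, eta_p = 1, eta_d = 1,
                     tmax_p = 1, tmax_d = 1.2)
  st <- list(T_p = 1, T_d = 1.2, refractory_remaining = 0)
  set.seed(3)
  for (i in 1:500) {
    st <- update_traces(st, runif(1, 0, 1e5), tp, 1)
    expect_lte(st$T_p, 1)
    expect_lte(st$T_d, 1.2)
    expect_gte(st$T_p, 0)
  }
})

test_that("reward schedule marks every onset and offset once", {
  expect_equal(reward_schedule(data.frame(duration = numeric(0))), numeric(0))
  fig_seq <- make_fixture("four_element")
  expect_equal(reward_schedule(fig_seq), c(0, 500, 1500, 2200, 4000))
  expect_equal(reward_schedule(data.frame(duration = 500)), c(0, 500))
})

test_that("reward conversion: sign, consumption, and refractory", {
  tp <- trace_params(tau_p = 800, tau_d = 267, eta_p = 0.05, eta_d = 0.05,
                     eta_lr = 0.1, w_min = 0, w_max = 10)
  st <- list(T_p = 0.5, T_d = 0.5, refractory_remaining = 0)
  out <- apply_reward(2, st, tp)
  expect_equal(out$weights, 2)        # equal traces: no change
  st <- list(T_p = 0.8, T_d = 0.3, refractory_remaining = 0)
  out <- apply_reward(2, st, tp)
  expect_equal(out$weights, 2 + 0.1 * 0.5)   # potentiation
  expect_equal(out$state$T_p, 0)
  expect_equal(out$state$T_d, 0)
  expect_equal(out$state$refractory_remaining, 25)
  # during the refractory window Hebbian input is ignored
  st2 <- update_traces(out$state, 1e5, tp, 1)
  expect_equal(st2$T_p, 0)
  st <- list(T_p = 0.1, T_d = 0.6, refractory_remaining = 0)
  expect_lt(apply_reward(2, st, tp)$weights, 2)  # depression
})

test_that("effective trace parameters match limits and long integrations", {
  tp <- trace_params(tau_p = 800, tau_d = 267, eta_p = 0.05, eta_d = 0.05,
                     tmax_p = 1, tmax_d = 1.03)
  e0 <- effective_trace_params(0, tp)
  expect_equal(e0$T_tilde_p, 0)
  expect_equal(e0$tau_tilde_p, 800)
  e_inf <- effective_trace_params(1e9, tp)
  expect_equal(e_inf$T_tilde_p, 1, tolerance = 1e-6)
  expect_equal(e_inf$T_tilde_d, 1.03, tolerance = 1e-6)
  # moderate H: long constant-H Euler integration lands on the formula
  e <- effective_trace_params(40, tp)
  st <- list(T_p = 0, T_d = 0, refractory_remaining = 0)
  for (i in 1:100000) st <- update_traces(st, 40, tp, 0.1)
  expect_equal(st$T_p, e$T_tilde_p, tolerance = 1e-3)
  expect_equal(st$T_d, e$T_tilde_d, tolerance = 1e-3)
})

test_that("falling-phase fixed point matches the numeric trace crossing", {
  tp <- trace_params(tau_p = 800, tau_d = 267, eta_p = 0.05, eta_d = 0.05,
                     tmax_p = 1, tmax_d = 1.05)
  eff <- effective_trace_params(1000, tp)
  expect_equal(falling_fixed_point_D(tp, 1, 1), 0)  # equal saturations
  tp_bad <- trace_params(tau_p = 500, tau_d = 500, eta_p = 1, eta_d = 1)
  expect_error(falling_fixed_point_D(tp_bad, 1, 1), "singular")
  D <- falling_fixed_point_D(tp, eff$T_tilde_p, eff$T_tilde_d)
  # independent oracle: bracketing root of the two decaying exponentials
  gap <- function(t) eff$T_tilde_p * exp(-t / tp$tau_p) -
    eff$T_tilde_d * exp(-t / tp$tau_d)
  D_ref <- uniroot(gap, c(1e-6, 2000), tol = 1e-10)$root
  expect_lt(abs(D - D_ref), 0.1)
  expect_gt(D, 0)
})

test_that("rising-phase fixed point is self-consistent and unique on the bracket", {
  tp <- trace_params(tau_p = 400, tau_d = 1200, eta_p = 0.01, eta_d = 0.002,
                     tmax_p = 1, tmax_d = 1.3, role = "feedforward")
  fp <- rising_fixed_point_H(300, tp)
  expect_lt(fp$residual, 1e-9)
  bal <- function(H) {
    e <- effective_trace_params(H, tp)
    e$T_tilde_p * (1 - exp(-300 / e$tau_tilde_p)) -
      e$T_tilde_d * (1 - exp(-300 / e$tau_tilde_d))
  }
  grid <- 10^seq(-6, 6, length.out = 4000)
  signs <- sign(bal(grid))
  expect_equal(sum(diff(signs[signs != 0]) != 0), 1)  # single sign change
  # wrong parameter ordering is rejected
  tp_rec <- trace_params(tau_p = 800, tau_d = 267, eta_p = 0.05, eta_d = 0.05)
  expect_error(rising_fixed_point_H(300, tp_rec), "ordering")
})

test_that("closed-loop feed-forward learning converges to the rising fixed point", {
  # idealised two-population protocol: presynaptic rate fixed, postsynaptic
  # rate proportional to the weight, reward a fixed time after activation
  tp <- trace_params(tau_p = 400, tau_d = 1200, eta_p = 0.01, eta_d = 0.002,
                     tmax_p = 1, tmax_d = 1.3, r_th = 0.1, eta_lr = 1,
                     w_min = 0, w_max = 1e4, role = "feedforward")
  t_reward <- 250
  r_pre <- 20
  gain <- 1.5    # r_post = gain * W
  W <- 0.3
  for (trial in 1:1500) {
    st <- list(T_p = 0, T_d = 0, refractory_remaining = 0)
    H <- hebbian_term(r_pre, gain * W, tp$r_th)
    for (i in seq_len(t_reward)) st <- update_traces(st, H, tp, 1)
    out <- apply_reward(W, st, tp)
    W <- out$weights
  }
  H_star <- rising_fixed_point_H(t_reward, tp)$H_star
  expect_equal(r_pre * gain * W, H_star, tolerance = 0.02)
})
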