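test_that("reservoir projection is block-structured and gain-scaled", {
  rs <- build_reservoir(K = 300, n_columns = 3, g = 0.9, seed = 2)
  expect_equal(dim(rs$J), c(300, 3))
  expect_true(all(rowSums(rs$J > 0) == 1))
  expect_true(all(rs$J[1:100, 1] > 0))      # first K/n rows read column 1
  expect_true(all(rs$J[101:200, 2] > 0))
  rs2 <- build_reservoir(300, 3, g = 0.9, seed = 2)
  expect_identical(rs$W_res, rs2$W_res)
  expect_error(build_reservoir(2, 3), "at least")
  # empirical variance of the recurrent weights ~ g^2 / K at K = 1000
  big <- build_reservoir(1000, 4, g = 1.2, seed = 5)
  expect_equal(var(as.numeric(big$W_res)), 1.2^2 / 1000, tolerance = 0.05)
})

test_that("sparse projection has the configured non-zero fraction", {
  sp <- build_sparse_pattern(M = 500, K = 200, rho_sparse = 0.04, seed = 3)
  frac <- mean(sp$O != 0)
  expect_equal(frac, 0.04, tolerance = 0.1)
  expect_error(build_sparse_pattern(10, 10, rho_sparse = 0), "rho_sparse")
})

test_that("reservoir step matches a hundred-fold finer integration", {
  rs <- build_reservoir(K = 12, n_columns = 2, g = 0.9, tau_net = 100,
                        theta_m = 1, seed = 4)
  m <- c(30, 0)
  u1 <- rep(0.1, 12)
  for (i in 1:200) u1 <- step_reservoir(u1, m, rs, 1)
  u2 <- rep(0.1, 12)
  for (i in 1:20000) u2 <- step_reservoir(u2, m, rs, 0.01)
  expect_lt(max(abs(u1 - u2)) / max(abs(u2)), 0.01)
})

test_that("patterns are gated by Messenger activity and thresholded", {
  rs <- build_reservoir(K = 50, n_columns = 2, g = 0.9, seed = 6)
  sp <- build_sparse_pattern(M = 200, K = 50, theta_o = 1e6, seed = 6)
  u <- rnorm(50)
  expect_true(all(sparse_pattern(u, c(30, 0), sp, theta_m = 1) == 0))
  sp$theta_o <- 0.01
  nu_on <- sparse_pattern(u, c(30, 0), sp, theta_m = 1)
  expect_gt(sum(nu_on), 0)
  expect_true(all(sparse_pattern(u, c(0.5, 0), sp, theta_m = 1) == 0))
  # determinism: same state, same pattern
  expect_identical(nu_on, sparse_pattern(u, c(30, 0), sp, theta_m = 1))
})

test_that("distinct input histories produce nearly non-overlapping patterns", {
  rs <- build_reservoir(K = 150, n_columns = 3, g = 0.9, tau_net = 400,
                        theta_m = 8, seed = 7, j_scale = 0.15)
  sp <- build_sparse_pattern(M = 400, K = 150, theta_o = 0.055, g = 0.9,
                             seed = 8)
  run_history <- function(seq_cols) {
    u <- rep(0, rs$K)
    for (el in seq_cols) {
      for (i in 1:150) {  # 150 ms Messenger pulse from this column
        m <- rep(0, 3); m[el] <- 45
        u <- step_reservoir(u, m, rs, 1)
      }
      for (i in 1:350) u <- step_reservoir(u, rep(0, 3), rs, 1)  # silence
    }
    u
  }
  u_a <- run_history(c(2, 1))   # history: column 2 then column 1
  u_b <- run_history(c(3, 1))   # history: column 3 then column 1
  nu_a <- sparse_pattern(u_a, c(45, 0, 0), sp, theta_m = 8)
  nu_b <- sparse_pattern(u_b, c(45, 0, 0), sp, theta_m = 8)
  expect_gt(sum(nu_a), 0)
  expect_gt(sum(nu_b), 0)
  expect_lt(pattern_overlap(nu_a, nu_b), 0.5)
  expect_equal(pattern_overlap(nu_a, nu_a), 1)
})

test_that("feedback weights follow the Hebbian product and stay bounded", {
  Q <- matrix(0, 2, 3)
  nu <- c(1, 0, 1)
  Q1 <- update_Q(Q, c(10, 0), nu, dt = 1, q_max = 2)
  expect_equal(Q1[1, 1], 0.01)           # 10 Hz x 1 ms
  expect_equal(Q1[2, ], rep(0, 3))
  expect_equal(Q1[, 2], rep(0, 2))
  expect_identical(update_Q(Q, c(50, 50), c(0, 0, 0), 1, 2), Q)
  for (i in 1:500) Q <- update_Q(Q, c(100, 100), nu, dt = 10, q_max = 2)
  expect_true(all(Q <= 2))
  expect_equal(max(Q), 2)
  # thresholded variant ignores sub-threshold timers
  Q2 <- update_Q(matrix(0, 2, 3), c(10, 40), nu, 1, 2, r_threshold = 25)
  expect_equal(Q2[1, 1], 0)
  expect_equal(Q2[2, 1], 0.04)
})

test_that("Q stays within bounds under randomized stress inputs", {
  set.seed(12)
  Q <- matrix(runif(6, 0, 2), 2, 3)
  for (i in 1:300) {
    Q <- update_Q(Q, runif(2, 0, 300), rbinom(3, 1, 0.5), runif(1, 0.1, 5), 2)
    expect_true(all(Q >= 0 & Q <= 2))
  }
})

test_that("the three-stage extension requires the non-Markovian rate variant", {
  cfg <- default_config()
  net_m <- build_network(3, cfg, backend = "rate", seed = 1)
  expect_error(attach_three_stage(net_m, cfg), "nonmarkov")
  net_s <- suppressWarnings(build_network(2, cfg, backend = "spiking",
                                          sizes = 8, variant = "nonmarkov",
                                          seed = 1))
  expect_error(attach_three_stage(net_s, cfg), "rate backend")
})
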