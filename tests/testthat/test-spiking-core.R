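test_that("leak-only membrane relaxes exponentially toward EL", {
  p <- neuron_params(sigma = 0)
  st <- population_state(1, p, v0 = p$EL + 10)
  dt <- 0.1
  for (i in 1:2000) st <- step_membrane(st, 0, 0, p, dt)  # 200 ms
  tau_m <- p$C / p$gL
  expect_equal(st$v, p$EL + 10 * exp(-200 / tau_m), tolerance = 1e-3)
})

test_that("constant subthreshold excitation converges to the conductance steady state", {
  p <- neuron_params(sigma = 0)
  gE <- 1.5  # keeps v* below threshold
  v_star <- (p$gL * p$EL + gE * p$EE) / (p$gL + gE)
  expect_lt(v_star, p$vth)
  st <- population_state(1, p)
  for (i in 1:20000) st <- step_membrane(st, gE, 0, p, 0.1)
  expect_equal(st$v, v_star, tolerance = 1e-4)
})

test_that("suprathreshold ISI matches a hundred-fold finer integration", {
  p <- neuron_params(sigma = 0)
  gE <- 5  # strongly suprathreshold
  isi_at <- function(dt) {
    st <- population_state(1, p)
    spikes <- c()
    t <- 0
    while (length(spikes) < 4 && t < 300) {
      st <- step_membrane(st, gE, 0, p, dt)
      t <- t + dt
      if (st$spiked) spikes <- c(spikes, t)
    }
    diff(spikes)[2]
  }
  isi_coarse <- isi_at(0.1)
  isi_fine <- isi_at(0.001)
  expect_lt(abs(isi_coarse - isi_fine) / isi_fine, 0.01)
})

test_that("refractory neurons hold the reset potential and do not integrate", {
  p <- neuron_params(sigma = 0, tref = 5)
  st <- population_state(1, p, v0 = p$vth + 1)
  st <- step_membrane(st, 10, 0, p, 0.1)  # spikes, enters refractory
  expect_true(st$spiked)
  st <- step_membrane(st, 10, 0, p, 0.1)
  expect_false(st$spiked)
  expect_equal(st$v, p$vreset)
})

test_that("synaptic activation decays, jumps by rho(1-s), and saturates", {
  s <- update_synaptic_activation(0.5, FALSE, tau_s = 80, rho_syn = 0.05,
                                  dt = 80)
  expect_equal(s, 0.5 * exp(-1))
  s <- update_synaptic_activation(0, TRUE, 80, 0.05, dt = 1e-9)
  expect_equal(s, 0.05, tolerance = 1e-6)
  s <- update_synaptic_activation(1, TRUE, 80, 0.05, dt = 1e-12)
  expect_equal(s, 1, tolerance = 1e-9)
})

test_that("activation stays in [0,1] for any random spike raster", {
  set.seed(42)
  for (rep in 1:5) {
    s <- runif(20)
    for (i in 1:500) {
      spk <- runif(20) < 0.3
      s <- update_synaptic_activation(s, spk, tau_s = 10, rho_syn = 0.9,
                                      dt = 0.5)
      expect_true(all(s >= 0 & s <= 1))
    }
  }
})

test_that("conductances equal the weight block times activations", {
  expect_equal(conductances(matrix(2, 1, 1), NULL, 0.5)$gE, 1)
  expect_equal(conductances(NULL, NULL, rep(1, 3))$gE, 0)
  set.seed(7)
  W_e <- matrix(runif(35), 5, 7)
  W_i <- matrix(runif(35), 5, 7)
  s <- runif(7)
  g <- conductances(W_e, W_i, s)
  # brute-force double loop oracle
  gE_ref <- numeric(5)
  gI_ref <- numeric(5)
  for (i in 1:5) for (j in 1:7) {
    gE_ref[i] <- gE_ref[i] + W_e[i, j] * s[j]
    gI_ref[i] <- gI_ref[i] + W_i[i, j] * s[j]
  }
  expect_equal(g$gE, gE_ref)
  expect_equal(g$gI, gI_ref)
  expect_error(conductances(matrix(-1, 1, 1), NULL, 1), "negative")
})

test_that("rate estimator decays, jumps by 1000/tau_r, and is unbiased for Poisson input", {
  r <- estimate_rates(10, FALSE, tau_r = 50, dt = 50)
  expect_equal(r, 10 * exp(-1))
  r <- estimate_rates(0, TRUE, tau_r = 50, dt = 1e-9)
  expect_equal(r, 1000 / 50, tolerance = 1e-6)
  # Poisson train at 40 Hz, 50 s: time-averaged estimate ~ 40 Hz
  set.seed(11)
  dt <- 1
  r <- 0
  acc <- 0
  n <- 50000
  for (i in 1:n) {
    r <- estimate_rates(r, runif(1) < 40 * dt / 1000, 50, dt)
    acc <- acc + r
  }
  expect_equal(acc / n, 40, tolerance = 0.05)
})

test_that("halving dt changes a deterministic voltage trajectory only slightly", {
  p <- neuron_params(sigma = 0)
  run <- function(dt) {
    st <- population_state(1, p, v0 = p$EL + 5)
    for (i in seq_len(1000 / dt)) st <- step_membrane(st, 1.0, 0.2, p, dt)
    st$v
  }
  expect_lt(abs(run(0.1) - run(0.05)), 0.01)  # first-order Euler, 1 s horizon
})

test_that("without noise or input, network activity decays to silence", {
  cfg <- default_config()
  cfg$neuron$sigma <- 0
  net <- suppressWarnings(build_network(1, cfg, backend = "spiking",
                                        sizes = 10, seed = 1, wta = c(0, 0)))
  out <- simulate_network(net, matrix(0, 0, 4), numeric(0), 500,
                          seed = 1, record_spikes = TRUE)
  expect_true(is.null(out$record$spikes) || nrow(out$record$spikes) == 0)
  expect_true(all(out$record$rates[nrow(out$record$rates), ] == 0))
})
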