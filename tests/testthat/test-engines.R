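# the compiled engines against the composed R reference steps

test_that("spiking engine matches the composed R single-step updates", {
  cfg <- default_config()
  cfg$neuron$sigma <- 0
  cfg$neuron$vth_jitter <- 0
  net <- suppressWarnings(build_network(1, cfg, backend = "spiking",
                                        sizes = 4, seed = 1, wta = c(0, 0)))
  # hand the engine a nonzero initial state and let it run freely
  v0 <- lapply(net$pops, function(p) {
    v <- rep(p$EL, p$size)
    if (p$role == "timer") v <- p$EL + c(12, 8, 4, 2)
    v
  })
  s0 <- lapply(net$pops, function(p) {
    if (p$role == "timer") rep(0.6, p$size) else numeric(p$size)
  })
  out <- simulate_network(net, matrix(0, 0, 4), numeric(0), 20, seed = 1,
                          init = list(v = v0, s = s0))
  # independent reference: compose the exported single-step operations
  np <- do.call(neuron_params,
                c(cfg$neuron[setdiff(names(cfg$neuron), "vth_jitter")]))
  states <- lapply(net$pops, function(pp) {
    st <- population_state(pp$size, np)
    st
  })
  states[[1]]$v <- v0[[1]]
  states[[1]]$s <- s0[[1]]
  dt <- cfg$sim$dt_spiking
  w_of <- function(lbl) Filter(function(g) g$label == lbl, net$groups)[[1]]
  r_tr <- NULL
  for (step in 0:(20 / dt)) {
    sT <- states[[1]]$s
    g_ti <- w_of("w_t_ti")$w * sum(sT)    # uniform blocks: w * sum(s_pre)
    g_tm <- w_of("w_tm")$w * sum(sT)
    g_tt <- as.numeric(w_of("w_tt")$W %*% sT)
    g_im <- w_of("w_im")$w * sum(states[[2]]$s)
    g_mmi <- w_of("w_m_mi")$w * sum(states[[3]]$s)
    g_mim <- w_of("w_mi_m")$w * sum(states[[4]]$s)
    tau_s_of <- c(80, 10, 80, 10)
    gE <- list(g_tt, rep(g_ti, 4), rep(g_tm, 4), rep(g_mmi, 4))
    gI <- list(rep(0, 4), rep(0, 4), rep(g_im + g_mim, 4), rep(0, 4))
    for (k in 1:4) {
      states[[k]] <- step_membrane(states[[k]], gE[[k]], gI[[k]], np, dt)
      states[[k]]$s <- update_synaptic_activation(
        states[[k]]$s, states[[k]]$spiked, tau_s_of[k], np$rho_syn, dt)
      states[[k]]$r <- estimate_rates(states[[k]]$r, states[[k]]$spiked,
                                      np$tau_r, dt)
    }
    # the engine samples after the in-step update
    if (step %% (cfg$sim$record_dt / dt) == 0) {
      r_tr <- rbind(r_tr, vapply(states, function(st) mean(st$r), 1))
    }
  }
  expect_equal(unname(out$record$rates), unname(r_tr[seq_len(
    nrow(out$record$rates)), ]), tolerance = 1e-8)
})

test_that("rate engine matches the composed R rate steps", {
  cfg <- default_config()
  net <- suppressWarnings(build_network(1, cfg, backend = "rate", seed = 1,
                                        wta = c(0, 0)))
  out <- simulate_network(net, matrix(0, 0, 4), numeric(0), 300, seed = 1,
                          init = list(u = c(20, 3, 1, 0)))
  rp <- rate_params(tau_u = 1, theta = cfg$rate$theta, u_c = cfg$rate$u_c,
                    v_scale = cfg$rate$v_scale)
  rm <- ttlnet:::rate_matrices(net)
  rp$tau_u <- rm$tau
  st <- list(u = c(20, 3, 1, 0), r = transfer(c(20, 3, 1, 0), rp))
  ref <- NULL
  for (step in 0:300) {
    st <- step_rate_units(st, rm$W, rp, 1)
    if (step %% 5 == 0) ref <- rbind(ref, st$r)
  }
  expect_equal(unname(out$record$rates),
               unname(ref[seq_len(nrow(out$record$rates)), ]),
               tolerance = 1e-8)
})

test_that("identical seeds give byte-identical spike event files", {
  cfg <- default_config()
  net <- suppressWarnings(build_network(1, cfg, backend = "spiking",
                                        sizes = 8, seed = 1, wta = c(0, 0)))
  r1 <- recall(net, 1, sim_duration = 400, seed = 33)
  r2 <- recall(net, 1, sim_duration = 400, seed = 33)
  f1 <- tempfile(); f2 <- tempfile()
  write_spike_events(r1, f1)
  write_spike_events(r2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  r3 <- recall(net, 1, sim_duration = 400, seed = 34)
  expect_false(identical(r1$spikes, r3$spikes))
})

test_that("divergent rates abort with a diagnostic", {
  cfg <- default_config()
  cfg$sim$rate_ceiling <- 1e-6
  net <- suppressWarnings(build_network(1, cfg, backend = "spiking",
                                        sizes = 8, seed = 1, wta = c(0, 0)))
  expect_error(recall(net, 1, sim_duration = 500, seed = 1), "divergent|exceeded")
})

test_that("training with zero trials leaves the network unchanged", {
  cfg <- default_config()
  net <- build_network(2, cfg, backend = "rate", seed = 1)
  prot <- stimulus_protocol(1:2, c(500, 500))
  out <- train(net, prot, n_trials = 0, seed = 1)
  expect_identical(out$net, net)
})
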