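test_that("default column has four populations wired as a CNA", {
  cfg <- default_config()
  cs <- column_spec(1, weights = cfg$network$weights$spiking)
  cna <- build_cna(cs, do.call(neuron_params,
                               cfg$neuron[setdiff(names(cfg$neuron),
                                                  "vth_jitter")]))
  expect_length(cna$pops, 4)
  expect_equal(sum(vapply(cna$pops, function(p) p$size, 1)), 400)
  labels <- vapply(cna$groups, function(g) g$label, "")
  expect_true(all(c("w_tt", "w_t_ti", "w_tm", "w_im") %in% labels))
  # inhibitory populations carry the short synaptic time constant
  expect_equal(cna$pops[[2]]$tau_s, 10)
  expect_equal(cna$pops[[1]]$tau_s, 80)
  expect_true(cna$groups[[1]]$plastic)
  expect_true(all(cna$groups[[1]]$W > 0))  # random and weak, never negative
})

test_that("an inert column specification is rejected", {
  w0 <- list(w_tt0 = 0.1, w_t_ti = 0, w_tm = 0, w_im = 0, w_m_mi = 0,
             w_mi_m = 0)
  expect_error(column_spec(1, weights = w0), "inert")
  expect_error(column_spec(1, sizes = c(timer = 0, timer_inh = 1,
                                        messenger = 1, messenger_inh = 1)),
               "positive")
})

test_that("plasticity masks match the allowed set for each variant", {
  cfg <- default_config()
  net <- build_network(4, cfg, backend = "rate", seed = 1)
  role_of <- function(i) net$pops[[i]]$role
  col_of <- function(i) net$pops[[i]]$column
  plastic <- Filter(function(g) isTRUE(g$plastic), net$groups)
  for (g in plastic) {
    if (g$class == "recurrent") {
      expect_equal(role_of(g$pre), "timer")
      expect_equal(role_of(g$post), "timer")
      expect_equal(col_of(g$pre), col_of(g$post))
    } else {
      expect_equal(role_of(g$pre), "messenger")
      expect_equal(role_of(g$post), "timer")
      expect_false(col_of(g$pre) == col_of(g$post))
    }
  }
  # no plastic group originates from a Timer onto a foreign population
  bad <- Filter(function(g) isTRUE(g$plastic) && role_of(g$pre) == "timer" &&
                  col_of(g$pre) != col_of(g$post), net$groups)
  expect_length(bad, 0)
  # counts: one recurrent group per column plus all-to-all feed-forward
  expect_equal(sum(vapply(plastic, function(g) g$class == "recurrent", TRUE)), 4)
  expect_equal(sum(vapply(plastic, function(g) g$class == "feedforward", TRUE)),
               4 * 3)
  # non-Markovian variant removes the direct Messenger-to-Timer path
  nm <- build_network(4, cfg, backend = "rate", variant = "nonmarkov",
                      seed = 1)
  pl_nm <- Filter(function(g) isTRUE(g$plastic), nm$groups)
  expect_true(all(vapply(pl_nm, function(g) g$class == "recurrent", TRUE)))
})

test_that("twelve columns by default; zero WTA permitted with a warning", {
  cfg <- default_config()
  net <- build_network(config = cfg, backend = "rate", seed = 1)
  expect_equal(net$n_columns, 12)
  expect_equal(vapply(net$columns, function(cc) cc$stimulus_id, 1), 1:12)
  expect_warning(build_network(2, cfg, backend = "rate", wta = 0, seed = 1),
                 "WTA")
})

test_that("LGN input is pulsed, Poissonian and deterministic under a seed", {
  prot <- stimulus_protocol(1:2, c(500, 700), pulse_ms = 50,
                            peak_rate_hz = 800)
  a <- generate_lgn_input(prot, seed = 5)
  b <- generate_lgn_input(prot, seed = 5)
  expect_identical(a, b)
  # input confined to the first 50 ms of each element
  el2 <- unlist(a[[2]])
  expect_true(all(el2 >= 500 & el2 <= 550))
  # Poisson count statistics over many draws
  counts <- vapply(1:200, function(s) {
    length(generate_lgn_input(prot, seed = s)[[1]][[1]])
  }, 1)
  lambda <- 800 * 0.05
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 200))
})

test_that("fixed-weight perturbation is bounded, seeded and identity at zero", {
  cfg <- default_config()
  net <- build_network(2, cfg, backend = "rate", seed = 1)
  same <- perturb_fixed_weights(net, 0, seed = 3)
  expect_identical(lapply(same$groups, `[[`, "w"),
                   lapply(net$groups, `[[`, "w"))
  p1 <- perturb_fixed_weights(net, 0.2, seed = 3)
  p2 <- perturb_fixed_weights(net, 0.2, seed = 3)
  expect_identical(lapply(p1$groups, `[[`, "w"),
                   lapply(p2$groups, `[[`, "w"))
  for (i in seq_along(net$groups)) {
    g0 <- net$groups[[i]]
    g1 <- p1$groups[[i]]
    if (g0$label %in% c("w_tm", "w_im")) {
      ratio <- g1$w / g0$w
      expect_gte(ratio, 0.8)
      expect_lte(ratio, 1.2)
    } else if (isTRUE(g0$uniform)) {
      expect_identical(g1$w, g0$w)
    }
  }
  expect_error(perturb_fixed_weights(net, 1), "magnitude")
})

test_that("pre-learning spiking CNA: brief transient, Messenger at the end", {
  cfg <- default_config()
  net <- suppressWarnings(build_network(1, cfg, backend = "spiking",
                                        sizes = 20, seed = 1, wta = c(0, 0)))
  rec <- recall(net, 1, sim_duration = 2000, seed = 2, record_spikes = FALSE)
  tmr <- rec$rates[, "c1.timer"]
  msg <- rec$rates[, "c1.messenger"]
  iv <- timer_intervals(rec, 1, min_peak_hz = 10)
  expect_equal(nrow(iv), 1)              # transient response only
  expect_lt(iv$duration[1], 800)         # a few hundred ms before learning
  expect_gt(iv$duration[1], 30)
  # Messenger peak occurs after the Timer peak
  expect_gt(rec$time[which.max(msg)], rec$time[which.max(tmr)])
  # the Messenger's inhibition is carried by fast synapses, its excitation
  # by slow ones; that asymmetry is what opens the end-of-element window
  expect_lt(net$pops[[2]]$tau_s, net$pops[[1]]$tau_s)
})
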