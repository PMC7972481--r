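# Wrappers translating a ttl_network plus a schedule of inputs and
# neuromodulator events into a call to the compiled engine, and back.

pop_label <- function(pop) paste0("c", pop$column, ".", pop$role)

engine_pops <- function(net) {
  lapply(net$pops, function(p) {
    list(size = p$size, C = p$C, gL = p$gL, EL = p$EL, EE = p$EE, EI = p$EI,
         vth = p$vth, vreset = p$vreset, tref = p$tref, sigma = p$sigma,
         tau_s = p$tau_s, rho_syn = p$rho_syn, tau_r = p$tau_r,
         tau_s_in = p$tau_s_in)
  })
}

engine_groups <- function(net) {
  cfg <- net$config
  lapply(net$groups, function(g) {
    out <- list(pre = g$pre, post = g$post, cls = g$cls,
                uniform = isTRUE(g$uniform), w = g$w, W = g$W,
                plastic = isTRUE(g$plastic))
    if (out$plastic) {
      tp <- cfg$learning[[net$backend]][[g$class]]
      n_pre <- net$pops[[g$pre]]$size
      # per-synapse learning rate and bound scale with 1/n_pre so the summed
      # drive behaves the same at any population size
      tp$eta_lr <- tp$eta_lr / n_pre
      tp$w_max <- tp$w_max / n_pre
      tp$w_min <- tp$w_min / n_pre
      out$tp <- tp
    }
    out
  })
}

plastic_labels <- function(net) {
  lab <- vapply(net$groups, function(g) {
    if (!isTRUE(g$plastic)) return(NA_character_)
    if (g$class == "recurrent") paste0("w_tt.c", g$column)
    else paste0("w_ff.c", g$from_column, ".c", g$to_column)
  }, "")
  lab[!is.na(lab)]
}

rate_unit_tau <- function(net) {
  vapply(net$pops, function(p) {
    switch(p$role,
           timer_inh = ,
           messenger_inh = net$config$rate$tau_u_inh,
           messenger = net$config$rate$tau_u_mess,
           net$config$rate$tau_u_exc)
  }, 1)
}

rate_matrices <- function(net) {
  n <- length(net$pops)
  W <- matrix(0, n, n)
  pl <- list()
  for (g in net$groups) {
    w <- if (isTRUE(g$uniform)) g$w else g$W[1, 1]
    sgn <- if (g$cls == "I") -1 else 1
    W[g$post, g$pre] <- W[g$post, g$pre] + sgn * w
    if (isTRUE(g$plastic)) {
      pl[[length(pl) + 1L]] <- c(g$pre, g$post,
                                 if (g$class == "recurrent") 1L else 2L)
    }
  }
  plastic <- if (length(pl)) do.call(rbind, pl) else
    matrix(integer(0), 0, 3)
  storage.mode(plastic) <- "integer"
  list(W = W, plastic = plastic, tau = rate_unit_tau(net))
}

timer_pop_index <- function(net, column) (column - 1L) * 4L + 1L

# Input intervals (t0, t1, column, raw amplitude) are rendered onto each
# column's Timer population and, as feedforward inhibition, onto its
# Messenger-inhibitory partner.  The spiking backend receives Poisson rates
# plus synapse weights; the rate backend receives injected amplitudes.
expand_inputs <- function(net, inputs) {
  w <- net$config$network$weights[[net$backend]]
  if (nrow(inputs) == 0) return(matrix(0, 0, 5))
  t_pop <- (inputs[, 3] - 1L) * 4L + 1L
  mi_pop <- (inputs[, 3] - 1L) * 4L + 4L
  if (net$backend == "spiking") {
    out <- rbind(cbind(inputs[, 1], inputs[, 2], t_pop, inputs[, 4], w$w_in),
                 cbind(inputs[, 1], inputs[, 2], mi_pop, inputs[, 4],
                       w$w_in_mi))
  } else {
    out <- rbind(cbind(inputs[, 1], inputs[, 2], t_pop,
                       inputs[, 4] * w$w_in, 0),
                 cbind(inputs[, 1], inputs[, 2], mi_pop,
                       inputs[, 4] * w$w_in_mi, 0))
  }
  out[order(out[, 3], out[, 1]), , drop = FALSE]
}

#' Run one simulation of a network
#'
#' Low-level runner: takes explicit input intervals and neuromodulator event
#' times, simulates for `t_total` ms on the network's backend, and returns a
#' `ttl_record`.  [train()] and [recall()] are the high-level entry points.
#'
#' @param net a `ttl_network`.
#' @param inputs matrix with columns (t0, t1, column, amplitude): input
#'   intervals routed to each column (Poisson peak rate for the spiking
#'   backend, injected amplitude for the rate backend).
#' @param rewards neuromodulator event times (ms); ignored unless `learn`.
#' @param t_total simulation length (ms).
#' @param learn enable plasticity (training runs); recall runs freeze
#'   weights.
#' @param seed RNG seed (input spikes and membrane noise).
#' @param record_spikes record individual spike events (spiking backend).
#' @param snapshot_times times at which plastic weights are snapshotted.
#' @param init optional initial state (backend-specific).
#'
#' @return A list with the updated network (`net`) and the simulation record
#'   (`record`).
#' @export
simulate_network <- function(net, inputs, rewards, t_total, learn = FALSE,
                             seed = 1, record_spikes = FALSE,
                             snapshot_times = numeric(0), init = NULL) {
  set.seed(seed)
  cfg <- net$config

  if (net$backend == "spiking") {
    inp <- expand_inputs(net, inputs)
    res <- sim_spiking_cpp(engine_pops(net), engine_groups(net), inp,
                           rewards, t_total, cfg$sim$dt_spiking, learn,
                           cfg$sim$record_dt, snapshot_times, record_spikes,
                           cfg$sim$rate_ceiling, cfg$sim$trace_dt, init)
    for (i in seq_along(net$groups)) {
      if (isTRUE(net$groups[[i]]$plastic)) net$groups[[i]]$W <- res$weights[[i]]
    }
    dt <- cfg$sim$dt_spiking
  } else {
    rm <- rate_matrices(net)
    inp <- expand_inputs(net, inputs)
    tcl <- list(cfg$learning$rate$recurrent, cfg$learning$rate$feedforward)
    ts <- NULL
    if (!is.null(net$three_stage)) {
      s3 <- net$three_stage
      ts <- list(J = s3$reservoir$J, W_res = s3$reservoir$W_res,
                 O = s3$sparse$O, Q = s3$Q,
                 mess_idx = vapply(seq_len(net$n_columns),
                                   function(k) (k - 1L) * 4L + 3L, 1L),
                 timer_idx = vapply(seq_len(net$n_columns),
                                    function(k) timer_pop_index(net, k), 1L),
                 tau_net = s3$reservoir$tau_net,
                 theta_m = s3$reservoir$theta_m,
                 theta_o = s3$sparse$theta_o, q_max = s3$sparse$q_max,
                 q_rth = cfg$nonmarkov$q_rth %||% 0,
                 q_learn = learn,
                 q_drive = !learn || isTRUE(cfg$nonmarkov$feedback_during_training),
                 record_nu = isTRUE(attr(net$three_stage, "record_nu")),
                 u_res0 = init$u_res)
    }
    res <- sim_rate_cpp(rm$W, rm$tau, cfg$rate$theta, cfg$rate$u_c,
                        cfg$rate$v_scale, inp, rm$plastic, tcl, rewards,
                        t_total, cfg$sim$dt_rate, learn, cfg$sim$record_dt,
                        snapshot_times, cfg$sim$rate_ceiling, init$u, ts)
    if (nrow(rm$plastic) > 0) {
      for (i in seq_along(net$groups)) {
        g <- net$groups[[i]]
        if (isTRUE(g$plastic)) {
          net$groups[[i]]$W <- matrix(res$W[g$post, g$pre], 1, 1)
        }
      }
    }
    if (!is.null(net$three_stage)) {
      net$three_stage$Q <- res$Q
      attr(net$three_stage, "u_res_final") <- res$u_res_final
    }
    dt <- cfg$sim$dt_rate
  }

  rates <- res$rates
  colnames(rates) <- vapply(net$pops, pop_label, "")
  plab <- plastic_labels(net)
  for (nm in c("trace_p", "trace_d", "hebb")) {
    if (ncol(res[[nm]]) == length(plab)) colnames(res[[nm]]) <- plab
  }
  spikes <- NULL
  if (net$backend == "spiking" && nrow(res$spikes) > 0) {
    spikes <- data.frame(time_ms = res$spikes[, 1],
                         population_id = res$spikes[, 2],
                         neuron_index = res$spikes[, 3])
  }
  snapshots <- res$snapshots
  if (length(plab) && ncol(snapshots) == length(plab)) {
    colnames(snapshots) <- plab
  }
  record <- structure(list(
    time = as.numeric(res$time), rates = rates, spikes = spikes,
    trace_p = res$trace_p, trace_d = res$trace_d, hebb = res$hebb,
    snapshots = snapshots, reward_log = res$reward_log,
    reward_times = rewards, backend = net$backend, dt = dt,
    n_columns = net$n_columns, seed = seed, t_total = t_total,
    nu = res$nu, learn = learn), class = "ttl_record")
  list(net = net, record = record)
}

#' @export
print.ttl_record <- function(x, ...) {
  cat("ttl_record:", x$backend, "backend,", round(x$t_total), "ms,",
      ncol(x$rates), "populations\n")
  if (!is.null(x$spikes)) cat("  spikes recorded:", nrow(x$spikes), "\n")
  if (nrow(x$snapshots) > 0) cat("  weight snapshots:", nrow(x$snapshots), "\n")
  invisible(x)
}
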