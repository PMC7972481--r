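#' Specification of one stimulus-selective column
#'
#' A column houses one core microcircuit (CNA): an excitatory Timer
#' population, its inhibitory partner, an excitatory Messenger population and
#' its inhibitory partner.  The fixed (non-learned) weights establish the
#' Timer/Messenger division of labour: Timers excite the inhibitory cells and
#' the Messengers; the inhibitory cells decay faster than the Timers (short
#' inhibitory synaptic time constant and small Timer-to-inhibitory weight),
#' so the Messengers are unmasked and fire selectively near the end of the
#' Timer transient.
#'
#' Weight values are totals: the per-synapse weight in a population of
#' `n` presynaptic neurons is `value / n`, so the summed drive is
#' approximately independent of the population size.
#'
#' @param stimulus_id the stimulus this column is selective for (integer).
#' @param sizes named vector of population sizes (`timer`, `timer_inh`,
#'   `messenger`, `messenger_inh`).
#' @param weights named list of fixed weight totals: `w_t_ti` (Timer to
#'   inhibitory), `w_tm` (Timer to Messenger, the static weight
#'   `W_EE^MT`), `w_im` (inhibitory to Messenger, `W_EI^MT`), `w_m_mi` and
#'   `w_mi_m` (Messenger/inhibitory partners), and `w_tt0`, the weak random
#'   initial value of the plastic recurrent Timer weight.
#'
#' @return A `column_spec` object.
#' @export
column_spec <- function(stimulus_id,
                        sizes = c(timer = 100, timer_inh = 100,
                                  messenger = 100, messenger_inh = 100),
                        weights = list()) {
  stopifnot(
    "population sizes must be positive" = all(sizes > 0),
    "exactly one stimulus id per column" = length(stimulus_id) == 1
  )
  fixed <- weights[c("w_t_ti", "w_tm", "w_im", "w_m_mi", "w_mi_m")]
  if (any(unlist(fixed) < 0)) stop("fixed weights must be non-negative")
  if (all(unlist(fixed[c("w_t_ti", "w_tm", "w_im")]) == 0)) {
    stop("all core fixed weights are zero: the column would be inert")
  }
  structure(list(stimulus_id = stimulus_id, sizes = sizes, weights = weights),
            class = "column_spec")
}

pop_roles <- c("timer", "timer_inh", "messenger", "messenger_inh")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the populations and fixed synapse groups of one CNA column
#'
#' Wires the four populations of a column: Timer to inhibitory, Timer to
#' Messenger (fixed excitation), inhibitory to Messenger (fixed, faster
#' decaying inhibition), the Messenger inhibitory partner, and the plastic
#' recurrent Timer group initialised random and weak.
#'
#' @param spec a [column_spec()].
#' @param neuron_params a [neuron_params()] object for the excitatory
#'   populations; inhibitory populations get the short synaptic time constant
#'   `tau_s_inh`.
#' @param tau_s_inh inhibitory synaptic time constant (ms).
#' @param base 0-based population index offset (used when assembling columns
#'   into a network).
#'
#' @return List with `pops` (population descriptors) and `groups` (synapse
#'   group descriptors with population indices relative to `base`).
#' @export
build_cna <- function(spec, neuron_params, tau_s_inh = 10, base = 0) {
  np <- neuron_params
  w <- spec$weights
  mk_pop <- function(role, size) {
    p <- unclass(np)
    if (role %in% c("timer_inh", "messenger_inh")) p$tau_s <- tau_s_inh
    c(list(size = size, role = role, column = spec$stimulus_id), p)
  }
  pops <- mapply(mk_pop, pop_roles, spec$sizes[pop_roles], SIMPLIFY = FALSE)
  idx <- function(role) base + match(role, pop_roles)
  n_t <- spec$sizes[["timer"]]
  grp <- function(pre, post, cls, wval, plastic = FALSE, W = NULL,
                  label = "") {
    list(pre = idx(pre), post = idx(post), cls = cls,
         uniform = is.null(W), w = wval, W = W, plastic = plastic,
         class = if (plastic) "recurrent" else NA_character_, label = label,
         column = spec$stimulus_id)
  }
  groups <- list(
    grp("timer", "timer", "E", NA, plastic = TRUE,
        W = matrix(stats::runif(n_t^2, 0.5, 1.5) * w$w_tt0 / n_t, n_t, n_t),
        label = "w_tt"),
    grp("timer", "timer_inh", "E", w$w_t_ti / n_t, label = "w_t_ti"),
    grp("timer_inh", "timer", "I",
        (w$w_ti_t %||% 0) / spec$sizes[["timer_inh"]], label = "w_ti_t"),
    grp("timer", "messenger", "E", w$w_tm / n_t, label = "w_tm"),
    grp("timer_inh", "messenger", "I",
        w$w_im / spec$sizes[["timer_inh"]], label = "w_im"),
    grp("messenger", "messenger_inh", "E",
        w$w_m_mi / spec$sizes[["messenger"]], label = "w_m_mi"),
    grp("messenger_inh", "messenger", "I",
        w$w_mi_m / spec$sizes[["messenger_inh"]], label = "w_mi_m")
  )
  list(pops = pops, groups = groups)
}

#' Assemble a multi-column network
#'
#' Builds `n_columns` stimulus-selective CNA columns, installs soft
#' winner-take-all inhibition between homologous Timer populations and
#' between homologous Messenger populations of different columns, and lays
#' down the plastic synapse groups allowed by the chosen variant:
#' \describe{
#'   \item{markov}{recurrent Timer-to-Timer within each column, plus
#'     all-to-all feed-forward Messenger-to-Timer groups across columns.}
#'   \item{nonmarkov}{recurrent Timer-to-Timer only; the direct
#'     Messenger-to-Timer path is removed and replaced by the sparse pattern
#'     net (see [attach_three_stage()]).}
#' }
#' Timer cells never learn connections onto foreign populations, and
#' Messenger cells never learn connections within their own column.
#'
#' @param n_columns number of columns (each selective for one stimulus id,
#'   numbered 1..n).
#' @param config a configuration list from [default_config()] or
#'   [load_config()].
#' @param backend `"spiking"` or `"rate"`.
#' @param sizes optional scalar or named vector overriding population sizes
#'   (the rate backend always uses one unit per population).
#' @param variant `"markov"` or `"nonmarkov"`.
#' @param wta winner-take-all inhibition strength; defaults to the config
#'   value.  Zero is permitted (with a warning): WTA is a guard against
#'   spurious runaway excitation in the noisy spiking regime and is generally
#'   unnecessary in the low-noise case.
#' @param seed seed for the weak random initial plastic weights.
#'
#' @return A `ttl_network` object.
#' @export
build_network <- function(n_columns = 12, config = default_config(),
                          backend = config$backend, sizes = NULL,
                          variant = c("markov", "nonmarkov"), wta = NULL,
                          seed = 1) {
  variant <- match.arg(variant)
  stopifnot(n_columns >= 1)
  backend <- match.arg(backend, c("spiking", "rate"))
  set.seed(seed)

  wcfg <- config$network$weights[[backend]]
  if (is.null(wta)) {
    wta <- c(t = wcfg$wta_t, m = wcfg$wta_m)
  } else {
    wta <- c(t = wta[[1]], m = if (length(wta) > 1) wta[[2]] else wta[[1]])
  }
  if (all(wta == 0)) {
    warning("WTA inhibition disabled; acceptable in the low-noise regime")
  }

  if (backend == "rate") {
    sz <- c(timer = 1, timer_inh = 1, messenger = 1, messenger_inh = 1)
  } else if (is.null(sizes)) {
    sz <- c(timer = config$network$sizes$timer,
            timer_inh = config$network$sizes$timer_inh,
            messenger = config$network$sizes$messenger,
            messenger_inh = config$network$sizes$messenger_inh)
  } else if (length(sizes) == 1) {
    sz <- c(timer = sizes, timer_inh = sizes, messenger = sizes,
            messenger_inh = sizes)
  } else {
    sz <- sizes[pop_roles]
  }

  np_args <- config$neuron
  vth_jitter <- np_args$vth_jitter %||% 0
  np_args$vth_jitter <- NULL
  np <- do.call(neuron_params, np_args)
  cols <- vector("list", n_columns)
  pops <- list()
  groups <- list()
  for (k in seq_len(n_columns)) {
    cs <- column_spec(k, sizes = sz, weights = wcfg)
    cols[[k]] <- cs
    cna <- build_cna(cs, np, tau_s_inh = config$neuron_inh$tau_s,
                     base = (k - 1) * 4L)
    if (backend == "spiking" && vth_jitter > 0) {
      # per-neuron threshold heterogeneity: smooths the population transfer
      # so recruitment (and the recurrent transient) is graded, not all-or-none
      cna$pops <- lapply(cna$pops, function(p) {
        p$vth <- p$vth + stats::runif(p$size, -vth_jitter, vth_jitter)
        p
      })
    }
    pops <- c(pops, cna$pops)
    groups <- c(groups, cna$groups)
  }
  if (anyDuplicated(vapply(cols, function(cc) cc$stimulus_id, 1)) > 0) {
    stop("duplicate stimulus ids across columns")
  }

  pidx <- function(col, role) (col - 1L) * 4L + match(role, pop_roles)
  for (k in seq_len(n_columns)) {
    for (l in seq_len(n_columns)) {
      if (l == k) next
      n_t <- sz[["timer"]]
      if (wta[["t"]] > 0) {
        groups[[length(groups) + 1L]] <- list(
          pre = pidx(k, "timer"), post = pidx(l, "timer"), cls = "I",
          uniform = TRUE, w = wta[["t"]] / n_t, W = NULL, plastic = FALSE,
          class = NA_character_, label = "wta_t", column = NA)
      }
      if (wta[["m"]] > 0) {
        # Messenger WTA routed as long-range excitation onto the local
        # Messenger-inhibitory partner (which also shields against the brief
        # onset transient when a column is ignited)
        groups[[length(groups) + 1L]] <- list(
          pre = pidx(k, "messenger"), post = pidx(l, "messenger_inh"),
          cls = "E", uniform = TRUE, w = wta[["m"]] / sz[["messenger"]],
          W = NULL, plastic = FALSE, class = NA_character_, label = "wta_m",
          column = NA)
      }
      if (variant == "markov") {
        n_m <- sz[["messenger"]]
        groups[[length(groups) + 1L]] <- list(
          pre = pidx(k, "messenger"), post = pidx(l, "timer"), cls = "E",
          uniform = FALSE, w = NA,
          W = matrix(stats::runif(sz[["timer"]] * n_m, 0, wcfg$w_ff0) / n_m,
                     sz[["timer"]], n_m),
          plastic = TRUE, class = "feedforward", label = "w_ff",
          column = NA, from_column = k, to_column = l)
      }
    }
  }

  net <- structure(list(
    backend = backend, n_columns = n_columns, variant = variant,
    columns = cols, sizes = sz, pops = pops, groups = groups,
    neuron = np, config = config, wta = wta, three_stage = NULL,
    init_seed = seed), class = "ttl_network")
  net
}

#' @export
print.ttl_network <- function(x, ...) {
  npl <- sum(vapply(x$groups, function(g) isTRUE(g$plastic), TRUE))
  cat("ttl_network:", x$n_columns, "columns,", x$backend, "backend,",
      x$variant, "variant\n")
  cat("  populations:", length(x$pops), " synapse groups:", length(x$groups),
      sprintf(" (%d plastic)\n", npl))
  if (!is.null(x$three_stage)) {
    cat("  three-stage extension: K =", nrow(x$three_stage$reservoir$W_res),
        " sparse units =", nrow(x$three_stage$sparse$O), "\n")
  }
  invisible(x)
}

#' Ordered stimulus protocol
#'
#' An ordered list of (element id, duration) pairs.  Elements are contiguous
#' within a trial: element k+1 begins when element k ends.  Each element is
#' rendered as LGN-like input: an independent Poisson pulse at the peak rate
#' during the first `pulse_ms` of the element, routed to the Timer cells of
#' that element's column.
#'
#' @param elements integer element ids (must map to existing columns).
#' @param durations element durations (ms), all positive.
#' @param pulse_ms input pulse width (ms).
#' @param peak_rate_hz Poisson peak rate of the input pulse (spiking
#'   backend).
#' @param input_amp input amplitude during the pulse (rate backend).
#' @param gap_ms inter-trial gap (ms).
#' @param n_trials default number of training trials.
#' @param labels optional element labels (e.g. colour names).
#'
#' @return A `stimulus_protocol` data frame with one row per element.
#' @export
stimulus_protocol <- function(elements, durations, pulse_ms = 50,
                              peak_rate_hz = 800, input_amp = 50,
                              gap_ms = 4000, n_trials = 80, labels = NULL) {
  stopifnot("durations must be positive" = all(durations > 0),
            length(elements) == length(durations))
  onset <- c(0, cumsum(durations))[seq_along(durations)]
  p <- data.frame(element = as.integer(elements), duration = durations,
                  onset = onset,
                  label = if (is.null(labels)) as.character(elements) else labels)
  attr(p, "pulse_ms") <- pulse_ms
  attr(p, "peak_rate_hz") <- peak_rate_hz
  attr(p, "input_amp") <- input_amp
  attr(p, "gap_ms") <- gap_ms
  attr(p, "n_trials") <- n_trials
  class(p) <- c("stimulus_protocol", "data.frame")
  p
}

#' LGN-like input spike trains for a protocol
#'
#' For each element occurrence, draws an independent Poisson spike train at
#' the peak rate confined to the first `pulse_ms` of the element (the input
#' layer responds with a short pulsed peak; the remainder of the element
#' carries no input).  Deterministic given the seed.
#'
#' @param protocol a [stimulus_protocol()].
#' @param seed RNG seed.
#' @param n_channels independent channels per element occurrence.
#'
#' @return A list with one entry per element occurrence, each a list of
#'   numeric spike-time vectors (one per channel), plus `onset` and
#'   `element` attributes.
#' @export
generate_lgn_input <- function(protocol, seed = 1, n_channels = 1) {
  set.seed(seed)
  pulse <- attr(protocol, "pulse_ms")
  rate <- attr(protocol, "peak_rate_hz")
  lapply(seq_len(nrow(protocol)), function(i) {
    trains <- lapply(seq_len(n_channels), function(ch) {
      nspk <- stats::rpois(1, rate * pulse / 1000)
      sort(stats::runif(nspk, 0, pulse)) + protocol$onset[i]
    })
    structure(trains, onset = protocol$onset[i],
              element = protocol$element[i])
  })
}

#' Randomly perturb the fixed CNA weights
#'
#' Multiplies each targeted fixed weight by an independent draw from
#' `U[1 - magnitude, 1 + magnitude]`.  The default targets are the two static
#' weights that establish the Messenger response, Timer-to-Messenger
#' excitation (`w_tm`) and inhibitory-to-Messenger inhibition (`w_im`), with
#' an independent draw per column and per weight class.
#'
#' @param net a `ttl_network`.
#' @param magnitude perturbation magnitude in `[0, 1)`; 0.2 means +/- 20%.
#' @param seed RNG seed (same seed, same perturbation).
#' @param labels which fixed weight labels to perturb.
#'
#' @return The perturbed network.
#' @export
perturb_fixed_weights <- function(net, magnitude, seed = 1,
                                  labels = c("w_tm", "w_im")) {
  stopifnot("magnitude must be in [0, 1)" = magnitude >= 0 && magnitude < 1)
  set.seed(seed)
  net$groups <- lapply(net$groups, function(g) {
    if (!isTRUE(g$plastic) && g$label %in% labels) {
      f <- stats::runif(1, 1 - magnitude, 1 + magnitude)
      if (g$uniform) g$w <- g$w * f else g$W <- g$W * f
    }
    g
  })
  net
}
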