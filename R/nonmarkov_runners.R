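#' Active Timer intervals of one column
#'
#' Finds every interval during which a column's Timer mean rate stays above
#' the onset threshold (with debounced offsets), so repeated activations of
#' the same column — as happen when an element occurs several times in a
#' sequence — are measured separately.
#'
#' @param record a `ttl_record`.
#' @param column column id.
#' @param onset_frac,offset_frac,debounce_ms,min_peak_hz as in
#'   [extract_elements()].
#'
#' @return Data frame with `onset`, `offset`, `duration` (one row per
#'   activation; zero rows if the column never activates).
#' @export
timer_intervals <- function(record, column, onset_frac = 0.5,
                            offset_frac = 0.5, debounce_ms = 50,
                            min_peak_hz = 5) {
  r <- record$rates[, paste0("c", column, ".timer")]
  tt <- record$time
  dt_rec <- if (length(tt) > 1) tt[2] - tt[1] else 1
  pk <- max(r)
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      duration = numeric(0))
  if (pk < min_peak_hz) return(empty)
  need <- max(1L, ceiling(debounce_ms / dt_rec))
  out <- empty
  i <- 1L
  n <- length(r)
  while (i <= n) {
    on_rel <- which(r[i:n] >= onset_frac * pk)[1]
    if (is.na(on_rel)) break
    on_i <- i + on_rel - 1L
    below <- r < offset_frac * pk
    run <- 0L
    off_i <- NA_integer_
    j <- on_i
    while (j <= n) {
      if (below[j]) {
        run <- run + 1L
        if (run >= need) { off_i <- j - run + 1L; break }
      } else run <- 0L
      j <- j + 1L
    }
    if (is.na(off_i)) off_i <- n
    out <- rbind(out, data.frame(onset = tt[on_i], offset = tt[off_i],
                                 duration = tt[off_i] - tt[on_i]))
    i <- off_i + need
  }
  out
}

#' Element order expressed in a recall record
#'
#' Collects every Timer activation interval across the given columns and
#' returns them in onset order, giving the occurrence-level sequence the
#' network expressed (repeated elements appear once per activation).
#'
#' @param record a `ttl_record`.
#' @param columns columns to scan (default all).
#' @param ... passed to [timer_intervals()].
#'
#' @return Data frame with `element`, `onset`, `offset`, `duration`, sorted
#'   by onset.
#' @export
recall_order <- function(record, columns = NULL, ...) {
  if (is.null(columns)) columns <- seq_len(record$n_columns)
  rows <- do.call(rbind, lapply(columns, function(k) {
    iv <- timer_intervals(record, k, ...)
    if (nrow(iv) == 0) return(NULL)
    cbind(element = k, iv)
  }))
  if (is.null(rows)) {
    return(data.frame(element = integer(0), onset = numeric(0),
                      offset = numeric(0), duration = numeric(0)))
  }
  rows[order(rows$onset), ]
}

# Repeated-element protocols see extra neuromodulator events between the
# occurrences of the same element; the trial-sum fixed point then needs a
# larger LTD saturation to balance, configured in the nonmarkov section.
nonmarkov_overrides <- function(config) {
  if (!is.null(config$nonmarkov$tmax_d)) {
    config$learning$rate$recurrent$tmax_d <- config$nonmarkov$tmax_d
  }
  if (!is.null(config$nonmarkov$wta_t)) {
    config$network$weights$rate$wta_t <- config$nonmarkov$wta_t
  }
  config
}

#' Train and recall the six-element non-Markovian sequence
#'
#' End-to-end three-stage run on the BGBRBO protocol (blue appears three
#' times, each time followed by a different element): builds a four-column
#' rate network without the direct Messenger-to-Timer path, attaches the
#' reservoir and sparse pattern net, trains Timer durations (two-trace rule)
#' and pattern-to-Timer feedback (Hebbian) jointly, then recalls from a blue
#' cue with sparse-pattern recording enabled.
#'
#' @param config configuration list.
#' @param seed root seed.
#' @param n_trials training trials.
#'
#' @return List with the trained `net`, the recall `record`, the recall
#'   `order` (occurrence-level), and a `summary` containing the expressed
#'   element order, the number of correct history-dependent transitions out
#'   of blue, and the pairwise overlaps of the sparse patterns at the three
#'   blue offsets.
#' @export
run_nonmarkov_sequence <- function(config = default_config(), seed = 1,
                                   n_trials = 40) {
  config <- nonmarkov_overrides(config)
  prot <- make_fixture("six_element_nonmarkov",
                       input_amp = config$protocol$input_amp,
                       gap_ms = config$nonmarkov$gap_ms)
  net <- build_network(4, config, backend = "rate", variant = "nonmarkov",
                       seed = seed)
  net <- attach_three_stage(net, config, seed = seed)
  fit <- train(net, prot, n_trials = n_trials, seed = seed)
  attr(fit$net$three_stage, "record_nu") <- TRUE
  rec <- recall(fit$net, cue = 1, sim_duration = sum(prot$duration) + 1500,
                seed = seed + 1, record_spikes = FALSE)
  ord <- recall_order(rec)
  expressed <- ord$element
  target <- prot$element
  # transitions out of blue: element following each blue activation
  blue_pos <- which(expressed == 1)
  after_blue <- expressed[blue_pos[blue_pos < length(expressed)] + 1]
  want_after <- c(2, 3, 4)
  n_correct <- sum(utils::head(after_blue, 3) == utils::head(
    want_after, length(after_blue)))
  # sparse patterns at the three blue offsets
  blue_off <- ord$offset[expressed == 1]
  overlaps <- NULL
  if (length(blue_off) >= 2 && !is.null(rec$nu)) {
    pats <- lapply(blue_off, function(t) pattern_at(rec, t - 25))
    pr <- utils::combn(length(pats), 2)
    overlaps <- apply(pr, 2, function(ij)
      pattern_overlap(pats[[ij[1]]], pats[[ij[2]]]))
  }
  list(net = fit$net, record = rec, order = ord,
       summary = list(expressed = expressed, target = target,
                      order_correct = identical(expressed[seq_along(target)],
                                                target) &&
                        length(expressed) >= length(target),
                      correct_blue_transitions = n_correct,
                      pattern_overlaps = overlaps))
}

#' Train and recall two overlapping sequences
#'
#' Stores BRO (blue, red, orange) and then GRP (green, red, purple) in the
#' same three-stage network; transitions out of red are history-dependent.
#' Recall is then cued with blue (expect orange third) and with green (expect
#' purple third).
#'
#' @param config configuration list.
#' @param seed root seed.
#' @param n_trials training trials per sequence.
#' @param reservoir_jitter optional sd of a perturbation applied to the
#'   reservoir's initial state before each recall (robustness probe).
#'
#' @return List with the trained `net`, both recall records, both expressed
#'   orders, and a `summary` with the third element reached from each cue.
#' @export
run_overlap_pair <- function(config = default_config(), seed = 1,
                             n_trials = 40, reservoir_jitter = 0) {
  config <- nonmarkov_overrides(config)
  prots <- make_fixture("overlap_pair",
                        input_amp = config$protocol$input_amp,
                        gap_ms = config$nonmarkov$gap_ms)
  net <- build_network(5, config, backend = "rate", variant = "nonmarkov",
                       seed = seed)
  net <- attach_three_stage(net, config, seed = seed)
  fit <- train(net, prots$BRO, n_trials = n_trials, seed = seed)
  fit <- train(fit$net, prots$GRP, n_trials = n_trials, seed = seed + 1)
  net <- fit$net

  one_recall <- function(cue, sd_seed) {
    init <- NULL
    if (reservoir_jitter > 0) {
      set.seed(sd_seed)
      K <- net$three_stage$reservoir$K
      init <- list(u_res = stats::rnorm(K, 0, reservoir_jitter))
    }
    rec <- recall(net, cue = cue, sim_duration = 2500, seed = sd_seed,
                  record_spikes = FALSE, init = init)
    recall_order(rec)
  }
  ord_b <- one_recall(1, seed + 10)
  ord_g <- one_recall(4, seed + 11)
  third <- function(ord) if (nrow(ord) >= 3) ord$element[3] else NA_integer_
  list(net = net, order_blue = ord_b, order_green = ord_g,
       summary = list(blue_third = third(ord_b), green_third = third(ord_g),
                      blue_order = ord_b$element, green_order = ord_g$element,
                      blue_correct = identical(ord_b$element[1:3], c(1L, 2L, 3L)),
                      green_correct = identical(ord_g$element[1:3], c(4L, 2L, 5L))))
}
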