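#' Named stimulus-protocol fixtures
#'
#' The protocols used throughout the package's experiments:
#' \describe{
#'   \item{`"four_element"`}{four elements of 500, 1000, 700
#'     and 1800 ms (blue, red, green, orange).}
#'   \item{`"six_element_nonmarkov"`}{the non-Markovian sequence BGBRBO:
#'     blue, green, blue, red, blue, orange of 500, 700, 500, 1300, 500 and
#'     700 ms — blue appears three times, each time followed by a different
#'     element.}
#'   \item{`"overlap_pair"`}{two overlapping three-element sequences, BRO
#'     (blue, red, orange) and GRP (green, red, purple), every element
#'     500 ms; returned as a list of two protocols sharing one column
#'     numbering.}
#'   \item{`"two_column"`}{a 700 ms element followed by a 500 ms element.}
#'   \item{`"eight_element"`}{eight elements of varied durations.}
#' }
#'
#' @param name fixture name.
#' @param ... passed to [stimulus_protocol()] (e.g. `gap_ms`, `n_trials`).
#'
#' @return A [stimulus_protocol()], or a list of two for the overlapping
#'   pair.
#' @export
make_fixture <- function(name, ...) {
  known <- c("four_element", "six_element_nonmarkov", "overlap_pair",
             "two_column", "eight_element")
  if (!name %in% known) {
    stop("unknown fixture '", name, "'; available: ",
         paste(known, collapse = ", "))
  }
  switch(name,
    four_element = stimulus_protocol(1:4, c(500, 1000, 700, 1800),
                             labels = c("blue", "red", "green", "orange"),
                             ...),
    six_element_nonmarkov = stimulus_protocol(c(1, 2, 1, 3, 1, 4),
                             c(500, 700, 500, 1300, 500, 700),
                             labels = c("blue", "green", "blue", "red",
                                        "blue", "orange"), ...),
    overlap_pair = list(
      BRO = stimulus_protocol(c(1, 2, 3), c(500, 500, 500),
                              labels = c("blue", "red", "orange"), ...),
      GRP = stimulus_protocol(c(4, 2, 5), c(500, 500, 500),
                              labels = c("green", "red", "purple"), ...)),
    two_column = stimulus_protocol(1:2, c(700, 500), ...),
    eight_element = stimulus_protocol(1:8, c(500, 700, 500, 1000, 700,
                                             500, 900, 600), ...)
  )
}

trial_schedule <- function(net, protocol, n_trials, gap_ms = NULL) {
  cfg <- net$config
  gap <- if (!is.null(gap_ms)) gap_ms else attr(protocol, "gap_ms")
  pulse <- attr(protocol, "pulse_ms")
  trial_len <- sum(protocol$duration)
  period <- trial_len + gap
  amp <- if (net$backend == "spiking") attr(protocol, "peak_rate_hz") else
    attr(protocol, "input_amp")
  inputs <- do.call(rbind, lapply(seq_len(n_trials), function(tr) {
    t0 <- (tr - 1) * period
    cbind(t0 + protocol$onset,
          t0 + protocol$onset + pmin(pulse, protocol$duration),
          protocol$element, amp)
  }))
  if (is.null(inputs)) inputs <- matrix(0, 0, 4)
  rewards <- as.numeric(vapply(seq_len(n_trials), function(tr)
    (tr - 1) * period + reward_schedule(protocol),
    numeric(length(reward_schedule(protocol)))))
  snapshots <- seq_len(n_trials) * period - gap / 2
  list(inputs = inputs, rewards = sort(rewards), snapshots = snapshots,
       t_total = n_trials * period, period = period, trial_len = trial_len)
}

#' Train a network on a stimulus protocol
#'
#' Presents the protocol for `n_trials` trials (elements rendered as pulsed
#' input to the selective columns' Timers, a neuromodulator event at every
#' element onset and offset), with eligibility traces updated at every step
#' and weights updated at every neuromodulator event.  Plastic weights are
#' snapshotted once per trial.
#'
#' @param net a `ttl_network` whose columns cover the protocol's element ids.
#' @param protocol a [stimulus_protocol()].
#' @param n_trials number of training trials (defaults to the protocol's).
#' @param seed RNG seed.
#' @param gap_ms inter-trial gap override (ms).
#'
#' @return List with the trained `net` and the training `record`.
#' @export
train <- function(net, protocol, n_trials = NULL, seed = 1, gap_ms = NULL) {
  if (!all(protocol$element %in% seq_len(net$n_columns))) {
    stop("protocol elements do not map to existing columns")
  }
  if (is.null(n_trials)) n_trials <- attr(protocol, "n_trials")
  if (n_trials == 0) {
    return(list(net = net,
                record = NULL))
  }
  sch <- trial_schedule(net, protocol, n_trials, gap_ms)
  out <- simulate_network(net, sch$inputs, sch$rewards, sch$t_total,
                          learn = TRUE, seed = seed,
                          snapshot_times = sch$snapshots)
  out$record$protocol <- protocol
  out$record$n_trials <- n_trials
  out$record$trial_period <- sch$period
  out
}

#' Recall from a trained network
#'
#' Presents only the cue element(s) as input (weights frozen) and simulates
#' freely for `sim_duration` ms.  A successful recall re-expresses the whole
#' trained sequence: each column's Timer sustains its learned duration and
#' its Messengers hand activity to the next column.
#'
#' For a multi-element cue (needed when stored sequences share a prefix),
#' cues are presented contiguously using the durations in `cue_durations`.
#'
#' @param net a trained `ttl_network`.
#' @param cue element id(s) to present.
#' @param sim_duration simulation length (ms).
#' @param seed RNG seed.
#' @param cue_durations durations (ms) of all but the last cue element when
#'   more than one is presented.
#' @param pulse_ms,input_rate optional overrides of the input pulse.
#' @param record_spikes record spike events (spiking backend; default TRUE).
#' @param init optional initial state (e.g. a perturbed reservoir state).
#'
#' @return A `ttl_record`.
#' @export
recall <- function(net, cue, sim_duration = 5000, seed = 1,
                   cue_durations = NULL, pulse_ms = NULL, input_rate = NULL,
                   record_spikes = TRUE, init = NULL) {
  if (!all(cue %in% seq_len(net$n_columns))) {
    stop("unknown cue element: ",
         paste(setdiff(cue, seq_len(net$n_columns)), collapse = ", "))
  }
  cfg <- net$config
  pulse <- if (is.null(pulse_ms)) cfg$protocol$pulse_ms else pulse_ms
  onsets <- if (length(cue) > 1) {
    stopifnot(length(cue_durations) >= length(cue) - 1)
    c(0, cumsum(cue_durations[seq_len(length(cue) - 1)]))
  } else 0
  amp <- if (!is.null(input_rate)) input_rate else
    if (net$backend == "spiking") cfg$protocol$peak_rate_hz else
      cfg$protocol$input_amp
  inputs <- cbind(onsets, onsets + pulse, cue, amp)
  out <- simulate_network(net, inputs, numeric(0), sim_duration,
                          learn = FALSE, seed = seed,
                          record_spikes = record_spikes, init = init)
  out$record$cue <- cue
  out$record
}
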