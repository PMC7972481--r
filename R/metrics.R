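#' Extract recalled elements from a simulation record
#'
#' Measures, for each column, the onset and offset of Timer activity from the
#' population mean-rate trace: the onset is the first time the rate exceeds
#' `onset_frac` of the column's peak, and the offset the first subsequent
#' time it stays below `offset_frac` of the peak for at least `debounce_ms`.
#' Columns whose peak never reaches `min_peak_hz` are marked absent.  When a
#' protocol is supplied, per-element relative duration errors and an overall
#' success flag (order correct and every present element within
#' `duration_tol`) are attached.
#'
#' @param record a `ttl_record`.
#' @param protocol optional [stimulus_protocol()] for reference durations.
#' @param onset_frac,offset_frac thresholds as fractions of the per-column
#'   peak rate.
#' @param debounce_ms minimum time below threshold to count as an offset;
#'   brief dips shorter than this do not terminate an element.
#' @param min_peak_hz minimum peak rate for a column to count as recalled.
#' @param duration_tol relative duration error defining success.
#' @param columns columns to measure (default: all, or the protocol's).
#'
#' @return A `recall_report` data frame with one row per measured column:
#'   `element`, `onset`, `offset`, `duration`, `trained`, `rel_error`,
#'   `present`; attributes `order` (element ids by onset) and `success`.
#' @export
extract_elements <- function(record, protocol = NULL, onset_frac = 0.5,
                             offset_frac = 0.5, debounce_ms = 50,
                             min_peak_hz = 5, duration_tol = 0.10,
                             columns = NULL) {
  if (is.null(columns)) {
    columns <- if (!is.null(protocol)) unique(protocol$element)
    else seq_len(record$n_columns)
  }
  tt <- record$time
  dt_rec <- if (length(tt) > 1) tt[2] - tt[1] else 1
  rows <- lapply(columns, function(k) {
    r <- record$rates[, paste0("c", k, ".timer")]
    pk <- max(r)
    if (pk < min_peak_hz) {
      return(data.frame(element = k, onset = NA_real_, offset = NA_real_,
                        duration = NA_real_, present = FALSE))
    }
    on_i <- which(r >= onset_frac * pk)[1]
    below <- r < offset_frac * pk
    below[seq_len(on_i)] <- FALSE
    off_i <- NA_integer_
    need <- max(1L, ceiling(debounce_ms / dt_rec))
    run <- 0L
    for (i in seq_along(below)) {
      if (below[i]) {
        run <- run + 1L
        if (run >= need) { off_i <- i - run + 1L; break }
      } else run <- 0L
    }
    if (is.na(off_i) && below[length(below)]) off_i <- length(below)
    data.frame(element = k, onset = tt[on_i],
               offset = if (is.na(off_i)) NA_real_ else tt[off_i],
               duration = if (is.na(off_i)) NA_real_ else tt[off_i] - tt[on_i],
               present = TRUE)
  })
  rep <- do.call(rbind, rows)
  if (!is.null(protocol)) {
    trained <- protocol$duration[match(rep$element, protocol$element)]
    rep$trained <- trained
    rep$rel_error <- (rep$duration - trained) / trained
  }
  present <- rep[rep$present & !is.na(rep$onset), , drop = FALSE]
  ord <- present$element[order(present$onset)]
  attr(rep, "order") <- ord
  if (!is.null(protocol)) {
    want <- protocol$element[!duplicated(protocol$element)]
    ok_order <- length(ord) == length(want) && all(ord == want)
    ok_dur <- all(abs(rep$rel_error) <= duration_tol, na.rm = TRUE) &&
      !any(is.na(rep$rel_error[rep$present]))
    attr(rep, "success") <- ok_order && ok_dur
  }
  class(rep) <- c("recall_report", "data.frame")
  rep
}

#' Interspike-interval coefficients of variation
#'
#' Computes, per neuron with at least `min_spikes` spikes inside the window,
#' the coefficient of variation of its interspike intervals (sd / mean).
#' Poisson-like irregular firing gives CV near 1; clock-like firing gives CV
#' near 0.
#'
#' @param record a `ttl_record` with recorded spikes.
#' @param window optional `c(t0, t1)` restricting the analysis (ms).
#' @param min_spikes minimum spike count per neuron.
#'
#' @return List with `cv` (per-neuron values), `median` and `iqr`.
#' @export
isi_cv <- function(record, window = NULL, min_spikes = 3) {
  sp <- record$spikes
  if (is.null(sp) || nrow(sp) == 0) {
    stop("record contains no spikes; run recall with record_spikes = TRUE")
  }
  if (!is.null(window)) {
    sp <- sp[sp$time_ms >= window[1] & sp$time_ms <= window[2], ]
  }
  key <- paste(sp$population_id, sp$neuron_index)
  cvs <- vapply(split(sp$time_ms, key), function(ts) {
    if (length(ts) < max(min_spikes, 3)) return(NA_real_)
    isi <- diff(sort(ts))
    stats::sd(isi) / mean(isi)
  }, 1)
  cvs <- cvs[!is.na(cvs)]
  list(cv = cvs, median = stats::median(cvs),
       iqr = unname(diff(stats::quantile(cvs, c(0.25, 0.75)))))
}

#' First trial at which learning has converged
#'
#' Given per-trial weight snapshots, returns the first trial index after
#' which the maximum relative per-trial weight change stays below `tolerance`
#' for all remaining trials.
#'
#' @param snapshots numeric matrix, one row per trial, one column per plastic
#'   synapse group (e.g. `record$snapshots`), or a `ttl_record`.
#' @param tolerance relative change threshold.
#'
#' @return List with `trial` (index, or `NA` if never converged),
#'   `converged`, and `final_change` (the last per-trial change observed).
#' @export
convergence_trial <- function(snapshots, tolerance = 0.02) {
  if (inherits(snapshots, "ttl_record")) snapshots <- snapshots$snapshots
  snapshots <- as.matrix(snapshots)
  if (nrow(snapshots) < 2) stop("need at least two weight snapshots")
  prev <- snapshots[-nrow(snapshots), , drop = FALSE]
  curr <- snapshots[-1, , drop = FALSE]
  relchg <- abs(curr - prev) / pmax(abs(prev), .Machine$double.eps)
  per_trial <- apply(relchg, 1, max)           # change into trial i+1
  ok <- rev(cumprod(rev(per_trial < tolerance))) > 0
  if (!any(ok)) {
    return(list(trial = NA_integer_, converged = FALSE,
                final_change = per_trial[length(per_trial)]))
  }
  list(trial = which(ok)[1], converged = TRUE,
       final_change = per_trial[length(per_trial)])
}

#' Sweep the learnable element-duration range
#'
#' For each duration in the grid, trains a fresh two-column network on a
#' protocol whose first element has that duration (followed by a fixed
#' 500 ms element, so the first element's offset is marked by the next
#' stimulus), recalls from the first element, and marks success when the
#' recalled order is correct and the swept element's duration error is within
#' `duration_tol`.
#'
#' @param durations grid of element durations (ms).
#' @param config configuration list.
#' @param backend `"spiking"` or `"rate"`.
#' @param n_trials training trials per grid point.
#' @param seed seed (the sweep is deterministic per seed).
#' @param sizes population sizes (spiking backend).
#' @param duration_tol success tolerance on the relative duration error.
#'
#' @return Data frame with `duration`, `recalled`, `rel_error`, `success`.
#' @export
duration_sweep <- function(durations, config = default_config(),
                           backend = "rate", n_trials = 60, seed = 1,
                           sizes = 25, duration_tol = 0.10) {
  rows <- lapply(durations, function(d) {
    prot <- stimulus_protocol(1:2, c(d, 500),
                              input_amp = config$protocol$input_amp,
                              peak_rate_hz = config$protocol$peak_rate_hz,
                              gap_ms = config$protocol$gap_ms)
    net <- build_network(2, config, backend = backend, sizes = sizes,
                         seed = seed)
    fit <- train(net, prot, n_trials = n_trials, seed = seed)
    rec <- recall(fit$net, cue = 1, sim_duration = d + 1500,
                  seed = seed + 1, record_spikes = FALSE)
    rep <- extract_elements(rec, prot, duration_tol = duration_tol)
    e1 <- rep[rep$element == 1, ]
    ord <- attr(rep, "order")
    ok <- isTRUE(all(ord == c(1, 2))) && isTRUE(abs(e1$rel_error) <= duration_tol)
    data.frame(duration = d, recalled = e1$duration,
               rel_error = e1$rel_error, success = ok)
  })
  do.call(rbind, rows)
}
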