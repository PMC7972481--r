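#' Write spike events as delimited text
#'
#' One event per row with a header: `time_ms`, `population_id`,
#' `neuron_index`.
#'
#' @param record a `ttl_record` with spikes, or a spike data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spike_events <- function(record, path) {
  sp <- if (inherits(record, "ttl_record")) record$spikes else record
  if (is.null(sp)) sp <- data.frame(time_ms = numeric(0),
                                    population_id = numeric(0),
                                    neuron_index = numeric(0))
  utils::write.table(sp, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read spike events written by [write_spike_events()]
#'
#' @param path input path.
#' @return A spike data frame.
#' @export
read_spike_events <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' Write population mean-rate traces as delimited text
#'
#' First column `time_ms`, one column per population mean rate.  The same
#' format is used by both backends, so the measurement operators work on
#' either.
#'
#' @param record a `ttl_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rate_traces <- function(record, path) {
  df <- data.frame(time_ms = record$time, record$rates, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a recall report as JSON
#'
#' @param report a `recall_report` from [extract_elements()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recall_report <- function(report, path) {
  out <- list(elements = as.data.frame(report),
              order = attr(report, "order"),
              success = attr(report, "success"))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Save or load network weights
#'
#' Weight matrices and (if present) three-stage feedback weights are
#' persisted as a named R serialization, one entry per synapse group.
#'
#' @param net a `ttl_network`.
#' @param path file path.
#' @return `path` (save) or the updated network (load), invisibly.
#' @export
save_weights <- function(net, path) {
  w <- lapply(net$groups, function(g) if (isTRUE(g$uniform)) g$w else g$W)
  names(w) <- vapply(seq_along(net$groups), function(i) {
    g <- net$groups[[i]]
    paste0(i, ":", g$label)
  }, "")
  obj <- list(weights = w, Q = net$three_stage$Q)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(net, path) {
  obj <- readRDS(path)
  if (length(obj$weights) != length(net$groups)) {
    stop("weight file does not match the network (",
         length(obj$weights), " groups vs ", length(net$groups), ")")
  }
  for (i in seq_along(net$groups)) {
    if (isTRUE(net$groups[[i]]$uniform)) {
      net$groups[[i]]$w <- obj$weights[[i]]
    } else {
      net$groups[[i]]$W <- obj$weights[[i]]
    }
  }
  if (!is.null(obj$Q) && !is.null(net$three_stage)) net$three_stage$Q <- obj$Q
  net
}
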