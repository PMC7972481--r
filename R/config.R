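#' Default run configuration
#'
#' All tunable parameters of the package live in one shipped YAML file
#' (`inst/extdata/default-params.yaml`); this reads it.  Nothing in the
#' simulation code hard-codes a parameter value.
#'
#' @return A nested configuration list.
#' @export
default_config <- function() {
  path <- system.file("extdata", "default-params.yaml", package = "ttlnet")
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' Load a run configuration
#'
#' Reads a YAML configuration file and merges it over the shipped defaults.
#' Unknown keys are rejected (they are almost always typos), and structural
#' constraints are validated: positive time constants, feed-forward trace
#' ordering (`eta_p > eta_d`, `tau_d > tau_p`), and the `tau_p != tau_d`
#' requirement without which the falling-phase fixed point is singular.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.  An empty
#'   file yields the all-defaults configuration.
#'
#' @return A validated configuration list with attribute `"user_set"` listing
#'   the keys the user overrode.
#' @export
load_config <- function(path = NULL) {
  cfg <- yaml::read_yaml(system.file("extdata", "default-params.yaml",
                                     package = "ttlnet"))
  user_keys <- character(0)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (length(user)) {
      merged <- merge_config(cfg, user, parent = "")
      cfg <- merged$cfg
      user_keys <- merged$keys
    }
  }
  cfg <- validate_config(cfg)
  attr(cfg, "user_set") <- user_keys
  cfg
}

merge_config <- function(base, user, parent) {
  keys <- character(0)
  for (k in names(user)) {
    full <- if (nzchar(parent)) paste0(parent, ".", k) else k
    if (!k %in% names(base)) {
      stop("unknown configuration key: '", full, "'")
    }
    if (is.list(base[[k]]) && is.list(user[[k]])) {
      sub <- merge_config(base[[k]], user[[k]], full)
      base[[k]] <- sub$cfg
      keys <- c(keys, sub$keys)
    } else {
      base[[k]] <- user[[k]]
      keys <- c(keys, full)
    }
  }
  list(cfg = base, keys = keys)
}

validate_config <- function(cfg) {
  np <- cfg$neuron
  stopifnot("neuron.vth_jitter must be non-negative" =
              is.null(np$vth_jitter) || np$vth_jitter >= 0)
  np$vth_jitter <- NULL
  do.call(neuron_params, np)   # runs the neuron invariants
  do.call(rate_params, list(tau_u = cfg$rate$tau_u_exc, theta = cfg$rate$theta,
                            u_c = cfg$rate$u_c, v_scale = cfg$rate$v_scale))
  for (bk in names(cfg$learning)) {
    for (class in names(cfg$learning[[bk]])) {
      lp <- cfg$learning[[bk]][[class]]
      if (lp$tau_p == lp$tau_d) {
        stop("learning.", bk, ".", class, ": tau_p == tau_d makes the ",
             "falling-phase fixed point singular")
      }
      role <- if (class == "feedforward") "feedforward" else "recurrent"
      do.call(trace_params, c(lp, list(role = role)))
    }
  }
  stopifnot(
    "nonmarkov.rho_sparse must be in (0, 1)" =
      cfg$nonmarkov$rho_sparse > 0 && cfg$nonmarkov$rho_sparse < 1,
    "nonmarkov.g must be positive" = cfg$nonmarkov$g > 0
  )
  cfg
}

#' Write a configuration to a YAML file
#'
#' The dumped file round-trips through [load_config()] to an identical
#' configuration; resolved configurations are echoed into run output
#' directories for provenance.
#'
#' @param cfg a configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  attr(cfg, "user_set") <- NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Trace parameters for one synapse class from a configuration
#'
#' @param config configuration list.
#' @param backend `"spiking"` or `"rate"`.
#' @param class `"recurrent"` or `"feedforward"`.
#' @return A [trace_params()] object.
#' @export
config_trace_params <- function(config, backend, class) {
  lp <- config$learning[[backend]][[class]]
  role <- if (class == "feedforward") "feedforward" else "recurrent"
  do.call(trace_params, c(lp, list(role = role)))
}
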