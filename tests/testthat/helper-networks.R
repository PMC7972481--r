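# Shared fixtures, built lazily and cached for the whole test run.  All
# simulations here are deliberately small (few columns, short elements,
# reduced populations) so the default suite stays fast.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

small_config <- function() {
  cfg <- default_config()
  cfg$protocol$gap_ms <- 4000
  cfg
}

# rate-backend two-column network trained on a 700/500 ms protocol
trained_rate_two_col <- function() {
  cached("rate2col", function() {
    cfg <- small_config()
    prot <- stimulus_protocol(1:2, c(700, 500),
                              input_amp = cfg$protocol$input_amp,
                              gap_ms = 4000)
    net <- build_network(2, cfg, backend = "rate", seed = 1)
    fit <- train(net, prot, n_trials = 60, seed = 1)
    list(fit = fit, prot = prot, cfg = cfg)
  })
}

# rate-backend network trained on three distinct durations (the last element
# short enough that its incoming transition converts before the feed-forward
# traces decay)
trained_rate_three_col <- function() {
  cached("rate3col", function() {
    cfg <- small_config()
    prot <- stimulus_protocol(1:3, c(300, 800, 500),
                              input_amp = cfg$protocol$input_amp,
                              gap_ms = 4000)
    net <- build_network(3, cfg, backend = "rate", seed = 1)
    fit <- train(net, prot, n_trials = 80, seed = 1)
    list(fit = fit, prot = prot, cfg = cfg)
  })
}

# small spiking two-column network trained on a 500/500 ms protocol
trained_spiking_two_col <- function() {
  cached("spk2col", function() {
    cfg <- small_config()
    prot <- stimulus_protocol(1:2, c(500, 500), gap_ms = 3000)
    net <- build_network(2, cfg, backend = "spiking", sizes = 16, seed = 1)
    fit <- train(net, prot, n_trials = 25, seed = 1)
    list(fit = fit, prot = prot, cfg = cfg)
  })
}
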