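# Small configurations reused across tests.

tiny_config <- function(...) {
  defaults <- list(
    n_early = 25L, n_late = 20L,
    regions = c("G_insular_short", "S_orbital_med-olfact", "G_occipital_sup",
                "G_cuneus"),
    noise_sd = 0.1, seed = 101L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# Noise-free one-region config with distinct stage rates.
line_config <- function(rate_early = -0.07, rate_late = -0.02, ...) {
  tiny_config(regions = "G_insular_short", hemispheres = "left",
              rate_early = rate_early, rate_late = rate_late,
              noise_sd = 0, ...)
}
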