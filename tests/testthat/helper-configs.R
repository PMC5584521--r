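# Shared generator configurations.
#
# `noise_free_config()` keeps the study-like defaults (0.2 l, sulfate from
# 0.5 mM) under which low-sulfate treatments are sulfate-limited and the
# generator caps sulfate reduction. `uncapped_config()` enlarges the liquid
# volume so the supplied sulfate always covers the partition-law demand,
# which is the regime in which the exact-linearity properties hold.

zero_noise <- list(methane = 0, sulfate = 0, delta = 0, hexadecane = 0)

noise_free_config <- function(...) {
  simulation_config(noise_sd = zero_noise, ...)
}

uncapped_config <- function(noise_sd = zero_noise, ...) {
  simulation_config(liquid_volume = 0.6, noise_sd = noise_sd, ...)
}

quiet_generate <- function(cfg) suppressWarnings(generate_experiment(cfg))
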