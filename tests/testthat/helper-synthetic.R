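# Shared fixtures, built in code at test time.

# A small, well-separated spike set: distinct single units, low noise,
# no multi-unit background unless asked for.
easy_spikes <- function(seed = 3L, n_units = 5L, duration = 200,
                        noise_sd = 0.02, multiunit = FALSE,
                        peak_jitter = 0L, samples = 79L) {
  spec <- simulation_spec(n_single_units = n_units,
                          samples_per_spike = samples,
                          duration = duration, noise_sd = noise_sd,
                          multiunit_n_shapes = if (multiunit) 20L else 0L,
                          peak_jitter = peak_jitter)
  generate_labeled_spikes(spec, seed = seed)
}

# Standard preprocessing used across tests: align to middle, scale, shuffle.
prep <- function(spikes, seed = 11L) {
  shuffle_spikes(scale_unit_interval(align_spikes(spikes)), seed = seed)
}

# Small random MLP encoder/decoder net for gradient-style checks.
random_net <- function(widths, acts, seed = 1L) {
  net <- withr::with_seed(seed, glorot_init(widths))
  net$acts <- acts
  net
}
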