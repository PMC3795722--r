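# Shared fixtures: noise-free and default-noise configurations, and a
# convenience wrapper for a single fully spanning fibre.

zero_noise_config <- function(..., orientation_prob = 0, seed = 1) {
  cohort_config(boundary_jitter_sd_kb = 0, dropout_prob = 0,
                false_signal_rate = 0, stretch_sd = 0,
                orientation_prob = orientation_prob,
                fibre_length_mean_kb = 1200, fibre_length_sd_kb = 0,
                seed = seed, ...)
}

# one fibre whose window covers the whole haplotype
full_span_fibre <- function(hap, config, seed = 42) {
  simulate_fibre(hap, config, seed, cover = c(hap$hap_start, hap$hap_end))
}

test_map <- default_locus_map()
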