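Synthetic toy fixtures generated with the package's own simulator:
`synthetic_config(genome_length = 7e4, probe_spacing = 70,
domain_mean_length = 8000, noise_sd = 0.8, rng_seed = 42)`,
12 genes / 2 clusters, values rounded for compactness.
`toy_truth.bed` holds the planted domain states.
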