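# small shared template library used across test files
lib6 <- make_template_library(n_per_combo = 1, seed = 11)
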