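# a tiny shared training bundle for selection/ablation smoke tests
tiny_bundle <- function(n_long = 45, n_short = 15, seed = 21) {
  spec <- synthetic_spec(n_long = n_long, n_short = n_short,
                         length_range = c(50L, 90L), motif = "W.W.W",
                         p_motif = 0.9, effect_size = 2, seed = seed)
  ds <- generate_synthetic(spec)
  emb <- synthetic_embedder(seed = 5L, d_local = 22L, d_global = 8L,
                            L_padded = 95L,
                            signal_map = signal_map_from_spec(spec))
  prepare_training_data(ds$sequences, ds$labels$label, emb)
}
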