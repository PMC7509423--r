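# Shared fixtures, built once per test run and memoised.  All data is
# generated programmatically; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# tiny network for exact-math tests
tiny_net <- function(seed = 2L) {
  cfg <- network_config(
    d = c(assoc = 3, prop_slow = 4, prop_fast = 5, vis_slow = 4, vis_fast = 5),
    z = c(assoc = 1, prop_slow = 2, prop_fast = 2, vis_slow = 2, vis_fast = 2),
    tau = c(assoc = 4, prop_slow = 2, prop_fast = 1, vis_slow = 2, vis_fast = 1),
    p_dim = 3, l_dim = 2)
  build_network(cfg, seed = seed)
}

# desk-scale corpus: 6 sequences x (4 segments x 25 steps), 16 px frames,
# trained codec, latent targets filled.  Matches the generator's stated
# noise world (joint sd 0.01, pixel sd 0.15).
shared_corpus <- function() memo("corpus", function() {
  ds <- build_dataset(n_sequences = 6, n_segments = 4, segment_len = 25,
                      seed = 1, image_size = 16)
  frames <- do.call(pvrnnagency:::abind_first,
                    lapply(ds[1:4], `[[`, "frames"))
  codec <- train_codec(frames, codec_config(16, 8), epochs = 40, seed = 1,
                       alpha = 3e-3)
  ds <- encode_dataset(ds, codec)
  list(train = ds[1:4], test = ds[5:6], codec = codec)
})

# the half-width model trained 500 epochs on 4 sequences x 100 steps --
# exactly the scaled training protocol of the convergence criterion
shared_fit <- function() memo("fit", function() {
  corp <- shared_corpus()
  net <- build_network(network_config_scaled(l_dim = 8), seed = 7,
                       meta = meta_priors_w1())
  train(net, corp$train, train_config(epochs = 500, seed = 11,
                                      log_every = 50))
})

er_cfg_scaled <- function(meta = NULL)
  er_config(window_len = 12L, iters = 10L, meta = meta)

# relative error helper for gradient checks
rel_err <- function(a, b) abs(a - b) / pmax(abs(b), 1e-8)
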