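# Shared builders for tiny, fast test fixtures; everything is generated in
# code at test time.

sub_only_channel <- function(rate = 0.02) {
  channel_config(list(error_source(
    "substitution-only", c(substitution = rate, insertion = 0, deletion = 0))))
}

mixed_channel <- function(total = 0.068,
                          pattern = c(substitution = 0.6, insertion = 0.2,
                                      deletion = 0.2)) {
  channel_config(list(error_source("mixed", total * pattern)))
}

zero_channel <- function() {
  channel_config(list(error_source(
    "silent", c(substitution = 0, insertion = 0, deletion = 0))))
}

gc_graph_printed <- function() {
  probability_graph(data.frame(x = c(0, 40, 41, 59, 60, 100),
                               y = c(100, 100, 0, 0, 100, 100)))
}

tiny_codec_config <- function(...) {
  defaults <- list(block_bits = 8L, rate_mode = "third", latent_redundancy = 0L,
                   decoder_iterations = 2L, units = 6L, layers = 2L,
                   kernel = 3L, batch_size = 8L, learning_rate = 1e-3,
                   t_enc = 1L, t_dec = 1L)
  do.call(codec_config, utils::modifyList(defaults, list(...)))
}

# The smoke-training setup: block 24, rate 1/3, CNN encoder, ResNet
# transcoder, CNN decoder, batch 256, substitution-only channel at 2%
# total error. Per-epoch batch counts and network width are scaled to the
# one-CPU test budget.
smoke_codec_config <- function(...) {
  defaults <- list(block_bits = 24L, rate_mode = "third",
                   latent_redundancy = 0L, decoder_iterations = 2L,
                   encoder = "cnn", transcoder = "resnet", decoder = "cnn",
                   units = 14L, layers = 2L, kernel = 5L,
                   batch_size = 256L, learning_rate = 2e-3,
                   t_enc = 2L, t_dec = 4L)
  do.call(codec_config, utils::modifyList(defaults, list(...)))
}

smoke_channel <- function() sub_only_channel(0.02)

# Cache heavyweight trained models across acceptance tests within a run.
.trained_cache <- new.env(parent = emptyenv())

smoke_train_cached <- function(seed, epochs = 50L, latent_redundancy = 0L) {
  key <- sprintf("s%d_r%d_e%d", seed, latent_redundancy, epochs)
  if (is.null(.trained_cache[[key]])) {
    cfg <- smoke_codec_config(latent_redundancy = latent_redundancy)
    .trained_cache[[key]] <- train(cfg, epochs = epochs, seed = seed,
                                   channel = smoke_channel())
  }
  .trained_cache[[key]]
}

random_dna_string <- function(len) {
  paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
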