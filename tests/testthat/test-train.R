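test_that("smooth L1 matches the closed forms on both sides of beta", {
  expect_equal(smooth_l1(1, 1), 0)
  expect_equal(smooth_l1(0.5, 0, beta = 1), 0.125)   # 0.5 * 0.25 / 1
  expect_equal(smooth_l1(2, 0, beta = 1), 1.5)       # 2 - 0.5
  for (beta in c(0.5, 1, 2)) {
    d <- seq(-3, 3, by = 0.01)
    expected <- ifelse(abs(d) < beta, 0.5 * d^2 / beta, abs(d) - 0.5 * beta)
    got <- vapply(d, function(di) smooth_l1(di, 0, beta), numeric(1))
    expect_equal(got, expected, tolerance = 1e-12)
    # continuity at |d| = beta
    expect_equal(smooth_l1(beta - 1e-9, 0, beta), smooth_l1(beta + 1e-9, 0, beta),
                 tolerance = 1e-6)
  }
  expect_error(smooth_l1(1:3, 1:2), "length mismatch")
  expect_error(smooth_l1(1, 1, beta = 0), "positive")
})

test_that("reconstruction accuracy identities", {
  u <- sample(0:1, 24, TRUE)
  expect_equal(reconstruction_accuracy(u, u), 1)
  expect_equal(reconstruction_accuracy(u, 1 - u), 0)
  uhat <- u; uhat[1:6] <- 1 - uhat[1:6]
  expect_equal(reconstruction_accuracy(u, uhat), 0.75)
  expect_error(reconstruction_accuracy(u, u[-1]), "length mismatch")
  # complement identity as a property
  set.seed(31)
  for (i in 1:50) {
    a <- sample(0:1, 40, TRUE); b <- sample(0:1, 40, TRUE)
    expect_equal(reconstruction_accuracy(a, b) +
                   reconstruction_accuracy(a, 1 - b), 1)
  }
})

test_that("generate_bit_blocks is reproducible, uniform and handles n = 0", {
  b1 <- generate_bit_blocks(10, 24, seed = 5)
  b2 <- generate_bit_blocks(10, 24, seed = 5)
  expect_identical(b1, b2)
  expect_length(b1, 10L)
  expect_true(all(vapply(b1, length, integer(1)) == 24L))
  expect_identical(generate_bit_blocks(0, 24, seed = 5), list())
  bits <- unlist(generate_bit_blocks(5000, 24, seed = 6))
  freq <- mean(bits)
  se <- sqrt(0.25 / length(bits))
  expect_lt(abs(freq - 0.5), 3 * se)
})

test_that("encoder loss decomposes into reconstruction and stability terms", {
  cfg <- tiny_codec_config(block_bits = 16L)
  m <- build_model(cfg, seed = 9)
  U <- matrix(sample(0:1, 8 * 16, TRUE), 8)
  l0 <- encoder_loss(U, m, channel = NULL, stability_weight = 0, seed = 1)
  expect_equal(l0$total, l0$reconstruction)
  expect_equal(l0$stability_term, 0)
  # an always-violating constraint drives w_DNA to 0, adding exactly the weight
  always <- constraint_config(
    gc_graph = probability_graph(data.frame(x = 0, y = 100)))
  l1 <- encoder_loss(U, m, constraints = always, stability_weight = 1, seed = 1)
  expect_equal(l1$w_DNA, 0)
  expect_equal(l1$total, l1$reconstruction + 1)
  # an unsatisfiable-to-violate config adds nothing
  never <- constraint_config(
    gc_graph = probability_graph(data.frame(x = 0, y = 0)))
  l2 <- encoder_loss(U, m, constraints = never, stability_weight = 1, seed = 1)
  expect_equal(l2$w_DNA, 1)
  expect_equal(l2$total, l2$reconstruction)
})

test_that("constraint surrogate gradient descends toward fewer violations", {
  # analytic sanity: on a strand with a borderline GC content, the gradient
  # with respect to the second mapped bit is nonzero and points away from
  # the violating side of the graph
  cfg <- finetune_constraint_config()
  set.seed(32)
  xb <- matrix(sample(c(-1, 1), 4 * 40, TRUE), 4)
  sg <- dnaturbo:::.stability_surrogate_grad(xb, cfg)
  expect_length(sg$p, 4L)
  expect_true(all(sg$p >= 0 & sg$p <= 1))
  expect_equal(dim(sg$grad), dim(xb))
  # hard-violation strand (run of 4+): surrogate detects it
  run_strand <- c(rep(c(1, 1), 10), rep(c(-1, 1), 10))  # CCCC... homopolymer
  xb2 <- rbind(run_strand, sample(c(-1, 1), 40, TRUE))
  sg2 <- dnaturbo:::.stability_surrogate_grad(xb2, cfg)
  expect_equal(unname(sg2$p[1]), 1)
})

test_that("epochs = 0 yields an initialized checkpoint and empty log", {
  cfg <- tiny_codec_config()
  dir <- tempfile(); dir.create(dir)
  r <- train(cfg, epochs = 0, seed = 40, channel = zero_channel(),
             checkpoint_dir = dir)
  expect_equal(nrow(r$log), 0L)
  expect_true(file.exists(file.path(dir, "checkpoint.rds")))
  ck <- load_checkpoint(file.path(dir, "checkpoint.rds"))
  expect_equal(ck$epoch, 0L)
})

test_that("training logs the five per-epoch quantities and reduces the loss", {
  cfg <- tiny_codec_config(block_bits = 8L, batch_size = 32L,
                           t_enc = 2L, t_dec = 2L, learning_rate = 2e-3)
  r <- train(cfg, epochs = 4, seed = 41, channel = zero_channel())
  expect_equal(nrow(r$log), 4L)
  expect_true(all(c("loss_encoder", "loss_decoder", "loss_transcoder",
                    "accuracy", "stability", "noise_level", "perfect_blocks")
                  %in% names(r$log)))
  expect_equal(r$log$epoch, 1:4)
  expect_equal(r$log$noise_level, rep(0, 4))
  expect_lt(r$log$loss_decoder[4], r$log$loss_decoder[1])
})

test_that("resume continues bit-identically from the stored RNG state", {
  cfg <- tiny_codec_config(block_bits = 8L, batch_size = 16L,
                           t_enc = 1L, t_dec = 1L)
  ch <- sub_only_channel(0.05)
  dir_a <- tempfile(); dir.create(dir_a)
  ra <- train(cfg, epochs = 6, seed = 42, channel = ch, checkpoint_dir = dir_a)
  dir_b <- tempfile(); dir.create(dir_b)
  train(cfg, epochs = 3, seed = 42, channel = ch, checkpoint_dir = dir_b)
  rb <- train(cfg, epochs = 6, seed = 42, channel = ch, checkpoint_dir = dir_b,
              resume = TRUE)
  expect_equal(rb$log$epoch, 1:6)
  expect_equal(rb$log$loss_decoder, ra$log$loss_decoder, tolerance = 1e-12)
  expect_equal(rb$log$accuracy, ra$log$accuracy, tolerance = 1e-12)
  # structural mismatch is refused with a diagnostic
  cfg2 <- tiny_codec_config(block_bits = 16L)
  expect_error(train(cfg2, epochs = 7, seed = 42, channel = ch,
                     checkpoint_dir = dir_b, resume = TRUE),
               "mismatch on resume")
})

test_that("online hyperparameter change is picked up at epoch boundaries", {
  cfg <- tiny_codec_config(block_bits = 8L, batch_size = 8L,
                           t_enc = 1L, t_dec = 1L)
  cfg_path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(learning_rate = 5e-3), cfg_path, auto_unbox = TRUE)
  expect_message(
    r <- train(cfg, epochs = 1, seed = 43, channel = zero_channel(),
               config_path = cfg_path),
    "online hyperparameter change")
  expect_equal(r$model$cfg$learning_rate, 5e-3)
})

test_that("fine-tuning with zero epochs leaves the model unchanged", {
  cfg <- tiny_codec_config(block_bits = 8L, batch_size = 8L)
  dir <- tempfile(); dir.create(dir)
  train(cfg, epochs = 1, seed = 44, channel = zero_channel(),
        checkpoint_dir = dir)
  ck <- load_checkpoint(file.path(dir, "checkpoint.rds"))
  U <- matrix(sample(0:1, 3 * 8, TRUE), 3)
  before <- encode_blocks(U, ck$model)
  ft <- fine_tune_constraints(file.path(dir, "checkpoint.rds"),
                              finetune_constraint_config(), epochs = 0)
  expect_identical(encode_blocks(U, ft$model), before)
})

test_that("evaluate_model reports over fresh blocks, deterministic in the seed", {
  cfg <- tiny_codec_config(block_bits = 8L)
  m <- build_model(cfg, seed = 11)
  e1 <- evaluate_model(m, zero_channel(), 16, seed = 3,
                       constraints = finetune_constraint_config())
  e2 <- evaluate_model(m, zero_channel(), 16, seed = 3,
                       constraints = finetune_constraint_config())
  expect_identical(e1, e2)
  expect_true(e1$accuracy >= 0 && e1$accuracy <= 1)
  expect_true(e1$stability >= 0 && e1$stability <= 1)
  e0 <- evaluate_model(m, zero_channel(), 0)
  expect_equal(e0$n, 0L)
  expect_true(is.na(e0$accuracy))
})
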