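# Finite-difference gradient checks of the layer library. These guard the
# hand-written backward passes that everything else depends on.

fd_check_params <- function(mod, x, loss = function(y) sum(y^2),
                            n_per_cell = 4L, eps = 1e-5, seed = NULL) {
  fwd <- function() {
    if (!is.null(seed)) set.seed(seed)
    mod_fwd(mod, x, train = TRUE)
  }
  r <- fwd()
  mod_bwd(mod, r$tape, 2 * r$y, accum = TRUE)
  worst <- 0
  for (p in mod_cells(mod)) {
    idx <- sample(length(p$value), min(n_per_cell, length(p$value)))
    for (i in idx) {
      v0 <- p$value[i]
      p$value[i] <- v0 + eps; yp <- fwd()$y
      p$value[i] <- v0 - eps; ym <- fwd()$y
      p$value[i] <- v0
      fd <- (loss(yp) - loss(ym)) / (2 * eps)
      worst <- max(worst, abs(fd - p$grad[i]) / max(1e-4, abs(fd)))
    }
    p$grad <- 0
  }
  worst
}

test_that("parameter gradients match finite differences for every architecture", {
  set.seed(21)
  x1 <- array(rnorm(3 * 10), c(3, 10, 1))
  for (arch in c("cnn", "rnn", "transformer")) {
    mod <- dnaturbo:::.build_encoder_net(arch, 10L, 12L, 5L, 2L, 3L, 0)
    expect_lt(fd_check_params(mod, x1), 1e-4)
  }
  x5 <- array(rnorm(3 * 14 * 5), c(3, 14, 5))
  for (arch in c("cnn", "rnn", "resnet")) {
    mod <- dnaturbo:::.build_transcoder_net(arch, 14L, 12L, 5L, 2L, 3L)
    expect_lt(fd_check_params(mod, x5), 1e-4)
  }
  x3 <- array(rnorm(3 * 10 * 3), c(3, 10, 3))
  for (arch in c("cnn", "rnn", "resnet", "transformer")) {
    mod <- dnaturbo:::.build_decoder_net(arch, 3L, 5L, 2L, 3L)
    expect_lt(fd_check_params(mod, x3), 1e-4)
  }
})

test_that("VAE gradients (with fixed latent noise) match finite differences", {
  set.seed(22)
  mod <- dnaturbo:::mod_vae(10L, 12L, 6L, 2L, kl_weight = 0)
  x <- array(rnorm(3 * 10), c(3, 10, 1))
  expect_lt(fd_check_params(mod, x, seed = 99), 1e-4)
})

test_that("decoder input gradients are exact through all turbo iterations", {
  set.seed(23)
  cfg <- tiny_codec_config(decoder_iterations = 3L)
  m <- build_model(cfg, seed = 4)
  B <- 3L
  Y <- matrix(rnorm(B * m$total_bits), B)
  lossf <- function(Y) sum(dnaturbo:::.dec_forward(m, Y, train = TRUE)$logits^2)
  df <- dnaturbo:::.dec_forward(m, Y, train = TRUE)
  dY <- dnaturbo:::.dec_backward(m, df, 2 * df$logits, accum = FALSE,
                                 need_dY = TRUE)
  for (i in sample(length(Y), 10)) {
    eps <- 1e-5
    Yp <- Y; Yp[i] <- Yp[i] + eps
    Ym <- Y; Ym[i] <- Ym[i] - eps
    fd <- (lossf(Yp) - lossf(Ym)) / (2 * eps)
    expect_lt(abs(fd - dY[i]) / max(1e-5, abs(fd)), 1e-5)
  }
})

test_that("row normalization backward matches finite differences", {
  set.seed(24)
  X <- matrix(rnorm(12), 3, 4)
  w <- matrix(rnorm(12), 3, 4)
  lossn <- function(X) sum(w * dnaturbo:::.normalize_rows(X)$y^3)
  nf <- dnaturbo:::.normalize_rows(X)
  dX <- dnaturbo:::.normalize_rows_bwd(3 * w * nf$y^2, nf$y, nf$sigma)
  for (i in seq_along(X)) {
    eps <- 1e-6
    Xp <- X; Xp[i] <- Xp[i] + eps
    Xm <- X; Xm[i] <- Xm[i] - eps
    fd <- (lossn(Xp) - lossn(Xm)) / (2 * eps)
    expect_lt(abs(fd - dX[i]) / max(1e-4, abs(fd)), 1e-4)
  }
})

test_that("straight-through binarization: composed gradient equals the
           gradient with binarization removed", {
  # 4-element toy: loss = sum(w * STE(x)); the straight-through contract
  # makes the gradient equal to that of loss = sum(w * x).
  x <- c(0.3, -0.2, 1.5, -0.7)
  w <- c(2, -1, 0.5, 3)
  # forward: binarized values
  expect_equal(binarize(x), c(1, 0, 1, 0))
  # backward under the contract: d/dx sum(w * STE(x)) == w, the same as
  # the finite-difference gradient of sum(w * x)
  eps <- 1e-6
  fd <- vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (sum(w * xp) - sum(w * xm)) / (2 * eps)
  }, numeric(1))
  expect_equal(fd, w, tolerance = 1e-6)
})

test_that("Adam updates all parameters and zeroes gradients", {
  set.seed(25)
  mod <- dnaturbo:::.build_decoder_net("cnn", 3L, 4L, 2L, 3L)
  x <- array(rnorm(2 * 6 * 3), c(2, 6, 3))
  r <- mod_fwd(mod, x)
  mod_bwd(mod, r$tape, 2 * r$y, accum = TRUE)
  cells <- mod_cells(mod)
  before <- lapply(cells, function(p) p$value)
  opt <- adam_new(lr = 1e-2)
  adam_step(opt, cells)
  for (i in seq_along(cells)) {
    expect_false(isTRUE(all.equal(before[[i]], cells[[i]]$value)))
    expect_identical(cells[[i]]$grad, 0)
  }
})

test_that("checkpoint state snapshot/restore is lossless", {
  set.seed(26)
  cfg <- tiny_codec_config()
  m1 <- build_model(cfg, seed = 7)
  m2 <- build_model(cfg, seed = 8)
  U <- matrix(sample(0:1, 4 * cfg$block_bits, TRUE), 4)
  expect_false(identical(encode_blocks(U, m1), encode_blocks(U, m2)))
  dnaturbo:::.model_restore(m2, dnaturbo:::.model_state(m1))
  expect_identical(encode_blocks(U, m1), encode_blocks(U, m2))
})
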