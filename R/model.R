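## Model bundle: encoder streams E0..E2, indel-reduction transcoder Q and
## the two-network iterative turbo decoder (D0, D1), plus checkpointing.

#' Build a codec model bundle
#'
#' Constructs the encoder stream networks, the transcoder and the two
#' decoder networks for any supported architecture combination, together
#' with the shared interleaver permutations. The interleaver spec yields a
#' message-side permutation of length `block_bits` (applied to the input
#' of the interleaved encoder stream) and a code-side permutation of
#' length `block_bits + latent_redundancy` (used inside the decoder); for
#' zero latent redundancy the two coincide.
#'
#' @param cfg a [codec_config()].
#' @param seed integer seed for weight initialization.
#' @return object of class `dt_model`.
#' @export
build_model <- function(cfg, seed = 1L) {
  .assert(inherits(cfg, "dt_codec_config"), "not a codec config")
  .validate_architectures(cfg)
  n <- cfg$block_bits
  N <- .stream_len(cfg)
  total <- .total_bits(cfg)
  window <- .strand_bases(cfg) + cfg$window_margin
  .with_seed(seed, {
    perm_msg <- make_interleaver(cfg$interleaver, n)
    perm_code <- make_interleaver(cfg$interleaver, N)
    enc <- lapply(seq_len(cfg$streams), function(i) {
      .build_encoder_net(cfg$encoder, n, N, cfg$units, cfg$layers,
                         cfg$kernel, cfg$kl_weight)
    })
    trans <- .build_transcoder_net(cfg$transcoder, window, total,
                                   cfg$units, cfg$layers, cfg$kernel)
    dec_c0 <- if (cfg$rate_mode == "third") 3L else 2L
    dec0 <- .build_decoder_net(cfg$decoder, dec_c0, cfg$units, cfg$layers,
                               cfg$kernel)
    dec1 <- .build_decoder_net(cfg$decoder, 3L, cfg$units, cfg$layers,
                               cfg$kernel)
    m <- list(cfg = cfg, n = n, N = N, total_bits = total, window = window,
              perm_msg = perm_msg, perm_code = perm_code,
              enc = enc, trans = trans, dec0 = dec0, dec1 = dec1)
    class(m) <- "dt_model"
    np <- sum(vapply(.model_cell_groups(m), function(g) {
      sum(vapply(g, function(p) length(p$value), numeric(1)))
    }, numeric(1)))
    .dt_log("debug", sprintf("built model: %s/%s/%s, %d parameters",
                             cfg$encoder, cfg$transcoder, cfg$decoder, np))
    m
  })
}

.enc_cells <- function(model) {
  do.call(c, lapply(model$enc, mod_cells))
}

.dec_cells <- function(model) {
  cells <- c(mod_cells(model$dec0), mod_cells(model$dec1))
  if (model$trans$kind != "bypass") cells <- c(cells, mod_cells(model$trans))
  cells
}

.model_cell_groups <- function(model) list(enc = .enc_cells(model), dec = .dec_cells(model))

## ---- encoder pass ---------------------------------------------------------

## U: matrix (B, n) of 0/1. Returns env with xbip (B, streams*N) in {-1,+1}
## and, when train = TRUE, the per-stream tapes needed for backward.
.enc_forward <- function(model, U, train = FALSE) {
  B <- nrow(U)
  n <- model$n
  .assert(ncol(U) == n, "input block length %d != configured %d", ncol(U), n)
  Ub <- 2 * U - 1
  s <- model$cfg$streams
  out <- vector("list", s)
  xcols <- vector("list", s)
  kl <- 0
  for (i in seq_len(s)) {
    xin <- if (i == s) Ub[, model$perm_msg, drop = FALSE] else Ub
    dim(xin) <- c(B, n, 1L)
    r <- mod_fwd(model$enc[[i]], xin, train = train)
    nrm <- .normalize_rows(r$y)
    xb <- .binarize_bipolar(nrm$y)
    out[[i]] <- list(tape = r$tape, normed = nrm$y, sigma = nrm$sigma,
                     kl = if (!is.null(r$tape$kl)) r$tape$kl else 0)
    kl <- kl + out[[i]]$kl
    xcols[[i]] <- xb
  }
  list(xbip = do.call(cbind, xcols), streams = out, kl = kl, B = B)
}

## Backward from d(loss)/d(xbip) into the encoder parameters.
## Straight-through: the binarization derivative is treated as identity.
.enc_backward <- function(model, ef, dxbip, accum = TRUE) {
  s <- model$cfg$streams
  N <- model$N
  for (i in seq_len(s)) {
    dxb <- dxbip[, ((i - 1L) * N + 1L):(i * N), drop = FALSE]
    st <- ef$streams[[i]]
    dpre <- .normalize_rows_bwd(dxb, st$normed, st$sigma)
    mod_bwd(model$enc[[i]], st$tape, dpre, accum)
  }
  invisible(NULL)
}

#' Encode bit blocks
#'
#' Runs each row of `u` through the encoder streams (the final stream on
#' the interleaved input), normalizes each stream output to zero mean and
#' unit variance, binarizes, and concatenates the streams.
#'
#' @param u a 0/1 vector of length `block_bits`, or a matrix with one
#'   block per row.
#' @param model a [build_model()] bundle (or trained checkpoint model).
#' @return binary (0/1) matrix of encoded blocks, one per row, with
#'   `streams * (block_bits + latent_redundancy)` columns.
#' @export
encode_blocks <- function(u, model) {
  .assert(inherits(model, "dt_model"), "not a dt_model")
  if (is.vector(u)) u <- matrix(u, nrow = 1L)
  .assert(all(u %in% c(0, 1)), "u must be binary")
  ef <- .enc_forward(model, u, train = FALSE)
  (ef$xbip + 1) / 2
}

#' Encode bit blocks to DNA strands
#'
#' [encode_blocks()] followed by the bit-pair mapping `lambda`.
#'
#' @inheritParams encode_blocks
#' @return character vector of DNA strands of
#'   `streams * (block_bits + latent_redundancy) / 2` bases.
#' @export
encode_to_dna <- function(u, model) {
  x <- encode_blocks(u, model)
  apply(x, 1L, bits_to_dna)
}

## Bipolar code matrix (B, total_bits) -> integer base matrix (B, bases).
.bip_to_bases <- function(xbip) {
  B <- nrow(xbip)
  b1 <- (xbip[, seq(1L, ncol(xbip), 2L), drop = FALSE] + 1) / 2
  b2 <- (xbip[, seq(2L, ncol(xbip), 2L), drop = FALSE] + 1) / 2
  lut <- c(1L, 3L, 4L, 2L)               # 00->A 01->G 10->T 11->C in ACGT codes
  m <- lut[2L * b1 + b2 + 1L]
  dim(m) <- dim(b1)
  m
}

## ---- transcoder pass ------------------------------------------------------

## reads: list of integer base vectors (variable length). One-hot channel 5
## is the pad symbol; reads longer than the window are right-truncated.
.reads_to_onehot <- function(reads, window) {
  B <- length(reads)
  oh <- array(0, c(B, window, 5L))
  for (b in seq_len(B)) {
    x <- reads[[b]]
    L <- min(length(x), window)
    if (L > 0L) oh[cbind(b, seq_len(L), x[seq_len(L)])] <- 1
    if (L < window) oh[cbind(b, (L + 1L):window, 5L)] <- 1
  }
  oh
}

## Deterministic bypass transcoder: de-map bases to bipolar bits, pad with
## zeros / truncate to the decoder's expected length.
.bypass_transcode <- function(reads, total_bits) {
  B <- length(reads)
  Y <- matrix(0, B, total_bits)
  for (b in seq_len(B)) {
    x <- reads[[b]]
    if (!length(x)) next
    bits <- as.integer(t(.lambda_bits[x, , drop = FALSE])) * 2L - 1L
    L <- min(length(bits), total_bits)
    Y[b, seq_len(L)] <- bits[seq_len(L)]
  }
  Y
}

## Forward transcoder on a list of integer reads. Returns list(y, pre, tape,
## onehot_dims); y is the decoder input (binarized when configured).
.trans_forward <- function(model, reads, train = FALSE) {
  if (model$trans$kind == "bypass") {
    Y <- .bypass_transcode(reads, model$total_bits)
    return(list(y = Y, pre = Y, tape = NULL))
  }
  oh <- .reads_to_onehot(reads, model$window)
  r <- mod_fwd(model$trans, oh, train = train)
  pre <- r$y
  y <- if (model$cfg$binarize_transcoder) .binarize_bipolar(pre) else pre
  list(y = y, pre = pre, tape = r$tape)
}

#' Transcode a noisy read into the decoder's fixed-size input
#'
#' The indel-reduction component Q: fits a variable-length (possibly
#' empty) read into the fixed transcoder window (padding with a dedicated
#' pad symbol, right-truncating overlong reads) and maps it to a vector of
#' exactly `streams * (block_bits + latent_redundancy)` values, binarized
#' to -1/+1 when the binarized training mode is active and continuous
#' otherwise.
#'
#' @param noisy a `dt_noisy_read`, or a DNA string.
#' @param model a `dt_model`.
#' @return numeric vector of length `streams * (block_bits +
#'   latent_redundancy)`.
#' @export
transcode <- function(noisy, model) {
  .assert(inherits(model, "dt_model"), "not a dt_model")
  seq <- if (inherits(noisy, "dt_noisy_read")) noisy$sequence else noisy
  if (nchar(seq) > 0L) .check_dna(seq)
  reads <- list(.dna_to_int(seq))
  drop(.trans_forward(model, reads, train = FALSE)$y)
}

## ---- turbo decoder pass ---------------------------------------------------

.stack3 <- function(...) {
  mats <- list(...)
  B <- nrow(mats[[1L]]); L <- ncol(mats[[1L]])
  a <- array(0, c(B, L, length(mats)))
  for (i in seq_along(mats)) a[, , i] <- mats[[i]]
  a
}

## Y: matrix (B, total_bits). Returns list(logits (B, n), tapes) where the
## logits are the first n positions of the de-interleaved final posterior.
.dec_forward <- function(model, Y, train = FALSE) {
  cfg <- model$cfg
  B <- nrow(Y)
  N <- model$N
  pc <- model$perm_code
  ipc <- attr(pc, "inverse")
  third <- cfg$rate_mode == "third"
  y0 <- Y[, 1:N, drop = FALSE]
  y1 <- Y[, (N + 1L):(2L * N), drop = FALSE]
  y2 <- if (third) Y[, (2L * N + 1L):(3L * N), drop = FALSE] else NULL
  prior <- matrix(0, B, N)
  iters <- cfg$decoder_iterations
  tapes0 <- vector("list", iters)
  tapes1 <- vector("list", iters)
  for (it in seq_len(iters)) {
    in0 <- if (third) .stack3(y0, y1, prior) else .stack3(y0, prior)
    r0 <- mod_fwd(model$dec0, in0, train = train)
    q <- r0$y; dim(q) <- c(B, N)
    in1 <- if (third) {
      .stack3(q[, pc, drop = FALSE], y0[, pc, drop = FALSE], y2)
    } else {
      .stack3(q[, pc, drop = FALSE], y0[, pc, drop = FALSE], y1)
    }
    r1 <- mod_fwd(model$dec1, in1, train = train)
    z <- r1$y; dim(z) <- c(B, N)
    prior <- z[, ipc, drop = FALSE]
    if (train) { tapes0[[it]] <- r0$tape; tapes1[[it]] <- r1$tape }
  }
  list(logits = prior[, seq_len(model$n), drop = FALSE], prior = prior,
       tapes0 = tapes0, tapes1 = tapes1, B = B)
}

## Slice channel i of a (B, L, C) array, keeping matrix shape at B = 1.
.sl <- function(a, i) {
  m <- a[, , i]
  if (is.null(dim(m))) dim(m) <- dim(a)[1:2]
  m
}

## Backward through the unrolled iterations (shared weights accumulate).
## Returns d(loss)/dY when need_dY, else NULL.
.dec_backward <- function(model, df, dlogits, accum = TRUE, need_dY = FALSE) {
  cfg <- model$cfg
  B <- df$B
  N <- model$N
  pc <- model$perm_code
  ipc <- attr(pc, "inverse")
  third <- cfg$rate_mode == "third"
  dprior <- matrix(0, B, N)
  dprior[, seq_len(model$n)] <- dlogits
  dy0 <- matrix(0, B, N); dy1 <- matrix(0, B, N)
  dy2 <- if (third) matrix(0, B, N) else NULL
  for (it in rev(seq_len(cfg$decoder_iterations))) {
    dz <- dprior[, pc, drop = FALSE]
    dim(dz) <- c(B, N, 1L)
    din1 <- mod_bwd(model$dec1, df$tapes1[[it]], dz, accum)
    dqpc <- .sl(din1, 1L); dy0pc <- .sl(din1, 2L)
    if (third) dy2 <- dy2 + .sl(din1, 3L) else dy1 <- dy1 + .sl(din1, 3L)
    dq <- dqpc[, ipc, drop = FALSE]
    dy0 <- dy0 + dy0pc[, ipc, drop = FALSE]
    dim(dq) <- c(B, N, 1L)
    din0 <- mod_bwd(model$dec0, df$tapes0[[it]], dq, accum)
    dy0 <- dy0 + .sl(din0, 1L)
    if (third) {
      dy1 <- dy1 + .sl(din0, 2L)
      dprior <- .sl(din0, 3L)
    } else {
      dprior <- .sl(din0, 2L)
    }
  }
  if (!need_dY) return(invisible(NULL))
  if (third) cbind(dy0, dy1, dy2) else cbind(dy0, dy1)
}

#' Turbo-decode fixed-length code vectors
#'
#' Splits the input into the per-stream subsequences, runs the configured
#' number of iterations in which the two decoder networks exchange
#' posterior/prior information through the interleaver, and applies a
#' sigmoid threshold at 0.5 to the final de-interleaved posterior.
#'
#' @param y numeric vector of length `streams * (block_bits +
#'   latent_redundancy)` (or a matrix of such rows), e.g. a [transcode()]
#'   output.
#' @param model a `dt_model`.
#' @return 0/1 matrix of decoded blocks (`block_bits` columns).
#' @export
turbo_decode <- function(y, model) {
  .assert(inherits(model, "dt_model"), "not a dt_model")
  if (is.vector(y)) y <- matrix(y, nrow = 1L)
  .assert(ncol(y) == model$total_bits,
          "decoder input has %d values, expected %d", ncol(y), model$total_bits)
  df <- .dec_forward(model, y, train = FALSE)
  (1 / (1 + exp(-df$logits)) >= 0.5) * 1L
}

## ---- checkpointing --------------------------------------------------------

.model_state <- function(model) {
  list(enc = lapply(model$enc, function(m) cells_state(mod_cells(m))),
       trans = if (model$trans$kind == "bypass") NULL
               else cells_state(mod_cells(model$trans)),
       dec0 = cells_state(mod_cells(model$dec0)),
       dec1 = cells_state(mod_cells(model$dec1)))
}

.model_restore <- function(model, state) {
  for (i in seq_along(model$enc)) {
    cells_restore(mod_cells(model$enc[[i]]), state$enc[[i]])
  }
  if (!is.null(state$trans) && model$trans$kind != "bypass") {
    cells_restore(mod_cells(model$trans), state$trans)
  }
  cells_restore(mod_cells(model$dec0), state$dec0)
  cells_restore(mod_cells(model$dec1), state$dec1)
  invisible(model)
}

#' Save a training checkpoint
#'
#' Stores model weights, optimizer state, the full configuration
#' (including the interleaver spec), channel and constraint
#' configurations, the epoch counter, the training log and the RNG state
#' as plain R data.
#'
#' @param bundle a checkpoint bundle as assembled by [train()].
#' @param path file path (conventionally `checkpoint.rds`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(bundle, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(bundle, path)
  invisible(path)
}

#' Load a training checkpoint
#'
#' Rebuilds the model from the stored configuration and restores weights
#' and optimizer state.
#'
#' @param path checkpoint file path.
#' @return list with `model`, `cfg`, `channel`, `constraints`, `epoch`,
#'   `log`, `opt` (optimizer step counters), `random_seed`.
#' @export
load_checkpoint <- function(path) {
  .assert(file.exists(path), "checkpoint not found: %s", path)
  ck <- readRDS(path)
  .assert(!is.null(ck$cfg) && !is.null(ck$state), "malformed checkpoint")
  model <- build_model(ck$cfg, seed = ck$init_seed %||% 1L)
  .model_restore(model, ck$state)
  ck$model <- model
  ck
}

## Structural fields that must match for a resume to be accepted.
.structural_keys <- c("block_bits", "rate_mode", "streams", "latent_redundancy",
                      "encoder", "transcoder", "decoder", "units", "layers",
                      "kernel", "window_margin")

.check_resume_compatible <- function(cfg, ck_cfg) {
  for (k in .structural_keys) {
    if (!identical(cfg[[k]], ck_cfg[[k]])) {
      .stopf("checkpoint/config mismatch on resume: field '%s' is %s in the checkpoint but %s now",
             k, format(ck_cfg[[k]]), format(cfg[[k]]))
    }
  }
  invisible(TRUE)
}

#' @export
print.dt_model <- function(x, ...) {
  cat(sprintf("<dnaturbo model: %s encoder x%d | %s transcoder | %s decoder>\n",
              x$cfg$encoder, x$cfg$streams, x$cfg$transcoder, x$cfg$decoder))
  cat(sprintf("  block %d bits -> %d code bits -> %d-base strands (code rate %.4f)\n",
              x$n, x$total_bits, x$total_bits %/% 2L, code_rate(x$cfg)))
  invisible(x)
}
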