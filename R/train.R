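## Losses, metrics, the alternating-phase training schedule, constraint
## fine-tuning and the synthetic bit-block generator.

#' Smooth L1 loss
#'
#' Elementwise `0.5 * d^2 / beta` for `|d| < beta`, else `|d| - 0.5 *
#' beta`, with `d = u - uhat`; reduced by the mean over all elements.
#'
#' @param u,uhat numeric vectors or matrices of equal length.
#' @param beta positive transition point (default 1.0).
#' @return scalar loss.
#' @export
smooth_l1 <- function(u, uhat, beta = 1.0) {
  .assert(length(u) == length(uhat), "length mismatch: %d vs %d",
          length(u), length(uhat))
  .assert(beta > 0, "beta must be positive")
  d <- abs(u - uhat)
  q <- pmin(d, beta)                     # branchless piecewise form
  mean(0.5 * q * q / beta + (d - q))
}

## d(smooth_l1)/d(uhat) elementwise, without the mean reduction factor;
## the derivative is diff/beta clamped to [-1, 1].
.smooth_l1_d <- function(diff, beta) {
  pmin(pmax(diff / beta, -1), 1)
}

#' Bitwise reconstruction accuracy
#'
#' Fraction of positions where the decoded block equals the input block.
#'
#' @param u,uhat equal-length binary vectors (or matrices).
#' @return fraction in `[0, 1]`.
#' @export
reconstruction_accuracy <- function(u, uhat) {
  .assert(length(u) == length(uhat), "length mismatch: %d vs %d",
          length(u), length(uhat))
  mean(u == uhat)
}

#' Generate random bit blocks
#'
#' I.i.d. uniform bits, reproducible from the seed. Training data for the
#' codec are such seeded random blocks; no external dataset is involved.
#'
#' @param n number of blocks.
#' @param block_bits bits per block.
#' @param seed integer seed.
#' @return list of 0/1 integer vectors.
#' @export
generate_bit_blocks <- function(n, block_bits, seed = 1L) {
  .assert(block_bits > 0, "block_bits must be positive")
  if (n == 0) return(list())
  .assert(n > 0, "n must be >= 0")
  m <- .with_seed(seed, .rand_bits(n, block_bits))
  lapply(seq_len(n), function(i) m[i, ])
}

.rand_bits <- function(B, n) {
  matrix(as.integer(runif(B * n) < 0.5), B, n)
}

## ---- tensor-space channel surrogate (encoder phase) -----------------------

## A uniform base substitution flips each of the two mapped bits with
## probability 2/3; the encoder-phase surrogate therefore flips code-bit
## signs independently at rate (2/3) * total error rate. Indels are not
## modelled in the surrogate (see the methods vignette).
.flip_rate <- function(channel) {
  if (is.null(channel)) return(0)
  (2 / 3) * total_error_rate(channel)
}

.flip_mask <- function(B, ncol, p) {
  if (p <= 0) return(matrix(1, B, ncol))
  matrix(1 - 2 * (runif(B * ncol) < p), B, ncol)
}

## ---- constraint surrogate gradient (straight-through fine-tuning) ---------

## Value/gradient of a differentiable surrogate of the per-sequence
## constraint error probability, computed on the bipolar code bits. The
## GC term follows the configured (piecewise linear) GC graph evaluated at
## the soft GC fraction, plus a hinge pull toward 50% GC on zero-slope
## violation plateaus; the homopolymer term is a product-of-equalities
## soft indicator of runs reaching the graph's threshold length. k-mer
## and motif constraints contribute no gradient.
.hp_threshold <- function(graph) {
  if (is.null(graph)) return(NULL)
  base <- evaluate_graph(graph, 1)
  for (t in 2:30) {
    v <- evaluate_graph(graph, t)
    if (v > base + 1e-9) return(list(len = t, jump = v / 100))
  }
  NULL
}

.stability_surrogate_grad <- function(xbip, constraints) {
  B <- nrow(xbip)
  S <- ncol(xbip) %/% 2L
  a <- xbip[, seq(1L, 2L * S, 2L), drop = FALSE]
  b <- xbip[, seq(2L, 2L * S, 2L), drop = FALSE]
  da <- matrix(0, B, S); db <- matrix(0, B, S)
  p_gc <- rep(0, B); p_hp <- rep(0, B)
  dpgc_db <- matrix(0, B, S)
  dphp_da <- matrix(0, B, S); dphp_db <- matrix(0, B, S)
  if (!is.null(constraints$gc_graph)) {
    gfrac <- rowMeans((1 + b) / 2)       # G/C iff second mapped bit is 1
    gpct <- 100 * gfrac
    p_gc <- evaluate_graph(constraints$gc_graph, gpct) / 100
    slope <- .graph_slope(constraints$gc_graph, gpct)   # d%/d%
    dfrac <- slope / (2 * S)             # dp01/db_j
    plateau <- p_gc > 0 & abs(slope) < 1e-9
    pull <- ifelse(plateau, p_gc * sign(gfrac - 0.5) / (2 * S), 0)
    dpgc_db <- matrix(dfrac + pull, B, S)
  }
  hp <- .hp_threshold(constraints$homopolymer_graph)
  if (!is.null(hp) && S >= hp$len) {
    E <- ((1 + a[, -S, drop = FALSE] * a[, -1L, drop = FALSE]) / 2) *
         ((1 + b[, -S, drop = FALSE] * b[, -1L, drop = FALSE]) / 2)
    nb <- hp$len - 1L                    # equalities per run window
    nw <- S - hp$len + 1L                # windows
    W <- matrix(1, B, nw)
    for (o in 0:(nb - 1L)) W <- W * E[, (1:nw) + o, drop = FALSE]
    one <- W >= 1 - 1e-12
    nruns <- rowSums(one)
    P_any <- 1 - apply(1 - W, 1L, prod)
    p_hp <- hp$jump * P_any
    dPdW <- matrix(0, B, nw)
    dPdW[nruns == 0, ] <- 1
    if (any(nruns == 1)) {
      r1 <- nruns == 1
      dPdW[r1, ] <- one[r1, , drop = FALSE] * 1
    }
    dE <- matrix(0, B, S - 1L)
    for (o in 0:(nb - 1L)) {
      rest <- matrix(1, B, nw)
      for (o2 in setdiff(0:(nb - 1L), o)) {
        rest <- rest * E[, (1:nw) + o2, drop = FALSE]
      }
      dE[, (1:nw) + o] <- dE[, (1:nw) + o, drop = FALSE] + dPdW * rest
    }
    dE <- dE * hp$jump
    ## E_j depends on a_j, a_{j+1}, b_j, b_{j+1}
    eb <- (1 + b[, -S, drop = FALSE] * b[, -1L, drop = FALSE]) / 2
    ea <- (1 + a[, -S, drop = FALSE] * a[, -1L, drop = FALSE]) / 2
    dphp_da[, -S] <- dphp_da[, -S, drop = FALSE] + dE * (a[, -1L, drop = FALSE] / 2) * eb
    dphp_da[, -1L] <- dphp_da[, -1L, drop = FALSE] + dE * (a[, -S, drop = FALSE] / 2) * eb
    dphp_db[, -S] <- dphp_db[, -S, drop = FALSE] + dE * (b[, -1L, drop = FALSE] / 2) * ea
    dphp_db[, -1L] <- dphp_db[, -1L, drop = FALSE] + dE * (b[, -S, drop = FALSE] / 2) * ea
  }
  ## independent-failure combination p = 1 - (1 - p_gc)(1 - p_hp)
  p <- 1 - (1 - p_gc) * (1 - p_hp)
  db <- dpgc_db * (1 - p_hp) + dphp_db * (1 - p_gc)
  da <- dphp_da * (1 - p_gc)
  g <- matrix(0, B, 2L * S)
  g[, seq(1L, 2L * S, 2L)] <- da
  g[, seq(2L, 2L * S, 2L)] <- db
  list(p = p, grad = g / B)              # gradient of mean(p) over the batch
}

## ---- encoder loss ---------------------------------------------------------

#' Encoder loss on a batch
#'
#' Smooth L1 between the input bits and the decoded output, plus
#' `stability_weight * (1 - w_DNA)` where `w_DNA` is the hard stability
#' score of the batch's encoded DNA under the constraint configuration.
#' A stability weight of 0 recovers pure reconstruction training. The
#' encoder phase of [train()] uses the same forward path (with the
#' tensor-space channel surrogate).
#'
#' @param batch 0/1 matrix of input blocks (rows).
#' @param model a `dt_model`.
#' @param channel optional `dt_channel_config`; its total rate sets the
#'   surrogate sign-flip noise level (`NULL` = noiseless).
#' @param constraints optional `dt_constraint_config`.
#' @param stability_weight weight of the stability term.
#' @param seed optional seed for the surrogate noise.
#' @return list with `total`, `reconstruction`, `stability_term`,
#'   `w_DNA`.
#' @export
encoder_loss <- function(batch, model, channel = NULL, constraints = NULL,
                         stability_weight = 0, seed = NULL) {
  if (is.vector(batch)) batch <- matrix(batch, nrow = 1L)
  .with_seed(seed, {
    ef <- .enc_forward(model, batch, train = FALSE)
    M <- .flip_mask(nrow(batch), ncol(ef$xbip), .flip_rate(channel))
    df <- .dec_forward(model, ef$xbip * M, train = FALSE)
    uhat <- 1 / (1 + exp(-df$logits))
    rec <- smooth_l1(batch, uhat, model$cfg$beta)
    w_dna <- NA_real_
    stab <- 0
    if (stability_weight > 0) {
      .assert(!is.null(constraints), "stability_weight > 0 requires constraints")
      strands <- apply((ef$xbip + 1) / 2, 1L, bits_to_dna)
      w_dna <- stability_batch(strands, constraints)$w_DNA
      stab <- stability_weight * (1 - w_dna)
    }
    list(total = rec + stab, reconstruction = rec, stability_term = stab,
         w_DNA = w_dna)
  })
}

## ---- training -------------------------------------------------------------

## One encoder-phase step. Returns the reconstruction loss value.
.train_step_enc <- function(model, opt, B, flip_p, constraints,
                            stability_weight, beta) {
  U <- .rand_bits(B, model$n)
  ef <- .enc_forward(model, U, train = TRUE)
  M <- .flip_mask(B, ncol(ef$xbip), flip_p)
  df <- .dec_forward(model, ef$xbip * M, train = TRUE)
  uhat <- 1 / (1 + exp(-df$logits))
  loss <- smooth_l1(U, uhat, beta)
  dlogits <- .smooth_l1_d(uhat - U, beta) / length(U) * uhat * (1 - uhat)
  dY <- .dec_backward(model, df, dlogits, accum = FALSE, need_dY = TRUE)
  dxbip <- dY * M
  w_dna <- NA_real_
  if (stability_weight > 0 && !is.null(constraints)) {
    sg <- .stability_surrogate_grad(ef$xbip, constraints)
    dxbip <- dxbip + stability_weight * sg$grad
    strands <- apply((ef$xbip + 1) / 2, 1L, bits_to_dna)
    w_dna <- stability_batch(strands, constraints)$w_DNA
  }
  .enc_backward(model, ef, dxbip, accum = TRUE)
  adam_step(opt, .enc_cells(model))
  list(loss = loss, w_dna = w_dna)
}

## One decoder/transcoder-phase step through the real string channel.
.train_step_dec <- function(model, opt, B, rates, beta) {
  U <- .rand_bits(B, model$n)
  ef <- .enc_forward(model, U, train = FALSE)
  bases <- .bip_to_bases(ef$xbip)
  reads <- lapply(seq_len(B), function(i) .corrupt_int(bases[i, ], rates)$seq)
  tf <- .trans_forward(model, reads, train = TRUE)
  df <- .dec_forward(model, tf$y, train = TRUE)
  uhat <- 1 / (1 + exp(-df$logits))
  loss_dec <- smooth_l1(U, uhat, beta)
  dlogits <- .smooth_l1_d(uhat - U, beta) / length(U) * uhat * (1 - uhat)
  dY <- .dec_backward(model, df, dlogits, accum = TRUE, need_dY = TRUE)
  loss_trans <- 0
  if (model$trans$kind != "bypass") {
    ## supervised transcoder target: the (binarized) encoder output;
    ## straight-through makes both gradient paths act on the pre-binarized
    ## transcoder output
    tb <- if (model$cfg$binarize_transcoder) tf$y else tf$pre
    loss_trans <- smooth_l1(ef$xbip, tb, beta)
    dpre <- dY + .smooth_l1_d(tb - ef$xbip, beta) / length(tb)
    mod_bwd(model$trans, tf$tape, dpre, accum = TRUE)
  }
  adam_step(opt, .dec_cells(model))
  list(loss_dec = loss_dec, loss_trans = loss_trans)
}

## Full-pipeline evaluation batch (real channel, no gradients).
.eval_pipeline <- function(model, channel, B, constraints = NULL) {
  U <- .rand_bits(B, model$n)
  ef <- .enc_forward(model, U, train = FALSE)
  bases <- .bip_to_bases(ef$xbip)
  rates <- if (is.null(channel)) {
    c(substitution = 0, insertion = 0, deletion = 0)
  } else .combined_rates(channel)
  reads <- lapply(seq_len(B), function(i) .corrupt_int(bases[i, ], rates)$seq)
  tf <- .trans_forward(model, reads, train = FALSE)
  df <- .dec_forward(model, tf$y, train = FALSE)
  uhat <- (df$logits >= 0) * 1L
  acc_blocks <- rowMeans(uhat == U)
  w_dna <- NA_real_
  if (!is.null(constraints)) {
    strands <- apply((ef$xbip + 1) / 2, 1L, bits_to_dna)
    w_dna <- stability_batch(strands, constraints)$w_DNA
  }
  list(accuracy = mean(acc_blocks), perfect = mean(acc_blocks == 1),
       block_accuracy = acc_blocks, w_dna = w_dna)
}

## Non-structural keys that may be changed online via the config file.
.online_keys <- c("learning_rate", "t_enc", "t_dec", "batch_size", "beta",
                  "stability_weight", "decoder_iterations")

.maybe_reread_config <- function(cfg, config_path) {
  if (is.null(config_path) || !file.exists(config_path)) return(cfg)
  x <- tryCatch(jsonlite::read_json(config_path, simplifyVector = TRUE),
                error = function(e) NULL)
  if (is.null(x)) return(cfg)
  for (k in intersect(names(x), .online_keys)) {
    old <- cfg[[k]]
    new <- if (is.integer(old)) as.integer(x[[k]]) else as.numeric(x[[k]])
    if (!identical(old, new)) {
      .dt_log("info", sprintf("online hyperparameter change: %s %s -> %s",
                              k, format(old), format(new)))
      cfg[[k]] <- new
    }
  }
  structural <- setdiff(intersect(names(x), names(cfg)), .online_keys)
  if (length(structural)) {
    .dt_log("warn", "ignoring structural keys in online config: ",
            paste(structural, collapse = ", "))
  }
  cfg
}

#' Train a codec
#'
#' Per epoch, an alternating schedule: `t_enc` encoder-phase batches
#' (decoder and transcoder frozen, tensor-space channel surrogate) followed
#' by `t_dec` decoder/transcoder-phase batches (encoder frozen, real
#' string channel with substitutions, insertions and deletions). Each
#' batch uses fresh seeded random bit blocks. After every epoch a log
#' record (component losses, reconstruction accuracy, stability score,
#' noise level and fraction of perfectly recovered blocks) is appended,
#' and, when `checkpoint_dir` is given, a checkpoint plus a JSON-lines log
#' file are written; training resumes bit-identically from the stored RNG
#' state.
#'
#' @param cfg a [codec_config()].
#' @param epochs number of epochs (0 writes an initialized checkpoint and
#'   an empty log).
#' @param seed integer master seed.
#' @param channel a `dt_channel_config` (or `NULL` for a noiseless
#'   channel).
#' @param constraints optional `dt_constraint_config` used when
#'   `cfg$stability_weight > 0` and for per-epoch stability logging.
#' @param checkpoint_dir optional directory for `checkpoint.rds`,
#'   `run_config.json` and `train_log.jsonl`.
#' @param resume continue from the checkpoint in `checkpoint_dir`.
#' @param config_path optional JSON file re-read at each epoch boundary;
#'   non-structural hyperparameters found there take effect online.
#' @return list with `model`, `log` (one row per epoch), `epoch`, and
#'   `checkpoint` (path or `NULL`).
#' @export
train <- function(cfg, epochs, seed, channel = NULL, constraints = NULL,
                  checkpoint_dir = NULL, resume = FALSE, config_path = NULL) {
  .assert(inherits(cfg, "dt_codec_config"), "not a codec config")
  .assert(epochs >= 0, "epochs must be >= 0")
  log <- data.frame()
  start_epoch <- 1L
  opt_enc <- adam_new(lr = cfg$learning_rate)
  opt_dec <- adam_new(lr = cfg$learning_rate)
  if (resume) {
    .assert(!is.null(checkpoint_dir), "resume requires checkpoint_dir")
    ck <- load_checkpoint(file.path(checkpoint_dir, "checkpoint.rds"))
    .check_resume_compatible(cfg, ck$cfg)
    model <- ck$model
    log <- ck$log
    start_epoch <- ck$epoch + 1L
    opt_enc$t <- ck$opt$enc_t
    opt_dec$t <- ck$opt$dec_t
    if (!is.null(ck$random_seed)) {
      assign(".Random.seed", ck$random_seed, envir = globalenv())
    }
    .dt_log("info", sprintf("resuming after epoch %d", ck$epoch))
  } else {
    set.seed(as.integer(seed))
    model <- build_model(cfg, seed = .child_seed(seed, 1L))
  }
  rates <- if (is.null(channel)) {
    c(substitution = 0, insertion = 0, deletion = 0)
  } else .combined_rates(channel)
  noise_level <- sum(rates)
  write_out <- function(epoch) {
    if (is.null(checkpoint_dir)) return(NULL)
    bundle <- list(cfg = model$cfg, channel = channel,
                   constraints = constraints,
                   state = .model_state(model), epoch = epoch, log = log,
                   opt = list(enc_t = opt_enc$t, dec_t = opt_dec$t),
                   init_seed = .child_seed(seed, 1L),
                   random_seed = get(".Random.seed", envir = globalenv()),
                   package = "dnaturbo")
    path <- file.path(checkpoint_dir, "checkpoint.rds")
    save_checkpoint(bundle, path)
    jsonlite::write_json(
      lapply(seq_len(nrow(log)), function(i) as.list(log[i, ])),
      file.path(checkpoint_dir, "train_log.jsonl"), auto_unbox = TRUE,
      digits = NA)
    path
  }
  if (epochs == 0L || start_epoch > epochs) {
    path <- write_out(start_epoch - 1L)
    return(list(model = model, log = log, epoch = start_epoch - 1L,
                checkpoint = path))
  }
  for (epoch in start_epoch:epochs) {
    cfg_now <- .maybe_reread_config(model$cfg, config_path)
    model$cfg <- cfg_now
    opt_enc$lr <- cfg_now$learning_rate
    opt_dec$lr <- cfg_now$learning_rate
    B <- cfg_now$batch_size
    flip_p <- .flip_rate(channel)
    enc_losses <- numeric(0); w_dna_log <- NA_real_
    for (t in seq_len(cfg_now$t_enc)) {
      r <- .train_step_enc(model, opt_enc, B, flip_p, constraints,
                           cfg_now$stability_weight, cfg_now$beta)
      enc_losses <- c(enc_losses, r$loss)
      if (!is.na(r$w_dna)) w_dna_log <- r$w_dna
    }
    dec_losses <- numeric(0); trans_losses <- numeric(0)
    for (t in seq_len(cfg_now$t_dec)) {
      r <- .train_step_dec(model, opt_dec, B, rates, cfg_now$beta)
      dec_losses <- c(dec_losses, r$loss_dec)
      trans_losses <- c(trans_losses, r$loss_trans)
    }
    ev <- .eval_pipeline(model, channel, B, constraints)
    stab <- if (!is.na(ev$w_dna)) ev$w_dna else w_dna_log
    log <- rbind(log, data.frame(
      epoch = epoch,
      loss_encoder = if (length(enc_losses)) mean(enc_losses) else NA_real_,
      loss_decoder = if (length(dec_losses)) mean(dec_losses) else NA_real_,
      loss_transcoder = if (length(trans_losses)) mean(trans_losses) else NA_real_,
      accuracy = ev$accuracy,
      stability = stab,
      noise_level = noise_level,
      perfect_blocks = ev$perfect))
    write_out(epoch)
    .dt_log("debug", sprintf("epoch %d: acc %.4f perfect %.3f", epoch,
                             ev$accuracy, ev$perfect))
  }
  path <- if (!is.null(checkpoint_dir)) file.path(checkpoint_dir, "checkpoint.rds") else NULL
  list(model = model, log = log, epoch = epochs, checkpoint = path)
}

#' Fine-tune a trained codec for constraint adherence
#'
#' Continues training from a checkpoint with a positive stability weight,
#' so the encoder receives the `(1 - w_DNA)` constraint term in addition
#' to the reconstruction loss. The stability score is logged per epoch.
#'
#' @param checkpoint path to a `checkpoint.rds`, or a loaded checkpoint.
#' @param constraints a `dt_constraint_config`.
#' @param epochs number of additional epochs.
#' @param stability_weight weight of the stability term (default 1.0).
#' @param seed seed (used only when continuing without a stored RNG
#'   state).
#' @param checkpoint_dir optional output directory for the fine-tuned
#'   checkpoint.
#' @param t_enc,t_dec optional overrides of the per-epoch batch counts.
#' @return as [train()].
#' @export
fine_tune_constraints <- function(checkpoint, constraints, epochs,
                                  stability_weight = 1.0, seed = 1L,
                                  checkpoint_dir = NULL,
                                  t_enc = NULL, t_dec = NULL) {
  ck <- if (is.character(checkpoint)) load_checkpoint(checkpoint) else checkpoint
  .assert(inherits(constraints, "dt_constraint_config"), "not a constraint config")
  model <- ck$model
  cfg <- model$cfg
  cfg$stability_weight <- stability_weight
  if (!is.null(t_enc)) cfg$t_enc <- as.integer(t_enc)
  if (!is.null(t_dec)) cfg$t_dec <- as.integer(t_dec)
  model$cfg <- cfg
  if (epochs == 0L) {
    return(list(model = model, log = ck$log, epoch = ck$epoch,
                checkpoint = NULL))
  }
  if (!is.null(ck$random_seed)) {
    assign(".Random.seed", ck$random_seed, envir = globalenv())
  } else {
    set.seed(as.integer(seed))
  }
  opt_enc <- adam_new(lr = cfg$learning_rate); opt_enc$t <- ck$opt$enc_t %||% 0L
  opt_dec <- adam_new(lr = cfg$learning_rate); opt_dec$t <- ck$opt$dec_t %||% 0L
  rates <- if (is.null(ck$channel)) {
    c(substitution = 0, insertion = 0, deletion = 0)
  } else .combined_rates(ck$channel)
  log <- data.frame()
  flip_p <- .flip_rate(ck$channel)
  B <- cfg$batch_size
  for (epoch in seq_len(epochs)) {
    enc_losses <- numeric(0); w_dna <- NA_real_
    for (t in seq_len(cfg$t_enc)) {
      r <- .train_step_enc(model, opt_enc, B, flip_p, constraints,
                           stability_weight, cfg$beta)
      enc_losses <- c(enc_losses, r$loss)
      if (!is.na(r$w_dna)) w_dna <- r$w_dna
    }
    dec_losses <- numeric(0)
    for (t in seq_len(cfg$t_dec)) {
      r <- .train_step_dec(model, opt_dec, B, rates, cfg$beta)
      dec_losses <- c(dec_losses, r$loss_dec)
    }
    ev <- .eval_pipeline(model, ck$channel, B, constraints)
    log <- rbind(log, data.frame(
      epoch = (ck$epoch %||% 0L) + epoch,
      loss_encoder = mean(enc_losses),
      loss_decoder = if (length(dec_losses)) mean(dec_losses) else NA_real_,
      loss_transcoder = NA_real_,
      accuracy = ev$accuracy, stability = ev$w_dna,
      noise_level = sum(rates), perfect_blocks = ev$perfect))
  }
  path <- NULL
  if (!is.null(checkpoint_dir)) {
    bundle <- list(cfg = model$cfg, channel = ck$channel,
                   constraints = constraints, state = .model_state(model),
                   epoch = (ck$epoch %||% 0L) + epochs,
                   log = rbind(ck$log, log),
                   opt = list(enc_t = opt_enc$t, dec_t = opt_dec$t),
                   init_seed = ck$init_seed %||% 1L,
                   random_seed = get(".Random.seed", envir = globalenv()),
                   package = "dnaturbo")
    path <- save_checkpoint(bundle, file.path(checkpoint_dir, "checkpoint.rds"))
  }
  list(model = model, log = log, epoch = (ck$epoch %||% 0L) + epochs,
       checkpoint = path)
}

#' Evaluate a model over the full pipeline
#'
#' Encodes `n_blocks` fresh random blocks, maps to DNA, transmits through
#' the channel, transcodes and turbo-decodes, and reports reconstruction
#' accuracy, the fraction of perfectly recovered blocks and (when
#' constraints are given) the batch stability score.
#'
#' @param model a `dt_model`.
#' @param channel `dt_channel_config` or `NULL` (noiseless).
#' @param n_blocks number of blocks.
#' @param seed integer seed.
#' @param constraints optional `dt_constraint_config`.
#' @return list with `accuracy`, `perfect_fraction`, `stability`, `n`.
#' @export
evaluate_model <- function(model, channel, n_blocks, seed = 1L,
                           constraints = NULL) {
  if (n_blocks == 0) {
    return(list(accuracy = NA_real_, perfect_fraction = NA_real_,
                stability = NA_real_, n = 0L))
  }
  .with_seed(seed, {
    ev <- .eval_pipeline(model, channel, n_blocks, constraints)
    list(accuracy = ev$accuracy, perfect_fraction = ev$perfect,
         stability = ev$w_dna, n = as.integer(n_blocks))
  })
}
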