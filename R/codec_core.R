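## Deterministic codec machinery: interleavers, block normalization,
## straight-through binarization, bit/base mapping and payload segmentation.

#' Construct an interleaver specification
#'
#' Two modes are supported: `"pseudo_random"` (a permutation drawn
#' reproducibly from `seed`) and `"deterministic"`, the affine permutation
#' `pi(i) = (k * i + u) mod N` for `0 <= i < N`, which is a bijection iff
#' `gcd(k, N) = 1`.
#'
#' @param mode `"pseudo_random"` or `"deterministic"`.
#' @param seed integer seed (pseudo-random mode).
#' @param k,u integers of the affine form (deterministic mode).
#' @return object of class `dt_interleaver_spec`.
#' @export
interleaver_spec <- function(mode = c("pseudo_random", "deterministic"),
                             seed = 1L, k = 1L, u = 0L) {
  mode <- match.arg(mode)
  structure(list(mode = mode, seed = as.integer(seed),
                 k = as.integer(k), u = as.integer(u)),
            class = "dt_interleaver_spec")
}

#' Generate an interleaver permutation
#'
#' @param spec an [interleaver_spec()].
#' @param length permutation length `N`.
#' @return integer permutation of `1..N` (1-based) with attribute
#'   `"inverse"` holding the inverse permutation: `x[perm]` interleaves,
#'   `x[attr(perm, "inverse")]` de-interleaves.
#' @export
make_interleaver <- function(spec, length) {
  .assert(inherits(spec, "dt_interleaver_spec"), "not an interleaver spec")
  N <- as.integer(length)
  .assert(N >= 1L, "interleaver length must be positive")
  if (spec$mode == "deterministic") {
    if (.gcd(spec$k, N) != 1L) {
      .stopf("invalid interleaver spec: gcd(k = %d, N = %d) != 1, not a bijection",
             spec$k, N)
    }
    i <- 0:(N - 1L)
    perm <- ((spec$k * i + spec$u) %% N) + 1L
  } else {
    perm <- .with_seed(.child_seed(spec$seed, N), sample.int(N))
  }
  attr(perm, "inverse") <- order(perm)
  perm
}

#' Normalize a block to zero mean and unit standard deviation
#'
#' `x_i = (b_i - mu(b)) / sigma(b)` with the population standard
#' deviation. A constant (degenerate) block returns zeros with a warning.
#'
#' @param b numeric vector.
#' @return normalized numeric vector.
#' @export
normalize_block <- function(b) {
  .assert(is.numeric(b) && length(b) >= 1L, "block must be a numeric vector")
  mu <- mean(b)
  sigma <- sqrt(mean((b - mu)^2))
  if (sigma == 0) {
    warning("degenerate (constant) block: returning zeros", call. = FALSE)
    return(rep(0, length(b)))
  }
  (b - mu) / sigma
}

## Row-wise population normalization of a matrix; returns list(y, sigma, mu)
## for use in backward passes.
.normalize_rows <- function(x) {
  mu <- rowMeans(x)
  xc <- x - mu
  sigma <- sqrt(rowMeans(xc * xc))
  sigma[sigma == 0] <- 1
  list(y = xc / sigma, sigma = sigma)
}

## Backward of row-wise normalization: given y and sigma from forward.
.normalize_rows_bwd <- function(dy, y, sigma) {
  (dy - rowMeans(dy) - y * rowMeans(dy * y)) / sigma
}

#' Binarize a real vector (straight-through forward value)
#'
#' Forward thresholding at zero: values `>= 0` map to 1, values `< 0` map
#' to 0. During training the straight-through contract treats the
#' operation's derivative as the identity, so gradients pass through
#' unchanged; the training code applies that contract internally.
#'
#' @param x numeric vector (or matrix).
#' @return binary vector/matrix of 0/1.
#' @export
binarize <- function(x) {
  (x >= 0) * 1
}

## Internal bipolar binarization {-1, +1}; ties at 0 map to +1.
.binarize_bipolar <- function(x) {
  (x >= 0) * 2 - 1
}

## Bit-pair -> base mapping lambda: 00->A, 01->G, 10->T, 11->C.
.lambda_bases <- c("A", "G", "T", "C")
## base code (A=1,C=2,G=3,T=4 as in .dna_alphabet) -> (bit1, bit2)
.lambda_bits <- matrix(c(0L, 0L,   # A
                         1L, 1L,   # C
                         0L, 1L,   # G
                         1L, 0L),  # T
                       nrow = 4L, byrow = TRUE)

#' Map a binary vector to a DNA string
#'
#' Consecutive bit pairs are mapped through `lambda`: 00 -> A, 01 -> G,
#' 10 -> T, 11 -> C.
#'
#' @param bits binary vector of even length.
#' @return DNA string of `length(bits) / 2` bases.
#' @export
bits_to_dna <- function(bits) {
  .assert(length(bits) %% 2L == 0L, "bit vector must have even length")
  if (length(bits) == 0L) return("")
  .assert(all(bits %in% c(0, 1)), "bits must be 0/1")
  b1 <- bits[seq(1L, length(bits), by = 2L)]
  b2 <- bits[seq(2L, length(bits), by = 2L)]
  paste0(.lambda_bases[2L * b1 + b2 + 1L], collapse = "")
}

#' Map a DNA string back to its binary representation
#'
#' Exact inverse of [bits_to_dna()].
#'
#' @param seq DNA string over `{A,C,G,T}`.
#' @return integer vector of bits, length `2 * nchar(seq)`.
#' @export
dna_to_bits <- function(seq) {
  .check_dna(seq)
  x <- .dna_to_int(seq)
  if (length(x) == 0L) return(integer(0))
  as.integer(t(.lambda_bits[x, , drop = FALSE]))
}

#' Construct a codec configuration
#'
#' @param block_bits message block length n in bits.
#' @param rate_mode `"third"` (three encoder streams) or `"half"` (two).
#' @param latent_redundancy extra output units per encoder stream beyond
#'   `block_bits`; fractionally lowers the code rate.
#' @param decoder_iterations number of turbo iterations (default 6).
#' @param beta smooth-L1 beta (default 1.0).
#' @param interleaver an [interleaver_spec()].
#' @param encoder,transcoder,decoder architecture names. Encoder:
#'   `"cnn"`, `"rnn"`, `"vae"`, `"transformer"`. Transcoder: `"cnn"`,
#'   `"rnn"`, `"resnet"`, plus the deterministic `"bypass"` de-mapper.
#'   Decoder: `"cnn"`, `"rnn"`, `"resnet"`, `"transformer"`.
#' @param units hidden width / channel count of each network.
#' @param layers trunk depth of each network.
#' @param kernel convolution kernel size (odd).
#' @param window_margin extra bases of transcoder input window beyond the
#'   nominal strand length (absorbs indel-induced length changes).
#' @param binarize_transcoder binarize the transcoder output (straight
#'   through) before decoding; `FALSE` passes continuous values.
#' @param kl_weight KL term weight for the VAE encoder (0 disables).
#' @param batch_size,learning_rate,t_enc,t_dec,stability_weight training
#'   hyperparameters: batch size, Adam learning rate, encoder-phase and
#'   decoder-phase batches per epoch, and the weight of the
#'   `(1 - w_DNA)` stability term in the encoder loss.
#' @return object of class `dt_codec_config`.
#' @export
codec_config <- function(block_bits = 64L,
                         rate_mode = c("third", "half"),
                         latent_redundancy = 0L,
                         decoder_iterations = 6L,
                         beta = 1.0,
                         interleaver = interleaver_spec("pseudo_random", seed = 42L),
                         encoder = "cnn",
                         transcoder = "resnet",
                         decoder = "cnn",
                         units = 100L,
                         layers = 2L,
                         kernel = 5L,
                         window_margin = 8L,
                         binarize_transcoder = TRUE,
                         kl_weight = 1e-3,
                         batch_size = 256L,
                         learning_rate = 1e-4,
                         t_enc = 100L,
                         t_dec = 500L,
                         stability_weight = 0) {
  rate_mode <- match.arg(rate_mode)
  block_bits <- as.integer(block_bits)
  latent_redundancy <- as.integer(latent_redundancy)
  .assert(block_bits > 0L, "block_bits must be positive")
  .assert(latent_redundancy >= 0L, "latent_redundancy must be >= 0")
  .assert(decoder_iterations >= 1L, "decoder_iterations must be >= 1")
  .assert(beta > 0, "beta must be positive")
  .assert(kernel %% 2L == 1L, "kernel size must be odd")
  streams <- if (rate_mode == "third") 3L else 2L
  total_bits <- streams * (block_bits + latent_redundancy)
  .assert(total_bits %% 2L == 0L,
          "total encoded bits (%d) must be even to map to bases", total_bits)
  cfg <- structure(list(
    block_bits = block_bits, rate_mode = rate_mode, streams = streams,
    latent_redundancy = latent_redundancy,
    decoder_iterations = as.integer(decoder_iterations), beta = beta,
    interleaver = interleaver,
    encoder = encoder, transcoder = transcoder, decoder = decoder,
    units = as.integer(units), layers = as.integer(layers),
    kernel = as.integer(kernel),
    window_margin = as.integer(window_margin),
    binarize_transcoder = isTRUE(binarize_transcoder),
    kl_weight = kl_weight,
    batch_size = as.integer(batch_size), learning_rate = learning_rate,
    t_enc = as.integer(t_enc), t_dec = as.integer(t_dec),
    stability_weight = stability_weight
  ), class = "dt_codec_config")
  .validate_architectures(cfg)
  cfg
}

#' Code rate of a codec configuration
#'
#' `block_bits / (streams * (block_bits + latent_redundancy))`.
#'
#' @param cfg a [codec_config()].
#' @return numeric code rate.
#' @export
code_rate <- function(cfg) {
  .assert(inherits(cfg, "dt_codec_config"), "not a codec config")
  cfg$block_bits / (cfg$streams * (cfg$block_bits + cfg$latent_redundancy))
}

## Derived sizes.
.stream_len <- function(cfg) cfg$block_bits + cfg$latent_redundancy
.total_bits <- function(cfg) cfg$streams * .stream_len(cfg)
.strand_bases <- function(cfg) .total_bits(cfg) %/% 2L

#' Segment a byte payload into fixed-size bit blocks
#'
#' Bits are taken in `rawToBits()` order (LSB-first per byte); the final
#' block is zero-padded. The returned header records everything needed to
#' invert the segmentation exactly.
#'
#' @param data raw vector (byte stream).
#' @param block_bits bits per block.
#' @return list with `blocks` (list of 0/1 integer vectors) and `header`
#'   (`payload_bits`, `block_bits`, `n_blocks`, `pad_bits`).
#' @export
segment_payload <- function(data, block_bits) {
  .assert(is.raw(data), "data must be a raw vector")
  block_bits <- as.integer(block_bits)
  .assert(block_bits > 0L, "block_bits must be positive")
  bits <- as.integer(rawToBits(data))
  nb <- length(bits)
  if (nb == 0L) {
    return(list(blocks = list(),
                header = list(payload_bits = 0L, block_bits = block_bits,
                              n_blocks = 0L, pad_bits = 0L)))
  }
  n_blocks <- ceiling(nb / block_bits)
  pad <- n_blocks * block_bits - nb
  bits <- c(bits, integer(pad))
  blocks <- split(bits, rep(seq_len(n_blocks), each = block_bits))
  names(blocks) <- NULL
  list(blocks = blocks,
       header = list(payload_bits = nb, block_bits = block_bits,
                     n_blocks = as.integer(n_blocks), pad_bits = as.integer(pad)))
}

#' Reassemble a byte payload from bit blocks
#'
#' Exact inverse of [segment_payload()].
#'
#' @param blocks list of 0/1 integer vectors.
#' @param header header list produced by [segment_payload()].
#' @return raw vector.
#' @export
reassemble_payload <- function(blocks, header) {
  if (header$payload_bits == 0L) return(raw(0))
  .assert(length(blocks) == header$n_blocks,
          "expected %d blocks, got %d", header$n_blocks, length(blocks))
  bits <- unlist(blocks, use.names = FALSE)[seq_len(header$payload_bits)]
  packBits(as.integer(bits) != 0L, type = "raw")
}

#' @export
print.dt_codec_config <- function(x, ...) {
  cat(sprintf(
    "<dnaturbo codec config: block %d bits, rate 1/%d + redundancy %d (code rate %.4f)>\n",
    x$block_bits, x$streams, x$latent_redundancy, code_rate(x)))
  cat(sprintf("  encoder %s | transcoder %s | decoder %s (%d iterations)\n",
              x$encoder, x$transcoder, x$decoder, x$decoder_iterations))
  invisible(x)
}
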