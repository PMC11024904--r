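## Architecture catalogs and network builders for the three codec
## components. Every network is a "module": either a sequential layer
## stack or the custom VAE encoder, with a uniform fwd/bwd interface.

.arch_sets <- list(
  encoder = c("cnn", "rnn", "vae", "transformer"),
  transcoder = c("cnn", "rnn", "resnet", "bypass"),
  decoder = c("cnn", "rnn", "resnet", "transformer")
)

.validate_architectures <- function(cfg) {
  for (comp in names(.arch_sets)) {
    a <- cfg[[comp]]
    if (!a %in% .arch_sets[[comp]]) {
      .stopf("unsupported %s architecture '%s'; valid options: %s",
             comp, a, paste(.arch_sets[[comp]], collapse = ", "))
    }
  }
  invisible(TRUE)
}

mod_seq <- function(layers) list(kind = "seq", layers = layers)

mod_fwd <- function(mod, x, train = TRUE) {
  if (mod$kind == "seq") return(net_fwd(mod$layers, x))
  if (mod$kind == "vae") return(.vae_fwd(mod, x, train))
  .stopf("unknown module kind '%s'", mod$kind)
}

mod_bwd <- function(mod, tape, dy, accum = TRUE) {
  if (mod$kind == "seq") return(net_bwd(mod$layers, tape, dy, accum))
  if (mod$kind == "vae") return(.vae_bwd(mod, tape, dy, accum))
  .stopf("unknown module kind '%s'", mod$kind)
}

mod_cells <- function(mod) {
  if (mod$kind == "seq") return(net_cells(mod$layers))
  if (mod$kind == "vae") {
    return(c(net_cells(mod$trunk), net_cells(mod$mu_head),
             net_cells(mod$lv_head), net_cells(mod$out_head)))
  }
  .stopf("unknown module kind '%s'", mod$kind)
}

## ---- VAE encoder stream ---------------------------------------------------
## Dense trunk -> (mu, logvar) heads -> reparameterized latent -> output
## head. At inference the latent collapses to mu (deterministic encoding).
## The KL term (weighted by kl_weight) is injected into the backward pass.

mod_vae <- function(n_in, n_out, units, layers, kl_weight) {
  trunk <- list(layer_flatten(), layer_dense(n_in, units, first = TRUE), layer_elu())
  if (layers > 1L) {
    for (i in seq_len(layers - 1L)) {
      trunk <- c(trunk, list(layer_dense(units, units), layer_elu()))
    }
  }
  list(kind = "vae",
       trunk = trunk,
       mu_head = list(layer_dense(units, units)),
       lv_head = list(layer_dense(units, units, init_sd = 1e-2)),
       out_head = list(layer_dense(units, n_out)),
       latent = units, kl_weight = kl_weight)
}

.vae_fwd <- function(mod, x, train = TRUE) {
  rt <- net_fwd(mod$trunk, x)
  rmu <- net_fwd(mod$mu_head, rt$y)
  rlv <- net_fwd(mod$lv_head, rt$y)
  eps <- if (train) {
    matrix(rnorm(length(rmu$y)), nrow(rmu$y), ncol(rmu$y))
  } else {
    matrix(0, nrow(rmu$y), ncol(rmu$y))
  }
  z <- rmu$y + eps * exp(0.5 * rlv$y)
  ro <- net_fwd(mod$out_head, z)
  kl <- 0.5 * mean(exp(rlv$y) + rmu$y^2 - 1 - rlv$y)
  list(y = ro$y,
       tape = list(trunk = rt$tape, mu = rmu$tape, lv = rlv$tape,
                   out = ro$tape, eps = eps, mu_y = rmu$y, lv_y = rlv$y,
                   kl = kl))
}

.vae_bwd <- function(mod, tape, dy, accum = TRUE) {
  dz <- net_bwd(mod$out_head, tape$out, dy, accum)
  dmu <- dz
  dlv <- dz * tape$eps * 0.5 * exp(0.5 * tape$lv_y)
  if (mod$kl_weight > 0 && accum) {
    nel <- length(tape$mu_y)
    dmu <- dmu + mod$kl_weight * tape$mu_y / nel
    dlv <- dlv + mod$kl_weight * 0.5 * (exp(tape$lv_y) - 1) / nel
  }
  dh <- net_bwd(mod$mu_head, tape$mu, dmu, accum) +
    net_bwd(mod$lv_head, tape$lv, dlv, accum)
  net_bwd(mod$trunk, tape$trunk, dh, accum)
}

## ---- builders -------------------------------------------------------------

.build_encoder_net <- function(arch, n_in, n_out, units, layers, kernel,
                               kl_weight) {
  U <- units
  if (arch == "vae") return(mod_vae(n_in, n_out, U, layers, kl_weight))
  ls <- switch(arch,
    cnn = {
      l <- list(layer_conv1d(1L, U, kernel, first = TRUE), layer_elu())
      for (i in seq_len(max(0L, layers - 1L))) {
        l <- c(l, list(layer_conv1d(U, U, kernel), layer_elu()))
      }
      l
    },
    rnn = list(layer_rnn(1L, U, first = TRUE)),
    transformer = list(layer_conv1d(1L, U, 1L, first = TRUE), layer_attention(U))
  )
  ls <- c(ls, list(layer_flatten(), layer_dense(n_in * U, n_out)))
  mod_seq(ls)
}

.build_transcoder_net <- function(arch, window, n_out, units, layers, kernel) {
  if (arch == "bypass") return(list(kind = "bypass"))
  U <- units
  ls <- switch(arch,
    cnn = {
      l <- list(layer_conv1d(5L, U, kernel, first = TRUE), layer_elu())
      for (i in seq_len(max(0L, layers - 1L))) {
        l <- c(l, list(layer_conv1d(U, U, kernel), layer_elu()))
      }
      l
    },
    resnet = list(layer_conv1d(5L, U, kernel, first = TRUE), layer_elu(),
                  layer_residual(list(layer_conv1d(U, U, kernel), layer_elu(),
                                      layer_conv1d(U, U, kernel))),
                  layer_elu()),
    rnn = list(layer_rnn(5L, U, first = TRUE))
  )
  ls <- c(ls, list(layer_flatten(), layer_dense(window * U, n_out)))
  mod_seq(ls)
}

.build_decoder_net <- function(arch, c_in, units, layers, kernel) {
  U <- units
  ls <- switch(arch,
    cnn = {
      l <- list(layer_conv1d(c_in, U, kernel), layer_elu())
      for (i in seq_len(max(0L, layers - 1L))) {
        l <- c(l, list(layer_conv1d(U, U, kernel), layer_elu()))
      }
      l
    },
    resnet = list(layer_conv1d(c_in, U, kernel), layer_elu(),
                  layer_residual(list(layer_conv1d(U, U, kernel), layer_elu(),
                                      layer_conv1d(U, U, kernel))),
                  layer_elu()),
    rnn = list(layer_rnn(c_in, U)),
    transformer = list(layer_conv1d(c_in, U, 1L), layer_attention(U))
  )
  ls <- c(ls, list(layer_conv1d(U, 1L, 1L)))
  mod_seq(ls)
}
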