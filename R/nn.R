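## Minimal neural-network layer library with manual backpropagation.
## No deep-learning runtime is available in the target environment, so the
## layers needed by the codec (dense, 1-D convolution, Elman RNN,
## single-head self-attention, residual blocks, ELU) are implemented
## directly on BLAS-backed matrix operations.
##
## Conventions: sequence tensors are arrays of dim (batch, length,
## channels); feature tensors are matrices (batch, features). Every layer
## is a list with closures `fwd(x) -> list(y, cache)` and
## `bwd(cache, dy, accum) -> dx`; parameters live in environment cells so
## repeated applications of the same layer (weight sharing across turbo
## iterations) accumulate gradients in place. `accum = FALSE` propagates
## gradients without updating the layer (frozen components).

.pcell <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- 0
  e$m <- 0
  e$v <- 0
  e
}

.addb <- function(y, b) y + matrix(b, nrow(y), length(b), byrow = TRUE)

layer_dense <- function(n_in, n_out, init_sd = sqrt(2 / n_in), first = FALSE) {
  W <- .pcell(matrix(rnorm(n_in * n_out, sd = init_sd), n_in, n_out))
  b <- .pcell(numeric(n_out))
  list(
    kind = "dense", params = list(W = W, b = b),
    fwd = function(x) list(y = .addb(x %*% W$value, b$value), cache = x),
    bwd = function(cache, dy, accum = TRUE) {
      if (accum) {
        W$grad <- W$grad + crossprod(cache, dy)
        b$grad <- b$grad + colSums(dy)
      }
      if (first) return(NULL)            # input gradient unused upstream
      dy %*% t(W$value)
    }
  )
}

layer_elu <- function() {
  list(
    kind = "elu", params = list(),
    fwd = function(x) {
      y <- x
      neg <- x < 0
      y[neg] <- expm1(x[neg])
      list(y = y, cache = list(neg = neg, yneg = y[neg]))
    },
    bwd = function(cache, dy, accum = TRUE) {
      dx <- dy
      dx[cache$neg] <- dy[cache$neg] * (cache$yneg + 1)
      dx
    }
  )
}

## 1-D convolution over the length axis, stride 1, zero 'same' padding.
## Implemented as k shifted matrix products on a row-blocked padded matrix
## (rows ordered batch-fastest, position-slower), which keeps every gather
## a contiguous row-range extraction.
layer_conv1d <- function(c_in, c_out, k = 5L, first = FALSE) {
  stopifnot(k %% 2L == 1L)
  W <- .pcell(matrix(rnorm(k * c_in * c_out, sd = sqrt(2 / (k * c_in))),
                     k * c_in, c_out))
  b <- .pcell(numeric(c_out))
  pad <- (k - 1L) %/% 2L
  list(
    kind = "conv1d", params = list(W = W, b = b),
    fwd = function(x) {
      d <- dim(x); B <- d[1L]; L <- d[2L]
      x2 <- x; dim(x2) <- c(B * L, c_in)
      xp2 <- matrix(0, B * (L + k - 1L), c_in)
      xp2[(B * pad + 1L):(B * pad + B * L), ] <- x2
      Y2 <- NULL
      for (t in seq_len(k)) {
        Wt <- W$value[((t - 1L) * c_in + 1L):(t * c_in), , drop = FALSE]
        Zt <- xp2[((t - 1L) * B + 1L):((t - 1L) * B + B * L), , drop = FALSE] %*% Wt
        Y2 <- if (is.null(Y2)) Zt else Y2 + Zt
      }
      Y <- .addb(Y2, b$value)
      dim(Y) <- c(B, L, c_out)
      list(y = Y, cache = list(xp2 = xp2, B = B, L = L))
    },
    bwd = function(cache, dy, accum = TRUE) {
      B <- cache$B; L <- cache$L
      dY2 <- dy
      dim(dY2) <- c(B * L, c_out)
      if (accum) {
        dW <- matrix(0, k * c_in, c_out)
        for (t in seq_len(k)) {
          rows <- ((t - 1L) * B + 1L):((t - 1L) * B + B * L)
          dW[((t - 1L) * c_in + 1L):(t * c_in), ] <-
            crossprod(cache$xp2[rows, , drop = FALSE], dY2)
        }
        W$grad <- W$grad + dW
        b$grad <- b$grad + colSums(dY2)
      }
      if (first) return(NULL)            # input gradient unused upstream
      dxp2 <- matrix(0, B * (L + k - 1L), c_in)
      for (t in seq_len(k)) {
        Wt <- W$value[((t - 1L) * c_in + 1L):(t * c_in), , drop = FALSE]
        rows <- ((t - 1L) * B + 1L):((t - 1L) * B + B * L)
        dxp2[rows, ] <- dxp2[rows, , drop = FALSE] + dY2 %*% t(Wt)
      }
      dx <- dxp2[(B * pad + 1L):(B * pad + B * L), , drop = FALSE]
      dim(dx) <- c(B, L, c_in)
      dx
    }
  )
}

## (B, L, C) -> (B, L*C); column-major reshape is its own inverse.
layer_flatten <- function() {
  list(
    kind = "flatten", params = list(),
    fwd = function(x) {
      d <- dim(x)
      y <- x
      dim(y) <- c(d[1L], d[2L] * d[3L])
      list(y = y, cache = d)
    },
    bwd = function(cache, dy, accum = TRUE) {
      if (is.null(dy)) return(NULL)
      dim(dy) <- cache
      dy
    }
  )
}

## (B, F) -> (B, L, C) with F = L*C.
layer_unflatten <- function(L, C) {
  list(
    kind = "unflatten", params = list(),
    fwd = function(x) {
      y <- x
      dim(y) <- c(nrow(x), L, C)
      list(y = y, cache = nrow(x))
    },
    bwd = function(cache, dy, accum = TRUE) {
      dim(dy) <- c(cache, L * C)
      dy
    }
  )
}

## Elman RNN over the length axis; returns per-position hidden states.
layer_rnn <- function(c_in, H, first = FALSE) {
  Wx <- .pcell(matrix(rnorm(c_in * H, sd = sqrt(1 / c_in)), c_in, H))
  Wh <- .pcell(matrix(rnorm(H * H, sd = 1 / sqrt(H)), H, H))
  b <- .pcell(numeric(H))
  list(
    kind = "rnn", params = list(Wx = Wx, Wh = Wh, b = b),
    fwd = function(x) {
      d <- dim(x); B <- d[1L]; L <- d[2L]
      hs <- array(0, c(B, L, H))
      h <- matrix(0, B, H)
      for (t in seq_len(L)) {
        xt <- x[, t, , drop = FALSE]; dim(xt) <- c(B, c_in)
        h <- tanh(.addb(xt %*% Wx$value + h %*% Wh$value, b$value))
        hs[, t, ] <- h
      }
      list(y = hs, cache = list(x = x, hs = hs, B = B, L = L))
    },
    bwd = function(cache, dy, accum = TRUE) {
      B <- cache$B; L <- cache$L
      dx <- if (first) NULL else array(0, c(B, L, c_in))
      dh_next <- matrix(0, B, H)
      for (t in rev(seq_len(L))) {
        ht <- cache$hs[, t, , drop = FALSE]; dim(ht) <- c(B, H)
        dh <- dy[, t, , drop = FALSE]; dim(dh) <- c(B, H)
        dh <- dh + dh_next
        da <- dh * (1 - ht * ht)
        if (accum) {
          xt <- cache$x[, t, , drop = FALSE]; dim(xt) <- c(B, c_in)
          Wx$grad <- Wx$grad + crossprod(xt, da)
          if (t > 1L) {
            hp <- cache$hs[, t - 1L, , drop = FALSE]; dim(hp) <- c(B, H)
            Wh$grad <- Wh$grad + crossprod(hp, da)
          }
          b$grad <- b$grad + colSums(da)
        }
        dh_next <- da %*% t(Wh$value)
        if (!first) dx[, t, ] <- da %*% t(Wx$value)
      }
      dx
    }
  )
}

## Single-head self-attention block with residual connection and a
## position-wise feed-forward sub-block (also residual). No layer norm:
## widths are small and inputs are standardized upstream.
layer_attention <- function(d, f = 2L * d) {
  sc <- sqrt(1 / d)
  Wq <- .pcell(matrix(rnorm(d * d, sd = sc), d, d))
  Wk <- .pcell(matrix(rnorm(d * d, sd = sc), d, d))
  Wv <- .pcell(matrix(rnorm(d * d, sd = sc), d, d))
  Wo <- .pcell(matrix(rnorm(d * d, sd = sc), d, d))
  W1 <- .pcell(matrix(rnorm(d * f, sd = sqrt(2 / d)), d, f))
  b1 <- .pcell(numeric(f))
  W2 <- .pcell(matrix(rnorm(f * d, sd = sqrt(1 / f)), f, d))
  b2 <- .pcell(numeric(d))
  list(
    kind = "attention",
    params = list(Wq = Wq, Wk = Wk, Wv = Wv, Wo = Wo,
                  W1 = W1, b1 = b1, W2 = W2, b2 = b2),
    fwd = function(x) {
      dd <- dim(x); B <- dd[1L]; L <- dd[2L]
      X2 <- x; dim(X2) <- c(B * L, d)
      Q <- X2 %*% Wq$value; K <- X2 %*% Wk$value; V <- X2 %*% Wv$value
      H2 <- matrix(0, B * L, d)
      As <- vector("list", B)
      for (bb in seq_len(B)) {
        ridx <- bb + B * (0:(L - 1L))
        S <- (Q[ridx, , drop = FALSE] %*% t(K[ridx, , drop = FALSE])) / sqrt(d)
        S <- S - apply(S, 1L, max)
        A <- exp(S); A <- A / rowSums(A)
        As[[bb]] <- A
        H2[ridx, ] <- A %*% V[ridx, , drop = FALSE]
      }
      O <- H2 %*% Wo$value
      Z2 <- X2 + O                       # attention residual
      A1 <- .addb(Z2 %*% W1$value, b1$value)
      G <- A1; neg <- A1 < 0; G[neg] <- expm1(A1[neg])
      F2 <- .addb(G %*% W2$value, b2$value)
      Y2 <- Z2 + F2                      # feed-forward residual
      Y <- Y2; dim(Y) <- c(B, L, d)
      list(y = Y, cache = list(X2 = X2, Q = Q, K = K, V = V, H2 = H2,
                               Z2 = Z2, G = G, neg = neg, As = As,
                               B = B, L = L))
    },
    bwd = function(cache, dy, accum = TRUE) {
      B <- cache$B; L <- cache$L
      dY2 <- dy; dim(dY2) <- c(B * L, d)
      ## FFN residual
      dF2 <- dY2
      dG <- dF2 %*% t(W2$value)
      dA1 <- dG
      dA1[cache$neg] <- dG[cache$neg] * (cache$G[cache$neg] + 1)
      dZ2 <- dY2 + dA1 %*% t(W1$value)
      if (accum) {
        W2$grad <- W2$grad + crossprod(cache$G, dF2)
        b2$grad <- b2$grad + colSums(dF2)
        W1$grad <- W1$grad + crossprod(cache$Z2, dA1)
        b1$grad <- b1$grad + colSums(dA1)
      }
      ## attention residual
      dO <- dZ2
      dH2 <- dO %*% t(Wo$value)
      if (accum) Wo$grad <- Wo$grad + crossprod(cache$H2, dO)
      dQ <- matrix(0, B * L, d); dK <- dQ; dV <- dQ
      for (bb in seq_len(B)) {
        ridx <- bb + B * (0:(L - 1L))
        A <- cache$As[[bb]]
        Vb <- cache$V[ridx, , drop = FALSE]
        dHb <- dH2[ridx, , drop = FALSE]
        dA <- dHb %*% t(Vb)
        dV[ridx, ] <- t(A) %*% dHb
        dS <- A * (dA - rowSums(dA * A))
        dS <- dS / sqrt(d)
        Qb <- cache$Q[ridx, , drop = FALSE]
        Kb <- cache$K[ridx, , drop = FALSE]
        dQ[ridx, ] <- dS %*% Kb
        dK[ridx, ] <- t(dS) %*% Qb
      }
      if (accum) {
        Wq$grad <- Wq$grad + crossprod(cache$X2, dQ)
        Wk$grad <- Wk$grad + crossprod(cache$X2, dK)
        Wv$grad <- Wv$grad + crossprod(cache$X2, dV)
      }
      dX2 <- dZ2 + dQ %*% t(Wq$value) + dK %*% t(Wk$value) + dV %*% t(Wv$value)
      dim(dX2) <- c(B, L, d)
      dX2
    }
  )
}

## Residual wrapper: y = x + f(x) for an inner layer stack of matching shape.
layer_residual <- function(inner) {
  list(
    kind = "residual", params = list(), inner = inner,
    fwd = function(x) {
      r <- net_fwd(inner, x)
      list(y = x + r$y, cache = r$tape)
    },
    bwd = function(cache, dy, accum = TRUE) {
      dy + net_bwd(inner, cache, dy, accum)
    }
  )
}

## ---- sequential plumbing --------------------------------------------------

net_fwd <- function(layers, x) {
  tape <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layers[[i]]$fwd(x)
    tape[[i]] <- r$cache
    x <- r$y
  }
  list(y = x, tape = tape)
}

net_bwd <- function(layers, tape, dy, accum = TRUE) {
  for (i in rev(seq_along(layers))) {
    dy <- layers[[i]]$bwd(tape[[i]], dy, accum)
  }
  dy
}

net_cells <- function(layers) {
  out <- list()
  for (l in layers) {
    out <- c(out, unname(l$params))
    if (!is.null(l$inner)) out <- c(out, net_cells(l$inner))
  }
  out
}

n_params <- function(layers) {
  sum(vapply(net_cells(layers), function(p) length(p$value), numeric(1)))
}

## ---- optimizer ------------------------------------------------------------

adam_new <- function(lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps; e$t <- 0L
  e
}

adam_step <- function(opt, cells) {
  opt$t <- opt$t + 1L
  c1 <- 1 - opt$beta1^opt$t
  c2 <- 1 - opt$beta2^opt$t
  for (p in cells) {
    g <- p$grad
    p$m <- opt$beta1 * p$m + (1 - opt$beta1) * g
    p$v <- opt$beta2 * p$v + (1 - opt$beta2) * g * g
    p$value <- p$value - opt$lr * (p$m / c1) / (sqrt(p$v / c2) + opt$eps)
    p$grad <- 0
  }
  invisible(NULL)
}

zero_grads <- function(cells) {
  for (p in cells) p$grad <- 0
  invisible(NULL)
}

## Plain-data snapshots (checkpoints store these, never closures).
cells_state <- function(cells) {
  lapply(cells, function(p) list(value = p$value, m = p$m, v = p$v))
}

cells_restore <- function(cells, state) {
  .assert(length(cells) == length(state), "parameter count mismatch in checkpoint")
  for (i in seq_along(cells)) {
    .assert(length(cells[[i]]$value) == length(state[[i]]$value),
            "parameter shape mismatch in checkpoint")
    cells[[i]]$value <- state[[i]]$value
    cells[[i]]$m <- state[[i]]$m
    cells[[i]]$v <- state[[i]]$v
  }
  invisible(NULL)
}
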