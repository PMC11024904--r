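## Channel simulator: substitution / insertion / deletion noise with
## per-component error profiles and a total-rate amplifier.

.err_types <- c("substitution", "insertion", "deletion")

#' Construct a channel error source
#'
#' An error source models one component of the DNA storage channel (a
#' synthesis method, a sequencing technology, a PCR setup or a storage
#' host). Rates are per-base event probabilities.
#'
#' @param name human-readable component name.
#' @param rates named numeric vector with entries `substitution`,
#'   `insertion`, `deletion`, each in `[0,1]`.
#' @param substitution_bias optional list mapping each base to a named
#'   probability vector over the three alternative bases. `NULL` means
#'   uniform substitution targets.
#' @return a list of class `dt_error_source`.
#' @export
error_source <- function(name, rates, substitution_bias = NULL) {
  .assert(is.character(name) && length(name) == 1L, "name must be a string")
  rates <- unlist(rates)
  missing <- setdiff(.err_types, names(rates))
  .assert(length(missing) == 0L, "source '%s' is missing rates: %s",
          name, paste(missing, collapse = ", "))
  rates <- rates[.err_types]
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1)) {
    .stopf("source '%s': rates must be in [0,1], got [%s]",
           name, paste(signif(rates, 4), collapse = ", "))
  }
  if (!is.null(substitution_bias)) {
    for (b in names(substitution_bias)) {
      p <- unlist(substitution_bias[[b]])
      .assert(all(p >= 0) && abs(sum(p) - 1) < 1e-6,
              "source '%s': substitution bias for %s must be a probability vector",
              name, b)
    }
  }
  structure(list(name = name, rates = rates,
                 substitution_bias = substitution_bias),
            class = "dt_error_source")
}

#' Construct a channel configuration
#'
#' @param sources list of [error_source()] objects.
#' @param amplifier_total optional target total per-base error rate; when
#'   set, the configuration is amplified on construction (see [amplify()]).
#' @return object of class `dt_channel_config`.
#' @export
channel_config <- function(sources, amplifier_total = NULL) {
  .assert(is.list(sources), "sources must be a list")
  sources <- lapply(sources, function(s) {
    if (inherits(s, "dt_error_source")) s
    else error_source(s$name, s$rates, s$substitution_bias)
  })
  cfg <- structure(list(sources = sources, amplifier_total = NULL),
                   class = "dt_channel_config")
  if (!is.null(amplifier_total)) cfg <- amplify(cfg, amplifier_total)
  cfg
}

#' Total per-base error rate of a channel configuration
#'
#' Sum of the substitution, insertion and deletion rates over all sources.
#'
#' @param config a `dt_channel_config`.
#' @return numeric scalar.
#' @export
total_error_rate <- function(config) {
  .assert(inherits(config, "dt_channel_config"), "not a channel config")
  sum(vapply(config$sources, function(s) sum(s$rates), numeric(1)))
}

## Collapse all sources into one named rate triple.
.combined_rates <- function(config) {
  r <- c(substitution = 0, insertion = 0, deletion = 0)
  for (s in config$sources) r <- r + s$rates
  total <- sum(r)
  .assert(total <= 1 + 1e-12,
          "combined per-base event rate %.4f exceeds 1; reduce rates", total)
  r
}

## Combined substitution bias: rate-weighted mean of per-source biases;
## sources without a bias contribute uniform targets. Returns a 4x4 matrix
## (row = original base index, col = replacement index, diagonal 0).
.combined_bias <- function(config) {
  M <- matrix(0, 4, 4, dimnames = list(.dna_alphabet, .dna_alphabet))
  wsum <- 0
  for (s in config$sources) {
    w <- s$rates[["substitution"]]
    if (w <= 0) next
    Ms <- matrix(0, 4, 4, dimnames = dimnames(M))
    for (b in .dna_alphabet) {
      others <- setdiff(.dna_alphabet, b)
      if (!is.null(s$substitution_bias) && !is.null(s$substitution_bias[[b]])) {
        p <- unlist(s$substitution_bias[[b]])[others]
        p[is.na(p)] <- 0
        if (sum(p) > 0) p <- p / sum(p) else p <- rep(1 / 3, 3)
      } else p <- setNames(rep(1 / 3, 3), others)
      Ms[b, others] <- p
    }
    M <- M + w * Ms
    wsum <- wsum + w
  }
  if (wsum == 0) {
    for (b in .dna_alphabet) M[b, setdiff(.dna_alphabet, b)] <- 1 / 3
    return(M)
  }
  M / wsum
}

#' Amplify a channel configuration to a target total error rate
#'
#' Every per-type, per-source rate is scaled by
#' `target_total / total_error_rate(config)`, so relative proportions of
#' error types and per-source contributions are preserved exactly (one
#' multiplication per rate).
#'
#' @param config a `dt_channel_config`.
#' @param target_total target total per-base error rate in `(0, 1]`.
#' @return a new `dt_channel_config`.
#' @export
amplify <- function(config, target_total) {
  .assert(inherits(config, "dt_channel_config"), "not a channel config")
  .assert(is.numeric(target_total) && length(target_total) == 1L &&
            target_total > 0 && target_total <= 1,
          "target_total must be in (0, 1]")
  cur <- total_error_rate(config)
  if (cur == 0) .stopf("cannot amplify a zero-rate channel configuration")
  f <- target_total / cur
  sources <- lapply(config$sources, function(s) {
    s$rates <- s$rates * f
    if (any(s$rates > 1)) .stopf("amplification drives a rate above 1")
    s
  })
  structure(list(sources = sources, amplifier_total = target_total),
            class = "dt_channel_config")
}

## ---- JSON loading (native dialect + MESA-style export layout) -------------

.parse_pattern_source <- function(name, x) {
  ## native: either explicit per-type rates, or rate + pattern proportions
  bias <- x$substitution_bias
  if (!is.null(x$rates)) {
    return(error_source(name, x$rates, bias))
  }
  if (!is.null(x$rate)) {
    .assert(!is.null(x$pattern), "source '%s': 'rate' requires 'pattern'", name)
    p <- unlist(x$pattern)[.err_types]
    p[is.na(p)] <- 0
    .assert(all(p >= 0), "source '%s': pattern proportions must be >= 0", name)
    s <- sum(p)
    .assert(s > 0, "source '%s': pattern proportions sum to 0", name)
    if (abs(s - 1) > 1e-6) {
      .dt_log("warn", sprintf("source '%s': pattern proportions sum to %.4f; renormalizing", name, s))
    }
    p <- p / s
    rate <- as.numeric(x$rate)
    if (!is.finite(rate) || rate < 0 || rate > 1) {
      .stopf("source '%s': rate %.4g outside [0,1]", name, rate)
    }
    return(error_source(name, setNames(rate * p, .err_types), bias))
  }
  ## MESA-style: err_data with raw_rate and mutation proportions
  if (!is.null(x$err_data)) {
    ed <- x$err_data
    rate <- as.numeric(ed$raw_rate %||% ed$rate)
    mut <- unlist(ed$mutations %||% ed$pattern)
    if (!is.null(x$err_attributes)) {
      .dt_log("info", sprintf(
        "source '%s': positional/pattern error attributes collapsed to flat per-base rates", name))
    }
    p <- mut[.err_types]; p[is.na(p)] <- 0
    s <- sum(p); .assert(s > 0, "source '%s': no mutation proportions", name)
    p <- p / s
    if (!is.finite(rate) || rate < 0 || rate > 1) {
      .stopf("source '%s': rate %.4g outside [0,1]", name, rate)
    }
    return(error_source(name, setNames(rate * p, .err_types), bias))
  }
  .stopf("source '%s': unrecognized layout (need 'rates', 'rate'+'pattern' or 'err_data')", name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a channel configuration from JSON
#'
#' Two layouts are accepted and normalized on load: the native schema
#' (`error_sources` as a list of `{name, rate, pattern}` or
#' `{name, rates}` objects) and a MESA-style export layout where each
#' source carries an `err_data` object with `raw_rate` and `mutations`
#' proportions. Unknown top-level keys are ignored with a logged warning.
#'
#' @param path path to a JSON file.
#' @return a `dt_channel_config`.
#' @export
load_channel_config <- function(path) {
  .assert(file.exists(path), "channel config file not found: %s", path)
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                error = function(e) .stopf("malformed channel JSON in '%s': %s",
                                           path, conditionMessage(e)))
  known <- c("error_sources", "amplifier_total", "name", "description")
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    .dt_log("warn", "ignoring unknown channel config keys: ",
            paste(unknown, collapse = ", "))
  }
  .assert(!is.null(x$error_sources), "channel JSON lacks 'error_sources'")
  srcs <- x$error_sources
  nms <- names(srcs)
  sources <- lapply(seq_along(srcs), function(i) {
    s <- srcs[[i]]
    nm <- s$name %||% s$id %||% nms[i] %||% sprintf("source_%d", i)
    .parse_pattern_source(nm, s)
  })
  channel_config(sources, amplifier_total = x$amplifier_total)
}

#' Path of the bundled default channel profile
#'
#' A constructed stand-in profile for column synthesis with ErrASE error
#' correction, Illumina single-end sequencing, 30 PCR cycles with Taq, and
#' 24 months of storage in E. coli. Only its total per-base error rate of
#' 0.33% is a published quantity; the per-component split is synthetic and
#' documented in the file itself.
#'
#' @return file path of the packaged JSON profile.
#' @export
default_channel_path <- function() {
  system.file("extdata", "default_channel_synthetic.json",
              package = "dnaturbo", mustWork = TRUE)
}

## ---- transmission ---------------------------------------------------------

## Fast integer-path corruption used by training. `x` is an integer vector
## (codes 1..4); returns list(seq = integer vector, n_events).
.corrupt_int <- function(x, rates, bias = NULL) {
  L <- length(x)
  ps <- rates[["substitution"]]; pi_ <- rates[["insertion"]]; pd <- rates[["deletion"]]
  u <- runif(L)
  ev <- integer(L)                       # 0 none, 1 sub, 2 ins, 3 del
  ev[u < ps] <- 1L
  ev[u >= ps & u < ps + pi_] <- 2L
  ev[u >= ps + pi_ & u < ps + pi_ + pd] <- 3L
  if (all(ev == 0L)) return(list(seq = x, events = ev, subs = integer(0), ins = integer(0)))
  subs_at <- which(ev == 1L)
  new_base <- integer(length(subs_at))
  if (length(subs_at)) {
    if (is.null(bias)) {
      ## uniform over the three alternatives
      off <- sample.int(3L, length(subs_at), replace = TRUE)
      new_base <- ((x[subs_at] - 1L + off) %% 4L) + 1L
    } else {
      for (j in seq_along(subs_at)) {
        p <- bias[x[subs_at[j]], ]
        new_base[j] <- sample.int(4L, 1L, prob = p)
      }
    }
  }
  ins_at <- which(ev == 2L)
  ins_base <- if (length(ins_at)) sample.int(4L, length(ins_at), replace = TRUE) else integer(0)
  y <- x
  if (length(subs_at)) y[subs_at] <- new_base
  keep <- ev != 3L
  ## assemble output with insertions placed after their position
  if (length(ins_at)) {
    pieces <- vector("list", L)
    for (i in seq_len(L)) {
      pieces[[i]] <- if (keep[i]) y[i] else integer(0)
    }
    for (j in seq_along(ins_at)) {
      i <- ins_at[j]
      pieces[[i]] <- c(pieces[[i]], ins_base[j])
    }
    out <- unlist(pieces, use.names = FALSE)
  } else {
    out <- y[keep]
  }
  list(seq = out, events = ev, subs = new_base, ins = ins_base)
}

#' Transmit a DNA sequence through the simulated channel
#'
#' Each base independently suffers at most one event, drawn from a
#' categorical distribution over {none, substitution, insertion, deletion}
#' with probabilities given by the combined per-type rates of `config`.
#' A substitution replaces the base by a different base (uniform over the
#' three alternatives unless the configuration supplies a substitution
#' bias); an insertion places one uniform-random base after the position;
#' a deletion removes the base.
#'
#' @param seq DNA string over `{A,C,G,T}`, nonempty.
#' @param config a `dt_channel_config`.
#' @param seed optional integer seed for a reproducible, isolated random
#'   stream; `NULL` draws from the current RNG.
#' @return object of class `dt_noisy_read` with fields `sequence`,
#'   `length`, and `event_log` (data frame with columns `position`,
#'   `type`, `original`, `replacement`; positions refer to the clean
#'   input).
#' @export
transmit <- function(seq, config, seed = NULL) {
  .check_dna(seq, "input sequence")
  .assert(nchar(seq) > 0L, "input sequence must be nonempty")
  .assert(inherits(config, "dt_channel_config"), "not a channel config")
  rates <- .combined_rates(config)
  bias <- NULL
  if (any(vapply(config$sources, function(s) !is.null(s$substitution_bias), logical(1)))) {
    bias <- .combined_bias(config)
  }
  x <- .dna_to_int(seq)
  res <- .with_seed(seed, .corrupt_int(x, rates, bias))
  ev <- res$events
  idx <- which(ev != 0L)
  if (length(idx)) {
    typ <- c("substitution", "insertion", "deletion")[ev[idx]]
    orig <- .dna_alphabet[x[idx]]
    repl <- character(length(idx))
    repl[typ == "substitution"] <- .dna_alphabet[res$subs]
    repl[typ == "insertion"] <- .dna_alphabet[res$ins]
    repl[typ == "deletion"] <- ""
    orig[typ == "insertion"] <- ""
    log <- data.frame(position = idx, type = typ, original = orig,
                      replacement = repl, stringsAsFactors = FALSE)
  } else {
    log <- data.frame(position = integer(0), type = character(0),
                      original = character(0), replacement = character(0),
                      stringsAsFactors = FALSE)
  }
  out <- .int_to_dna(res$seq)
  structure(list(sequence = out, length = nchar(out), event_log = log),
            class = "dt_noisy_read")
}

#' Replay an event log on a clean sequence
#'
#' Applies the ordered events of a [transmit()] event log to the clean
#' input, reproducing the noisy output deterministically.
#'
#' @param seq the clean DNA string that was transmitted.
#' @param event_log the `event_log` data frame of a `dt_noisy_read`.
#' @return the reconstructed noisy DNA string.
#' @export
replay_events <- function(seq, event_log) {
  .check_dna(seq)
  x <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pieces <- as.list(x)
  if (nrow(event_log)) {
    for (i in seq_len(nrow(event_log))) {
      pos <- event_log$position[i]
      switch(event_log$type[i],
        substitution = { pieces[[pos]] <- event_log$replacement[i] },
        deletion = { pieces[[pos]] <- character(0) },
        insertion = { pieces[[pos]] <- c(pieces[[pos]], event_log$replacement[i]) },
        .stopf("unknown event type '%s'", event_log$type[i]))
    }
  }
  paste0(unlist(pieces), collapse = "")
}

#' Empirical per-base event rate of a channel configuration
#'
#' Transmits `n_seqs` uniform-random sequences of length `seq_len` and
#' returns the total event count divided by the number of transmitted
#' bases. A calibration utility: for a well-formed configuration the
#' result converges on [total_error_rate()].
#'
#' @param config a `dt_channel_config`.
#' @param n_seqs number of sequences to transmit.
#' @param seq_len length of each sequence in bases.
#' @param seed integer seed.
#' @return empirical event probability per base.
#' @export
empirical_error_rate <- function(config, n_seqs, seq_len, seed = 1L) {
  .assert(n_seqs > 0 && seq_len > 0, "n_seqs and seq_len must be positive")
  rates <- .combined_rates(config)
  .with_seed(seed, {
    n_events <- 0L
    for (i in seq_len(n_seqs)) {
      x <- sample.int(4L, seq_len, replace = TRUE)
      res <- .corrupt_int(x, rates)
      n_events <- n_events + sum(res$events != 0L)
    }
    n_events / (n_seqs * seq_len)
  })
}

#' @export
print.dt_channel_config <- function(x, ...) {
  cat(sprintf("<dnaturbo channel config: %d source(s), total rate %.5f>\n",
              length(x$sources), total_error_rate(x)))
  for (s in x$sources) {
    cat(sprintf("  %-38s sub %.5f  ins %.5f  del %.5f\n", s$name,
                s$rates[["substitution"]], s$rates[["insertion"]],
                s$rates[["deletion"]]))
  }
  invisible(x)
}
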