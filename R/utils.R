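#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif setNames approx
#' @importFrom utils modifyList head tail
NULL

.dna_alphabet <- c("A", "C", "G", "T")

.log_level <- new.env(parent = emptyenv())
.log_level$threshold <- "info"

.level_rank <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Set the package log level
#'
#' Messages below the threshold are suppressed. Levels, in increasing
#' severity: `"debug"`, `"info"`, `"warn"`, `"error"`.
#'
#' @param level character scalar, one of the levels above.
#' @return the previous level, invisibly.
#' @export
dt_log_level <- function(level = c("info", "debug", "warn", "error")) {
  level <- match.arg(level)
  old <- .log_level$threshold
  .log_level$threshold <- level
  invisible(old)
}

.dt_log <- function(level, ...) {
  if (.level_rank[[level]] >= .level_rank[[.log_level$threshold]]) {
    message(sprintf("[dnaturbo %s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assert <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) .stopf(fmt, ...)
  invisible(TRUE)
}

.check_dna <- function(seq, what = "sequence") {
  .assert(is.character(seq) && length(seq) == 1L, "%s must be a single string", what)
  if (nchar(seq) == 0L) return(invisible(TRUE))
  bad <- gsub("[ACGT]", "", seq)
  if (nchar(bad) > 0L) {
    .stopf("%s contains characters outside {A,C,G,T}: '%s'", what,
           substr(bad, 1L, 10L))
  }
  invisible(TRUE)
}

## DNA string <-> integer codes 1..4 (A,C,G,T)
.dna_to_int <- function(seq) {
  if (nchar(seq) == 0L) return(integer(0))
  m <- match(strsplit(seq, "", fixed = TRUE)[[1L]], .dna_alphabet)
  if (anyNA(m)) .stopf("invalid DNA character in '%s'", substr(seq, 1L, 20L))
  m
}

.int_to_dna <- function(x) {
  if (length(x) == 0L) return("")
  paste0(.dna_alphabet[x], collapse = "")
}

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's RNG stream afterwards. Used wherever a seed argument is optional.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

## Derive a bounded child seed from a base seed and a stream label.
.child_seed <- function(seed, offset) {
  (as.integer(seed) * 1103L + as.integer(offset) * 7919L) %% 2147483629L
}

.random_dna <- function(len) .int_to_dna(sample.int(4L, len, replace = TRUE))

.gcd <- function(a, b) {
  a <- abs(as.integer(a)); b <- abs(as.integer(b))
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}
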