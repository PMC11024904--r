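## Constraint evaluator f(.): GC content, homopolymer runs, k-mer repeats
## and undesired motifs, each mapped to an error probability (percent)
## through user-defined probability graphs; combined per sequence and
## aggregated into a batch stability score.

#' Construct a probability graph
#'
#' A probability graph maps a constraint value (GC percent, homopolymer
#' run length, k-mer repeat count) to an error probability in percent via
#' a list of (x, y) points, evaluated by step lookup or linear
#' interpolation.
#'
#' @param points two-column structure of points: a data frame or matrix
#'   with columns `x` and `y`, or a list of `{x, y}` pairs. `x` must be
#'   strictly increasing, `y` in `[0, 100]`.
#' @param interpolation `"linear"` (default; smooths curves between
#'   points) or `"step"` (y of the greatest point with `x_p <= x`).
#' @return object of class `dt_prob_graph`.
#' @export
probability_graph <- function(points, interpolation = c("linear", "step")) {
  interpolation <- match.arg(interpolation)
  if (is.list(points) && !is.data.frame(points) && !is.null(points[[1L]]$x)) {
    points <- data.frame(x = vapply(points, function(p) as.numeric(p$x), numeric(1)),
                         y = vapply(points, function(p) as.numeric(p$y), numeric(1)))
  }
  points <- as.data.frame(points)
  .assert(all(c("x", "y") %in% names(points)), "points need x and y columns")
  .assert(nrow(points) >= 1L, "a probability graph needs at least one point")
  .assert(!is.unsorted(points$x, strictly = TRUE), "graph x values must be strictly increasing")
  .assert(all(points$y >= 0 & points$y <= 100), "graph y values must be in [0, 100]")
  structure(list(x = as.numeric(points$x), y = as.numeric(points$y),
                 interpolation = interpolation),
            class = "dt_prob_graph")
}

#' Evaluate a probability graph at a constraint value
#'
#' Values outside the graph's x-range are clamped to the boundary.
#'
#' @param graph a [probability_graph()].
#' @param x numeric constraint value(s).
#' @return error probability in percent (vectorized over `x`).
#' @export
evaluate_graph <- function(graph, x) {
  .assert(inherits(graph, "dt_prob_graph"), "not a probability graph")
  .assert(length(graph$x) >= 1L, "empty probability graph")
  x <- pmin(pmax(x, graph$x[1L]), graph$x[length(graph$x)])
  if (length(graph$x) == 1L) return(rep(graph$y, length(x)))
  if (graph$interpolation == "linear") {
    approx(graph$x, graph$y, xout = x, rule = 2)$y
  } else {
    graph$y[findInterval(x, graph$x)]
  }
}

## Derivative of a linear graph at x (0 outside range / step mode); used by
## the straight-through constraint surrogate during fine-tuning.
.graph_slope <- function(graph, x) {
  if (graph$interpolation != "linear" || length(graph$x) < 2L) return(rep(0, length(x)))
  i <- findInterval(x, graph$x, all.inside = TRUE)
  s <- (graph$y[i + 1L] - graph$y[i]) / (graph$x[i + 1L] - graph$x[i])
  s[x < graph$x[1L] | x > graph$x[length(graph$x)]] <- 0
  s
}

#' GC content of a sequence in percent
#'
#' @param seq nonempty DNA string.
#' @return `100 * (#G + #C) / length`.
#' @export
gc_percent <- function(seq) {
  .check_dna(seq)
  .assert(nchar(seq) > 0L, "sequence must be nonempty")
  x <- .dna_to_int(seq)
  100 * sum(x == 2L | x == 3L) / length(x)
}

#' Longest homopolymer run of a sequence
#'
#' @param seq nonempty DNA string.
#' @return length of the longest run of an identical base.
#' @export
max_homopolymer <- function(seq) {
  .check_dna(seq)
  .assert(nchar(seq) > 0L, "sequence must be nonempty")
  max(rle(.dna_to_int(seq))$lengths)
}

#' Maximum overlapping repeat count over all k-mers of a sequence
#'
#' Counts overlapping occurrences of every k-mer present in the sequence
#' and returns the maximum count (the most conservative per-sequence
#' reading of k-mer repetitiveness).
#'
#' @param seq DNA string.
#' @param k k-mer length.
#' @return maximum occurrence count (0 when the sequence is shorter than
#'   `k`).
#' @export
max_kmer_repeat <- function(seq, k) {
  .check_dna(seq)
  L <- nchar(seq)
  if (L < k) return(0L)
  kmers <- substring(seq, seq_len(L - k + 1L), k:L)
  max(table(kmers))
}

#' Construct a motif entry
#'
#' @param motif nonempty DNA string.
#' @param error_probability percent in `[0, 100]` associated with an
#'   occurrence of the motif.
#' @param description optional free text.
#' @return object of class `dt_motif`.
#' @export
motif_entry <- function(motif, error_probability, description = "") {
  .check_dna(motif, "motif")
  .assert(nchar(motif) > 0L, "motif must be nonempty")
  .assert(error_probability >= 0 && error_probability <= 100,
          "motif error probability must be in [0, 100]")
  structure(list(motif = motif, error_probability = error_probability,
                 description = description), class = "dt_motif")
}

#' Construct a constraint configuration
#'
#' Any component may be `NULL`, in which case it contributes zero error
#' probability.
#'
#' @param gc_graph probability graph over GC percent.
#' @param homopolymer_graph probability graph over run length.
#' @param kmer_graph probability graph over repeat count.
#' @param kmer_k k-mer length for `kmer_graph` (default 10).
#' @param motifs list of [motif_entry()] objects.
#' @param match_reverse_complement also match motifs on the reverse
#'   complement strand (off by default).
#' @return object of class `dt_constraint_config`.
#' @export
constraint_config <- function(gc_graph = NULL, homopolymer_graph = NULL,
                              kmer_graph = NULL, kmer_k = 10L,
                              motifs = list(),
                              match_reverse_complement = FALSE) {
  for (g in list(gc_graph, homopolymer_graph, kmer_graph)) {
    .assert(is.null(g) || inherits(g, "dt_prob_graph"), "graphs must be probability graphs")
  }
  motifs <- lapply(motifs, function(m) {
    if (inherits(m, "dt_motif")) m
    else motif_entry(m$motif, m$error_probability, m$description %||% "")
  })
  structure(list(gc_graph = gc_graph, homopolymer_graph = homopolymer_graph,
                 kmer_graph = kmer_graph, kmer_k = as.integer(kmer_k),
                 motifs = motifs,
                 match_reverse_complement = isTRUE(match_reverse_complement)),
            class = "dt_constraint_config")
}

.revcomp <- function(seq) {
  x <- rev(.dna_to_int(seq))
  .int_to_dna(c(4L, 3L, 2L, 1L)[x])
}

#' Error probability of a sequence under a constraint configuration
#'
#' Each configured constraint yields a probability `p_c` (percent): the GC
#' graph evaluated at the sequence's GC percent, the homopolymer graph at
#' its longest run, the k-mer graph at its maximum repeat count, and each
#' occurring motif's probability. Constraints are combined as independent
#' failure modes: `p = 100 * (1 - prod(1 - p_c/100))`.
#'
#' @param seq nonempty DNA string.
#' @param cfg a [constraint_config()].
#' @return combined error probability in percent.
#' @export
sequence_error_probability <- function(seq, cfg) {
  .assert(inherits(cfg, "dt_constraint_config"), "not a constraint config")
  .check_dna(seq)
  .assert(nchar(seq) > 0L, "sequence must be nonempty")
  p <- numeric(0)
  if (!is.null(cfg$gc_graph)) p <- c(p, evaluate_graph(cfg$gc_graph, gc_percent(seq)))
  if (!is.null(cfg$homopolymer_graph)) {
    p <- c(p, evaluate_graph(cfg$homopolymer_graph, max_homopolymer(seq)))
  }
  if (!is.null(cfg$kmer_graph)) {
    p <- c(p, evaluate_graph(cfg$kmer_graph, max_kmer_repeat(seq, cfg$kmer_k)))
  }
  for (m in cfg$motifs) {
    hit <- grepl(m$motif, seq, fixed = TRUE) ||
      (cfg$match_reverse_complement && grepl(m$motif, .revcomp(seq), fixed = TRUE))
    if (hit) p <- c(p, m$error_probability)
  }
  if (!length(p)) return(0)
  100 * (1 - prod(1 - p / 100))
}

#' Batch stability score
#'
#' `w_DNA = 1 - mean(x_i)` for per-block error probabilities `x_i` on the
#' `[0, 1]` scale. Used as an auxiliary encoder training metric.
#'
#' @param probabilities numeric vector of per-block error probabilities in
#'   `[0, 1]` (already normalized from percent).
#' @return stability score in `[0, 1]`.
#' @export
stability_score <- function(probabilities) {
  .assert(length(probabilities) > 0L, "stability score of an empty batch is undefined")
  .assert(all(probabilities >= 0 & probabilities <= 1),
          "probabilities must be in [0, 1]; normalize percent values first")
  1 - mean(probabilities)
}

#' Stability batch of a set of sequences
#'
#' Evaluates [sequence_error_probability()] on every sequence, normalizes
#' percent to `[0, 1]` (exactly once, here), and computes the stability
#' score.
#'
#' @param seqs character vector of DNA strings.
#' @param cfg a [constraint_config()].
#' @return list with `probabilities` (on `[0,1]`), `n` and `w_DNA`.
#' @export
stability_batch <- function(seqs, cfg) {
  .assert(length(seqs) > 0L, "empty batch")
  p <- vapply(seqs, function(s) sequence_error_probability(s, cfg) / 100,
              numeric(1), USE.NAMES = FALSE)
  list(probabilities = p, n = length(seqs), w_DNA = stability_score(p))
}

## ---- JSON loading ---------------------------------------------------------

.parse_graph_json <- function(g, what) {
  if (is.null(g)) return(NULL)
  pts <- g$points %||% g$data %||% g
  interp <- g$interpolation %||% "linear"
  tryCatch(probability_graph(pts, interp),
           error = function(e) .stopf("invalid %s graph: %s", what, conditionMessage(e)))
}

#' Load a constraint configuration from JSON
#'
#' Recognized keys: `gc` (or `gc_content`), `homopolymer`, `kmer` (with
#' optional `k`), `motifs`, `match_reverse_complement`. Graphs are given
#' as `points` lists of `{x, y}` pairs with an optional `interpolation`
#' mode; motifs as `{motif, error_probability, description}`. Unknown keys
#' are ignored with a logged warning.
#'
#' @param path path to a JSON file.
#' @return a `dt_constraint_config`.
#' @export
load_constraint_config <- function(path) {
  .assert(file.exists(path), "constraint config file not found: %s", path)
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                error = function(e) .stopf("malformed constraint JSON in '%s': %s",
                                           path, conditionMessage(e)))
  known <- c("gc", "gc_content", "homopolymer", "kmer", "motifs",
             "match_reverse_complement", "name", "description")
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    .dt_log("warn", "ignoring unknown constraint config keys: ",
            paste(unknown, collapse = ", "))
  }
  kmer <- x$kmer
  constraint_config(
    gc_graph = .parse_graph_json(x$gc %||% x$gc_content, "GC"),
    homopolymer_graph = .parse_graph_json(x$homopolymer, "homopolymer"),
    kmer_graph = .parse_graph_json(kmer, "k-mer"),
    kmer_k = kmer$k %||% 10L,
    motifs = lapply(x$motifs %||% list(), function(m) {
      motif_entry(m$motif, m$error_probability, m$description %||% "")
    }),
    match_reverse_complement = x$match_reverse_complement %||% FALSE
  )
}

#' The bundled fine-tuning constraint configuration
#'
#' Fully penalizes (100% error probability) sequences whose GC content is
#' outside 40--60% or that contain a homopolymer longer than three bases.
#' The GC graph uses the points (0,100), (40,100), (41,0), (59,0),
#' (60,100), (100,100); the homopolymer graph uses (1,0), (3,0), (4,100).
#'
#' @return a `dt_constraint_config`.
#' @export
finetune_constraint_config <- function() {
  constraint_config(
    gc_graph = probability_graph(data.frame(
      x = c(0, 40, 41, 59, 60, 100),
      y = c(100, 100, 0, 0, 100, 100))),
    homopolymer_graph = probability_graph(data.frame(
      x = c(1, 3, 4), y = c(0, 0, 100)))
  )
}

#' @export
print.dt_constraint_config <- function(x, ...) {
  on <- c(gc = !is.null(x$gc_graph), homopolymer = !is.null(x$homopolymer_graph),
          kmer = !is.null(x$kmer_graph))
  cat(sprintf("<dnaturbo constraint config: graphs [%s], %d motif(s)>\n",
              paste(names(on)[on], collapse = ", "), length(x$motifs)))
  invisible(x)
}
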