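test_that("probability graphs validate their points", {
  expect_error(probability_graph(data.frame(x = c(1, 1), y = c(0, 1))),
               "strictly increasing")
  expect_error(probability_graph(data.frame(x = c(0, 1), y = c(0, 101))),
               "\\[0, 100\\]")
  g <- probability_graph(list(list(x = 0, y = 37)))
  expect_equal(evaluate_graph(g, -5), 37)
  expect_equal(evaluate_graph(g, 123), 37)
})

test_that("graph evaluation: printed GC example, interpolation and clamping", {
  g <- gc_graph_printed()
  expect_equal(evaluate_graph(g, 30), 100)
  expect_equal(evaluate_graph(g, 50), 0)
  expect_equal(evaluate_graph(g, 40), 100)
  expect_equal(evaluate_graph(g, 41), 0)
  expect_equal(evaluate_graph(g, 40.5), 50)        # linear between the cliff
  # clamping equals boundary values
  expect_equal(evaluate_graph(g, -10), 100)
  expect_equal(evaluate_graph(g, 200), 100)
  # step mode takes the greatest point with x_p <= x
  gs <- probability_graph(data.frame(x = c(0, 40, 41), y = c(100, 100, 0)),
                          interpolation = "step")
  expect_equal(evaluate_graph(gs, 40.9), 100)
  expect_equal(evaluate_graph(gs, 41), 0)
})

test_that("sequence statistics are exact", {
  expect_equal(gc_percent("GGCC"), 100)
  expect_equal(gc_percent("ATAT"), 0)
  expect_equal(gc_percent("ACGT"), 50)
  expect_equal(max_homopolymer("ACGT"), 1)
  expect_equal(max_homopolymer("AAAAC"), 4)
  # scan oracle on random sequences
  set.seed(8)
  for (i in 1:25) {
    s <- random_dna_string(1000)
    ch <- strsplit(s, "")[[1L]]
    runs <- rle(ch)$lengths
    expect_equal(max_homopolymer(s), max(runs))
  }
  expect_equal(max_kmer_repeat("ACGACGACG", 3), 3)   # overlapping counting
  expect_equal(max_kmer_repeat("AAAA", 2), 3)
  expect_equal(max_kmer_repeat("ACG", 5), 0)
})

test_that("sequence error probability combines constraints independently", {
  cfg <- finetune_constraint_config()
  expect_equal(sequence_error_probability("ACGTAAAAGT", cfg), 100)
  expect_equal(sequence_error_probability("ACGTACGTAC", cfg), 0)
  # two independent 50% constraints -> 75
  half <- constraint_config(
    gc_graph = probability_graph(data.frame(x = 0, y = 50)),
    homopolymer_graph = probability_graph(data.frame(x = 1, y = 50)))
  expect_equal(sequence_error_probability("ACGT", half), 75)
  # motifs: forward-only by default, reverse complement when enabled
  mot <- constraint_config(motifs = list(motif_entry("GAATTC", 80, "EcoRI")))
  expect_equal(sequence_error_probability("TTGAATTCTT", mot), 80)
  expect_equal(sequence_error_probability("TTTTTTTT", mot), 0)
  rc <- constraint_config(motifs = list(motif_entry("AAGGG", 60)),
                          match_reverse_complement = TRUE)
  expect_equal(sequence_error_probability("ACCCTT", rc), 60)
})

test_that("monotone violation response under a nondecreasing homopolymer graph", {
  # homopolymer graph alone, so growing the longest run is the only change
  cfg <- constraint_config(homopolymer_graph = probability_graph(
    data.frame(x = c(1, 3, 4, 8), y = c(0, 10, 60, 100))))
  runs <- vapply(1:10, function(k) {
    s <- paste0(strrep("A", k), "CGTCGTCG")
    sequence_error_probability(s, cfg)
  }, numeric(1))
  expect_true(all(diff(runs) >= 0))
})

test_that("stability score is affine in the mean probability", {
  expect_equal(stability_score(rep(0, 5)), 1)
  expect_equal(stability_score(rep(1, 3)), 0)
  expect_equal(stability_score(c(0.25, 0.75)), 0.5)
  expect_error(stability_score(numeric(0)), "empty")
  expect_error(stability_score(c(0.5, 50)), "\\[0, 1\\]")
  # adding a zero-probability block moves the score predictably
  p <- c(0.2, 0.4, 0.9)
  w1 <- stability_score(p)
  w2 <- stability_score(c(p, 0))
  expect_equal(w2, 1 - sum(p) / 4)
  expect_gt(w2, w1)
})

test_that("stability_batch normalizes percent exactly once", {
  cfg <- finetune_constraint_config()
  sb <- stability_batch(c("ACGTAAAAGT", "ACGTACGTAC"), cfg)
  expect_equal(sb$probabilities, c(1, 0))
  expect_equal(sb$n, 2L)
  expect_equal(sb$w_DNA, 0.5)
})

test_that("constraint JSON round-trips through the loader", {
  path <- tempfile(fileext = ".json")
  writeLines('{
    "gc": {"points": [{"x": 0, "y": 100}, {"x": 40, "y": 100},
                      {"x": 41, "y": 0}, {"x": 59, "y": 0},
                      {"x": 60, "y": 100}, {"x": 100, "y": 100}]},
    "homopolymer": {"points": [{"x": 1, "y": 0}, {"x": 3, "y": 0},
                               {"x": 4, "y": 100}]},
    "kmer": {"k": 4, "points": [{"x": 0, "y": 0}, {"x": 5, "y": 100}]},
    "motifs": [{"motif": "GGATCC", "error_probability": 90,
                "description": "BamHI"}]
  }', path)
  cfg <- load_constraint_config(path)
  expect_equal(sequence_error_probability("ACGTAAAAGT", cfg), 100)
  expect_equal(evaluate_graph(cfg$kmer_graph, 2.5), 50)
  expect_equal(cfg$kmer_k, 4L)
  expect_equal(cfg$motifs[[1L]]$motif, "GGATCC")
})
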