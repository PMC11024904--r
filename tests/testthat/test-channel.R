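test_that("channel config loading validates and normalizes both dialects", {
  native <- tempfile(fileext = ".json")
  writeLines('{
    "error_sources": [
      {"name": "a", "rate": 0.01,
       "pattern": {"substitution": 0.6, "insertion": 0.2, "deletion": 0.2}},
      {"name": "b", "rates": {"substitution": 0.002, "insertion": 0.001,
                              "deletion": 0.001}}
    ]
  }', native)
  cfg <- load_channel_config(native)
  expect_s3_class(cfg, "dt_channel_config")
  expect_equal(total_error_rate(cfg), 0.014)
  expect_equal(unname(cfg$sources[[1L]]$rates),
               c(0.006, 0.002, 0.002))

  mesa <- tempfile(fileext = ".json")
  writeLines('{
    "error_sources": {
      "sequencing": {"err_data": {"raw_rate": 0.004,
        "mutations": {"substitution": 0.5, "insertion": 0.25, "deletion": 0.25}}}
    },
    "mystery_key": 1
  }', mesa)
  expect_message(cfg2 <- load_channel_config(mesa), "mystery_key")
  expect_equal(total_error_rate(cfg2), 0.004)
  expect_equal(cfg2$sources[[1L]]$name, "sequencing")

  bad <- tempfile(fileext = ".json")
  writeLines('{"error_sources": [{"name": "x",
    "rates": {"substitution": 1.5, "insertion": 0, "deletion": 0}}]}', bad)
  expect_error(load_channel_config(bad), "\\[0,1\\]")
  notjson <- tempfile(fileext = ".json")
  writeLines("{nope", notjson)
  expect_error(load_channel_config(notjson), "malformed")
})

test_that("bundled default profile totals 0.33%", {
  cfg <- load_channel_config(default_channel_path())
  expect_equal(total_error_rate(cfg), 0.0033, tolerance = 1e-12)
  expect_length(cfg$sources, 4L)
})

test_that("zero-rate config transmits unchanged and has empirical rate 0", {
  cfg <- zero_channel()
  expect_equal(total_error_rate(cfg), 0)
  nr <- transmit("ACGTACGT", cfg, seed = 1)
  expect_equal(nr$sequence, "ACGTACGT")
  expect_equal(nrow(nr$event_log), 0L)
  expect_equal(empirical_error_rate(cfg, 10, 20, seed = 1), 0)
})

test_that("amplify rescales every rate and preserves proportions exactly", {
  cfg <- mixed_channel(total = 0.0033,
                       pattern = c(substitution = 0.6, insertion = 0.2,
                                   deletion = 0.2))
  amp <- amplify(cfg, 0.068)
  expect_equal(total_error_rate(amp), 0.068, tolerance = 1e-12)
  f <- 0.068 / 0.0033
  expect_equal(amp$sources[[1L]]$rates, cfg$sources[[1L]]$rates * f)
  prop <- function(c) c$sources[[1L]]$rates / sum(c$sources[[1L]]$rates)
  expect_equal(unname(prop(amp)), unname(prop(cfg)), tolerance = 1e-14)
  # identity amplification
  same <- amplify(cfg, total_error_rate(cfg))
  expect_equal(same$sources[[1L]]$rates, cfg$sources[[1L]]$rates)
  expect_error(amplify(zero_channel(), 0.05), "zero-rate")
  expect_error(amplify(cfg, 1.5), "\\(0, 1\\]")
})

test_that("forced outcomes: deletion-only rate 1 deletes everything", {
  cfg <- channel_config(list(error_source(
    "del", c(substitution = 0, insertion = 0, deletion = 1))))
  nr <- transmit("ACGT", cfg, seed = 3)
  expect_equal(nr$sequence, "")
  expect_equal(nr$length, 0L)
  expect_equal(nrow(nr$event_log), 4L)
  expect_true(all(nr$event_log$type == "deletion"))
})

test_that("transmit validates inputs", {
  cfg <- zero_channel()
  expect_error(transmit("ACGU", cfg), "outside \\{A,C,G,T\\}")
  expect_error(transmit("", cfg), "nonempty")
})

test_that("event-log replay reproduces the noisy output (many seeds)", {
  cfg <- mixed_channel(total = 0.15)
  set.seed(42)
  for (i in 1:300) {
    s <- random_dna_string(sample(10:80, 1))
    nr <- transmit(s, cfg)
    expect_identical(replay_events(s, nr$event_log), nr$sequence)
    n_ins <- sum(nr$event_log$type == "insertion")
    n_del <- sum(nr$event_log$type == "deletion")
    expect_equal(nr$length, nchar(s) + n_ins - n_del)
  }
})

test_that("substitutions never reproduce the original base; bias respected", {
  cfg <- channel_config(list(error_source(
    "sub", c(substitution = 1, insertion = 0, deletion = 0))))
  nr <- transmit(strrep("A", 200), cfg, seed = 5)
  expect_false(grepl("A", nr$sequence, fixed = TRUE))
  biased <- channel_config(list(error_source(
    "sub", c(substitution = 1, insertion = 0, deletion = 0),
    substitution_bias = list(A = c(C = 1, G = 0, T = 0)))))
  nr2 <- transmit(strrep("A", 100), biased, seed = 6)
  expect_equal(nr2$sequence, strrep("C", 100))
})

test_that("determinism: identical seed, config and input give identical reads", {
  cfg <- mixed_channel(total = 0.1)
  s <- random_dna_string(60)
  r1 <- transmit(s, cfg, seed = 99)
  r2 <- transmit(s, cfg, seed = 99)
  expect_identical(r1, r2)
})

test_that("calibration: empirical rate within 3 binomial SE of configured total", {
  for (total in c(0.005, 0.033, 0.068)) {
    cfg <- mixed_channel(total = total)
    n <- 4000L; len <- 96L
    emp <- empirical_error_rate(cfg, n, len, seed = 7)
    se <- sqrt(total * (1 - total) / (n * len))
    expect_lt(abs(emp - total), 3 * se)
  }
})
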