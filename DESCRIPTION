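Package: dnaturbo
Title: Trainable Turbo-Autoencoder Codecs for the DNA Data Storage Channel
Version: 0.1.0
Authors@R:
    person("dnaturbo", "developers", email = "dnaturbo@example.org",
           role = c("aut", "cre"))
Description: Tools for designing and training neural error-correcting codecs
    for DNA data storage. Provides a configurable simulator of the DNA
    storage channel (substitution, insertion and deletion errors with
    per-component error profiles and a rate amplifier), an evaluator of
    sequence design constraints (GC content, homopolymer runs, k-mer
    repeats and undesired motifs) that yields a batch stability score, the
    deterministic codec core of a turbo autoencoder (interleavers, block
    normalization, straight-through binarization, bit/base mapping and
    payload segmentation), small trainable encoder, transcoder and
    iterative turbo-decoder networks with several architectures, and a
    command-line interface for training, encoding files to DNA strands,
    corrupting, scoring and decoding.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Biostrings,
    optparse,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
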