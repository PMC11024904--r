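---
title: "Methods: trainable turbo-autoencoder codecs for DNA storage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trainable turbo-autoencoder codecs for DNA storage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Storing digital data in synthetic DNA passes a message through a channel
made of synthesis, PCR amplification, storage and sequencing. Each stage
contributes characteristic errors: substitutions (a base changes),
insertions and deletions (indels, which shift every downstream base and
change the sequence length). On top of the error process, practical DNA
must satisfy design constraints — balanced GC content, no long
homopolymer runs, no problematic motifs — because violating them raises
synthesis and sequencing failure rates.

`dnaturbo` implements a trainable error-correcting codec for this
channel in the turbo-autoencoder family: a neural encoder produces an
overcomplete binary code that is mapped to DNA, a configurable channel
simulator corrupts the strands during training, an indel-reduction
transcoder maps variable-length noisy reads back to a fixed-size
representation, and an iterative two-network turbo decoder reconstructs
the message. An auxiliary constraint evaluator turns sequence-design
rules into a differentiable-in-practice training signal.

## Model components

**Interleaver.** A fixed permutation π shared by encoder and decoder,
either pseudo-random (reproducible from a seed) or the affine form
π(i) = (k·i + u) mod N. The affine form is a bijection exactly when
gcd(k, N) = 1, and the package enforces that condition against the
permutation length N. With latent redundancy r > 0 the message length n
and the per-stream code length N = n + r differ; one interleaver spec
therefore yields two permutations (length n on the message side, length
N on the code side). For r = 0 they coincide and the wiring reduces to
the published two-permutation-free form.

**Encoder.** Two (rate 1/2) or three (rate 1/3) stream networks; the
final stream sees the interleaved message. Architectures: 1-D CNN,
Elman RNN, VAE (reparameterized latent; the KL term enters the encoder
loss with a small configurable weight, 0 disables it; at inference the
latent collapses to its mean so encoding is deterministic), and a
single-head transformer encoder block. Each stream output of length
n + r is normalized per block to zero mean and unit *population*
standard deviation, then binarized by thresholding at 0 (ties map to 1)
with a straight-through estimator: forward pass is hard, the backward
contract is the identity. Streams are concatenated
[stream0 | stream1 | stream2] and consecutive bit pairs map to bases via
λ: 00→A, 01→G, 10→T, 11→C. Internally the code is bipolar (±1);
conversion to 0/1 happens only at the mapping boundary.

**Channel.** Per base, at most one event is drawn from a categorical
distribution over {none, substitution, insertion, deletion}, with per-type
probabilities summed over the configured error sources (synthesis,
sequencing, PCR, storage). This keeps the total event rate equal to the
sum of the type rates without compounding. Substitutions draw a
different base, uniformly unless a bias matrix is configured; insertions
add one uniform base after the position; multi-base insertions are out
of scope. An amplifier rescales every rate by one multiplication so that
the total hits a target while type and source proportions are preserved
exactly. The JSON dialect accepts both the native schema and a
MESA-style export layout; positional error attributes are collapsed to
flat per-base rates with a logged notice.

The bundled default profile (column synthesis with ErrASE, Illumina
single-end, Taq 30 cycles, E. coli 24 months) guarantees only its total
of 0.33% per base; the per-component split is a constructed stand-in and
the fixture is named `_synthetic` accordingly.

**Transcoder (indel reduction).** Noisy reads of any length are fitted
into a fixed window (nominal strand length plus an 8-base margin) as
one-hot vectors with a dedicated pad channel, right-truncating overlong
reads, and mapped by a CNN/RNN/ResNet to exactly the decoder's expected
input length. By default the output is binarized (straight-through) and
trained with smooth L1 against the binarized encoder output; a
continuous mode passes unbinarized values to the decoder. A
deterministic `bypass` transcoder (de-map + pad/truncate) is available
as a reference path.

**Decoder.** The code vector splits into y0, y1 (, y2). Each iteration:
D0 consumes (y0, y1, prior), producing a posterior q; D1 consumes
(interleaved q, interleaved y0, y2); the de-interleaved output of D1
becomes the next prior. The prior starts at all zeros and lives on a
log-odds-like real scale, so zero initialization is the uninformative
point. After the last iteration a sigmoid of the de-interleaved
posterior, thresholded at 0.5, yields the message estimate; with latent
redundancy the estimate is read from the first n positions. Two wirings
of the second stage appear in the turbo-autoencoder literature (one
feeds y2 together with interleaved q and y0, the other feeds y1 plus an
interleaved prior); this package implements the former throughout.

## Training

The loss is smooth L1 (elementwise 0.5·d²/β for |d| < β, else
|d| − 0.5·β; β defaults to 1.0) between input bits and the sigmoid
decoder output, reduced by the mean. Per epoch the schedule alternates:

* **Encoder phase** (`t_enc` batches, decoder and transcoder frozen):
  the discrete string channel is not differentiable, so this phase uses
  a tensor-space surrogate — independent sign flips on the bipolar code
  bits at rate (2/3)·(total error rate), because a uniform base
  substitution flips each of its two mapped bits with probability 2/3.
  Indels are not modelled in the surrogate; indel robustness is learned
  by the transcoder in the other phase.
* **Decoder/transcoder phase** (`t_dec` batches, encoder frozen): the
  real string channel corrupts the mapped strands; the transcoder is
  trained against the encoder output and, end to end, through the
  decoder's reconstruction loss.

Optimization is Adam (default learning rate 1e-4, batch size 256,
`t_enc` = 100 and `t_dec` = 500 — all config-overridable defaults of
this package; no published reference values exist for them). Training data are seeded uniform random bit
blocks; no external dataset exists. After every epoch the five logged
quantities (component losses, reconstruction accuracy, stability score,
noise level, fraction of perfect blocks) are appended to a JSON-lines
log, and a checkpoint (weights, optimizer state, full config,
interleaver spec, RNG state, epoch) is written; resuming restores the
RNG state so a paused run continues bit-identically. Non-structural
hyperparameters are re-read from the config file at epoch boundaries,
allowing online adjustment.

## Constraint fine-tuning

The constraint evaluator maps a sequence to an error probability:
probability graphs (points with step or linear interpolation — linear is
the default since interpolation is meant to smooth the curves) over GC
percent, longest homopolymer run and maximal overlapping k-mer repeat
count, plus motif hits, combined as independent failure modes
p = 1 − Π(1 − p_c). The batch stability score is w_DNA = 1 − mean(p) on
the [0, 1] scale; percent-to-fraction conversion happens exactly once,
at batch construction. Fine-tuning continues training with the encoder
loss augmented by `stability_weight · (1 − w_DNA)`.

The *value* of that term always uses the hard evaluator on the actual
encoded DNA. Its *gradient* cannot (strings are discrete), so a
straight-through surrogate acts on the bipolar code bits: the GC term
evaluates the configured piecewise-linear GC graph at the soft GC
fraction (the second mapped bit indicates G/C), adding a gentle pull
toward 50% GC on zero-slope violation plateaus where the graph itself
gives no direction; the homopolymer term is a product-of-equalities soft
indicator of runs reaching the graph's threshold length (the smallest
run length whose configured probability exceeds the length-1 value).
k-mer and motif constraints contribute value but no gradient — a known
limitation: fine-tuning cannot actively optimize against them.

## Decoding files and the re-encoding refinement

`cmd_encode` segments a byte payload into blocks (zero-padded tail), adds
an index-0 header strand carrying the payload bit length, and writes one
FASTA record per strand. `cmd_decode` de-maps strands of nominal length
directly and sends length-changed (indel-damaged) strands through the
transcoder, turbo-decodes, then applies a deterministic *re-encoding
refinement* that maximizes the agreement between the re-encoded
candidate and the received code bits: exact enumeration for blocks of at
most 12 bits; otherwise a Chase-style exhaustive toggle of the ten
least-confident bits (by decoder logit magnitude) followed by greedy
single-bit descent with a pairwise-flip escape stage. This is artifact
plumbing on top of the neural decoder: a network with accuracy below 1.0
cannot restore a file bit-exactly, while the refinement makes zero-noise
round trips exact and sharpens noisy decoding. It presupposes an
injective encoder; raw untrained encoders violate injectivity for a
small fraction of blocks (binarization collapses nearby inputs), which
training removes in practice.

## What the synthetic world does and does not establish

The test suite trains "smoke" models: block 24 bits, rate 1/3, CNN
encoder, ResNet transcoder, CNN decoder, batch 256, 50 epochs, and a
substitution-only channel at 2% total error. Width (14 units), decoder
iterations (2) and per-epoch batch counts (2 encoder + 4 decoder) are
scaled so the whole suite fits a single-CPU time budget; learning rate
2e-3 compensates for the short schedule. A green smoke test establishes
that the full pipeline — encoder, mapping, channel, transcoder,
iterative decoder, alternating training — learns a code clearly above
chance (accuracy > 0.95) under substitution noise, that latent
redundancy does not hurt, and that constraint fine-tuning moves the
stability score in the right direction. It does *not* establish the
reported large-scale accuracies (which require hundreds of epochs at
larger widths), nor indel-heavy decoding performance: indel handling is
exercised functionally (channel, event logs, transcoder shape contracts)
but not to convergence.

## Numerical choices and edge cases

* Population (not sample) standard deviation in block normalization;
  constant blocks return zeros with a warning.
* Binarization ties at exactly 0 map to 1 (+1 bipolar).
* Interleaver validity is checked against N (gcd(k, N) = 1).
* Empty reads transcode to an all-pad window; overlong reads are
  right-truncated.
* The header strand limits payloads to 2^min(block_bits, 53) − 1 bits.
* Decoding refuses a missing header strand and reports missing payload
  indices by number; length-0 records are skipped with a warning.
* Seeds: every stochastic entry point takes an explicit seed; derived
  child seeds stay below 2^31.

## Known limitations

* No FASTQ quality emission, no multi-read consensus, and single-copy
  decoding only.
* The constraint surrogate gives no gradient for k-mer and motif terms,
  and assumes threshold-style homopolymer graphs.
* Secondary-structure constraints are out of scope.
* The exact per-component rates of the default channel profile are
  synthetic stand-ins; only the 0.33% total is anchored.
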