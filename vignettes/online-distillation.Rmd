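---
title: "Online knowledge distillation for molecule generation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Online knowledge distillation for molecule generation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `moldistill`, the
assumptions behind it, the parameters that matter, what the synthetic data
generator does and does not emulate, and the numerical and design choices
made where the method description left the design open. It states no
empirical result that the package's test suite or `scripts/acceptance.R` do
not themselves compute.

## The model

Two autoregressive SMILES generators are trained simultaneously on the same
corpus of (molecule, Bemis–Murcko scaffold) pairs:

* the **from-scratch generator**: a pre-norm, decoder-only transformer
  (learned token and position embeddings, causal multi-head self-attention,
  GELU feed-forward blocks, final layer norm, vocabulary projection);
* the **scaffold-conditioned generator**: a standard encoder–decoder
  transformer. The encoder attends bidirectionally over the scaffold token
  sequence (an empty scaffold is encoded as a bare EOS); the decoder is
  causal over molecule tokens with cross-attention into the encoder states.

Both decoders are teacher-forced on the same batch, so their per-position
next-token distributions are aligned and comparable. Four loss terms are
combined:

| term | definition | gradient reaches |
|---|---|---|
| `L_CE1` | mean NLL of the target token under the from-scratch logits | from-scratch generator |
| `L_CE2` | same under the scaffold-model logits | scaffold generator |
| `L_mutual` | mean per-position `KL(softmax(z1) ‖ softmax(z2))`, `z2` detached | from-scratch generator only |
| `L_gen` | `mean log(1 − D(h1))`, `D` frozen for this term | from-scratch generator only |

with total `Loss = L_gen + λ1 L_CE1 + λ2 L_CE2 + λ3 L_mutual` and
`(λ1, λ2, λ3) = (1.5, 1, 0.5)`. `h1`/`h2` are the outputs of the last
decoder layer (after the final layer norm, before the vocabulary
projection). The discriminator — a two-layer bidirectional LSTM whose final
forward/backward states are concatenated and passed through an affine map
and a logistic squash — is optimised separately, once every
`disc_update_period = 5` steps, on detached copies of `h1` and `h2`.

Assumptions worth making explicit:

* the corpus is canonical-SMILES text; all inputs are canonicalized at load
  time, which makes uniqueness and novelty well-defined string comparisons
  (whether the original models saw canonical or raw strings is unknowable
  from the description; canonical is assumed);
* per-position KL is meaningful because both models are teacher-forced on
  identical target sequences;
* the scaffold of an acyclic molecule is the empty string; the encoder
  receives `[EOS]` for it.

## Sign of the discriminator objective

As printed, the discriminator loss `L_d = [log D(h2) + log(1 − D(h1))]/2`
would, if *minimised*, train the discriminator to misclassify both inputs —
the opposite of its described role of telling scaffold-derived feature maps
apart from from-scratch ones. The implementation therefore minimises its
negation, the standard GAN discriminator negative log-likelihood: `D` is
pushed toward 1 on `h2` and 0 on `h1`. This is the only reading consistent
with the adversarial setup; the generator side (`L_gen`) is implemented
exactly as printed.

## One-directional mutual learning

Classical deep mutual learning is symmetric. Here the KL is computed only
from the from-scratch model toward the scaffold model, and the
implementation realises that one-directionality with a stop-gradient on the
scaffold-side logits: `z2` enters `L_mutual` as a constant target. Both
models still update simultaneously — the scaffold model through its own
cross-entropy — but no gradient of the KL (or of the adversarial terms)
reaches it. The test suite asserts these routing contracts exactly (zero
gradient norms on a small model).

## Tunable parameters

| parameter | default | units | notes |
|---|---|---|---|
| `n_decoder_layers` / `n_encoder_layers` | 8 / 8 | layers | reference architecture |
| `n_heads` | 8 | heads | must divide `model_dim` |
| `model_dim` | 256 | dims | also the discriminator hidden size |
| `ffn_mult` | 4 | — | feed-forward width multiplier |
| `max_len` | 128 | tokens | learned positions; overlong records rejected at encode time |
| `dropout` | 0.1 | fraction | residual branches, training only |
| `lambda1, lambda2, lambda3` | 1.5, 1, 0.5 | — | composite-loss weights |
| `generator_lr` / `discriminator_lr` | 6e-4 / 3e-4 | — | AdamW, betas (0.9, 0.98) |
| `weight_decay` | 0.01 | — | AdamW decoupled decay |
| `disc_update_period` | 5 | steps | discriminator cadence |
| `grad_clip` | 1.0 | global L2 norm | generators only |
| `batch_size` | 512 | sequences | 300 is the long-sequence reference setting |
| `temperature` | 1.0 | — | sampling; `multinomial` or `greedy` |
| `start_token` | `"C"` | token | fed as first input *and* emitted |

`tiny_generator_config()` (2 layers, 64 dims, 4 heads, `ffn_mult` 2,
`max_len` 64) is the desk-scale preset used throughout the tests.

## Decisions where the design was open

* **Positional encoding**: learned embeddings up to `max_len`, the common
  choice for SMILES decoders; the architecture description is silent.
* **Weight tying** between the token embedding and the output projection is
  off, keeping the feature map and logit roles distinct.
* **Discriminator pooling**: the sequence summary is the concatenation of
  the final hidden states of the two directions of the top LSTM layer —
  mask-safe (padded steps carry state through unchanged) and simple; the
  pooling is otherwise unspecified.
* **Verdict clamping** to `[1e-7, 1 − 1e-7]` keeps every adversarial log
  term finite; `L_gen` is therefore bounded and ≤ 0, `L_d` ≥ 0.
* **KL in log space**: both KL losses are computed from log-softmax
  outputs, avoiding underflow for sharp distributions.
* **AdamW weight decay** 0.01: the optimiser family's customary default;
  only the learning rates and betas are prescribed.
* **Gradient clipping** at global norm 1.0 stabilises the adversarial term
  at toy scale.
* **Start token**: the literal chemical token `C` is fed as the first
  decoder input and emitted as the first character of every sample, so all
  samples begin with a carbon — consistent with canonical SMILES of
  drug-like sets, which overwhelmingly start with `C`. Passing
  `start_token = NULL` substitutes the non-emitting BOS.
* **Specials never sampled**: PAD and BOS logits are masked to −∞ during
  decoding, so every sample is a detokenizable chemical-token sequence by
  construction (EOS terminates). Validity is *not* enforced — it is a
  metric.
* **Token ids** are 1-based R indices internally; nothing 0-based surfaces
  in any file format.
* **Mixed precision** is not implemented: all arithmetic is double
  precision, which is what makes the exact closed-form and
  finite-difference tests meaningful. (A gradient scaler only matters for
  half-precision training.)
* **`offline_kd` pre-training** uses the scaffold model's cross-entropy
  alone for `pretrain_epochs` (default: the same number of epochs as
  co-training), then freezes the teacher bitwise.

## Numerical contracts

* Cross-entropy, KL and the adversarial terms operate on a packed ragged
  representation: PAD positions are removed before the computation rather
  than masked afterwards, so mask correctness is structural.
* The sampling path is a separate tape-free implementation with per-layer
  key/value caches; the test suite verifies it reproduces the
  teacher-forced training forward bitwise (to 1e−10) for both generators.
* All gradients come from a small reverse-mode autodiff engine; every
  primitive (including fused multi-head attention and the LSTM cell) is
  finite-difference checked in the tests.
* Pareto-front ties: duplicated non-dominated rows are both retained
  (domination requires strict improvement in at least one objective);
  output order is input order.
* Tanimoto similarity of two empty fingerprints is defined as 1 (the
  molecules are indistinguishable to the fingerprint); this case cannot
  arise in the shipped fixtures.

## The synthetic corpus

`generate_toy_corpus()` assembles molecules by attaching side-chain
fragments (`C`, `CC`, `CCC`, `O`, `N`, `F`, `Cl`, `OC` by default) at
substitutable ring carbons of six small ring systems (benzene, cyclohexane,
pyridine, cyclopentane, furan, piperidine), then canonicalizes. Every
record is valid by construction and carries its true Bemis–Murcko scaffold,
exactly the (molecule, scaffold) pairing the framework assumes; the token
vocabulary is ~11 chemical tokens, a grammar a 2-layer model can learn in
minutes on a CPU. `corrupt_smiles()` provides matched negative controls
(unclosed rings, unbalanced parentheses, valence violations) for the
validity metric.

What the toy corpus does **not** emulate: drug-like property distributions,
bracket atoms, stereochemistry, charges, fused or bridged ring systems,
long-range dependencies of 60+-token SMILES, and the scale (10^6 molecules)
of public benchmarks. Passing tests therefore demonstrate the correctness
of losses, gradient routing, cadence, sampling and metrics, and that the
co-training dynamics behave qualitatively as intended (falling
cross-entropy, large validity gain over an untrained model) — not that
benchmark-scale headline numbers are reproduced.

## Problem sizes used by the tests and the acceptance script

Chosen as the package's own desk-scale study conditions: tokenizer
round-trip over a 5,000-molecule corpus; metric-oracle equivalence on 50
molecules and 100 random objective matrices (up to 200×4); gradient and
causality checks on 16-dim models; cadence checks over 50 steps; and a
smoke-training run — tiny preset, 2,000 molecules, 5 epochs, batch 32 —
from which the falling cross-entropy and the trained-vs-untrained validity
gap are measured on 500 samples. The six ablation variants are additionally
run end-to-end for one epoch on a 200-molecule subset, where the property
under test is completion without numerical failure. `scripts/acceptance.R`
repeats the smoke run from scratch and reports its metrics.

## Scaling up (not run in CI)

The reference-scale experiment — 8 layers, 8 heads, 256 dims, batch 512,
100 epochs on a 1.6–1.9 M molecule corpus (MOSES or GuacaMol) — is
expressed by the package defaults:

```r
records <- read_smiles("moses_train.smi")       # user-downloaded
vocab   <- build_vocabulary(records$smiles)
fit <- train_distillation(
  records,
  gen_config = generator_config(length(vocab$index_to_token)),
  config     = train_config(epochs = 100, batch_size = 512, seed = 1),
  vocab      = vocab
)
```

Be aware that (a) this is a GPU-scale computation in the original setting
and far beyond a single-CPU R session, and (b) benchmark headline values
are stochastic and data-dependent; this package's pure-R engine is built
for desk-scale study, not for reproducing them.

## Known limitations

* The chemistry layer shells out to RDKit via Python in batches; per-call
  interpreter start-up (~1 s) is amortised by an in-session cache, but very
  chatty per-molecule loops should batch their inputs.
* No beam search, nucleus sampling or valence-constrained decoding.
* No distributed training, learning-rate schedules, or half precision.
* Affinity-based objectives (e.g. predicted pIC50) are out of scope;
  `pareto_front()` accepts any externally computed score column, which is
  the supported extension point.
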