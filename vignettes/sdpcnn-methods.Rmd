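---
title: "Path-CNN classification of protein-protein interactions: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path-CNN classification of protein-protein interactions: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdpcnn)
```

## The task and the representation

Given a dependency-parsed sentence containing two protein mentions, the
package decides whether the sentence asserts an interaction between
them. The working hypothesis, standard in PPI relation extraction, is
that the *shortest dependency path* (sdp) between the two mentions
concentrates the relation-bearing material — typically an interaction
verb ("binds", "inhibits", "activates") and the grammatical relations
connecting it to the two mentions — while the rest of the sentence is
mostly distraction.

The pipeline is:

1. **Entity heads.** A mention span may cover several tokens
   ("Acanthamoeba profilin"); the token whose governor lies outside the
   span is taken as its syntactic head, since that token carries the
   edge into the rest of the sentence. If no unique such token exists,
   the last span token is used and a warning is raised.
2. **Shortest path.** Breadth-first search over the head/dependent edge
   set viewed as an *undirected* graph — relevant paths routinely climb
   against edge direction (e.g. upward through `nsubj`). Neighbours are
   explored in ascending token index, so the path is deterministic when
   several shortest paths exist; the parses themselves are trees, where
   the path is unique, but the reader only requires connectivity.
3. **Blinding and serialization.** The two endpoints become the
   reserved symbols `Protein1`/`Protein2` (preventing memorisation of
   protein names and reducing sparsity); interior words are lowercased;
   the dependency relations along the path are spliced between the
   words. A k-node path yields 2k−1 tokens, e.g.
   `Protein1 nsubj affects dobj properties prep-of Protein2`.
   Relation labels are deliberately ordinary vocabulary items — the
   network treats them as words.
4. **Fixed length.** The network consumes exactly N tokens: shorter
   sequences are padded with `PADDING` (which embeds to the zero vector
   and never receives gradient); longer ones are truncated, by default
   removing a block centred on the path midpoint so that both entity
   anchors and their local context survive (`truncate = "tail"` is
   available).

## The network

Each token is looked up in an embedding table `D` (|V| × d). The N × d
path matrix P is convolved by M filters of width h (default 3): filter
k produces features `c_i = tanh(<W_k, P[i..i+h-1,]> + b1_k)` for the
N−h+1 windows, the elementwise product being summed over all h·d window
entries. Max-over-time pooling keeps each filter's maximum, giving a
fixed-size vector r of length M regardless of path length. A hidden
layer `O = tanh(W2 r + b2)` and a bias-free confidence transform
`I = W3 O` feed a two-class softmax, computed with max-subtraction
(the textbook form overflows for large confidences).

Training minimises the negative log-likelihood `−log S[y]` (clamped at
1e−12 before the log) with one exact backpropagation step per training
example: the softmax/NLL pair contributes `S − onehot(y)`, max-pooling
routes gradient only into each filter's argmax window, and — when
embeddings are trainable — the input gradient updates exactly the rows
of tokens present in the example. Updates use Adadelta (decay
ρ = 0.95, ε = 1e−6, the optimizer's published defaults), which scales
each coordinate by the ratio of running RMS update to running RMS
gradient and so needs no learning rate; a fixed-rate schedule is
exactly what makes plain per-example gradient descent unstable here.

### Embedding variants

* `random` — rows drawn i.i.d. uniform from [−a, a] (default
  a = 0.25), frozen.
* `random_update` — same initialization, rows of observed tokens
  fine-tuned during training (the package default).
* `pretrained` — rows found in a word2vec file are copied and frozen;
  the spread `a` for the remaining random rows is set to the standard
  deviation of all pretrained entries, so both populations live on the
  same scale. (Reading that spread as a *variance* of unit-scale
  vectors would give a near-zero range and a degenerate
  initialization.)
* `combined` — two input channels, one pretrained and one random table,
  each with its own filter bank; the pooled vectors are concatenated
  (r has length 2M) before the hidden layer. Both tables are frozen.

Out-of-vocabulary tokens at prediction time receive a stable random
vector seeded from the token string, so repeated runs agree.

### Numerical and degenerate-input choices

* Float64 throughout; gradient-check fidelity on desk-scale models
  matters more than speed here.
* Pooling ties resolve to the first maximum; BFS ties to the
  ascending-index neighbour; an exact probability tie predicts class 0.
* Identical entity spans are rejected as degenerate rather than
  classified; disconnected parses are rejected at read time.
* Filter width h should be odd so the attribution "middle token" is
  well defined; even h is accepted with a warning and uses the token
  left of centre.
* Convolution biases b1 start at zero rather than uniform like the
  other weights: at small d a positive initial bias can exceed every
  content-window response, making the all-zero padding window a fresh
  filter's argmax — and that window contributes no weight gradient, so
  the filter could never escape it.

## Key-word attribution

For each filter, the window at which its pooled maximum occurred is
known; the token in the middle of that window is the filter's
*key-word*. Counting key-words over predicted-positive instances yields
an automatically extracted interaction-verb dictionary. Two sources of
attribution noise are worth understanding:

* relation labels flank every verb, so windows centred on `nsubj` or
  `dobj` legitimately collect counts;
* filters that act as *negative-class evidence* tend to park their
  maximum, on positive instances, at an all-padding window (constant
  activation `tanh(b1)`), so `PADDING` itself accumulates votes.

On synthetic corpora with a single planted trigger verb the trigger is
reliably among the top-ranked key-words, and usually first; whether it
beats the `PADDING` aggregate in a strict ranking depends on how many
filters the optimizer turns into negative-class detectors, which varies
with the seed at desk scale (M = 16). With many filters per class the
counts concentrate and the effect washes out.

## Evaluation protocol

Precision, recall and F (harmonic mean, zero when undefined) with the
interaction class positive. Cross-validation uses stratified
instance-level folds whose sizes differ by at most one; each fold's
model is trained from scratch, including the vocabulary and embedding
tables, from that fold's training data only — held-out surface forms
never enter the tables. The learning-curve experiment holds out a
growing test fraction (0.1–0.9), trains on the remainder, and averages
metrics over seeds; F declines as the training share shrinks.
Document-level fold grouping, a known driver of score variance in PPI
benchmarks, is out of scope for the synthetic corpora (which have one
instance per sentence and no document structure).

## The synthetic corpus generator

Benchmarks in this area (Aimed, BioInfer) require external downloads, a
dependency parser and a multi-gigabyte embedding file, so the package
ships a generator that emulates the structural essentials instead: a
dependency tree whose path between two protein tokens passes through a
verb drawn from a positive *trigger lexicon* (label 1: "activates",
"binds", "inhibits", "phosphorylates", "regulates") or from a *neutral
lexicon* (label 0), with filler nouns on the path, distractor branches
off it, relation labels sampled uniformly from
{`nsubj`, `dobj`, `prep-of`, `amod`, `conj`}, and a configurable
distribution over odd raw path lengths (default 5/7/9 with weights
0.4/0.4/0.2; lengths below 5 are rejected because a two-node path has
no interior slot for a verb). The label depends on *nothing but* the
verb's lexicon membership, so a classifier beating chance must be
reading path content. The neutral lexicon is deliberately larger (12
verbs) than the trigger lexicon: interaction verbs form a compact class
while non-interaction contexts are diverse, and a neutral class as
compact as the trigger class would be equally learnable, blurring the
planted signal that recovery experiments rely on.

What the generator does **not** emulate: lexical diversity (a few dozen
word types versus tens of thousands), parser errors, negation and
speculation, multiple candidate pairs per sentence, document structure,
and any correlation between path length and label. Tests passing on
synthetic corpora therefore demonstrate that the machinery — path
extraction, gradients, optimization, evaluation — works and that the
model can recover a planted lexical signal; they say nothing about
absolute F-scores on real corpora.

## Problem sizes and defaults

`sdpcnn_config()` defaults mirror the benchmark settings (N = 20,
d = 300, h = 3, M = 100, H = 500, 100 epochs). The synthetic
experiments in the test suite and the acceptance script use a
desk-scale counterpart chosen for the generator's vocabulary and path
lengths: N = 11 (covers the longest generated path without
truncation), d = 50, M = 16, H = 16, 40 epochs (200 for the
overfitting capacity check). d = 50 is the smallest dimension at which
content-window activations comfortably dominate the constant windows
discussed under attribution; at very small d the random-projection
variance is too low and attribution degrades long before
classification does. 10-fold cross-validation on 500 instances with
these settings runs in a few minutes on one core.

## Known limitations

* C = 2 only; no multi-class relation typing, dropout or L2 — the
  architecture is kept exactly as described.
* No dependency parser is run or wrapped: parses are consumed in
  CoNLL-style files, whatever representation (basic or collapsed) the
  upstream parser produced; the worked example uses collapsed
  prepositions (`prep-of`).
* Per-example updates only (a batch-size knob exists in spirit but the
  published procedure is per-pair, which is what is implemented).
* Pure-R execution: fine for desk-scale studies; a benchmark-scale run
  (d = 300, M = 100, thousands of instances) is minutes-per-epoch
  territory.
```{r}
we <- worked_example()
extract_sdp(we$parse, we$instance)$tokens
```
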