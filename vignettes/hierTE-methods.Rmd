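---
title: "Hierarchical TE classification with an attention-fused CNN–GRU: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical TE classification with an attention-fused CNN-GRU: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Transposable elements (TEs) are classified into a rooted taxonomy: two
classes (retrotransposons with an RNA intermediate, DNA transposons without),
orders/subclasses beneath them (LTR, LINE, SINE, TIR, Helitron, ...), and
superfamilies at the leaves (Gypsy, Copia, hAT, TcMar, CACTA, ...). Two
properties make the classification problem awkward for a single flat
classifier: sequences vary in length from under a hundred to tens of
thousands of base pairs, and class frequencies are wildly imbalanced.
`hierTE` addresses both with a *local classifier per parent node*: one small
model is attached to every internal node of the taxonomy with at least two
children (nine nodes in the default tree) and discriminates only among that
node's children. Prediction is top-down and *nonmandatory*: a query may stop
at an internal node when no child is sufficiently supported, so an
unclassifiable sequence is labelled honestly as, say, `ClassII` rather than
forced into a leaf.

## Features

Each node classifier consumes two complementary views of a sequence:

* **Global view** — the vector of k-mer frequencies (length `4^k`, default
  `k = 7`). Counting uses a rolling Horner update: the base-4 index of each
  window is obtained from its predecessor by dropping the most significant
  digit and appending the new base, so scanning is constant work per
  position rather than O(k). Windows containing any non-ACGT symbol are
  skipped deterministically; a sequence shorter than `k` yields the zero
  vector. Frequencies (counts normalised to sum 1) are the default because
  they are invariant to the large length variation among TEs; raw counts
  are available behind a flag.
* **Local view** — the one-hot encoded *both-end* (BE) sequence: the first
  `L` and last `L` bases concatenated (default `L = 600`). The terminal
  regions carry the discriminative structure of most TE groups — long
  terminal direct repeats, terminal inverted repeats, CACTA termini,
  poly(A)/poly(T) tails. Sequences shorter than `2L` are covered by
  overlapping the two segments; segments shorter than `L` are padded with
  `N`, which one-hot encodes to the all-zero row and therefore contributes
  no signal (a deliberate contrast to schemes that pad with real symbols).

Coordinates in documentation and logs are 1-based inclusive.

## The node classifier

The global branch applies three convolution + max-pooling blocks (64, 128
and 256 kernels; width 3, stride 1, same padding; pool width and stride 2)
over the `4^k`-long frequency signal, flattens, and maps through a dense
layer of 128 units. The local branch runs the `2L x 4` one-hot matrix
through two stacked GRU layers (128 and 64 units, both returning their full
output sequence), flattens, applies dropout, and maps through a dense layer
of 128 units. ReLU is the activation of every hidden layer and dropout 0.5
is applied in the fully connected layers. The GRU follows the standard
update/reset-gate equations; bias terms are included (the gate equations are
often written without them, but they are standard in practice and cost
nothing).

The two 128-dimensional branch vectors `h_cnn` and `h_rnn` are fused by a
scalar attention: a single learned projection `w` scores each branch,
`e_s = tanh(w . h_s)`, the two scores are softmax-normalised into weights
`(alpha_cnn, alpha_rnn)`, and the context vector is the convex combination
`c = alpha_cnn h_cnn + alpha_rnn h_rnn`. The scalar (rather than
vector-valued) score is forced by the interpretation of the weights: each
sequence gets a single CNN-vs-RNN leaning, which `summarize_attention()`
aggregates into dominance fractions per TE group. The softmax output layer
acts directly on the context vector; no further hidden layer is inserted.

Kernel width, pooling geometry and the output head are the package's own
choices where reasonable alternatives exist; experiments with such
variations are reported in the literature as having minimal effect compared
with the choice of `k`.

Training minimises categorical cross-entropy with Adam (default learning
rate 5e-4, configurable), early stopping on a stratified validation split
(patience 5 by default), and an explicit seed for every stochastic step
(initialisation, shuffling, dropout, splits), so a fixed seed reproduces a
training trajectory exactly on fixed hardware. The whole network — forward
pass, backpropagation (including through time for the GRU), and Adam — is
implemented in the package: vectorised R for the convolutional and dense
algebra, C++ (RcppArmadillo) for the GRU recursion and the Horner k-mer
scan. The analytic gradients are verified against central finite
differences in the test suite, which pins every layer at once.

## Top-down prediction

`predict_topdown()` starts at the root and repeatedly queries the current
node's classifier. The descent rule reads the stopping criterion strictly:
the query descends into the argmax child if and only if the maximum child
probability is **at least** the threshold; a maximum strictly below the
threshold stops the traversal (so with the default threshold 0.60 a best
probability of 0.57 stops). Exact ties descend into the lexicographically
first tied child, deterministically. The threshold applies at the root too:
a root-level stop returns the bare root label, read as "TE, level
unassigned". Single-child internal nodes are traversed without a
classifier. Because raising the threshold can only convert descents into
stops, the path at a higher threshold is always a prefix of the path at a
lower one — `threshold_sweep()` relies on this and the tests assert it.

## Evaluation

Flat per-node metrics are the usual accuracy, per-class and macro
precision/recall/F1, and MCC (binary closed form at two classes, the
standard multiclass generalisation otherwise; the two agree on 2x2 inputs).
Hierarchical metrics compare ancestor-closed label sets: `P_i` is the
predicted label plus its ancestors, `T_i` the true label plus its
ancestors, and

    hP = sum |P_i ∩ T_i| / sum |P_i|
    hR = sum |P_i ∩ T_i| / sum |T_i|

with hF their harmonic mean. Under a rising stopping threshold the
predicted sets only shrink, so hR is exactly weakly decreasing; hP rises as
uncertain deep labels are pruned, but pruning a *correct* label can lower
the pooled ratio by up to one-label granularity (about `1 / sum |P_i|`), so
hP's increase holds as a trend, not pointwise — the sweep tests assert
exactly this. The universal root is excluded from both sets
by default: every sequence shares it, so including it inflates both metrics
without adding information (`include_root = TRUE` restores the strict
sets). Zero-division conventions: an empty class gets precision/recall 0, a
zero MCC denominator gives 0; occurrences are recorded in the result's
notes.

## The synthetic repeat simulator

Real benchmark libraries (Repbase, Dfam, TREP and relatives) cannot be
redistributed, so the package ships a seeded simulator whose classes carry
exactly the structural signals the classifier is meant to exploit:
direct terminal repeats (LTR-like), reverse-complement-matched terminal
inverted repeats (TIR-like), fixed termini (`CACTA...TAGTG`), 3'
poly(A)/poly(T) tails, global k-mer composition bias, and two decoy
mechanisms — the same motif content planted *away* from the termini, and
non-TE sequences (codon-structured coding-like decoys and mutated tandem
repeats). Backgrounds are uniform over A/C/G/T by default; planted motifs
receive point substitutions at a configurable per-base rate. Every
simulated record passes the preprocessing filters by construction
(length >= 80, ambiguity <= 20%).

What the simulator does *not* emulate: real family phylogenies, nested
insertions, genomic flanks, target-site duplications beyond fixed termini,
or realistic length distributions. Passing the synthetic recovery tests
therefore shows that the architecture can extract planted terminal
structure and composition bias at desk scale — not that it reaches any
particular accuracy on curated repeat libraries.

## Desk-scale study conditions

The package's own experiments (test suite and `scripts/acceptance.R`) run
on one CPU in minutes, so they use reduced problem sizes, fixed once:

* **Contrast datasets** — two classes separable *only* by terminal-motif
  placement (a 30-bp motif and its reverse complement at the termini,
  versus the same two motifs planted at interior positions, so global
  composition matches), and two classes separable *only* by which of two
  disjoint sets of eight 7-mers is enriched (3-fold target, planted outside
  the 100-bp terminal margins, so the local view matches). 200 sequences
  per class, lengths uniform 300–700 bp, motif mutation rate 0.02 — mild
  family divergence, calibrated at design time so the planted signal is
  learnable at this scale.
* **Reduced architecture** — `k = 5`, `L = 100`, conv channels 8/16/32,
  GRU 16/8, dense width 32, dropout 0.3, learning rate 1e-3, batch 8, at
  most 30 epochs (10 suffice for the terminal-motif experiment, 15 per node
  for the pipeline). The full-scale defaults (64/128/256, 128/64, dense 128, lr 5e-4)
  are impractical for a minutes-scale CPU run and are exercised only
  structurally (shape and gradient tests).
* **Pipeline dataset** — a three-level, four-leaf taxonomy (root splits on
  terminal structure, one subtree on composition bias, the other on
  distinct TIR motifs), 150 sequences per leaf, evaluated with a threshold
  sweep over 0.50–0.95 in steps of 0.05.

Under these conditions the local-only model recovers the terminal-motif
contrast essentially perfectly while the global-only model is near chance,
and the ranking reverses on the composition contrast — the desk-scale
mirror of the ablation logic that motivates fusing the two branches.

## Numerical choices and degenerate inputs

* The global branch rescales each frequency profile by `4^k` (equivalently,
  to fold-enrichment over the uniform expectation) so that input magnitudes
  are O(1) regardless of `k`; raw-count input is normalised per profile
  first. Without this, inputs of order `4^-k` start the network in a
  near-zero regime and slow optimisation badly.
* Max-pooling ties keep the left element; argmax ties in prediction are
  broken lexicographically; both choices are deterministic.
* Probabilities are computed with max-shifted softmax; cross-entropy clamps
  probabilities at 1e-12.
* Empty sequences one-hot to all-zero matrices and k-mer count to zero
  vectors; `extract_both_ends("")` warns and returns all-N padding.
* Early stopping restores the parameters of the best validation epoch; with
  `validation_split = 0` the final-epoch parameters are kept.

## Known limitations

* Training the full-scale architecture on a realistic library is a
  GPU-scale job; this implementation is CPU-bound and intended for
  method-level work, reduced-scale experiments, and small libraries.
* Errors at upper nodes propagate downward by construction of the top-down
  scheme; no cross-level calibration is attempted.
* The similarity deduplication mode is a greedy k-mer Jaccard clustering,
  a stand-in for alignment-based pairwise identity.
* Protein/domain evidence (the strength of alignment-based classifiers for
  divergent but domain-conserved families) is deliberately out of scope.
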