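---
title: "Classifying lncRNA and mRNA from k-mer frequency matrices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying lncRNA and mRNA from k-mer frequency matrices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerCNN)
```

## The problem and the idea

Long non-coding RNAs (lncRNAs) are transcripts longer than ~200 nt with no
protein-coding role; telling them apart from messenger RNAs (mRNAs) is a
routine annotation task. Coding and non-coding transcripts differ in local
nucleotide composition — mRNAs are GC-leaning and carry codon-usage
structure, lncRNAs are AT-leaning with flatter trinucleotide usage, and
both deplete the CpG dinucleotide — so the spectrum of short subsequence
(k-mer) frequencies carries class information without any alignment,
ORF-finding or homology search.

`kmerCNN` implements an image-style reading of that spectrum. Each
sequence is summarized as a vector of sliding-window k-mer frequencies,
the vector is laid out row-major on a small 2-D grid, and a compact
convolutional neural network learns which local patterns of the grid
separate the two classes. The package encodes lncRNA as class 0 (the
positive class for all metrics) and mRNA as class 1.

## Feature extraction

**Vocabulary order.** All k-mers of length k are enumerated in a base-4
positional system with digit order A < T < C < G: for k = 3 the
vocabulary starts `AAA, AAT, AAC, AAG, ATA, ...` and ends
`..., GGA, GGT, GGC, GGG`. This non-alphabetical order is part of the
method's definition (it fixes the matrix layout), so counts obtained from
`Biostrings` — which uses alphabetical ACGT order — are permuted into it.

**Counting.** A sequence of length m has m − k + 1 overlapping windows at
stride 1. Windows containing any non-ACGT character are skipped entirely:
ambiguous bases are retained in the record but never imputed into counts,
and denominators use the number of *valid* windows. A sequence shorter
than k yields an all-zero, flagged vector rather than an error, so corpus
runs never abort mid-stream.

**Normalization.** Frequencies are normalized per k: each k-block of a
vector sums to 1 on a clean sequence. Combined-k vectors (e.g. k = 1, 2,
3, giving 4 + 16 + 64 = 84 features) are deliberately **not** renormalized
to a global sum of 1 — a 1+2+3 vector sums to 3. Users comparing vectors
across k choices should keep this in mind.

**Matrix layout.** A vector of n features becomes an A × B grid
(A·B ≥ n), filled row-major in vocabulary order with exact zeros in any
trailing cells. Shapes come from a registry of the layouts this method
was developed with (64 → 8×8, 84 → 7×12, 115 → 5×23, 260 → 10×26, ...);
the registry is authoritative even where it is not the most-square
factorization. Unregistered sizes use the most-square factor pair with
rows ≤ cols, and a prime size greater than 3 is padded by one zero cell
so the grid never degenerates to a single row. One registry tension is
worth noting: published tables associate the 84-feature combination with
a 17 × 20 grid in one place and 7 × 12 in another; 17 × 20 cannot hold a
row-major 84-vector without 256 padding cells, so the registry follows
7 × 12.

## Relative-entropy screening

For large k most cells of the 4^k vocabulary are zero in any one
sequence, and the per-cell signal fragments. The screening stage ranks
k-mers by how much each contributes to the Kullback–Leibler divergence
between the two class-level distributions:

* Each class distribution pools raw window counts over **all** sequences
  of the class and normalizes once (corpus-level pooling, not the mean of
  per-sequence frequencies — long sequences weigh more).
* D(p, q) = Σ_i p(i) ln(p(i)/q(i)), with p the lncRNA distribution as the
  fixed reference and the 0·ln 0 = 0 convention.
* The per-k-mer terms d_i = p(i) ln(p(i)/q(i)) sum to D exactly. Sorted
  in descending order (ties broken by canonical vocabulary position, for
  determinism), the cumulative ratio R(r) = Σ_{top r} d / D is swept and
  the shortest prefix with R ≥ 98 % (configurable) is kept.

Two numerical choices matter here:

* **Pseudocount smoothing.** D is undefined where q(i) = 0 and p(i) > 0,
  which is common for k ≥ 5. A pseudocount (default 1) is added to every
  cell at the pooled-count level before normalizing. It is configurable;
  0 disables smoothing for dense, small-k distributions.
* **Negative terms and the first crossing.** d_i is negative wherever
  q(i) > p(i). Negative terms participate in the running sum, so R can
  overshoot 1 before settling back to 1 at the last rank; the screening
  takes the **first** crossing of the target. With identical classes
  (D = 0) screening is undefined; every k-mer is kept and a warning is
  raised.

Screened vocabularies keep canonical order, and a retained k-mer keeps
the frequency it had before screening (counting still runs over the full
4^k vocabulary; the screened entries are then extracted, without
renormalization).

## The network

The classifier is intentionally small:

| stage | spec | default |
|---|---|---|
| conv 1 | 3×3 kernels, zero same-padding, ReLU | 32 filters |
| conv 2 | 3×3 kernels, valid padding, ReLU | 64 filters |
| pool | max, 2×2 window, stride 2, ceiling tiling | — |
| dropout | before dense | 0.25 |
| dense | ReLU | 128 units |
| dropout | after dense | 0.5 |
| output | softmax | 2 classes |

Training minimizes cross-entropy with Adadelta (learning rate 1.0,
ρ = 0.95, ε = 1e−6 — the optimizer's standard settings; batch size 128,
epochs 200 by default, far fewer in the test suite). All randomness —
initialization (Glorot uniform), shuffling, dropout — flows from a single
config seed, so runs are bitwise reproducible on one platform; across
platforms only statistical reproducibility is promised.

Design points that were genuinely open:

* **Second-layer padding.** With same-padding everywhere an 8×8 input
  would stay 8×8 through both convolutions; with a valid second layer it
  passes 8×8 → 8×8 → 6×6 → 3×3. The architecture's own pooled-shape
  arithmetic (64 maps of 6×6 halving to 3×3) is only consistent with the
  valid second layer, so that is the default; `conv2_padding = "same"`
  selects the alternative.
* **Pooling odd dimensions.** The 2×2/2 pooling uses ceiling tiling
  (edge windows may be partial), so 7×12 pools to 4×6 and an 8×8 grid to
  4×4. The reference `max_pool` is shape-agnostic and follows the same
  rule.
* **Convolution = cross-correlation.** Kernels are slid without
  flipping, the convention of every deep-learning framework; the
  package's worked arithmetic example only reproduces under this
  convention.
* **Activation.** ReLU is the default throughout the network; the
  reference `conv2d` also offers sigmoid and identity (the worked
  example's printed numbers carry no nonlinearity, so its test uses
  identity).
* **Label convention.** lncRNA = 0, mRNA = 1, and lncRNA is the positive
  class of every metric. Prediction reports the hard label (`pre_label`)
  with the softmax probabilities.

The network engine is written in the package (batched im2col gathers
turning convolution into BLAS matrix products, a sparse scatter for the
backward pass) and is verified two ways: finite-difference gradient
checks on every parameter block, and a layer-equivalence test that runs
an extracted first-layer kernel through the loop-based reference
`conv2d`.

## Reference tensor operations and the worked example

`conv2d`, `zero_pad`, `max_pool`, `relu` and `softmax` are
framework-independent, exactly testable single-grid implementations. The
package ships one fully worked chain on a real 8×8 3-mer frequency
matrix:

```{r}
we <- worked_example()
round(we$feature_map, 4)[1:2, 1:3]
round(we$pooled, 4)
```

Floating-point comparisons against the printed chain use an absolute
tolerance of 5e−5 (the values are printed to 4 decimals).

## Baselines and evaluation

Random forest (`randomForest`), logistic regression (`glmnet` ridge,
α = 0, λ = 1/n — i.e. the common C = 1 L2-regularized formulation; an
unpenalized fit separates perfectly on clean synthetic data), decision
tree (`rpart`) and RBF SVM (`e1071`) consume the identical flattened
frequency vectors, with library-default hyperparameters and fixed seeds.
`compare_models` ranks reports by accuracy with alphabetical tie-breaks.

Evaluation uses the confusion matrix with lncRNA positive: precision
TP/(TP+FP), recall TP/(TP+FN), F1 = 2TP/(2TP+FP+FN) (equal to the
harmonic mean of P and R wherever both are defined — property-tested),
accuracy, and ROC/AUC from a descending threshold sweep with trapezoidal
integration. Tied scores collapse to one ROC point, making the area
identical to the concordant-pair estimator with ties counted one half;
zero-denominator metrics report `NA` rather than a crash.

## The synthetic corpus generator

Real transcript corpora are large downloads; the generator provides a
two-class stand-in with controlled contrast so every stage runs and can
be tested hermetically.

Each class is a first-order Markov chain over A/C/G/T. The default
profiles anchor the per-class base composition to observed mean contents
of real transcript sets (lncRNA ≈ 27/26/23/23 % A/T/C/G, mRNA ≈
24/22/27/27 %) and multiply the C→G transition by 0.25 (renormalizing row
C) to mimic vertebrate CpG depletion. A `divergence` knob convexly mixes
the mRNA-like transition table toward the lncRNA-like one: 1 gives the
full contrast, 0 makes the classes statistically identical (the no-signal
control). Lengths are uniform on per-class ranges, defaulting to
250–3500 nt (lncRNA-like) and 200–4000 nt (mRNA-like), matching the
length-filtering convention of `filter_by_length` (both bounds
inclusive).

First-order chains are a deliberate choice: they create the 1-, 2- and
3-mer contrasts the method exploits while keeping every expected window
probability computable in closed form
(`kmer_window_probability`), which gives the test suite exact
Monte-Carlo oracles. What the generator does **not** emulate: open
reading frames, codon periodicity, splice structure, empirical length
distributions, or k ≥ 4 structure beyond what first-order dependence
implies. Passing tests on synthetic corpora therefore demonstrate that
the pipeline recovers a planted compositional contrast — not that it
reaches any particular accuracy on real transcriptomes.

## Problem sizes and determinism in the test suite

The suite favors small, fixed-seed problems: unit tests train on
50–60 sequences per class of 200–900 nt for up to 30 epochs; the
end-to-end check uses 400 training and 100 test sequences per class
(84 features on the 7×12 grid, 20 epochs, one fixed seed) and requires
held-out accuracy ≥ 0.9 for both the network and the random forest, with
the divergence-0 control required to sit in [0.4, 0.6]. Stochastic
assertions use 3-standard-error bands around closed-form chain
probabilities.

## Known limitations

* Accuracies reported on public human/mouse/chicken corpora depend on
  those external downloads and are out of scope here; the synthetic
  end-to-end recovery is the substitute evidence.
* The CNN trains on CPU via BLAS; it is comfortable at thousands of
  sequences and 84–1104 features, but it is not a GPU-scale engine.
* Screening fixes the lncRNA distribution as the KL reference
  (asymmetric by construction); symmetric criteria are not implemented.
* Reverse-complement canonicalization, gapped k-mers and protein
  alphabets are out of scope.
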