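---
title: "chromdense: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromdense: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The prediction problem

Chromatin accessibility is cell type-specific, but DNA sequence is not. A
model that predicts accessibility from sequence alone therefore cannot
generalize to unseen cell types. chromdense predicts the accessibility of
fixed 200 bp genome tiles ("loci") in a given cell type by combining two
inputs:

* the locus **sequence**, extended to a 1000 bp window centered on the locus
  midpoint and one-hot encoded, read by a densely connected convolutional
  network (DenseNet), and
* a **TF feature**: for each transcription factor in a fixed panel, the
  maximum log2-odds motif-binding score over the window, multiplied
  element-wise by the TF's normalized expression in the target cell type.

The element-wise product encodes the biological assumption that a TF
contributes to opening chromatin only where its motif is present *and* the
TF is expressed. The fused vector is concatenated with the sequence features
and passed through a fully connected head: a sigmoid output with binary
cross-entropy for classification of accessible status, or a linear output
with mean squared error for regression of the continuous DNase-seq signal.

## Data model

The genome is tiled into non-overlapping 200 bp loci (trailing partial tiles
dropped — the network needs fixed-width inputs). A locus is labelled
accessible in a cell type when it overlaps, by at least one base, peak calls
in at least half of that cell type's DNase-seq replicates (`ceiling(R/2)` of
`R`). For regression, replicate read counts are pooled per cell type, scaled
to the minimum pooled depth across cell types (`N * n_lk / N_k` with
`N = min_k N_k`), and log-transformed with a pseudocount of one (base 2 by
default; the base is configurable).

TF expression enters as `log2(TPM + 1)`, quantile-normalized across samples
(reference distribution = mean of the sorted columns; ties receive the mean
of their rank positions) and averaged over replicates within a cell type.

Evaluation follows a cell type-level five-fold cross-validation: cell types,
not loci, are held out, so test cell types are entirely unseen. "Putative
known" loci are accessible in at least two training cell types; "putative
novel" loci are accessible in at least two testing cell types and absent
from the training data (by default: not in the known set and accessible in
zero training cell types).

## Architecture

The sequence branch is:

1. a first transition module — 160 kernels of size 4×15 (all four bases by
   15 bp) followed by ReLU, batch normalization, dropout, and max-pooling;
2. three dense blocks of five convolutional layers each. A layer is a 1×1
   bottleneck convolution (to `bottleneck_factor × growth_rate` channels)
   followed by a 3×1 convolution emitting `growth_rate` new channels; within
   a block each layer receives the channel-wise concatenation of the block
   input and all previous layer outputs;
3. transition modules between blocks: a 1×1 convolution halving the
   channels, then max-pooling.

ReLU follows every convolution, with batch normalization and dropout after
each ReLU. An ablation switch replaces the dense connectivity with residual
(ResNet-style) blocks of the same layer count, or removes the expression
(fused vector := motif scores) or motif (fused vector := expression) input.

Several architectural details are not pinned down by the published
description; they are free parameters here, with these defaults:

| parameter | default | role |
|---|---|---|
| `growth_rate` | 16 | channels added per dense-block layer |
| `bottleneck_factor` | 4 | 1×1 bottleneck width = 4 × growth |
| `pool_widths` | 4, 4, 4 | max-pooling of the three transitions |
| `dropout_rate` | 0.2 | after every ReLU |
| `hidden_units` | 256 | fully connected hidden layer |
| `head` | `"flatten"` | how positions enter the head (see below) |
| optimizer | Adam, lr 1e-3 | minibatch training, batch 64–128 |

Two choices deserve a note:

* **Flatten head.** After the last dense block the channel × position map
  can be global-average-pooled or flattened. Averaging discards position,
  but the label belongs to the *central* 200 bp of the 1000 bp window, so a
  position-blind head cannot distinguish a motif in the locus from one in
  the flanks. The default is therefore `head = "flatten"`; `"gap"` is kept
  as an option.
* **Fused-input conditioning.** Raw fused values (motif score ×
  expression) span tens of units and saturate the head at initialization.
  Each fused dimension is centered by its training mean, and all dimensions
  are divided by one pooled standard deviation, stored in the model and
  re-applied at prediction time. The single shared scale matters: per-TF
  scaling would divide each TF's input gradient by that TF's variability,
  systematically deflating the gradient importance of exactly the TFs the
  model relies on most. Gradients are chained back through this affine map,
  so GIS refers to the raw expression inputs.

The network is implemented directly in R with RcppArmadillo kernels
(im2col convolutions, a fused ReLU→batch-norm→dropout unit, pooling); the
backward pass is hand-written and verified against central finite
differences in the test suite (relative error below 1e-4). Training is
bit-reproducible given a seed: shuffling and initialization use R's RNG, and
dropout masks come from a splitmix64 stream seeded from R's RNG once per
layer call.

## Motif scanning

The per-TF motif feature is the maximum, over all offsets and both strands,
of the log2-odds score of the PWM against a uniform background
(`log2((p + c) / (0.25 + c))`, pseudocount `c = 1e-3` on both sides so a
flat column scores exactly zero). N bases contribute zero (neutral) rather
than a sentinel; windows consisting only of N are skipped, and a motif with
no scoreable window receives a finite floor (−10) so downstream layers never
see infinities. The scanner is deliberately self-contained — no external
motif-scanning tool is invoked — so its score scale is an affine relative of
other scanners' scales, which is irrelevant to the model because scores are
standardized at the fused input.

## Evaluation statistics

* **auPR** sweeps the threshold over every distinct predicted score with
  strict inequality (`score > t`), plus a final point below the minimum so
  the curve reaches recall 1; the area is the rectangle-rule sum of
  precision over recall increments. No interpolation is applied, and the
  implementation is tested for exact equality against an exhaustive
  threshold-sweep oracle. Cell types with zero positives are reported as
  missing and excluded from means.
* **PCC** is computed cell type-wise (across loci within a cell type) and
  locus-wise (across cell types for one locus); constant vectors yield NA.
* **PSE** = Σ(y − ŷ)² / Σ(y − ȳ\_k)², with ȳ\_k the per-cell-type mean
  over loci: 0 for a perfect prediction, 1 for the mean predictor.
* **Cell range / cell variability** are max − min and the population
  standard deviation (divide by K) of a locus's true signal across cell
  types; loci are grouped at the 1/3 and 2/3 quantiles with ties going to
  the lower group.

## Interpretation

* **Gradient importance score (GIS):** the average absolute gradient of the
  predicted accessibility with respect to a TF's expression, over the
  accessible loci within a window (200 kb by default) around an anchor
  locus. The gradient flows through the fused product, so a TF whose motif
  score is zero everywhere gets exactly zero. TFs are ranked by GIS with
  lexicographic tie-breaks.
* **Kernel → PWM:** a first-layer kernel is scanned over a sequence set;
  every 15-mer whose activation exceeds `alpha` (default 0.7) times the
  kernel's maximal activation value is collected, and the PWM is the
  position-wise base frequency of the collection. 15-mers containing N are
  skipped; `alpha ≥ 1` is rejected. Information content uses
  `Σ p log2 p − Σ b log2 b` with `0 log 0 = 0`, which equals the standard
  KL form for the uniform background.
* **Kernel influence:** the decrease in mean cell type-wise PCC when a
  kernel's weights are zeroed; the model is restored bit-identically.
* **PWM matching:** best alignment over offsets (≥ 4 overlapping columns)
  and reverse complement, scored by the mean per-column Pearson correlation
  of probability vectors. This is an internal similarity utility, not a
  statistical motif-match test: it returns a similarity in [−1, 1], no
  E-value.

## Variant scoring

VCF records are filtered to biallelic SNVs with minor-allele *count*
strictly above 5 (the published threshold is ambiguous between count and
percent; count is the default reading, and the threshold is configurable).
For a variant carrier, the 200 bp locus containing the variant is extended
to 1000 bp for the reference and the personal sequence, motif features are
recomputed for both, and the deleterious score is
`|log2((ŷ_personal + ε)/(ŷ_ref + ε))|` with ε = 0.01; regression outputs are
floored at zero first, since predicted signals are non-negative by
construction but a linear output head is not. Heterozygous and homozygous
genotypes are applied identically (single-sequence personal genome);
carriers of a variant therefore share one score. Cohort scores average over
carriers only. Variants in a 200 kb risk region are ranked by cohort score
with positional tie-breaks. The phenotype model is an l1-penalized linear
regression of the phenotype on per-individual scores (non-carriers
contribute 0), with penalty coefficient 0.5 and ten-fold cross-validated R².

## The synthetic-data generator

Real chromatin data cannot ship with a package; the generator produces a
fully self-contained dataset whose ground truth is known, in exactly the
formats the pipeline reads (FASTA, chrom sizes, per-replicate BED peaks and
count tables, TPM + replicate map, TF panel, MEME motifs, VCF, phenotype
table). The generative rule mirrors the model's core assumption:

> locus *l* is accessible in cell type *k* iff
> Σ\_o affinity\_o × activity(tf\_o, k) > θ,

summing over the motif occurrences *o* planted in the locus, plus a 2%
sequence-independent background accessibility (assay noise). Defaults (2
chromosomes × 200 kb, 8 cell types, 3 DNase replicates, 30-TF panel with 3
causal TFs, 20 individuals, 250 variants) were fixed once, with these
considerations:

* planted motifs are sharp 8-mers (consensus probability 0.95) so that
  sequence carries a clear signal; instances are sampled from the PWM;
* 15% of loci are planted, with at least three tiles of separation, so one
  locus's 1000 bp window never contains another locus's motifs;
* per-occurrence affinities ~ U(0.5, 1) model unobserved binding context
  and decorrelate loci that share a TF;
* TF activities ~ U(0, 1) per (causal TF, cell type); with threshold
  θ = 0.6 the per-cell-type positive fraction among putative known loci
  lands in the published 3–30% imbalance range;
* causal TF expression is monotone in activity (TPM = 10 + 150 × activity,
  with lognormal replicate noise); non-causal TF expression is pure noise,
  so expression-ablation comparisons have a known answer;
* replicate peaks drop accessible loci at 15% per replicate but never below
  half of the replicates, and spurious peaks appear in fewer than half, so
  the emitted labels round-trip *exactly* through the labelling rule;
* peak boundary jitter is inward-only, because outward jitter would
  legitimately spill into neighbouring tiles and flip their labels;
* counts are Poisson with per-replicate depths varying threefold, so depth
  normalization is exercised;
* a fraction of variants is planted at the highest-information position of
  a motif occurrence (alternate allele = the worst base), the rest in
  motif-free regions; indels, multiallelic records and rare variants are
  included so the filter has work to do; the phenotype is linear in carrier
  status of ten ablating variants plus Gaussian noise.

What the generator does **not** emulate: realistic base composition (GC
content, repeats), peak shapes, linkage disequilibrium among variants,
diploid haplotypes, and TF cooperativity. Passing tests on these data
demonstrate that the implementation recovers structure *of the kind the
model assumes*; they say nothing about performance on real chromatin data.

## Problem sizes used by tests and the acceptance script

Unit tests run on tiny configurations (40–60 bp windows, a handful of
kernels) where finite-difference checks and exhaustive oracles are exact.
The integration checks train reduced networks — 32 first-layer kernels,
growth 8, pooling (8, 4, 2), hidden width 64 — on a 20,000-locus synthetic
genome: the classification model for 20 epochs on a balanced subsample of at
most 6,000 (locus, cell type) pairs, and regression models for 8 epochs on
at most 4,000 pairs, with two of the eight cell types held out. The
acceptance script runs the same conditions end to end.
These sizes are the package's chosen desk-scale study conditions; the
generative rule and all thresholds are identical at any scale.

## Known limitations

* Training minimizes unweighted per-example loss; class weighting for the
  published 3–30% imbalance is exposed (`pos_weight`) but off by default.
* The scanner's score scale differs from external tools by an affine factor;
  absolute score values are not comparable across tools.
* The 1×1-bottleneck channel count, transition channel halving and head
  width are conventions, not published values.
* Batch normalization uses batch statistics during training; very small
  batches (< 8) make training noisy.
* `phenotype_lasso` fixes the l1 coefficient (no internal tuning), matching
  the published procedure rather than best practice.
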