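---
title: "Modeling the sequence context of RNA pseudouridylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the sequence context of RNA pseudouridylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pseudouridine (Ψ) is the most abundant post-transcriptional RNA
modification. High-throughput profiling (CMC-based protocols coupled to
sequencing) maps Ψ sites at single-base resolution, but the assays are
costly and incomplete, so computational prediction from sequence context is
the practical route to a transcriptome-wide picture. Pseudouridine synthases
recognize local sequence: the PUS4 context GUΨCNA and the PUS7 context UGΨAG
are the canonical examples. `psiCNN` models this recognition directly: a
small convolutional network reads the 101-nt window centered on a candidate
uridine (rendered as `T` in DNA-alphabet references) and emits a score in
[0, 1] — the local pseudouridylation potential score (lPPS) — interpretable
as the probability that the centered uridine is pseudouridylated.

## Sample construction

Positive samples are 101-nt windows (50 nt of flank on each side) centered
on profiled Ψ sites; sites whose strand-resolved reference base is not a
thymine are discarded at load time. Negative samples are windows centered on
the thymine nearest to each positive site whose own window shares no base
position with *any* positive window; imbalanced sets (PNR 1:n) take the
nearest *n* such thymines. Windows are encoded one-hot (channels A, C, G, T;
`N` is the zero row).

Several details are underdetermined by that recipe, and the package fixes
them as follows:

* **Coordinates** are 0-based half-open internally; BED input is interpreted
  as standard 0-based half-open, VCF positions are converted from 1-based at
  the reader boundary.
* **Strand**: minus-strand sites are reverse-complemented before windowing,
  so every sample reads 5'→3' with the candidate uridine at index 50. The
  modified base is a U in the transcript, so this is the biologically
  meaningful orientation.
* **Edge windows** are padded with `N` rather than dropped — the same rule
  the transcriptome scanner uses — so one convention holds everywhere.
* **Ties** between equidistant upstream/downstream negative candidates
  resolve to the larger coordinate. Arbitrary, but fixed and documented.
* Negative windows may overlap *each other*; only overlap with positive
  windows is forbidden. Duplicate negatives arising from different positives
  are removed.

## The network

The classifier is two alternately-stacked convolution and pooling layers
followed by a two-hidden-layer fully-connected network:

* conv1: 64 filters spanning 8 positions × 4 channels, no padding
  (feature-map length 101 − 8 + 1 = 94);
* batch normalization, PReLU, max-pool width 2 (→ 47);
* conv2: 32 filters spanning 8 positions × 64 channels (→ 40);
* batch normalization, PReLU, max-pool width 2 (→ 20);
* flatten (20 × 32 = 640) → dense 64 → dense 64 → dense 1, logistic output,
  with PReLU activations and dropout on the hidden dense layers.

The output stage is a single logistic unit rather than a two-unit softmax;
with one reference logit fixed the two are mathematically identical, and a
single unit matches the 64-64-1 layer widths and the 0.5 decision threshold
used by the transcript score below. PReLU slopes are learned per channel,
initialized at 0.25, and reused for the dense layers for uniformity.

Training minimizes binary cross-entropy by minibatch SGD with momentum,
dropout, batch normalization, and early stopping on a validation split.
Optimizer defaults (learning rate 0.01, momentum 0.9, batch size 64, dropout
0.25, patience 10) are tunable and exposed to the grid search; the default
grid explores learning rate {0.1, 0.01, 0.001} and dropout {0.25, 0.5}.
Since no deep-learning framework ships with this package's dependency set,
the forward and backward passes are implemented in base R matrix algebra:
convolutions are im2col gathers followed by a single BLAS multiplication,
and the backward pass is verified against central finite differences in the
test suite (worst relative error ~1e-5). Batch-norm inference uses running
statistics (exponential average, momentum 0.9, epsilon 1e-5), which makes
prediction independent of batch composition.

Model selection follows a nested cross-validation: the outer k folds
estimate generalization; within each outer training portion an inner k-fold
grid search picks the hyperparameter combination with the best mean inner
AUC, after which the outer-training data are merged and refit (with a 10%
stratified split carved out to drive early stopping) and scored on the
untouched outer fold. Out-of-fold predictions are pooled — metrics are
computed once on the pooled vector, never averaged per fold, because
per-fold averaging can overstate a model whose folds sit on different score
scales.

## Filter motifs

First-layer filters act as position-specific pattern detectors, and their
learned weights can be read back as sequence motifs: each filter is slid
over the positive windows, every 8-mer whose raw activation (convolution +
filter bias, before batch normalization, PReLU, and pooling, in inference
mode) strictly exceeds half the filter's global maximum is collected, and
the collected 8-mers are stacked into a position weight matrix. Motifs
covering more than 1% of the positive samples are retained. Choices the
procedure fixes:

* the "activation" is pre-nonlinearity, following the established
  filter-visualization lineage for sequence CNNs;
* the half-max reference is the *global* maximum over all positive samples
  and offsets (not per-sequence);
* the threshold is strict, so an all-zero (or never-positive) filter yields
  no segments rather than all of them;
* `N` characters contribute to no PWM channel, and each column renormalizes
  over observed bases; PWMs are raw frequencies with an optional pseudocount
  (default 0) for logo rendering.

Motifs export to MEME minimal format; clustering and database matching are
out of scope. One empirical caveat the tests document: individual filters
often capture a planted consensus piecewise (e.g. `TTCNNNAN` rather than
`NGTTCNAN`), so recovery is quantified by the best mean per-column Pearson
correlation between a retained PWM and the planted consensus after ungapped
alignment, not by literal substring matching.

## Transcriptome scores

* **lPPS** — every thymine of a transcript is scored on its 101-nt window,
  `N`-padded at the transcript ends.
* **tPPS** — for a transcript of length *L* with *K* thymines, of which
  `num_psi` score above 0.5 and `num_u` do not,
  `tPPS = (num_psi / num_u) / (K / L)`. The numerator is the predicted
  Ψ-to-uridine odds; the denominator removes the bias toward uridine-rich
  transcripts. `tPPS` is undefined (flagged, not NaN) when the transcript
  has no thymines or every thymine is called.
* **AFCP** — for an SNV with major allele matching the reference, the target
  uridine is the thymine nearest the variant (ties downstream) present in
  *both* allele sequences within 50 nt; both 101-nt windows centered on it
  are scored and `AFCP = log2((lPPS_major + ε) / (lPPS_minor + ε))` with
  ε = 1e-6 guarding against underflow. The implementation computes the
  difference of logs so that swapping the alleles negates the value
  bit-exactly. A positive AFCP means the minor allele lowers the
  pseudouridylation potential. One uridine is scored per variant (the
  nearest), not an aggregate over every window containing it.

The Ψ-call threshold is 0.5 everywhere — the same indicator the tPPS formula
uses — and is exposed as an argument for exploration.

## The synthetic benchmark

Real training data come from modification profiling databases and require
downloads, so the package carries a seeded generator that emulates the
essential structure of those data: 101-nt windows centered on a thymine,
with a planted recognition context. Defaults are the study conditions used
throughout the tests: the PUS4 and PUS7 contexts rendered in DNA
(`GT[T]CNA`, `TG[T]AG`, Ψ at index 2), uniform background (GC 0.5),
embedding probability 1, and 1000 positives / 1000 negatives. Negatives are
rejection-sampled against every configured consensus (with `N` expanded), so
labels are noise-free unless the embedding probability is lowered. With a
nonzero positional jitter, the offset is drawn uniformly from the offsets
compatible with the mandatory center thymine (a consensus `N` landing on the
center is instantiated as `T`); incompatible offsets are excluded rather
than corrupting either the center base or the planted motif. The generator
also emits synthetic transcriptomes with a truth table of planted sites
(kept one full window apart) and variant tables split between
motif-destroying and background positions, which exercise the scanner, the
tPPS pipeline, and AFCP end to end.

What the generator does *not* emulate: genomic base composition and repeat
structure, multiple overlapping motif grammars, profiling false negatives,
or strand ambiguity. Passing the synthetic benchmarks therefore demonstrates
that the implementation learns and recovers a planted signal under
controlled conditions — it does not certify accuracy on real profiling
data, which must be obtained from the public RNA-modification databases.

## Problem sizes and numerical choices

The test suite and the acceptance script run the study at desk scale, chosen
so the whole suite completes in minutes on one CPU while leaving the
conclusions unchanged:

* the headline benchmark is 5-fold cross-validation on the default
  2000-sample planted-motif dataset with `max_epochs = 10`,
  `early_stop_patience = 3` (the planted signal saturates within a few
  epochs; pooled AUC ≈ 0.98 against the 0.90 requirement);
* the permutation-null check trains on 1000 label-shuffled samples for 5
  epochs and scores 1000 held-out samples;
* module tests use reduced networks (8–16 filters) whose behavior is
  equivalent but train in seconds;
* the nested-CV selection property is exercised at 2 outer × 2 inner folds
  with a two-point learning-rate grid (a working rate vs. one too small to
  move the weights).

Numerical notes: initialization is He-scaled and fully seeded; training,
fold assignment, and generation restore the caller's RNG state; pooling ties
resolve to the earlier cell; zero-denominator evaluation metrics return 0
with an explicit degenerate flag; model files store IEEE-754 doubles
base64-encoded inside versioned JSON, so save/load round-trips predictions
bit-for-bit. Comparisons across *different batch shapes* (chunked vs.
one-shot prediction) agree to ~1e-15 relative rather than bit-exactly,
because BLAS may reorder summations; affected tests assert a 1e-12
tolerance.

## Limitations

* The two published models (human and mouse) differ in their number of
  training epochs, which was never printed; the epoch budget here is
  explicit configuration.
* The exact hyperparameter grid searched in the original workflow is
  unknown; the default grid is a documented stand-in and fully overridable.
* Transcript scanning processes the supplied strand only; callers provide
  transcript-orientation sequences.
* Training-set windows at sequence edges are padded, matching the scanner;
  whether the original workflow padded or dropped them is unknown.
* Whether negatives were constrained to the same chromosome/transcript as
  their positive is unknown; the same-sequence constraint is enforced here.
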