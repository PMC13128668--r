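---
title: "Classifying bacterial protein half-life from sequence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying bacterial protein half-life from sequence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Intracellular enzyme abundance is shaped not only by transcription and
translation but by protein turnover: a short-lived enzyme (half-life under
one hour) can bottleneck an entire synthetic metabolic pathway. Measured
bacterial half-life data are scarce, so `prohl` frames turnover as a binary
sequence-classification problem: given an amino-acid sequence of 50-1655
standard residues, predict *short-lived* (half-life < 1 h, strict
inequality; exactly 60 minutes is long-lived) versus *long-lived*. The
positive class throughout the package is long-lived, which in the kind of
proteome-wide training data this mirrors outnumbers the short-lived class
by roughly 12:1 (about 1,035 vs 83 after filtering), so the
imbalance-robust Matthews correlation coefficient (MCC) drives all model
selection.

## Data preparation

Training sequences are validated against the 20-letter alphabet (ambiguity
letters B/J/O/U/X/Z are rejected in strict mode, or masked to `X` on
request, in which case any descriptor term touching an `X` is simply
excluded from both numerator and denominator). Peptides shorter than 50
residues are removed. Redundancy is reduced by greedy incremental
clustering at 0.5 identity: sequences are visited longest-first (ties by
id), each joins the first cluster whose representative is at least 50%
identical, and representatives are retained. Identity is defined as the
optimal global alignment score under match = 1, mismatch = 0, gap = 0 —
i.e. the longest common subsequence — divided by the shorter length. That
scoring was chosen because it is deterministic and has a trivially
verifiable quadratic-time oracle; the word-based prefilter heuristics of
production clustering tools are deliberately out of scope at the few
thousand sequences this package targets.

## The three encoding views

**Physicochemical descriptors** (3,217 features by default) come in four
ablation groups:

* *Gapped k-mer composition* (CKSAAP): for gaps 0-5, the frequency of each
  ordered residue pair separated by the gap; each 400-feature gap block
  sums to 1. The maximum gap of 5 is a common toolkit default; it is
  configurable.
* *Grouped composition* (DDE): each dipeptide frequency standardized
  against its genetic-code expectation `Tm = (Ca/61)(Cb/61)` with variance
  `Tm(1-Tm)/N`, where `Ca` is the codon multiplicity of residue `a`.
* *Physicochemical property classes* (CTD): the standard seven attributes
  (hydrophobicity, van der Waals volume, polarity, polarizability, charge,
  secondary structure, solvent accessibility), each partitioning the
  alphabet into three classes; per attribute the class fractions, the
  between-class adjacent-pair frequencies, and the positions (as % of
  length) of the first/25%/50%/75%/last residue of each class.
* *Sequence order*: Moran autocorrelation of eight classical property
  scales over lags 1-30, plus sequence-order coupling numbers
  `tau_d = sum dist(s_i, s_{i+d})^2` for lags 1-30.

The bundled property tables are classical published scales written out in
`R/aa_tables.R`: Kyte-Doolittle hydropathy, Hopp-Woods hydrophilicity,
Eisenberg consensus hydrophobicity, average side-chain mass, Grantham
polarity and volume, isoelectric point, and net charge at pH 7. The SOCN
residue-distance matrix is computed from the package's own scales — the
Euclidean distance over standardized hydropathy, hydrophilicity, and
side-chain mass — rather than transcribed from a third-party matrix; it is
symmetric with zero diagonal, which is all the descriptor's definition
requires, and it is exposed as configuration so any 20x20 distance matrix
can be substituted. Degenerate denominators (zero-variance Moran profiles,
residue classes absent from a sequence) are defined as 0, never NaN,
because the downstream ANOVA requires finite values. Lags of 30 are always
valid because inputs are at least 50 residues.

**Residue-level embeddings** form a `d_local x L_padded` matrix per
sequence, zero-padded on the right to a fixed width (default 1655, the
longest accepted sequence) so the convolutional input shape is static;
padded columns are not masked, a deliberate simplification. **Sequence-level
embeddings** are a single `d_global` vector. Both sit behind a pluggable
embedder contract with two implementations: an adapter that reads
plain-text matrices exported from an external protein language-model run
(nothing is downloaded; a missing export is a loud error), and a synthetic
embedder for self-contained testing.

The synthetic embedder deserves emphasis because it defines what the test
suite can and cannot show. Its output is a deterministic function of a
seed and a hash of the sequence content (content-addressed: identical
sequences get identical embeddings regardless of record id). Because each
sequence's embedding is arbitrary noise with respect to any other
sequence, it carries **no generalisable sequence structure**: a model
cannot learn from it except through the optional planted signal, a stated
shift of the first sequence-vector coordinate for motif-bearing sequences.
Passing end-to-end tests therefore demonstrate that the pipeline recovers
signal placed in descriptors and in embedding coordinates, and that the
plumbing is leak-free and reproducible — not that any particular language
model is informative for real proteins.

## Feature processing

All feature processing is fit-and-apply with frozen state: per-column
z-scores (sample standard deviation, n-1; zero-variance columns are
force-dropped), a per-feature two-class ANOVA F-test keeping features with
p <= 0.01 (F with (1, n-2) degrees of freedom; equal to the squared pooled
t statistic, which the tests exploit as an oracle; no multiple-testing
correction by design), and PCA of the sequence-level embeddings retaining
the smallest number of components reaching 95% cumulative variance. PCA
centres but does not rescale, since embedding coordinates share a scale;
the physicochemical block is z-scored. Inside cross-validation all of this
state is refit on each fold's training rows only — the package treats
per-fold refitting as non-negotiable leakage control, and a checksum test
verifies that validation rows cannot influence fitted state.

## The classifier

The residue-level matrix passes through two blocks of (valid `KxK`
convolution with `F` filters, ReLU, 2x2 average pooling with stride 2,
dropout), is flattened, and concatenated with the processed feature block;
then `n_layers` fully connected ReLU layers of `n_units` (the string
`"input_dim"` resolves to the concatenated width) with dropout feed a
single sigmoid output. Choices the architecture description leaves open
are fixed as: ReLU after every convolution and dense layer, dropout after
every pooling block and dense layer at the single configured rate, pooling
window 2x2 (trailing odd rows/columns dropped), and a single-channel
input image. Training minimises binary cross-entropy with Adam
(beta1 0.9, beta2 0.999, eps 1e-8), stopping when validation loss fails to
improve for `patience = 5` epochs and restoring the best-validation
weights. There is no class reweighting by default. A probability of
exactly 0.5 is classed long-lived. All randomness (initialisation — He
normal for hidden layers, smaller Glorot-style for the output — batch
shuffling, dropout) flows through R's RNG, so one seed makes training bit
reproducible; the forward/backward pass is implemented in C++ (im2col +
GEMM convolutions) because no neural-network framework is part of the
package's dependency footprint and the model is the package's core.

## Model selection and ablation

The hyperparameter grid crosses kernel size {7, 9}, filters {8, 16},
layers {1, 2, 3}, units {512, 1024, input_dim}, dropout {0.1, 0.2},
learning rate {1e-3, 1e-5}, max epochs {10, 20, 30}, and batch size
{32, 64, 128} — 1,296 configurations, enumerated lexicographically with
earlier axes varying slowest. Cross-validation is stratified (with ~83
minority samples, unstratified 10-fold splits risk near-empty validation
classes; stratification is an explicit assumption), uses identical folds
for every configuration, and selects the highest mean MCC with ties broken
by enumeration order. The fold's validation part both drives early
stopping and is scored; a separate tuning split inside each fold would
cost a third of the minority class at this scale. The published
configuration (kernel 7x7, 8 filters, 2 layers, units = input_dim, dropout
0.2, lr 1e-3, batch 32) is the package default. The full search is gated
behind an explicit confirmation in the CLI; a reduced 8-configuration grid
exercises identical code paths at desk scale.

Ablation removes one descriptor group at a time (and all four together)
*before* feature processing, refits everything downstream per fold under
identical folds and seed, and never re-searches hyperparameters;
`"input_dim"` re-resolves to each condition's width. Embeddings always
remain in the model, so the all-groups condition measures what the
embedding path alone supports.

## Synthetic data and the problem sizes used

The generator emulates the structure of a proteome-wide labelled set:
defaults of 1,035 long-lived and 83 short-lived sequences, lengths
log-uniform on 50-1655 (so long sequences occur without dominating
compute), uniform background residue frequencies (configurable), and a
degron-like motif planted in a `p_motif` fraction of short-lived sequences
at a uniform position. The default motif is the ssrA degradation tag
(`AANDENYALAA`); motif strings may contain `.` wildcards filled from the
background, which concentrates the planted signal in *gapped* residue
pairs rather than adjacent dipeptides — the construction the ablation
ordering test uses (`W.W.W`). Half-lives are drawn uniformly on [1, 59]
and [61, 600] minutes so labels are consistent with generation by
construction. What the generator does **not** emulate: real amino-acid
composition, homology structure (every sequence is independent, so
identity clustering is exercised by dedicated fixtures instead), genuine
degron biology beyond a literal motif, and any coupling between sequence
and the synthetic embedding beyond the planted shift.

The stochastic end-to-end checks run at a documented desk scale chosen
once: 400 sequences (300 long / 100 short — imbalance retained but
softened from 12.5:1 so that each of 3 stratified folds holds ~33 minority
samples and fold-level MCC is a stable quantity), lengths 50-150,
synthetic embedder with `d_local` 22, `d_global` 16, padding 160, a
reduced 8-configuration grid, and 3-fold cross-validation. Under these
conditions the planted signal (`p_motif` 0.9, embedding effect 2.0) is
recovered with held-out MCC >= 0.8, the label-shuffled control sits within
|MCC| < 0.2, and excluding the gapped-k-mer group degrades MCC more than
excluding any other single group when the motif is the only signal.

## Numerical conventions and edge cases

* Metric denominators of zero yield 0 with a degeneracy flag (the standard
  MCC convention); metrics are reported at 3 decimals externally, full
  precision internally.
* Grid enumeration, fold assignment, clustering tie-breaks (longest first,
  then id), and best-configuration ties (first enumerated wins) are all
  deterministic.
* The trained artifact (weights, feature state, configs, embedder
  description) serializes to a single JSON file; an embedder is
  reconstructed from its description at load time, never serialized as
  code.

## Known limitations

Real pretrained embeddings are integrated only through the file-export
adapter; predictions on real proteomes inherit whatever biases the chosen
embedder has. The padded CNN input is unmasked, so very short sequences
carry mostly zero columns through the convolutional path. Absolute
half-life regression is out of scope by design — the one-hour threshold is
a modelling choice that trades resolution for robustness to
condition-dependent variation in absolute half-lives. Descriptor property
tables are classical scales bundled in code; swapping in other scales
changes feature values and is supported but untested territory.
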