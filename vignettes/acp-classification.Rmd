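---
title: "Classifying anticancer peptides with bidirectional LSTMs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying anticancer peptides with bidirectional LSTMs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acplearn)
```

## The problem

Anticancer peptides (ACPs) are short amino-acid sequences (here 3–50
residues over the 20 standard amino acids) that selectively damage cancer
cells, largely because their cationic and aromatic residues interact with
the anionic outer membrane of cancer cells. Classifying peptides as
ACP / non-ACP from sequence alone is a standard benchmark problem in
therapeutic peptide informatics. `acplearn` implements one family of
solutions — recurrent networks over physicochemically informed per-residue
encodings — together with the evaluation and explanation machinery needed to
use such models responsibly.

Peptide datasets are plain tibbles (`id`, `sequence`, optional binary
`label` with 1 = ACP), so every step composes with dplyr pipelines.

## Sequence encodings

A peptide of length $l$ becomes an $L_{max} \times d$ matrix with
$L_{max} = 50$: row $i$ encodes residue $p_i$, rows $l+1 \dots L_{max}$ are
filled with the pad value 0. Zero is used because after z-scoring it is the
least informative constant; the models are trained on fixed-width inputs
without masking by default (a `mask_padding` switch exists for users who
want length-exact recurrences and attention, and its gradients are tested,
but it is off by default).

Three per-residue blocks can be concatenated (always starting with the
one-hot block, which identifies the residue):

* **Binary profile (bpf, 20 values).** One-hot over the alphabetical
  residue order A, C, D, …, Y. The property tables below are *stored* in a
  different order; only the alphabetical order defines column layout.
* **Quantitative properties (quanc, +6 values).** Molecular mass,
  isoelectric point, pk1 (α-carboxyl), pk2 (α-amino), side-chain pKa and van
  der Waals volume, z-scored per column over the 20 amino acids:
  $z_{ij} = (x_{ij} - \mu_j)/\sigma_j$ with the population standard
  deviation (divisor 20, not 19). The statistics are computed once from the
  fixed 20-row table — never from training data — so encoding is
  dataset-independent; the $\mu/\sigma$ snapshot is still serialized with
  every model for provenance. Amino acids without an ionizable side chain
  carry a literal 0 in the pKa column, and that 0 enters the z-score as a
  value. The proline row of the shipped CSV is provisional: the upstream
  rendering of that row is ambiguous, and the values (pk1 1.99, pk2 10.60,
  pKa 0, volume 88) follow a column-count reading consistent with the other
  zero-pKa rows. They are isolated in one CSV row should a better source
  emerge.
* **Qualitative properties (qualc, +10 values).** Four one-hot category
  blocks — hydrophobicity {Y, N}, polarity {Y, N}, charge {negative,
  positive, none} and aromatic/aliphatic {aromatic, aliphatic, none}. Both
  levels of the binary properties are encoded (2 + 2 + 3 + 3 = 10), so each
  block sums to exactly 1 and no level is a silent reference category.

Scheme dimensions are therefore 20 (`bpf`), 26 (`quanc`), 30 (`qualc`) and
36 (`mix`). `"quanl"` is accepted as an alias for `qualc` because both
abbreviations circulate for the BPF+qualitative combination. A fifth scheme,
`embedding`, replaces the fixed features with a trainable $20 \times 36$
lookup learned jointly with the classifier; it is dimension-matched to `mix`
so the two can be compared fairly.

```{r encodings}
m <- encode_sequence("GLFDIVKKVVGTIAGL", "mix")
dim(m)
channel_names("mix")[21:26]
```

## Network architectures

Both architectures read the encoded matrix with a bidirectional LSTM of
$n$ units per direction (per-position output width $2n$) and end in
dense(ReLU) → dense(2, softmax), the output being
$(P(\text{non-ACP}), P(\text{ACP}))$.

* **basic** uses the final hidden state of each direction (a $2n$ vector).
* **selfatt** keeps all per-position outputs $x_t \in \mathbb{R}^{2n}$ and
  adds two attention stages. Additive self-attention scores every ordered
  position pair through a small hidden layer,
  $$h_{t,t'} = \tanh(x_t^\top W_t + x_{t'}^\top W_x + b_t), \qquad
    e_{t,t'} = \sigma(W_a h_{t,t'} + b_a),$$
  normalizes each row, $a_t = \mathrm{softmax}(e_t)$, and recombines the
  sequence, $l_t = \sum_{t'} a_{t,t'} x_{t'}$. Attention pooling then
  collapses positions with trainable $W \in \mathbb{R}^{2n}$,
  $b \in \mathbb{R}^{L_{max}}$: $e = hW + b$,
  $\alpha = \mathrm{softmax}(e)$, $att(h) = \sum_j \alpha_j h_j$. Pooling is
  applied to the self-attention output, i.e. the layer order is
  Bi-LSTM → self-attention → attention pooling.

Choices the architecture description leaves open, fixed here as package
defaults: $\sigma$ in the pair score is the logistic sigmoid (the usual
choice in additive self-attention implementations); the score path's hidden
width defaults to 32 (`attention_width`); the first dense layer uses ReLU;
no dropout. All parameters are initialized Glorot-uniform from the seeded
generator (forget-gate biases start at 1), so two builds with the same
config are identical.

The LSTM recurrences, both attention layers, and all of their gradients are
implemented in vectorized base R inside the package. This keeps the artifact
dependency-free and the mathematics inspectable; the cost is speed, which is
recovered by batched matrix operations through BLAS. Every analytic
gradient is checked against central finite differences in the test suite
(worst relative error below $10^{-4}$ at probe points), and the attention
layers are additionally tested against brute-force oracles.

## Training, cross-validation and model selection

Training minimizes categorical cross-entropy with Adam (default learning
rate $10^{-3}$, batch size 32 — community defaults, both exposed in
`model_config()`) for exactly `epochs` epochs, logging the mean loss per
epoch. Classification uses threshold 0.5 on $P(\text{ACP})$ with ties
counted positive. Determinism: initialization, batch shuffling and all
sampling run under seeds derived from `config$seed`, and the package never
touches the caller's RNG stream.

`cross_validate()` builds stratified folds (per class, fold sizes differ by
at most one), retrains from scratch per fold with fold-derived seeds
(`seed + fold`), and averages per-fold metrics arithmetically — AUC
included, averaged per fold rather than pooled, matching the convention of
averaging the K validation results. `grid_search()` selects the candidate
with the best mean CV MCC; MCC is preferred as the selection metric because
it is balanced and stringent. Ties break toward higher mean accuracy, then
fewer epochs (the smaller model), then grid order. A confusion matrix with
a zero denominator factor yields MCC = 0 rather than NaN so degenerate folds
cannot poison a search.

ROC AUC is computed from ranks as the Mann–Whitney concordance probability
(ties count 1/2), which makes it exactly invariant under monotone transforms
of the scores; the test suite checks it against exhaustive pair counting.

## Redundancy filtering

To measure generalization, test peptides too similar to the training set can
be removed before independent testing (`identity_filter()`, typical
thresholds 0.4/0.8/0.9). Identity between two peptides is the number of
identical aligned positions in an optimal global alignment (match 1,
mismatch 0, gap −1, via Biostrings) divided by the length of the shorter
sequence. This is a documented alignment-based stand-in for CD-HIT-2D's
greedy clustering — same denominator convention, not bit-compatible output —
and a test peptide is removed when its best identity to *any* training
peptide reaches the threshold.

## The synthetic benchmark

`make_benchmark()` generates positives from an enrichment-weighted residue
distribution (default weight 4 for K, R, H, F, W, Y; 0.25 for D, E; 1
otherwise) and negatives uniformly at random, lengths uniform on 3–50, by
default 200 + 200 peptides. The planted signal is deliberately
*compositional* (i.i.d. per residue): cationic/aromatic enrichment and
acidic depletion are the composition signature of real ACPs, and a
compositional plant is exactly what the downstream Shapley analysis should
rediscover. Defaults keep a full five-fold CV plus explanation run to a few
CPU-minutes (this is also the problem size used by the package's acceptance
checks).

What the generator does *not* emulate: motif or positional grammar
(N-/C-terminal preferences), ACP-vs-AMP subtlety (antimicrobial peptides
share the cationic signature, making that contrast far harder than
ACP-vs-random), and real length/composition correlations. Passing tests on
this benchmark therefore demonstrate that the pipeline learns and explains a
planted compositional signal — not that it reaches any particular accuracy
on curated experimental datasets.

## Explanations

`shapley_attributions()` estimates Shapley values per (position, channel)
cell of the encoded input with respect to the ACP-class probability, by
permutation sampling: features absent from a coalition are replaced by the
*mean encoded background* (by default up to 100 background peptides drawn
with a fixed internal seed). With mean replacement the per-permutation
increments telescope, so the additivity identity
$$\phi_0 + \sum_i \phi_i = f(x)$$
holds exactly for every explained sample regardless of `n_perm`; the base
value $\phi_0$ is the prediction at the background average. More
permutations only stabilize how credit splits between correlated cells. An
exhaustive enumerator (`shapley_exact()`, feasible to ~15 features) serves
as an independent oracle in the tests, which also verify the efficiency,
symmetry and null-player axioms on toy games. Channel importance is the
mean of $|\phi|$ over all samples *and* positions at each channel,
ranked descending with ties broken by channel index. Attributions are
defined only for the fixed encodings: the embedding scheme's features are
trained parameters, not per-input values, so `shapley_attributions()`
refuses it.

`pca_project()` centers penultimate-layer features (the first dense layer's
activations) and projects onto the top principal axes for 2-D visualization
of class separation; variance ratios are reported per component.

## Numerical and interface choices

* Pad value 0 for all schemes; no masking by default (see above).
* Population (÷20) standard deviation in the property z-scores.
* Literal pKa = 0 entries enter the standardization as printed.
* Decision threshold 0.5, ties positive; MCC 0 on zero denominators.
* Softmax rows are computed with max-shifting; probability pairs sum to 1
  within $10^{-6}$ and attention rows within $10^{-6}$.
* Grid-search tie-breaks: MCC, then ACC, then fewer epochs, then order.
* Serialization (`write_model()`/`read_model()`) stores config, weights,
  the standardization snapshot and channel names in one archive;
  reloaded models predict bit-identically.
* Degenerate inputs fail loudly with classed conditions (`acplearn_io_error`,
  `acplearn_validation_error`), which the CLI maps to distinct exit codes;
  non-alphabet residues are fatal rather than skipped, because silent data
  loss is worse than failure.

## Problem sizes used by the tests

The test suite trains only small models: the learning-sanity checks use the
default 200 + 200 benchmark with a 32-unit basic model for 15 epochs
(about a minute of CPU), toy separability checks use 8–20 homopolymer
peptides, and gradient checks use 3-unit networks. These sizes were chosen
as the smallest that make the scientific properties visible; they are
package defaults, and all are configurable upward.

## Known limitations

* Training is CPU-bound, single-threaded R; practical for benchmark-scale
  datasets (hundreds to a few thousand peptides), not for proteome-scale
  training.
* Only the 20 standard amino acids are supported; non-standard residues are
  rejected at validation.
* The identity filter approximates but does not replicate CD-HIT's
  clustering; published non-redundant splits should be loaded verbatim when
  available rather than regenerated.
* Per-fold AUC averaging (rather than pooling predictions) is a convention;
  pooled AUC can be computed from the exported per-fold predictions if
  needed.
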