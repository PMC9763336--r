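# acplearn

Anticancer peptides (ACPs) are short (3–50 residue) peptides that lyse cancer
cells, typically through electrostatic interaction between their cationic,
aromatic-rich sequences and the negatively charged cancer cell membrane.
Screening candidate peptides experimentally is slow and expensive, so
sequence-based classifiers are used to triage candidates. `acplearn` is an R
toolkit for building, evaluating and *explaining* such classifiers: it is
aimed at computational biologists who want a fully scriptable,
tidyverse-friendly ACP prediction pipeline that runs end to end on a laptop,
with no external downloads required.

## What it implements

**Multi-feature sequence encoding.** A peptide `P = p1 p2 … pL` (L ≤ Lmax =
50) is encoded as an `Lmax × d` matrix, one row per residue, zero-padded
beyond the true length. Per-residue feature blocks:

| scheme | blocks | d |
|---|---|---|
| `bpf` | one-hot binary profile over the 20 amino acids | 20 |
| `quanc` | bpf + 6 z-scored quantitative properties (molecular mass, isoelectric point, pk1, pk2, side-chain pKa, van der Waals volume) | 26 |
| `qualc` | bpf + 10 one-hot qualitative categories (hydrophobicity, polarity, charge, aromatic/aliphatic) | 30 |
| `mix` | all three blocks | 36 |
| `embedding` | trainable 20 × 36 residue lookup, learned with the network | 36 |

Quantitative properties are standardized per column over the 20 amino acids,
`z_ij = (x_ij − μ_j) / σ_j` with the *population* standard deviation
(divisor 20).

**Bi-LSTM classifiers.** Two architectures, trained with Adam on categorical
cross-entropy and a softmax output pair `(P(non-ACP), P(ACP))`:

* `basic` — Bi-LSTM (n units per direction, final state of each direction)
  → dense(ReLU) → dense(2, softmax);
* `selfatt` — Bi-LSTM per-position outputs `x_t ∈ R^{2n}` → additive
  self-attention over position pairs,
  `e_{t,t'} = σ(w_a · tanh(x_t W_t + x_{t'} W_x + b_t) + b_a)`,
  `a_t = softmax(e_t)`, `l_t = Σ_{t'} a_{t,t'} x_{t'}` → attention pooling
  `α = softmax(hW + b)`, `att(h) = Σ_j α_j h_j` → the same dense head.

The recurrent, attention and gradient computations are implemented directly
in vectorized R (gradients are validated against finite differences in the
test suite), so the package has no deep-learning framework dependency.

**Evaluation and selection.** Stratified K-fold cross-validation and 80/20
holdout splits; ACC/Sen/Spc (%), Matthews correlation coefficient
`MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN))` and ROC AUC (the
Mann–Whitney concordance probability); grid search selecting the
configuration with the best mean CV MCC.

**Explainability.** Permutation Shapley values per (position, channel) cell
of the encoded input, with exact additivity (base value + attributions =
predicted ACP probability), per-channel importance ranking (mean |φ|), and
PCA projection of penultimate-layer features.

**Data handling.** FASTA I/O (labels as `|1`/`|0` id suffixes or a TSV),
a global-alignment sequence-identity filter for removing test peptides
redundant with a training set (an alignment-based stand-in for CD-HIT-2D),
and a synthetic benchmark generator that plants the cationic/aromatic
compositional signal of real ACPs so the whole pipeline is testable offline.

## Worked example

```r
library(acplearn)

bench <- make_benchmark(seed = 7)    # 200 ACP-like + 200 random peptides
cfg <- model_config(scheme = "mix", architecture = "basic", n_units = 32,
                    dense_units = 50, epochs = 15, seed = 7)
cv <- cross_validate(cfg, bench, k = 5)
glance(cv)
#> # A tibble: 1 × 6
#>     acc   sen   spc   mcc   auc     k
#>   <dbl> <dbl> <dbl> <dbl> <dbl> <int>
#> 1  95.2  95.5    95 0.906 0.992     5

fit <- train_model(cfg, bench)
shap <- shapley_attributions(fit, bench[1:10, ], bench, n_perm = 2, seed = 7)
head(glance(shap), 5)
#> # A tibble: 5 × 3
#>   channel                 importance  rank
#>   <chr>                        <dbl> <int>
#> 1 quanc_pKa                  0.0132      1
#> 2 aroali_N                   0.0119      2
#> 3 quanc_isoelectric_point    0.00872     3
#> 4 quanc_vdw_volume           0.00870     4
#> 5 hydrophobicity_N           0.00565     5

queries <- peptide_tbl(c("cationic_aromatic", "mixed_random"),
                       c("KWKRFIHKFWRYAKKIL", "GIGKFLHSAKKFGKAFVGEIMNS"))
predict(fit, queries)
#> # A tibble: 2 × 4
#>   id                p_non_acp   p_acp  pred
#>   <chr>                 <dbl>   <dbl> <int>
#> 1 cationic_aromatic   0.00128 0.999       1
#> 2 mixed_random        0.994   0.00634     0
```

Reading the output: five-fold cross-validation classifies the synthetic
benchmark at 95.2% accuracy with MCC 0.906 and AUC 0.992; the Shapley
ranking recovers the planted signal — side-chain pKa, the aromatic/aliphatic
block and the isoelectric point (all ionization/aromaticity channels)
dominate; and the trained model scores a cationic/aromatic query at
P(ACP) = 0.999 versus 0.006 for a compositionally unremarkable one.

The same pipeline is available from the shell via the bundled CLI
(`system.file("cli", "acplearn", package = "acplearn")`) with subcommands
`simulate`, `encode`, `filter`, `cv`, `gridsearch`, `train`, `predict`,
`evaluate`, `explain`, all seeded through `--seed`.

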