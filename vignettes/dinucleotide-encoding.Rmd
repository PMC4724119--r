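---
title: "Di-nucleotide association encoding for donor splice-site prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Di-nucleotide association encoding for donor splice-site prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceRF)
```

## The model

Canonical donor splice sites start the intron with GT, so every GT in a
genomic sequence is a candidate site and prediction is a binary
classification of fixed GT-anchored windows. spliceRF works on windows of
length $l = 2f + 2$ with flank $f = 50$ by default (102 bp: 50 exon-side
bases, the GT, 50 intron-side bases), aligned on the anchor.

Per-position base composition of an aligned set of $N$ windows is summarized
by the position weight matrix (PWM)

$$p_j^i = \frac{1}{N}\sum_{k=1}^{N} I\!\left(s_{kj} = i\right),
\qquad i \in \{A,C,G,T\},\; j = 1,\dots,l .$$

The PWM treats positions independently. The contribution of this method is
to score the *dependency between adjacent positions*: with
$n_{j,j+1}^{i,i'}$ the observed count of the ordered pair $(i,i')$ at
positions $(j, j+1)$, three association scores compare observation against a
null expectation, all on a $\log_2$ scale:

* **P-1** — against the uniform null, every ordered pair equally likely:
  $s = \log_2\!\big(n / (N \cdot 1/16)\big)$.
* **P-2** — against positional independence with the PWM marginals:
  $s = \log_2\!\big(n / (N\, p_j^i\, p_{j+1}^{i'})\big)$.
* **P-3** — the absolute relative deviation from that expectation:
  $s = \log_2\!\big(|n - N p_j^i p_{j+1}^{i'}| \,/\, (N p_j^i p_{j+1}^{i'})\big)$.

Each procedure fills a $16 \times (l-1)$ scoring matrix (rows: ordered pairs
AA…TT, lexicographic over A<C<G<T; columns: adjacent position pairs
`1_2` … `(l-1)_l`). Matrices are built separately for true sites (TSS) and
false sites (FSS), and their cell-wise **difference matrix** is the encoder:
a window becomes the length-$(l-1)$ vector of difference cells indexed by
its own adjacent pairs. Cells where the two classes agree contribute near
zero; cells where they disagree push the feature away from zero in a
class-specific direction. A random forest then classifies the encoded
vectors.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `flank` | 50 | bases kept per side of the GT; window $l = 2f+2$, features $l-1$ |
| `procedure` | `"P-1"` | which null the association scores use |
| `pseudo` | 0.001 | pseudo count guarding the logarithms (see below) |
| `direction` | `fss_minus_tss` | subtraction order of the difference matrix |
| `mtry` | $\lfloor\sqrt{p}\rfloor$ | features tried per forest split |
| `ntree` | 1000 | trees in the final forest |
| `cutoffs` | 0.5/0.5 | per-class vote cutoffs; 0.9 FSS / 0.1 TSS for the imbalanced protocol |
| `k` | 10 | cross-validation folds, stratified per class |

**Pseudo count.** The pseudo count exists to keep every logarithm finite. We
add it to each log numerator ($n$, and $|n - E|$ for P-3) *and* to the
expected-count denominators of P-2/P-3, because a zero PWM probability
otherwise divides by zero; P-1's denominator $N/16$ can never vanish and
takes none. `pseudo = 0` is accepted (it reproduces the textbook values
exactly on sets without empty cells); only negative values are rejected. The
default 0.001 perturbs scores by at most $\log_2(1 + 0.001/n)$ — under
a millibit for any observed count.

**Difference direction.** "FSS minus TSS" is the default; a flag flips it.
Tree ensembles are invariant to a per-feature sign flip (every split
threshold flips with the feature), so the choice cannot change forest
accuracy; it only changes the sign convention of written matrices.

**mtry grid.** Tuning searches $\{1, \sqrt p, 0.2p, 0.3p, 0.5p, p\}$ with
fractional values rounded half-up (a "down" mode truncates instead; for
$p = 101$ the two modes give 51 and 50 for the half-of-$p$ entry). The
tuned value for real 102-bp human donor data is 50 — plausibly because each
interior position appears in two adjacent-pair features, so half the
features already cover every position. On the synthetic data used in the
test suite, small `mtry` (the $\sqrt p$ default) does better: the planted
signal is spread thinly over many columns and small `mtry` decorrelates the
trees. Both values are a config option away.

**ntree stabilization.** "Grow until the OOB error stabilizes" is
formalized as the smallest $t$ whose trailing window of `window` values has
range (max − min) at most `tol`, defaults `tol = 0.005`, `window = 50`;
`max_trees` is returned when no window qualifies.

**Imbalanced evaluation.** On imbalanced test folds, metrics can be computed
from the weighted confusion matrix: TP and FN scaled by
$w_1 = n^{FSS}/(n^{TSS}+n^{FSS})$, FP and TN by
$w_2 = n^{TSS}/(n^{TSS}+n^{FSS})$. TPR and TNR are invariant under this
scaling (numerator and denominator scale together); the composite metrics
are not. The unweighted matrix remains available. Class cutoffs use the
vote-*ratio* rule of the reference forest implementation — predict the class
maximizing $\text{prob}/\text{cutoff}$ — not a plain probability threshold;
ties go to TSS.

**Margins.** The margin of an instance is the vote share of its true class
minus that of the other class, in $[-1, 1]$; instances with margin $\ge 0$
are counted correctly classified, so a 50/50 vote counts as correct. With
an odd `ntree` exact ties cannot occur and the margin-based accuracy equals
the confusion-matrix accuracy (this identity is asserted in the tests).

## Cross-validation without leakage

Fold assignment is stratified per class (each fold receives
$\lfloor n/k \rfloor$ or $\lceil n/k \rceil$ windows of each class) under an
explicit integer seed; no global random state is consumed. Within each fold,
the PWMs, both scoring matrices and the difference matrix are built from the
*training* windows only, and both training and held-out windows are encoded
through that matrix. The suite verifies the hygiene directly: mutating a
held-out window leaves the fold's difference matrix bit-identical. Per-fold
metrics are aggregated as mean and standard error, with the standard error
taken as sample-SD$/\sqrt{k}$ over folds — the conventional reading of
bracketed errors in fold-wise results tables.

Fold-wise comparisons between classifiers use the two-sided Mann–Whitney
test, exact for small tie-free samples (the 10-vs-10 fold comparison is
always exact; its attainable floor is $2/\binom{20}{10} \approx 1.08\times
10^{-5}$), with the normal approximation and tie correction otherwise. A
fully tied zero-variance comparison reports $p = 1$.

## The synthetic generator

Every stage is testable without external downloads through a generator of
GT-anchored windows:

* **TSS model** — at each position the consensus base receives probability
  $0.25 + 0.75\,c\,e^{-d^2/(2\cdot 6^2)}$, where $c$ is
  `consensus_strength` and $d$ the distance to the anchor. Near the anchor
  the consensus follows the canonical donor motif (MAG|GTAAGT); far from it
  the bump decays to uniform. On top of this, with probability
  `dependency_strength` the next base is drawn from a fixed first-order
  transition matrix instead of the positional marginal — injecting exactly
  the adjacent-position dependency the encoding is designed to detect.
* **FSS model** — i.i.d. draws from a background distribution (uniform by
  default). Both classes have GT forced at the anchor.

Defaults are `n_tss = n_fss = 300`, `flank = 50`, `consensus_strength =
0.8`, `dependency_strength = 0.5`: a strong but not trivial signal at the
data scale a desk-top cross-validation handles in seconds. Under these
conditions the full pipeline (P-1 encoding, 200-tree forest, 10-fold CV)
recovers the signal at a mean weighted accuracy around 0.89–0.90 across
seeds.

What the generator does *not* emulate: real exonic/intronic base
composition and its asymmetry across the junction, branch-point and
polypyrimidine signals, long-range or higher-order dependencies, homology
between windows, and genome-scale TSS:FSS imbalance (real genomes have
orders of magnitude more decoy GTs than the generator's configurable
ratio). Passing the recovery tests therefore shows the pipeline is wired
correctly and detects planted first-order structure — not that it attains
any particular accuracy on real splice-site corpora, which must be
evaluated on real data.

## Numerical choices and degenerate inputs

* Scores are computed in double precision, $\log_2$ exactly as defined.
* The 16 di-nucleotide rows are fixed lexicographic (AA, AC, …, TT) so
  written matrices round-trip unambiguously; columns are labelled by their
  left position, 1-based (`1_2` … `101_102` for 102-bp windows).
* Coordinates in all user-facing output are 1-based inclusive; windows are
  deduplicated on the extracted window sequence (what the model sees), not
  on any longer source record.
* Windows containing non-ACGT characters are skipped at scan time and
  tallied in a skip report (reason `ambiguous_base` or `short_flank`)
  rather than imputed — the encoding has no row for ambiguous bases.
* A degenerate confusion matrix with a zero MCC denominator reports MCC 0
  with a warning instead of aborting, and precision/F default to 0 when
  nothing is predicted positive, so sweeps over extreme cutoffs complete.
  An entirely empty true class is still an error.
* `classify_with_cutoff` breaks exact ratio ties toward TSS (the minority
  class in every realistic use).

## Problem sizes in the shipped tests

The suite exercises the headline end-to-end checks at 300 + 300 windows of
102 bp with 200-tree forests, the classifier unit tests at flank 10 (21
features), and the oracle equivalence checks at $N \le 20$, $l \le 8$ where
brute-force re-counting is instant; these sizes are the package's choice of
a desk-scale experiment that still exercises every code path at the real
window geometry.

## Known limitations

* Donor (GT) sites only; acceptor (AG) windows, variable-length alignment
  and genome-scale indexing are out of scope.
* Only first-order, adjacent-position dependencies are modelled — no
  higher-order or non-adjacent interactions.
* The forest itself is delegated to the reference `randomForest`
  implementation; this package owns the encoding, evaluation protocol and
  orchestration, not tree induction.
* Baseline adapters (SVM, single-hidden-layer perceptron, bagging,
  boosting, logistic regression, kNN, naive Bayes) are thin delegations for
  comparison harnesses, not tuned reference implementations; the perceptron
  requires an explicit hidden-layer size rather than guessing one.
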