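---
title: "RNA secondary structure prediction as row-wise multi-class classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RNA secondary structure prediction as row-wise multi-class classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rowfold)
```

## The problem and the representation

The secondary structure of an RNA of length $L$ is the set of its base
pairs, encoded here as an $L \times L$ binary contact matrix $S$ with
$S_{ij} = 1$ exactly when bases $i$ and $j$ pair. A legal structure matrix
is **binary**, **symmetric**, has **at most one 1 per row and per column**
(a base pairs with at most one partner), and is zero on the band
$|i - j| < 4$ — a pair closing a loop of fewer than three bases is
sterically impossible ("no sharp loops"). Nothing else is assumed: in
particular, crossing pairs (pseudoknots) are representable, and no
pairing-chemistry mask is imposed, because non-canonical pairs occur in
real structures and reference datasets are themselves noisy. The auditor
(`audit_validity()`) treats chemistry as informational only.

Deep models that score every cell of $S$ independently need iterative
post-processing to make their output legal. The method implemented here
removes that need by recasting the problem as $L$ parallel $L$-class
classifications, one per row.

## Label transformation

A row of $S$ for an unpaired base is all zero, so rows are not directly
usable as classification targets. `modify_label()` places a 1 on the
diagonal of every zero row:

$$\hat S_{ij} = \begin{cases} S_{ij} & i \ne j \\ 1 - \sum_k S_{ik} & i = j. \end{cases}$$

An unpaired base is labelled as "pairing with itself". The result is a
symmetric permutation matrix — exactly one 1 per row and column — so each
row is a one-hot $L$-class label, and the transform is lossless off the
diagonal. Because $\hat S$ is symmetric, rows and columns carry the same
information; training on rows of the symmetrized scores is equivalent to
training on columns of their transpose, and the suite asserts this
numerically to $10^{-9}$.

## Loss

The raw network output $M$ is symmetrized, $\hat M = (M + M^\top)/2$, and
each row is passed through a softmax (`row_softmax()`, max-shifted for
stability). One row plus its label row is a *sub-sample*; a batch of $b$
sequences has $bL$ sub-samples. Unpaired bases dominate real structures,
so the unpaired sub-samples $D$ are reweighted:

$$\ell = \frac{1}{bL}\Big(\sum_{i \notin D} \ell_i + \frac{bL - |D|}{|D|}\sum_{i \in D} \ell_i\Big),$$

with $\ell_i$ the cross-entropy of sub-sample $i$. Choices the formula
itself does not settle:

* **Degenerate $|D|$.** At $|D| = 0$ the weight is undefined and at
  $|D| = bL$ the loss vanishes identically; `weighted_cross_entropy()`
  falls back to the plain mean in both cases and says so with a message,
  preserving a usable training signal.
* **Padding.** Batched variable-length sequences are right-padded; padded
  rows are excluded from both sums *and* from the $bL$ count, the only
  convention under which a sample's loss does not depend on how it was
  batched. The suite checks this batch-layout invariance directly.
* **$D$ is computed per batch**, following the formula's notation, not per
  sequence.
* Internally the training path works in log-softmax space; this is
  mathematically identical and avoids `log(0)`.

## Decoding without post-processing

`decode_structure()` produces a guaranteed-legal prediction with three
matrix operations: binarize each row of $\hat M$ at its maximum
(`row_argmax_binarize()`, ties to the lowest column index for
determinism), multiply element-wise with the transpose — a pair survives
only if bases $i$ and $j$ *select each other* — and apply the sharp-loop
mask $Z$ ($Z_{ij} = 0$ iff $|i-j| < 4$). Mutual selection makes the result
symmetric with at most one 1 per row and column; $Z$ removes sharp loops
and, because the diagonal is inside the masked band, turns every base that
selected itself back into "unpaired". Validity therefore holds for *any*
real input, trained or not — the suite decodes 1,000 random matrices and
audits every one, and checks bit-exact agreement with an independently
written per-entry loop reference on 200 more.

## The scoring network

No deep-learning framework for R is available in this stack, so the
network is implemented directly in base-R matrix algebra with hand-derived
backward passes (verified against central finite differences in the test
suite) and small C++ kernels for the convolution im2col/col2im. The
architecture follows the Transformer-encoder + U-Net family that this line
of work uses; the published description of the original model's exact
layer inventory is not public, so this is a configurable member of the
same family, not a replica, and nothing downstream depends on its details.

* one-hot embedding of A/U/C/G plus sinusoidal positions;
* `n_layers` pre-LN Transformer encoder layers (`n_heads` heads,
  feed-forward width `ff_dim`); pre-LN trains stably without a warm-up
  schedule at these scales;
* a pairwise grid $F_{ij} = [h_i, h_j, h_i \odot h_j]$ — the outer
  concatenation used throughout this model family;
* a U-Net trunk: 3×3 convolutions, 2×2 average pooling down
  `unet_depth` levels with channel doubling from `base_channels`,
  nearest-neighbour upsampling with skip concatenation, and a 1×1 head
  producing $M$.

Sequences are right-padded to a multiple of $2^{\text{unet\_depth}}$.
Padded positions are masked out of attention, zeroed before the pairwise
grid, and all-pad grid cells are re-zeroed at every U-Net level, which
makes real-region scores independent of the padding length to floating
point precision (asserted at $10^{-8}$). Defaults
(`embed_dim = 24`, 2 layers, 4 heads, depth 1, 10 channels, ~21k
parameters) are sized for desk-scale experiments; `max_len = 512` covers
the sub-500-base range the method targets, while the test suite works at
$L \le 64$.

Training is plain single-sample Adam with per-epoch shuffling. Every
source of randomness — initialization, shuffling, dropout — is derived
from explicit seeds, epochs are seeded individually, and checkpoints carry
parameters, config and optimiser state, so a resumed run reproduces an
uninterrupted one step for step.

## Data augmentation

Three operators generate extra training samples while touching **only
unpaired bases** (set $B$), so the original structure remains a plausible
label; all three conserve the pair count, and every output is audited.

* `add_noise()`: `round(p1·|B|)` bases of $B$ are each changed to one of
  the three *other* bases; the structure is reused unchanged.
* `remove_bases()`: `round(p2·|B|)` bases of $B$ are deleted and the
  matching rows/columns dropped, then noise is applied; a deletion that
  would squeeze a surviving pair below separation 4 is resampled, and in
  the rare geometry where no legal deletion exists the operator removes
  fewer bases with a warning rather than emit an illegal structure.
* `insert_bases()`: `round(p3·L)` of the $L+1$ inter-base gaps (sampled
  without replacement) each receive one uniform random base; zero
  rows/columns are inserted, then noise is applied.

Counts use round-half-up so the expected count tracks $p \cdot n$ (R's
banker's rounding would silently drop small selections). The default
fractions are $p_1 = p_2 = p_3 = 10\%$, and `augment_dataset()` applies
all three operators twice to each sample in the 150–500-base range — six
augmented samples per long RNA, with short samples passed through — the
working configuration for this method. "Followed by adding noise" inside
remove/insert reuses $p_1$ over the post-edit unpaired set, the most
literal reading of the operator composition.

## Knowledge merge

A folding method's knowledge is abstracted as a deterministic mapping from
sequences to structures. `generate_teacher_set()` samples sequences
uniformly (length uniform on $[L_1, L_2]$, bases i.i.d.), labels them with
a teacher, and the resulting "sequence–prediction" pairs are concatenated
with the real training set (no mixing ratio is prescribed, so none is
imposed). Full-scale defaults are $L_1 = 50$, $L_2 = 500$, $n = 30{,}000$.

The built-in teacher is a Nussinov-style base-pair maximizer
(`nussinov_fold()`): dynamic programming over canonical + wobble pairs
with minimum separation 4, so teacher labels are valid by construction,
and a deterministic traceback (prefer pairing, then the smallest partner).
It is exact — the suite compares its pair counts against exhaustive
enumeration for short sequences. `external_teacher()` adapts any R
function or shell command (e.g. an installed thermodynamic folder) to the
same audited contract; no external program is ever required by the tests.

`same_prediction_ratio()` quantifies teacher-tracking as the fraction of
bases whose predicted partner (a partner index or "unpaired") agrees
between two predictions; the denominator is all bases, stated explicitly
since "prediction of each base" admits both readings.

## Evaluation

Confusion counts live on the candidate universe of unordered pairs with
$j - i \ge 4$ — $(L-4)(L-3)/2$ positions — so each base pair is counted
once and cells that are structurally zero in *both* matrices cannot
inflate the true-negative count. F1 is insensitive to this choice; INF is
not, which is why the universe is stated prominently. $P$, $R$, $F1$
follow the usual formulas with $0/0$ terms taken as 0, except that two
empty structures agreeing exactly score 1. INF is computed identically to
the Matthews correlation coefficient, with the standard zero-denominator
→ 0 convention; the suite cross-checks it against the Pearson correlation
of the pair indicators, to which it is mathematically equal.
`stratified_report()` macro-averages per sample (mean ± sd), overall and
in length bins split at 150 inside the 50–500 range, optionally in
width-100 bins and per family tag.

## Formats

FASTA reading goes through Biostrings with lowercase/T→U normalization
before strict A/U/C/G validation. CT files use the dominant 6-column
dialect (header line starting with $L$; 1-based indices; partner 0 =
unpaired) with mutual-consistency checking of the partner columns.
Dot-bracket output decomposes pseudoknots into tiers by repeatedly
extracting a *maximum* non-crossing subset (the same DP as the folder,
restricted to the given pairs), assigning `()`, `[]`, `{}`, `<>` in turn;
beyond four mutually crossing tiers the writer refuses and CT is the
fallback. All indices are 1-based internally — the natural R convention —
and CT is 1-based on disk, so no index conversion exists to get wrong.

## What the synthetic data does and does not show

`make_fixture_dataset()` builds hairpins, two-stem structures and H-type
pseudoknots with complementary (canonical + wobble) stems and uniform
loops, valid by construction. This gives the model a learnable
sequence-to-structure signal analogous to real pairing rules, and it makes
every pipeline property testable offline. It does *not* reproduce the
thermodynamics, family structure, length distribution or noise of curated
RNA datasets, so the desk-scale learning results below demonstrate that
the training method works end to end, not that it attains benchmark
accuracy on real families.

Problem sizes used by the tests and the acceptance script, chosen to keep
a full run in the minutes range on one CPU core: 500 training / 100
held-out hairpins at $L \le 64$ and at most 10 epochs for the learning
check (the ~21k-parameter default network reaches mean held-out F1 ≈ 0.93,
majority over 3 seeds); 2,000 teacher-labelled sequences at
$L \in [20, 60]$, 2 epochs, 200 held-out sequences for the
knowledge-merge direction check, where the teacher-trained model tracks
the teacher markedly better than an identically configured hairpin-trained
control — the desk-scale analogue of the published effect, directional
only by design.

## Known limitations

* Attention and grid memory grow quadratically in $L$; the practical
  ceiling is the configured `max_len`.
* The R implementation is single-sample and CPU-bound; it is sized for
  method verification, not large-scale training.
* The architecture approximates, and cannot claim to replicate, the
  original model's unpublished layer details.
* Augmentation assigns the original structure to a perturbed sequence,
  which is only plausible for small perturbation rates; knowledge merge is
  bounded by its teacher and is intended for out-of-family inputs, not as
  a general accuracy improvement.
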