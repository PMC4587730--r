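---
title: "Detecting mislabeled protein sequences with repeated cross-validated SVM analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mislabeled protein sequences with repeated cross-validated SVM analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protnoise)
```

## The problem

Curated protein databases attach a class label — here, a receptor subtype —
to every sequence, but some of those labels are wrong or uncertain: they may
come from automated genome annotation, unreviewed submissions, or outdated
similarity analyses. Such label noise both degrades classifiers trained on
the data and, more importantly, points to sequences whose annotation deserves
expert re-examination. `protnoise` turns a multi-class protein classifier
into a label-noise detector: a sequence that a well-tuned classifier
*consistently and confidently* places in a class other than its label is a
label-noise candidate.

The package was designed around datasets like the class C G-protein-coupled
receptors, with seven subtypes (mG, CS, GB, VN, Ph, Od, Ta) of very unequal
size and sequence lengths from a few hundred to nearly two thousand residues,
but nothing ties it to receptors: any FASTA file plus an `id → subtype` table
works.

## Sequence representations

Variable-length sequences are mapped to fixed-length vectors by four
alignment-free transformations (`aac()`, `digram()`, `acc()`, `pdbt()`):

* **AAC** — relative frequencies of the 20 amino acids (20 features).
* **Digram** — relative frequencies of the 400 overlapping adjacent residue
  pairs. Frequencies rather than counts are used for both N-gram maps, so
  the features are invariant to sequence length.
* **ACC** — auto-cross covariance of physicochemical descriptor
  trajectories. Each residue is replaced by its five z-scale descriptor
  values; each descriptor trajectory is centered by its *per-sequence* mean;
  and for every lag $d = 1..l$ and descriptor pair $(j, k)$,
  $$\mathrm{acc}(j,k,d) = \frac{1}{n-d}\sum_{i=1}^{n-d}
    \tilde z_j(i)\,\tilde z_k(i+d),$$
  giving $25\,l$ features ($l = 13$ by default). Concatenation is lag-major,
  then $(j,k)$ row-major; this ordering is fixed for reproducibility.
* **PDBT** — physicochemical distance-based transformation over a large
  property set: 531 amino-acid scales (the complete, NA-free entries of the
  public AAindex collection shipped with `seqinr`), each standardized across
  the 20 amino acids, with
  $$\mathrm{pdbt}(p,d) = \frac{1}{L-d}\sum_{i=1}^{L-d}
    \left(\tilde P_p(a_i) - \tilde P_p(a_{i+d})\right)^2$$
  for lags $1..l$ ($l = 8$ by default, hence $531 \times 8 = 4248$
  features), concatenated property-major.

Two conventions deserve a note, because the literature leaves them open.
First, ACC centering: we center each descriptor trajectory by its
per-sequence mean, the classical auto-covariance convention; it makes every
homopolymer map exactly to the zero vector, and it makes the features focus
on *sequence-order* structure — by construction they are invariant to overall
amino-acid composition. Second, PDBT standardization is done at the table
level (over the 20 amino acids), so a property's scale does not dominate the
squared differences.

## The classifier contract

Classification uses soft-margin RBF-kernel SVMs in the one-against-one
scheme: $K(K-1)/2$ pairwise binary classifiers (21 for $K = 7$), each
casting one vote per test item; the predicted class is the vote argmax with
ties broken toward the lowest class index. The quadratic-program solver is
libsvm (via `e1071`); the package's contribution is the contract around it —
votes are reconstructed from the pairwise decision values using libsvm's own
rule (a positive decision value votes for the lower-indexed class of the
pair), which the test suite verifies against libsvm's predicted labels.

Decision values are reported in a fixed canonical orientation: for the pair
$(i, j)$ with $i < j$, positive favors class $i$. This is the sign
convention that the cumulative decision value (below) relies on.

Features are standardized (z-scored per feature) with *training-fold*
statistics by default; the RBF kernel on heterogeneous feature scales (PDBT
especially) needs it, and applying train statistics at test time avoids any
leakage. Constant features pass through unchanged. `C` and `γ` come from a
grid search (`tune_hyperparameters()`) over a libsvm-style powers-of-4 grid,
maximizing mean cross-validated accuracy; ties go to the smaller `C`, then
smaller `γ` — preferring the less complex model.

## The three-step misclassification analysis

Given the feature matrix, tuned `C_opt` and `gamma_opt`, and a
`detector_config()`, `detect_candidates()` runs:

1. **Error profiling** (`profile_errors()`). The dataset is reshuffled and
   stratified 5-fold cross-validated, 100 times. Every sequence is a test
   item exactly once per iteration, so the per-sequence error rate
   $ER_s$ is directly a percentage. `C` is jittered across folds
   (multipliers 0.5–1.5 around `C_opt` by default) so the 500 fitted models
   are *different* SVMs near the optimum — consistent misclassification
   across them is then model-robust evidence, not one model's artifact.
   Sequences with $ER_s \ge e$ ("at least", inclusive) are kept; the
   default boundary $e = 75\,\%$ is deliberately conservative and should be
   lowered for a more exploratory screen.
2. **Voting-ratio analysis** (`voting_ratio()`). For each frequently
   misclassified sequence, the most-predicted class is the one receiving
   most misclassified assignments (ties to the lowest class index), and
   $$R_s = VT_s / VP_s,$$
   where $VT_s$ and $VP_s$ are the one-vs-one vote totals of the true and
   the most-predicted class over *all* test occasions. $R_s \le \theta_R$
   (default 0.5) marks a consistent, "large" error.
3. **Cumulative decision value** (`cumulative_dv()`). For true class $i$
   and most-predicted class $j$,
   $$CDV_s = \sum_{k=1}^{100} DV_s(i,j,k)$$
   sums the decision value of the single pairwise classifier confronting
   $i$ and $j$ across the 100 test occasions. Under the canonical sign
   convention, consistent confident misclassification produces a large
   positive $CDV_s$ when $i > j$ and a large negative one when $i < j$;
   $|CDV_s| \ge \theta_{CDV}$ (default 60) marks a confident error.
   Because the CDV is an un-normalized sum, the threshold scales linearly
   when the iteration count is not 100.

The candidate shortlist is the **union** of the step-2 and step-3 large sets:
the two signals are complementary (a narrow two-class vote transfer can give
a high $R_s$ with a large $|CDV_s|$, and vice versa).

Vote totals in step 2 sum over all test occasions, not only misclassified
ones; a flag (`votes_log`, retained in the result) lets tests recount both
quantities independently. Stratified shuffling is used for the folds so that
very small classes (48 of 1510 in the motivating dataset) are present in
every training fold.

## The ensemble cross-check

`run_ensemble()` implements an independent noise-rank filter: naive Bayes,
random forest (500 trees), the tuned RBF SVM, and a one-hidden-layer MLP
(width `min(100, 2D)`) are each evaluated by stratified cross-validation
over one *shared* fold assignment, and every sequence records which
classifiers misclassified it. `noise_rank()` weights the failing classifiers
(MLP 3, SVM 2, NB 1, RF 1 — taken from the noise-rank filter literature) and
`ensemble_candidates()` keeps sequences failed by at least 3 of the 4
(reporting the all-fail consensus subset alongside). `overlap_report()`
quantifies the agreement with the SVM-based shortlist. The base-learner
hyperparameters are deliberately ordinary and configurable; the point of the
ensemble is diversity, not tuning.

## The synthetic generator, and what passing tests do (and do not) show

`generate_dataset()` emulates the structure of a multi-subtype collection:
per-class amino-acid emission profiles drawn from a symmetric Dirichlet,
sequences emitted i.i.d. from
`separation * profile + (1 - separation) / 20`, lengths uniform in a range,
and `inject_label_noise()` flipping an exact `round(ρN)` of labels with full
ground truth (uniformly, or toward the nearest profile in total-variation
distance to mimic similarity-driven mislabeling).

The default desk-scale profile — 7 classes × 30 sequences, lengths 60–200,
separation 0.8, ρ = 0.05 — keeps a full 100×5-CV detector run in tens of
seconds on one CPU; the test suite uses it for parameter-recovery runs over
5 fixed generator seeds, and smaller variants (3–4 classes, 5–20
iterations) for unit tests.

The i.i.d. residue model is a real limitation, and an instructive one. An
i.i.d. generator encodes class identity *only* in composition; it has no
lag structure. Composition-bearing transforms (AAC, Digram) therefore
separate the synthetic classes essentially perfectly, and the detector
recovers injected flips with precision and recall beyond the 0.8 target
the recovery tests assert. The
per-sequence-centered ACC transform, by contrast, is composition-invariant
by construction and its lagged covariances have zero expectation under
i.i.d. emission — on synthetic data it carries almost no class signal,
so parameter recovery *through
ACC features* fails on this generator even though the same pipeline
recovers flips through AAC features on the same datasets. On real protein
families, where subtypes differ in local sequence-order structure
(transmembrane periodicity, domain architecture), ACC is informative —
which is precisely what an i.i.d. generator cannot emulate. Passing
recovery tests therefore validate the detector's bookkeeping, thresholds
and end-to-end behavior, not the real-data merit of any particular
transform.

## Numerical choices and degenerate cases

* Two accuracy summaries coexist: the headline `accuracy_overall`
  (trace/N, the proportion of correctly classified instances) and the
  macro-averaged one-vs-rest binary accuracy, which counts every item
  once per binarization and is systematically higher; both are always
  reported.
* MCC with a zero denominator (single-class truth or predictions) returns
  0 with a `degenerate` flag; other metrics return `NA` on zero
  denominators.
* The multi-class MCC is computed in the covariance form
  $\left(N\,\mathrm{tr}(C) - \sum_k t_k p_k\right) /
  \sqrt{(N^2 - \sum_k p_k^2)(N^2 - \sum_k t_k^2)}$, which is algebraically
  identical to the full term-by-term sum over all confusion-matrix entries;
  the test suite keeps the sum form as an independent oracle.
* Vote ties break toward the lowest class index (libsvm's convention);
  most-predicted-class ties likewise.
* The frequent-misclassification boundary is inclusive ($ER \ge e$).
* Sequences shorter than `max_lag + 1` are rejected by ACC/PDBT with an
  error naming the offending record.
* Non-standard residue codes (B, Z, X, U, O, J, `*`, gaps) are dropped with
  a warning by default ("drop" policy keeps real database exports usable);
  a "strict" policy is available and used in tests.

## Known limitations

* The generator produces no positional motifs, domain architecture or
  phylogenetic correlation; see above for the consequence.
* Candidates are shortlisted, never relabeled automatically: thresholds
  ($e$, $\theta_R$, $\theta_{CDV}$) are screening knobs whose final
  setting belongs to the domain expert.
* The SVM solver is delegated to libsvm; only its documented behaviors
  (shrinking, cache) are relied upon, and training is deterministic for
  fixed inputs.
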