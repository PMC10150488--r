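---
title: "Methods: entropy-based similarity and ensemble voting for miRNA-disease association prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: entropy-based similarity and ensemble voting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entromir)
```

## The model and its assumptions

`entromir` ranks candidate miRNA-disease associations under one core
assumption: entities with similar function share target genes. miRNAs
acting in the same regulatory program repress overlapping mRNA sets, and
diseases with related etiology implicate overlapping gene sets. If that
holds, the target-set overlap between a miRNA and the neighbourhood of a
disease is predictive of an (as yet unobserved) association.

Crucially, the similarity networks are built **without** the known
association matrix. Predictors that fold known associations into their
similarity kernels (e.g. Gaussian interaction profiles) leak label
information into cross-validation; here the labels enter only as the
training targets of the classifier, so CV estimates are not inflated by
construction.

### Entropy-weighted set similarity

All entity-to-gene interactions of one kind form a corpus of `N`
deduplicated pairs; a gene `t` occurring in `n(t)` of them has frequency
`p(t) = n(t)/N`. A gene set `T` has information entropy

$$H(T) = \sum_{t \in T} -p(t)\,\log_2 p(t),$$

a sum of non-negative terms (every `p(t) \le 1`), hence monotone under set
inclusion. Rare genes carry more weight than ubiquitous ones, so sharing a
rarely annotated gene counts for more than sharing a promiscuous one.
Similarity is the normalized mutual information

$$\mathrm{NMI}(A, B) = \frac{2\,H(T_A \cap T_B)}{H(T_A) + H(T_B)} \in [0, 1],$$

which is 1 for identical positive-entropy sets and 0 for disjoint ones.
The intersection entropy is bounded by both marginals, which is what keeps
the ratio in range; the property suite asserts this bound on random
corpora. The miRNA corpus and the disease corpus are kept separate — each
has its own `N` and frequency table — because they come from different
databases with different annotation depths.

Disease similarity additionally blends in a precomputed semantic
similarity matrix (from disease-term hierarchies):
`SD = alpha * SD1 + (1 - alpha) * SD2`, default `alpha = 0.5` (equal
contribution). The miRNA side uses functional similarity only.

### Features

Each pair (i, j) is encoded from three blocks:

1. row i of the miRNA similarity matrix, PCA-reduced;
2. row j of the disease similarity matrix, PCA-reduced;
3. 17 structural descriptors: the miRNA's gene count and density, mean and
   population variance of its similarity row, mean similarity of its
   top-ranked neighbour groups (ranks 1-50, 51-100, 101-150, 151-200);
   the same eight for the disease; and the shared-gene count between the
   miRNA's targets and the disease's gene set.

Each PCA block keeps the smallest component count reaching 80 % explained
variance.

### Classifier ensemble

Four base learners are fitted on identical rows and combined by soft
voting (unweighted mean of positive-class probabilities): an RBF-kernel
SVM with probability calibration, gradient-boosted decision trees, a
probability random forest, and regularized gradient boosting (XGBoost).
The members span margin-based and tree-based inductive biases; averaging
their calibrated probabilities reduces the variance of any single
learner. Evaluation is stratified 5-fold cross-validation with precision,
recall, F1 at a fixed threshold, plus AUC (Mann-Whitney concordance) and
AUPR (step-wise precision-recall area, no interpolation).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.5 | weight of semantic vs functional disease similarity (unitless, [0,1]) |
| `variance_threshold` | 0.80 | PCA explained-variance fraction per block |
| `top_k` / `group_size` | 200 / 50 | neighbour ranks / group width for the structural group-mean features |
| `folds` / `repeats` | 5 / 1 | cross-validation protocol |
| `threshold` | 0.5 | voted-probability cutoff for precision/recall/F1 |
| `negative_ratio` | 1 | sampled negatives per positive |
| SVM | cost 1, gamma 1/p | `e1071` RBF with probability calibration |
| GBDT | 100 rounds, eta 0.1, depth 3, no regularization, full subsample | classic gradient-boosted trees |
| RF | 100 trees | probability forest (`ranger`) |
| XGBoost | 100 rounds, eta 0.1, depth 6, default regularization | regularized boosting |

None of the hyperparameters is tuned on data; they are conventional
defaults, exposed through `ensemble_spec()` and the CLI config. The GBDT
member runs on the same boosting backend as the XGBoost member but with
regularization disabled, depth 3 and full subsampling — the classic
gradient-boosted-trees configuration — so the two members occupy different
points of the bias-variance spectrum.

## Design choices where the design was open

- **Negative sampling.** Unknown pairs vastly outnumber known
  associations (the benchmark corpus has 5430 positives among 189,585
  pairs, 2.86 %). The default draws negatives uniformly without
  replacement from unknown pairs, one per positive. Uniform sampling is
  the neutral choice; the `strategy` argument is a seam for informed
  selectors. Some sampled "negatives" are inevitably undiscovered
  positives; this biases metrics pessimistically rather than
  optimistically.
- **PCA is fitted once on the unique similarity rows** (m rows for the
  miRNA block, d for the disease block), not per CV fold. The blocks
  contain only those distinct rows, the fit is label-free, deterministic
  and cheap; refitting per fold would change feature meaning across folds
  without touching labels. Loadings are sign-fixed (largest-magnitude
  coordinate positive) for bit-reproducibility.
- **Self-similarity is excluded** from the row mean/variance features and
  from the top-k neighbour ranking: the guaranteed diagonal 1 would shift
  every entity's features equally and carry no information. Variance is
  population variance (divide by n).
- **Density denominator**: an entity's gene count divided by the number
  of distinct genes in its own interaction corpus, making the two density
  features comparable across corpora of different depth.
- **Fewer than `top_k` comparators** (always, at desk scale): the
  `K = min(top_k, n-1)` ranked neighbours split into 4 contiguous groups
  of `ceiling(K/4)`; an empty group contributes 0. Similarity ties break
  by ascending entity index.
- **Zero-entropy rule**: if `H(A) + H(B) = 0` the NMI is defined as 0,
  and an entity with an empty (or zero-entropy) gene set gets
  self-similarity 0, not 1 — unannotated entities must not contribute
  fake signal. This matches the observation that sparse annotation makes
  many real similarity entries exactly 0.
- **Isolated-disease mode** removes the held-out disease's pairs from the
  positives *and* from the negative-sampling pool (configurable), so no
  information about its column enters training; the stricter variant is
  the default because the laxer one could sample the disease's unknown
  pairs as negatives.
- **Stratified CV.** Folds are stratified by class with overall sizes
  within one sample; stratification stabilizes per-fold metrics on
  balanced sets and is recorded in the report.
- **Metric threshold** 0.5 on the voted probability; degenerate ratios
  (no predicted positives) return 0 with an explicit flag instead of NaN.

## The synthetic fixture

Real benchmark inputs (HMDD, miRTarBase, DisGeNET, the semantic matrix)
must be downloaded and name-matched; the package therefore ships a
generator that emulates the *statistical structure* the method detects.
Genes are partitioned into clusters (functional modules); each miRNA and
disease belongs to a module and draws its annotations preferentially from
its own module's gene pool (80/20 within/between); associations are
Bernoulli with probability 0.3 for module-matched pairs versus 0.02
otherwise; the semantic surrogate is 0.9 within / 0.1 between plus
symmetric Gaussian noise (sd 0.05), clipped to [0, 1].

Defaults: 60 miRNAs, 40 diseases, 300 genes, 4 clusters, mean 60 gene
draws per entity. The draw count puts entities in the dense-annotation
regime — each covers most of its module's pool — so that target-set
overlap identifies the module; this is required for the generator to
plant a *recoverable* signal, and mirrors well-studied miRNAs whose
validated target lists are extensive. Two analytic facts about this
design are worth stating. First, given the association probabilities and
cluster sizes, even a Bayes-optimal classifier that knows the true
modules cannot exceed an AUC ceiling in the low 0.80s: association status
is Bernoulli given module match, so the only learnable signal is the
match itself. Second, what the pipeline can add over that ceiling is
nothing — so end-to-end AUC near the ceiling indicates the similarity and
feature stages preserve essentially all module information. The negative
control (equal within/between probabilities for both gene draws and
associations) destroys the signal entirely and must yield chance-level
AUC.

What the fixture does *not* emulate: the heavy-tailed degree
distributions of real databases, annotation biases toward well-studied
entities, name-variant noise, and the much lower density of real
similarity matrices. Passing tests on the fixture therefore demonstrates
that the machinery extracts a planted guilt-by-shared-targets signal —
not that real-data performance will match any particular number.

## Numerical notes

- Entropies use log base 2 throughout; values are bits.
- AUC is computed in closed form via midranks (ties contribute 1/2),
  which equals the trapezoidal ROC area; the test suite checks the
  equivalence to 1e-12 against an independent trapezoid implementation.
- AUPR uses the step-wise sum `precision_k * delta recall_k` over distinct
  thresholds (average-precision convention); linear interpolation of PR
  points is deliberately avoided as it overestimates the area.
- Similarity matrices are exactly symmetrized (`(S + t(S))/2`) and clipped
  to [0, 1] after floating-point products; file round trips preserve 17
  significant digits.
- Genes appearing in a query set but absent from the corpus have no
  defined frequency and are ignored with a warning.
- Degenerate PCA inputs (constant rows) fall back to a single zero
  component; the numerical rank caps the component count at
  `variance_threshold = 1`.
- All stochastic stages (fixture generation, negative sampling, fold
  assignment, every classifier fit) are seeded; member seeds derive from
  the run seed and the member's position, fold seeds from seed and
  repeat index, so end-to-end runs are bit-reproducible.

## Problem sizes

The shipped tests and the acceptance script run entirely at desk scale:
the default fixture (60 x 40, ~400-500 training samples, ~25-45 features
after PCA), three fixture seeds for the pipeline checks, a 30 x 16
fixture for prediction contracts, and 10 isolated-disease runs. The
benchmark-scale dimensional identities (189,585 pairs, width 878, final
width 216) are verified with lightweight registry arithmetic rather than
by materializing the full sample matrix.

## Known limitations

- Annotation sparsity: entities with few or no recorded target genes get
  zero similarity to everything; their candidates rank on structural
  features alone. Real miRNA/disease corpora are far sparser than the
  fixture.
- Sampled negatives are unverified: "unknown" is not "absent", so
  precision at the 0.5 threshold underestimates true precision.
- The semantic similarity matrix is consumed as given; computing it from
  a disease-term hierarchy is out of scope.
- Member weights are fixed (unweighted soft vote); weighted voting would
  require a held-out calibration set.
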