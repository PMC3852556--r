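---
title: "Classifying short coding sequences with iteratively adaptive sparse PLS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying short coding sequences with iteratively adaptive sparse PLS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iaspls)
```

## The problem

Short open reading frames (60–400 nt) carry too little sequence to be
recognized reliably by general-purpose prokaryotic gene finders: many
composition statistics that separate coding from non-coding DNA at
gene-typical lengths become noisy, sparse and strongly collinear on
fragments of a few dozen codons. `iaspls` treats the task as supervised
binary classification of extracted fragments, given in their putative
reading orientation, with labels +1 (coding) and −1 (non-coding).

The package has three layers:

1. a **feature catalogue** that maps each fragment to a fixed 426-column
   numeric vector;
2. an **IASPLS core** — a sparse partial least squares (PLS) classifier
   whose per-variable penalties adapt to estimated variable importance and
   are updated iteratively;
3. an **evaluation protocol** — majority voting over models fitted on
   disjoint sub-blocks, with stratified repeated cross-validation scored
   by sensitivity (Sn), specificity (Sp), accuracy (ACC) and Matthews
   correlation (MCC), stratified by length class
   `[60,100)`, `[100,200)`, `[200,300)`, `[300,400]`.

## The model

### From PLS to sparse PLS

PLS1 extracts latent components one at a time. With column-standardized
predictors $X$ and centered response $y_c$, each component maximizes
covariance with the response: the weight vector of component $a$ is the
dominant singular direction of $m = X_a^\top y_c$, the score is
$t_a = X_a u_a$, and $X$ is deflated by the rank-one fit
$X_{a+1} = X_a - t_a p_a^\top$ with loading
$p_a = X_a^\top t_a / t_a^\top t_a$. After $A$ components the regression
coefficients are $B = W (P^\top W)^{-1} C$ with y-loadings
$c_a = y_c^\top t_a / t_a^\top t_a$.

Sparse PLS penalizes the rank-one approximation of $m$ with an $\ell_1$
term. For a univariate response $m$ is a vector, the $Y$-side weight is a
scalar (its penalty does nothing for variable selection), and the
penalized subproblem

$$\min_u \; \lVert m - u \rVert^2 + 2\lambda_1 \sum_i \omega_i |u_i|$$

has the closed-form soft-threshold solution
$u_i^{raw} = \mathrm{sign}(m_i)\,\max(|m_i| - \lambda_1 \omega_i,\, 0)$,
normalized to unit length (`sparse_weight_vector()`). With all
$\omega_i = 1$ this is ordinary sparse PLS; with $\lambda_1 = 0$ it
collapses to classical PLS1 (a reduction the test suite checks against an
independently coded PLS1 to 1e-8).

### Adaptive weights and iteration

A constant penalty treats informative and uninformative variables alike.
IASPLS rescales each variable's penalty by the inverse of its estimated
importance, $\omega_i = 1 / |\hat\beta_i|$: important variables are
shrunk less, noise variables more — the adaptive-lasso idea transplanted
into the PLS SVD step. Importances are initialized by ridge regression
($\hat\beta = (X^\top X + \alpha I)^{-1} X^\top y$), and because the
coefficient of a variable depends on how many latent components are
extracted, the weights are re-evaluated iteratively from the model's own
coefficients until the coefficient vector (or its support) stabilizes
(`fit_iaspls()`).

Numerical choices, all overridable:

* **Sparsity is a fraction, not an absolute penalty.** Adaptive weights
  make absolute $\lambda_1$ scales incomparable across data sets and
  iterations, so the package parameterizes
  $\lambda_1 = \eta \cdot \max_i |m_i| / \omega_i$ per component, with
  $\eta \in [0, 1)$; any $\eta < 1$ guarantees a nonempty support.
  Default $\eta = 0.5$. `tune_iaspls()` selects $(\eta, A)$ by stratified
  cross-validated accuracy over a grid (default $\eta \in \{0,\dots,0.9\}$,
  $A \in \{1,\dots,10\}$), breaking ties toward the sparser model; the
  evaluation protocol uses fixed defaults ($\eta = 0.5$, $A = 3$) rather
  than per-fold tuning to keep repeated-CV runtimes predictable — tuning
  remains available and leakage-free when invoked inside a training fold.
* **Weight capping.** $1/|\beta|$ is unbounded; the package uses
  $\omega_i = 1/\max(|\hat\beta_i|, 10^{-12})$ so excluded variables get
  huge but finite penalties.
* **Ridge $\alpha = 1$** on standardized columns.
* **Convergence**: relative coefficient change below $10^{-6}$, or an
  unchanged support, within at most 10 re-weighting iterations;
  non-convergence returns the last model with a logged warning.
* **Deflation** is X-side only (standard PLS1 regression deflation);
  whether the importance update should instead sit inside the component
  loop is underdetermined — the outer-loop reading implemented here is
  one faithful choice and is documented as such.
* **Standardization** (mean 0, sd 1, denominator $n-1$) is mandatory;
  zero-variance columns are tracked by index and carry zero weight
  everywhere rather than being dropped silently. Class coding is −1/+1
  with decision threshold 0; an exact 0 classifies as +1 so behavior is
  total.

## The feature catalogue

With all blocks enabled the matrix has **426 columns**, concatenated in a
fixed order (block widths are exposed as an attribute):

| block | width | content |
|---|---|---|
| `zcurve` | 252 | Z-transforms of conditional k-mer frequencies, k = 1..3: 63 phase-independent + 63 per codon phase 0/1/2 |
| `kmer` | 84 | overlapping k-mer frequencies, k = 1 (4), 2 (16), 3 (64) |
| `gc_cai` | 3 | GC content, Fop, CAI |
| `gc3s` | 4 | base composition at third codon positions |
| `aa_props` | 2 | mean Kyte–Doolittle hydropathy, aromatic fraction of the frame-0 translation |
| `rho` | 16 | dinucleotide odds ratios $f(XY)/(f_X f_Y)$ |
| `dinuc_props` | 65 | mean dinucleotide property profile |

The commonly quoted total of 429 for this catalogue cannot be reconciled
with the block widths above (252 + 84 + 90 = 426); the package documents
and asserts its actual total instead of forcing the quoted one.

Each Z-curve triple maps the conditional frequencies after a prefix $s$ to
purine/pyrimidine, amino/keto and weak/strong-hydrogen-bond contrasts,
e.g. $x_s = (f_{sA}+f_{sG}) - (f_{sC}+f_{sT})$; the 252 = 63 + 3×63
decomposition (phase-independent plus three codon phases) is the
implementer's documented construction satisfying the fixed total, since
only the total and the frame dependence are conventionally fixed.

Conventions applied uniformly: frame 0 from the first base, trailing
partial codon dropped (inputs are putative CDS fragments); any window
containing a non-ACGT character is skipped and the denominator reduced;
sequences with more than 10% ambiguous bases are rejected at load
(configurable). Zero-denominator cases return 0 (rho) or exclude the
family (CAI), and are logged.

The CAI/Fop reference defaults to a table computed from the labelled
coding training sequences (relative adaptiveness = count/max within each
amino-acid family, pseudo-count 0.5 for zero cells, optimal codon =
family argmax; single-codon families never optimal); a user table can be
supplied. Note the reference is computed once from the labelled coding
set before cross-validation — a deliberate, mild simplification; the
leakage-sensitive choices ($\eta$, $A$) are confined to training folds.
The shipped dinucleotide property table is **synthetic** (deterministic
stand-in values, labelled as such); all property-profile tests use their
own tables so correctness is table-independent.

## Evaluation protocol

`train_voting_ensemble()` shuffles the training rows with a given seed,
splits them into $K$ (odd, default 3) nearly equal stratified sub-blocks
and fits one model per block; `predict()` takes the strict majority of
the $K$ votes (odd $K$ makes ties impossible). `cross_validate()` runs
stratified 5-fold CV, repeated (default 20 times) with fresh shuffles of
both fold assignment and sub-blocks — repeats reshuffle everything, which
is one defensible reading of an ambiguous protocol — and reports
per-repeat metrics from summed fold confusions plus their arithmetic
mean. An optional `balanced` mode downsamples the larger class per
repeat. MCC is computed with the standard subtractive numerator
$TP \cdot TN - FP \cdot FN$ (a printed additive variant circulates but is
not a balanced measure, which MCC is by definition); a zero factor in the
denominator yields MCC = 0 by convention.

## What the synthetic world does and does not establish

`generate_sequence_dataset()` emulates coding-like fragments as iid
codons from a codon-usage table (default: an E. coli-like table) with a
leading ATG and in-frame stops excluded, against iid-base background
noncoding fragments. This is the simplest world the frame-dependent
features can detect: it contains codon bias, reading-frame periodicity
and stop-codon depletion, but no dicodon structure, promoters, RBS,
operon context, or genome-scale GC heterogeneity. A green end-to-end test
therefore establishes that the pipeline detects codon-level composition
signal at realistic lengths — not field performance on genomic data.
Setting `add_start = FALSE`, `exclude_stops = FALSE` and
`codon_usage = background_codon_usage()` makes the two classes
distributionally identical; this no-signal null must score ACC ≈ 0.5 and
is part of the acceptance suite (0.5 ± 0.05).

`generate_sparse_linear_data()` draws iid normal columns and labels
$y = \mathrm{sign}(\text{effect} \cdot \sum_{j \in S} X_j + \varepsilon)$.
One property worth stating explicitly: with `noise_sd = 0` the classes
are exactly linearly separable, yet any least-squares-type linear scorer
(PLS included) fits the *sign* target, so the estimated hyperplane
carries $O(1/\sqrt n)$ coefficient noise and the margin density is
continuous at zero — training accuracy plateaus near 0.98 at
$n = 500, p = 50$ rather than reaching 1. The tests assert support
recovery plus ACC ≥ 0.95 there, which is what the model class can
honestly deliver.

## Known limitations

* Binary classification only; no multi-class response, no multivariate Y.
* Single-strand, frame-0 analysis: no reverse-complement scanning, no ORF
  extraction from genomes, no strand-symmetry guarantees.
* The adaptive-weight update sits outside the component loop; other
  orderings are conceivable and would change iterates (not the
  $\lambda_1 = 0$ limit).
* Dense in-memory linear algebra; intended for thousands of fragments ×
  hundreds of features, not genome-scale matrices.
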