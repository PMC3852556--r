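# iaspls

Classification of **short prokaryotic DNA fragments (60–400 nt)** as
protein-coding (+1) versus non-coding (−1), using an **iteratively
adaptive sparse partial least squares (IASPLS)** classifier over a fixed
426-column catalogue of sequence-composition features.

Short fragments defeat most gene finders: composition statistics become
sparse, noisy and strongly collinear at a few dozen codons. IASPLS is
built for exactly that regime — a linear PLS classifier whose weight
vectors are sparsified inside the SVD step, with per-variable penalties
rescaled by estimated importance and updated iteratively.

## The method in brief

For standardized predictors $X$ and class labels $y \in \{-1,+1\}$, each
PLS component solves the penalized rank-one problem

$$\min_u \lVert m - u \rVert^2 + 2\lambda_1 \sum_{i=1}^p \omega_i\,|u_i|,
\qquad m = X_a^\top y_c ,$$

whose solution is elementwise soft-thresholding,
$u_i = \mathrm{sign}(m_i)\max(|m_i| - \lambda_1\omega_i,\,0)$ (then unit
normalized). The adaptive weights are $\omega_i = 1/|\hat\beta_i|$ with
$\hat\beta$ first estimated by ridge regression and then re-estimated
from the model's own coefficients until the support stabilizes. With
$\lambda_1 = 0$ the whole procedure collapses to classical PLS1 (tested
against an independent implementation to 1e-8). Predicted labels are
$\mathrm{sign}(X_{std} \hat B + b_0)$, and the evaluation protocol uses
majority voting of $K$ (odd) models trained on disjoint stratified
sub-blocks, scored by Sn, Sp, ACC and MCC under repeated stratified
cross-validation.

Feature blocks (426 columns total): frame-dependent Z-curve transforms
(252), k-mer frequencies for k = 1..3 (84), GC/Fop/CAI (3), third-codon-
position composition (4), translated-peptide hydropathy and aromaticity
(2), dinucleotide odds ratios (16), dinucleotide property profile (65).
See `vignettes/iaspls-methods.Rmd` for definitions, conventions and
design rationale.

## Worked example

Everything below is generated offline from the package's own seeded
simulator — coding-like fragments with E. coli-like codon usage, ATG
starts and stop-free frames, against uniform-background non-coding
fragments.

```r
library(iaspls)

seqs <- generate_sequence_dataset(n_coding = 150, n_noncoding = 150,
                                  length_range = c(60, 400), seed = 1)
seqs
#> dna_set with 300 sequence(s); lengths 60-396 nt; 300 labelled

ref <- codon_reference_from_sequences(seqs[which(seqs$label == 1)])
X <- build_feature_matrix(seqs, feature_config(codon_reference = ref))
dim(X)
#> [1] 300 426

fit <- fit_iaspls(X, seqs$label)
fit
#> iaspls_model: 3 component(s), 5/426 nonzero coefficients, 4 iteration(s) (converged)

cv <- cross_validate(X, seqs$label,
                     plan = evaluation_plan(n_folds = 5, n_repeats = 5,
                                            seed = 1),
                     K = 3)
cv
#> cv_result: 5-fold x 5 repeat(s), K = 3
#>   mean Sn = 0.9867  Sp = 0.9707  ACC = 0.9787  MCC = 0.9575
```

Reading the output: the adaptive penalties kept 5 of 426 features (the
iteration converged when the support stopped changing); the
majority-vote ensemble (K = 3) recovers the coding class with mean
sensitivity 0.987 and specificity 0.971 over 5×5-fold CV — on *this
synthetic world*, which contains codon bias, frame periodicity and
stop-codon depletion but none of the harder structure of genomic data
(see the vignette for what a green benchmark does and does not
establish).

## Command line

```sh
Rscript -e 'quit(status = iaspls::iaspls_cli())' simulate \
    --out-fasta sim.fa --out-labels sim.labels --seed 1
Rscript -e 'quit(status = iaspls::iaspls_cli())' extract \
    --fasta sim.fa --labels sim.labels --out features.tsv
Rscript -e 'quit(status = iaspls::iaspls_cli())' train \
    --features features.tsv --labels sim.labels --out model.json --K 3
Rscript -e 'quit(status = iaspls::iaspls_cli())' evaluate \
    --fasta sim.fa --labels sim.labels --out report.tsv --repeats 5
```

(`inst/scripts/iaspls` wraps the same entry point.) Exit codes: 0
success, 2 usage error, 3 data error, 4 numerical failure. Every run
logs its resolved configuration and seed to stderr.

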