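# Seeded generators: (a) sparse linear classification data for the
# numerical core, (b) coding-like vs noncoding-like DNA for the end-to-end
# pipeline. Both are pure functions of their spec + seed.

#' E. coli-like codon usage table
#'
#' Approximate relative codon frequencies (per-1000 scale, normalized to a
#' probability vector) resembling a moderately expressed E. coli gene set.
#' Tests never depend on the exact values, only on divergence from a
#' uniform background.
#'
#' @return named numeric 64-vector summing to 1.
#' @export
default_codon_usage <- function() {
  u <- c(
    TTT = 22.1, TTC = 16.6, TTA = 13.9, TTG = 13.7, CTT = 11.0, CTC = 11.0,
    CTA =  3.9, CTG = 52.6, ATT = 30.3, ATC = 25.1, ATA =  4.4, ATG = 27.9,
    GTT = 18.3, GTC = 15.3, GTA = 10.9, GTG = 26.4, TCT =  8.5, TCC =  8.6,
    TCA =  7.2, TCG =  8.9, CCT =  7.0, CCC =  5.5, CCA =  8.4, CCG = 23.2,
    ACT =  9.0, ACC = 23.4, ACA =  7.1, ACG = 14.4, GCT = 15.3, GCC = 25.5,
    GCA = 20.1, GCG = 33.6, TAT = 16.2, TAC = 12.2, TAA =  2.0, TAG =  0.2,
    CAT = 12.9, CAC =  9.7, CAA = 15.3, CAG = 28.8, AAT = 17.7, AAC = 21.7,
    AAA = 33.6, AAG = 10.3, GAT = 32.1, GAC = 19.1, GAA = 39.4, GAG = 17.8,
    TGT =  5.2, TGC =  6.4, TGA =  1.0, TGG = 15.2, CGT = 20.9, CGC = 22.0,
    CGA =  3.6, CGG =  5.4, AGT =  8.8, AGC = 16.1, AGA =  2.1, AGG =  1.2,
    GGT = 24.7, GGC = 29.6, GGA =  8.0, GGG = 11.1)
  u <- u[all_kmers(3L)]
  u / sum(u)
}

#' Uniform codon usage implied by a base composition
#'
#' The codon distribution obtained by drawing three iid bases from
#' `background`; with the default uniform background this is the uniform
#' distribution over the 64 codons -- the matched "no-signal null" for the
#' sequence generator.
#'
#' @param background named base probabilities (A, C, G, T).
#' @return named numeric 64-vector summing to 1.
#' @export
background_codon_usage <- function(background = c(A = 0.25, C = 0.25,
                                                  G = 0.25, T = 0.25)) {
  background <- background[BASES] / sum(background)
  cods <- all_kmers(3L)
  u <- background[substring(cods, 1, 1)] *
    background[substring(cods, 2, 2)] *
    background[substring(cods, 3, 3)]
  stats::setNames(as.numeric(u), cods)
}

#' Generate sparse linear classification data
#'
#' X is iid standard normal; the latent score is
#' `effect_size * rowSums(X[, informative]) + N(0, noise_sd)` and
#' `y = sign(score)` (zeros to +1). If thresholding leaves one class empty
#' the draw is repeated (bounded retries, logged).
#'
#' @param n,p sample and variable counts.
#' @param n_informative number of informative columns (sampled without
#'   replacement).
#' @param effect_size per-column effect (default 2).
#' @param noise_sd noise standard deviation (default 1).
#' @param seed RNG seed; the output is fully determined by it.
#' @param max_retries bounded resampling attempts for degenerate draws.
#' @return list with `X`, `y` (-1/+1) and sorted `informative` indices.
#' @export
generate_sparse_linear_data <- function(n, p, n_informative,
                                        effect_size = 2, noise_sd = 1,
                                        seed = 1, max_retries = 10) {
  stopifnot(n_informative >= 1, n_informative <= p, noise_sd >= 0)
  set.seed(seed)
  informative <- sort(sample.int(p, n_informative))
  for (try in seq_len(max_retries)) {
    X <- matrix(stats::rnorm(n * p), n, p)
    score <- effect_size * rowSums(X[, informative, drop = FALSE]) +
      stats::rnorm(n, 0, noise_sd)
    y <- ifelse(score >= 0, 1, -1)
    if (length(unique(y)) == 2) {
      return(list(X = X, y = y, informative = informative))
    }
    ias_log("degenerate draw (one class absent); resampling", level = "WARN")
  }
  stop("could not generate two-class data in ", max_retries, " attempts",
       call. = FALSE)
}

#' Generate coding-like and noncoding-like sequences
#'
#' Coding-like sequences have a length that is a multiple of 3 within
#' `length_range`, optionally a leading ATG, and codons drawn iid from
#' `codon_usage` with in-frame stop codons excluded (unless
#' `exclude_stops = FALSE`). Noncoding-like sequences are iid bases from
#' `background` at any length in range. Setting `add_start = FALSE`,
#' `exclude_stops = FALSE` and `codon_usage = background_codon_usage()`
#' makes the two classes distributionally identical (the no-signal null).
#'
#' @param n_coding,n_noncoding sequence counts.
#' @param length_range integer min/max in nt, within \[60, 400\].
#' @param codon_usage named 64-entry probability table for coding codons.
#' @param background named base probabilities for the noncoding class.
#' @param seed RNG seed.
#' @param add_start prepend ATG to coding sequences (default TRUE).
#' @param exclude_stops forbid in-frame stop codons in coding sequences
#'   (default TRUE).
#' @return a [dna_set()] with labels +1 (coding) then -1 (noncoding).
#' @export
generate_sequence_dataset <- function(n_coding, n_noncoding,
                                      length_range = c(60L, 400L),
                                      codon_usage = default_codon_usage(),
                                      background = c(A = 0.25, C = 0.25,
                                                     G = 0.25, T = 0.25),
                                      seed = 1, add_start = TRUE,
                                      exclude_stops = TRUE) {
  length_range <- as.integer(length_range)
  if (length_range[2] < 60L || length_range[1] > length_range[2] ||
      length_range[1] < 60L || length_range[2] > 400L) {
    stop("length_range must satisfy 60 <= min <= max <= 400", call. = FALSE)
  }
  cods <- all_kmers(3L)
  codon_usage <- codon_usage[cods]
  if (anyNA(codon_usage) || any(codon_usage < 0)) {
    stop("codon_usage must cover all 64 codons with nonnegative mass",
         call. = FALSE)
  }
  codon_usage <- codon_usage / sum(codon_usage)
  background <- background[BASES] / sum(background)
  stops <- c("TAA", "TAG", "TGA")
  usage <- codon_usage
  if (exclude_stops) {
    usage[stops] <- 0
    usage <- usage / sum(usage)
  }
  set.seed(seed)
  cod_lengths <- possible_codon_lengths(length_range)
  coding <- character(n_coding)
  for (i in seq_len(n_coding)) {
    L <- if (length(cod_lengths) == 1) cod_lengths else sample(cod_lengths, 1)
    nc <- L %/% 3L
    codons <- sample(cods, nc, replace = TRUE, prob = usage)
    if (add_start) codons[1] <- "ATG"
    coding[i] <- paste(codons, collapse = "")
  }
  noncoding <- character(n_noncoding)
  for (i in seq_len(n_noncoding)) {
    L <- sample(seq(length_range[1], length_range[2]), 1)
    noncoding[i] <- paste(sample(BASES, L, replace = TRUE,
                                 prob = background), collapse = "")
  }
  dna_set(id = c(sprintf("cod_%04d", seq_len(n_coding)),
                 sprintf("nc_%04d", seq_len(n_noncoding))),
          bases = c(coding, noncoding),
          label = c(rep(1L, n_coding), rep(-1L, n_noncoding)))
}

possible_codon_lengths <- function(length_range) {
  L <- seq(length_range[1], length_range[2])
  L <- L[L %% 3L == 0L]
  if (!length(L)) {
    stop("no multiple-of-3 length inside the range", call. = FALSE)
  }
  L
}
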