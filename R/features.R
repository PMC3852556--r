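# Feature catalogue: every block maps a single sequence (uppercase string,
# possibly containing IUPAC ambiguity codes) to a fixed-length numeric
# vector. Windows containing any non-ACGT character are skipped and the
# denominator reduced; ambiguity codes are never mapped to a base.

BASES <- c("A", "C", "G", "T")

#' All k-mers in lexicographic order
#' @param k word length.
#' @return character vector of length 4^k (AA.. < ..TT).
#' @export
all_kmers <- function(k) {
  out <- BASES
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      out <- as.vector(t(outer(out, BASES, paste0)))
    }
  }
  out
}

# Overlapping windows of width k; `phase` (0/1/2) restricts to windows whose
# 0-based start is congruent to phase mod 3. Invalid (ambiguous) windows are
# dropped.
valid_windows <- function(bases, k, phase = NULL) {
  L <- nchar(bases)
  if (L < k) return(character(0))
  starts <- seq_len(L - k + 1L)
  if (!is.null(phase)) starts <- starts[(starts - 1L) %% 3L == phase]
  if (!length(starts)) return(character(0))
  w <- substring(bases, starts, starts + k - 1L)
  w[!grepl("[^ACGT]", w)]
}

kmer_counts <- function(bases, k, phase = NULL) {
  w <- valid_windows(bases, k, phase)
  tabulate(factor(w, levels = all_kmers(k)), nbins = 4L^k)
}

seq_string <- function(x) {
  if (inherits(x, "dna_set")) {
    stopifnot(length(x) == 1L)
    x$bases
  } else {
    toupper(as.character(x))
  }
}

#' Overlapping k-mer frequencies
#'
#' Counts of overlapping k-mers (windows containing ambiguity codes are
#' skipped) divided by the number of valid windows, in lexicographic k-mer
#' order.
#'
#' @param x a single sequence (character) or a one-sequence [dna_set()].
#' @param k word length, 1-3.
#' @return named numeric vector of length `4^k`, summing to 1.
#' @export
kmer_frequencies <- function(x, k) {
  stopifnot(k %in% 1:3)
  bases <- seq_string(x)
  cts <- kmer_counts(bases, k)
  tot <- sum(cts)
  if (tot == 0) {
    stop(sprintf("no valid %d-mer window in sequence '%s'", k,
                 substr(bases, 1, 20)), call. = FALSE)
  }
  stats::setNames(cts / tot, all_kmers(k))
}

# Z-transform of a k-mer count vector: counts (lexicographic) reshape to a
# (4^(k-1) prefixes) x (4 last bases) matrix; each prefix row is normalized
# to conditional frequencies and mapped to the three Z components
#   x = (fA+fG)-(fC+fT)   purine vs pyrimidine
#   y = (fA+fC)-(fG+fT)   amino vs keto
#   z = (fA+fT)-(fG+fC)   weak vs strong hydrogen bonding.
# A prefix with zero occurrences yields (0,0,0) by convention.
zcurve_triples <- function(counts, k) {
  mat <- matrix(counts, ncol = 4L, byrow = TRUE)
  tot <- rowSums(mat)
  f <- mat / ifelse(tot > 0, tot, 1)
  f[tot == 0, ] <- 0
  cbind(x = (f[, 1] + f[, 3]) - (f[, 2] + f[, 4]),
        y = (f[, 1] + f[, 2]) - (f[, 3] + f[, 4]),
        z = (f[, 1] + f[, 4]) - (f[, 3] + f[, 2]))
}

zcurve_block <- function(bases, phase = NULL) {
  out <- numeric(0)
  nms <- character(0)
  scope <- if (is.null(phase)) "all" else paste0("p", phase)
  for (k in 1:3) {
    cts <- kmer_counts(bases, k, phase)
    tr <- zcurve_triples(cts, k)
    prefixes <- if (k == 1) "" else all_kmers(k - 1L)
    v <- as.vector(t(tr))  # prefix-major, components x,y,z per prefix
    nm <- as.vector(t(outer(prefixes, c("x", "y", "z"), function(p, comp) {
      ifelse(p == "", sprintf("zc.%s.k%d.%s", scope, k, comp),
             sprintf("zc.%s.k%d.%s.%s", scope, k, p, comp))
    })))
    out <- c(out, v)
    nms <- c(nms, nm)
  }
  stats::setNames(out, nms)
}

#' Frame-dependent Z-curve features
#'
#' For k = 1..3, the Z-transform of (conditional) k-mer frequencies: 63
#' components computed phase-independently over all overlapping windows,
#' plus 63 for each codon phase 0/1/2 (windows whose 0-based start position
#' is congruent to the phase mod 3), for a total of 252. All components lie
#' in \[-1, 1\]. A conditioning prefix that never occurs contributes (0,0,0).
#'
#' @inheritParams kmer_frequencies
#' @return named numeric vector of length 252.
#' @export
zcurve_features <- function(x) {
  bases <- seq_string(x)
  if (nchar(bases) < 3 || length(valid_windows(bases, 1L)) == 0) {
    stop(sprintf("sequence '%s' too short or fully ambiguous for Z-curve",
                 substr(bases, 1, 20)), call. = FALSE)
  }
  c(zcurve_block(bases, NULL),
    zcurve_block(bases, 0L), zcurve_block(bases, 1L), zcurve_block(bases, 2L))
}

#' GC content
#'
#' (#G + #C) / (#A + #C + #G + #T); ambiguity codes excluded from both
#' numerator and denominator.
#'
#' @inheritParams kmer_frequencies
#' @return scalar in \[0, 1\].
#' @export
gc_content <- function(x) {
  bases <- seq_string(x)
  cts <- kmer_counts(bases, 1L)
  if (sum(cts) == 0) {
    stop("no unambiguous base in sequence '", substr(bases, 1, 20), "'",
         call. = FALSE)
  }
  (cts[2] + cts[3]) / sum(cts)
}

# Frame-0 codons of the complete-codon prefix; trailing partial codon
# dropped. valid_codons additionally drops codons containing ambiguity.
frame0_codons <- function(bases) {
  n <- nchar(bases) %/% 3L
  if (n == 0) return(character(0))
  starts <- 3L * (seq_len(n) - 1L) + 1L
  substring(bases, starts, starts + 2L)
}

valid_codons <- function(bases) {
  cd <- frame0_codons(bases)
  cd[!grepl("[^ACGT]", cd)]
}

#' Base composition at third codon positions
#'
#' Frequencies of A, C, G, T at the third position of complete frame-0
#' codons (trailing partial codon ignored; codons with an ambiguous third
#' base excluded).
#'
#' @inheritParams kmer_frequencies
#' @return named numeric 4-vector (A, C, G, T) summing to 1.
#' @export
gc3s_composition <- function(x) {
  bases <- seq_string(x)
  cd <- frame0_codons(bases)
  if (!length(cd)) {
    stop("no complete codon in sequence '", substr(bases, 1, 20), "'",
         call. = FALSE)
  }
  thirds <- substring(cd, 3L, 3L)
  thirds <- thirds[thirds %in% BASES]
  if (!length(thirds)) {
    stop("no unambiguous third-position base in sequence '",
         substr(bases, 1, 20), "'", call. = FALSE)
  }
  cts <- tabulate(factor(thirds, levels = BASES), nbins = 4L)
  stats::setNames(cts / sum(cts), BASES)
}

#' Codon usage indices: Fop and CAI
#'
#' Fop is the fraction of optimal codons among codons whose amino-acid
#' family has a defined optimal codon (stop codons excluded). CAI is the
#' geometric mean of relative adaptiveness w over codons, excluding stop
#' codons, single-codon families (Met, Trp) and codons of families the
#' reference excludes (w = NA).
#'
#' @inheritParams kmer_frequencies
#' @param reference a `codon_reference` (see
#'   [codon_reference_from_sequences()]).
#' @return named numeric vector `c(fop = , cai = )`, both in (0, 1] for
#'   sequences with countable codons (Fop falls back to 0 when no codon
#'   belongs to a family with an optimal codon).
#' @export
codon_usage_indices <- function(x, reference) {
  if (missing(reference) || is.null(reference)) {
    stop("a codon reference table is required (see ",
         "codon_reference_from_sequences)", call. = FALSE)
  }
  validate_codon_reference(reference)
  bases <- seq_string(x)
  cd <- valid_codons(bases)
  if (!length(cd)) {
    stop("zero countable codons in sequence '", substr(bases, 1, 20), "'",
         call. = FALSE)
  }
  idx <- match(cd, reference$codon)
  if (anyNA(idx)) {
    stop("codon(s) absent from reference: ",
         paste(unique(cd[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  aa <- reference$aa[idx]
  w <- reference$w[idx]
  opt <- reference$optimal[idx]

  # Fop: denominator = codons of families possessing an optimal codon
  fam_has_opt <- tapply(reference$optimal, reference$aa, any)
  in_scope <- aa != "*" & fam_has_opt[aa]
  fop <- if (any(in_scope)) sum(opt[in_scope]) / sum(in_scope) else {
    ias_log("Fop undefined (no codon in an optimal-codon family); using 0",
            level = "WARN")
    0
  }

  # CAI: exclude stops, single-codon families, excluded families (w = NA)
  fam_size <- table(reference$aa[reference$aa != "*"])
  cai_scope <- aa != "*" & fam_size[aa] > 1 & !is.na(w)
  if (!any(cai_scope)) {
    stop("zero CAI-countable codons in sequence '", substr(bases, 1, 20),
         "'", call. = FALSE)
  }
  cai <- exp(mean(log(w[cai_scope])))
  c(fop = unname(fop), cai = cai)
}

#' Translated-peptide properties
#'
#' Translates complete frame-0 codons with the standard genetic code (stop
#' codons and ambiguous codons skipped) and reports the mean Kyte-Doolittle
#' hydropathy and the fraction of aromatic residues (F, W, Y).
#'
#' @inheritParams kmer_frequencies
#' @param scale named per-residue hydropathy values (default
#'   [kyte_doolittle()]).
#' @return named numeric vector `c(hydrophobicity = , aromaticity = )`.
#' @export
protein_properties <- function(x, scale = kyte_doolittle()) {
  bases <- seq_string(x)
  cd <- valid_codons(bases)
  res <- unname(Biostrings::GENETIC_CODE[cd])
  res <- res[!is.na(res) & res != "*"]
  if (!length(res)) {
    stop("translation of sequence '", substr(bases, 1, 20),
         "' yields zero residues", call. = FALSE)
  }
  c(hydrophobicity = mean(scale[res]),
    aromaticity = mean(res %in% c("F", "W", "Y")))
}

#' Dinucleotide odds ratios (rho statistic)
#'
#' For each dinucleotide XY in lexicographic order,
#' `rho_XY = f(XY) / (f_X * f_Y)` with overlapping dinucleotide frequency
#' f(XY) and mononucleotide frequencies f_X, f_Y. When `f_X * f_Y = 0` the
#' entry is 0 by convention.
#'
#' @inheritParams kmer_frequencies
#' @return named numeric vector of length 16.
#' @export
rho_statistic <- function(x) {
  bases <- seq_string(x)
  f1 <- kmer_frequencies(x, 1L)
  f2 <- kmer_frequencies(x, 2L)
  dn <- all_kmers(2L)
  expected <- f1[substring(dn, 1, 1)] * f1[substring(dn, 2, 2)]
  out <- ifelse(expected > 0, f2[dn] / expected, 0)
  stats::setNames(as.numeric(out), dn)
}

#' Mean dinucleotide property profile
#'
#' Entry j is the mean, over valid overlapping dinucleotide windows, of
#' property j's table value.
#'
#' @inheritParams kmer_frequencies
#' @param table 16 x m numeric matrix, rownames the dinucleotides (see
#'   [read_dinuc_properties()]).
#' @return numeric m-vector named by the table's columns.
#' @export
dinucleotide_property_profile <- function(x, table) {
  validate_dinuc_properties(table)
  bases <- seq_string(x)
  w <- valid_windows(bases, 2L)
  if (!length(w)) {
    stop("no valid dinucleotide window in sequence '",
         substr(bases, 1, 20), "'", call. = FALSE)
  }
  colMeans(table[w, , drop = FALSE])
}

#' Feature extraction configuration
#'
#' @param enabled_blocks subset of
#'   `c("zcurve","kmer","gc_cai","gc3s","aa_props","rho","dinuc_props")`,
#'   in the fixed catalogue order (the argument order is ignored).
#' @param codon_reference `codon_reference` table; required when `gc_cai`
#'   is enabled.
#' @param property_table 16 x m dinucleotide property matrix; defaults to
#'   the shipped synthetic table when `dinuc_props` is enabled.
#' @param hydropathy_scale named per-residue values for `aa_props`.
#' @return a `feature_config` list.
#' @export
feature_config <- function(enabled_blocks = c("zcurve", "kmer", "gc_cai",
                                              "gc3s", "aa_props", "rho",
                                              "dinuc_props"),
                           codon_reference = NULL,
                           property_table = NULL,
                           hydropathy_scale = kyte_doolittle()) {
  order_all <- c("zcurve", "kmer", "gc_cai", "gc3s", "aa_props", "rho",
                 "dinuc_props")
  bad <- setdiff(enabled_blocks, order_all)
  if (length(bad)) {
    stop("unknown feature block(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  blocks <- order_all[order_all %in% enabled_blocks]
  if ("gc_cai" %in% blocks) {
    if (is.null(codon_reference)) {
      stop("block 'gc_cai' requires a codon reference table", call. = FALSE)
    }
    validate_codon_reference(codon_reference)
  }
  if ("dinuc_props" %in% blocks) {
    if (is.null(property_table)) property_table <- read_dinuc_properties()
    validate_dinuc_properties(property_table)
  }
  structure(list(enabled_blocks = blocks,
                 codon_reference = codon_reference,
                 property_table = property_table,
                 hydropathy_scale = hydropathy_scale),
            class = "feature_config")
}

feature_block_fun <- function(block, config) {
  switch(block,
    zcurve = function(s) zcurve_features(s),
    kmer = function(s) c(kmer_frequencies(s, 1L),
                         kmer_frequencies(s, 2L),
                         kmer_frequencies(s, 3L)),
    gc_cai = function(s) c(gc = unname(gc_content(s)),
                           codon_usage_indices(s, config$codon_reference)),
    gc3s = function(s) stats::setNames(gc3s_composition(s),
                                       paste0("gc3s.", BASES)),
    aa_props = function(s) protein_properties(s, config$hydropathy_scale),
    rho = function(s) stats::setNames(rho_statistic(s),
                                      paste0("rho.", all_kmers(2L))),
    dinuc_props = function(s) {
      v <- dinucleotide_property_profile(s, config$property_table)
      stats::setNames(v, paste0("dp.", colnames(config$property_table)))
    },
    stop("unknown block: ", block, call. = FALSE))
}

#' Build the feature matrix for a set of sequences
#'
#' Rows follow input order; columns are concatenated block by block in the
#' fixed catalogue order (Z-curve 252, k-mer 84, GC/Fop/CAI 3, GC3s 4,
#' peptide properties 2, rho 16, dinucleotide properties m). With all
#' blocks enabled and the default 65-property table the width is 426.
#' Extraction is a pure function of (sequences, config).
#'
#' @param seqs a [dna_set()].
#' @param config a [feature_config()].
#' @return a `feature_matrix`: numeric matrix with row names the sequence
#'   ids and attributes `block_widths` (named integer vector) and `labels`
#'   (the sequences' labels).
#' @export
build_feature_matrix <- function(seqs, config) {
  stopifnot(inherits(seqs, "dna_set"), inherits(config, "feature_config"))
  if (length(seqs) == 0) stop("empty sequence set", call. = FALSE)
  funs <- lapply(config$enabled_blocks, feature_block_fun, config = config)
  names(funs) <- config$enabled_blocks
  rows <- vector("list", length(seqs))
  for (i in seq_along(seqs$id)) {
    s <- seqs$bases[i]
    row <- lapply(names(funs), function(b) {
      tryCatch(funs[[b]](s), error = function(e) {
        stop(sprintf("feature block '%s' failed for sequence '%s': %s",
                     b, seqs$id[i], conditionMessage(e)), call. = FALSE)
      })
    })
    rows[[i]] <- unlist(row)
  }
  widths <- lengths(lapply(names(funs), function(b) funs[[b]](seqs$bases[1])))
  mat <- do.call(rbind, rows)
  rownames(mat) <- seqs$id
  if (any(!is.finite(mat))) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)
    stop("non-finite feature value(s), e.g. sequence '",
         rownames(mat)[bad[1, 1]], "' column '", colnames(mat)[bad[1, 2]],
         "'", call. = FALSE)
  }
  structure(mat,
            block_widths = stats::setNames(as.integer(widths),
                                           config$enabled_blocks),
            labels = seqs$label,
            class = c("feature_matrix", class(mat)))
}

#' Read / write feature matrices as TSV
#'
#' Tab-separated values with a header row of column names and first column
#' `id` holding the sequence identifiers.
#'
#' @param path file path.
#' @return `read_feature_matrix`: a numeric matrix with row names.
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_feature_matrix
#' @param x a feature matrix (numeric matrix with row and column names).
#' @export
write_feature_matrix <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
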