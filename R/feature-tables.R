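# Auxiliary tables for the feature catalogue: hydropathy scale, codon
# reference (relative adaptiveness + optimal codons), dinucleotide property
# table. The genetic code itself comes from Biostrings::GENETIC_CODE.

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values used by [protein_properties()].
#'
#' @return named numeric vector over the 20 standard amino acids.
#' @export
kyte_doolittle <- function() {
  c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)
}

#' Build a codon reference from coding sequences
#'
#' Computes per-codon relative adaptiveness w = count / max(count within
#' amino-acid family) and flags the most frequent codon of each degenerate
#' family as optimal, from the frame-0 codon counts of a set of (presumed
#' coding) sequences. Conventions:
#' \itemize{
#'   \item stop codons get `w = NA` and are never optimal;
#'   \item a family observed at least once has its zero-count members given
#'     a pseudo-count of 0.5 before computing w, keeping w in (0, 1];
#'   \item a wholly unobserved family is excluded (`w = NA`, logged) and its
#'     codons are skipped by the CAI;
#'   \item single-codon families (ATG/Met, TGG/Trp) are never flagged
#'     optimal, so Fop's denominator excludes them as is standard.
#' }
#'
#' @param x a [dna_set()] of coding sequences.
#' @return a `codon_reference` data.frame with columns `codon`, `aa`, `w`,
#'   `optimal`.
#' @export
codon_reference_from_sequences <- function(x) {
  stopifnot(inherits(x, "dna_set"))
  code <- Biostrings::GENETIC_CODE
  counts <- integer(length(code))
  names(counts) <- names(code)
  for (s in x$bases) {
    cd <- valid_codons(s)
    if (length(cd)) {
      tab <- table(cd)
      counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
    }
  }
  ref <- data.frame(codon = names(code), aa = unname(code),
                    w = NA_real_, optimal = FALSE,
                    stringsAsFactors = FALSE)
  for (aa in unique(ref$aa)) {
    if (aa == "*") next
    i <- which(ref$aa == aa)
    cts <- as.numeric(counts[ref$codon[i]])
    if (sum(cts) == 0) {
      ias_log("codon family '", aa, "' unobserved in reference set; excluded",
              level = "WARN")
      next
    }
    cts[cts == 0] <- 0.5
    ref$w[i] <- cts / max(cts)
    if (length(i) > 1) ref$optimal[i] <- ref$w[i] == 1
  }
  class(ref) <- c("codon_reference", "data.frame")
  ref
}

validate_codon_reference <- function(ref) {
  stopifnot(is.data.frame(ref),
            all(c("codon", "aa", "w", "optimal") %in% names(ref)))
  w <- ref$w[!is.na(ref$w)]
  if (any(w <= 0 | w > 1)) {
    stop("codon reference: relative adaptiveness w must lie in (0, 1]",
         call. = FALSE)
  }
  invisible(ref)
}

#' Read / write a codon reference table
#'
#' Tab-separated plain text with header `codon aa w optimal`.
#'
#' @param path file path.
#' @return `read_codon_reference`: a `codon_reference` data.frame.
#' @export
read_codon_reference <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ref <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  ref$optimal <- as.logical(ref$optimal)
  validate_codon_reference(ref)
  class(ref) <- c("codon_reference", "data.frame")
  ref
}

#' @rdname read_codon_reference
#' @param ref a `codon_reference` data.frame.
#' @export
write_codon_reference <- function(ref, path) {
  validate_codon_reference(ref)
  utils::write.table(ref, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Dinucleotide property table
#'
#' Reads a 16-row tab-separated table (first column the dinucleotide, one
#' numeric column per property). The package ships a SYNTHETIC default table
#' of 65 properties (`dinuc_properties_synthetic.tsv`): deterministic
#' stand-in values on physicochemically plausible scales, NOT measured
#' dinucleotide properties. Tests are table-independent by design.
#'
#' @param path path to a property table; default the shipped synthetic table.
#' @return 16 x m numeric matrix, rownames the dinucleotides.
#' @export
read_dinuc_properties <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dinuc_properties_synthetic.tsv",
                        package = "iaspls", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  validate_dinuc_properties(m)
  m
}

validate_dinuc_properties <- function(table) {
  if (!is.matrix(table) || !is.numeric(table)) {
    stop("property table must be a numeric matrix", call. = FALSE)
  }
  missing <- setdiff(all_kmers(2L), rownames(table))
  if (length(missing)) {
    stop("property table missing dinucleotide(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(table)
}
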