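#' Sequence container for short DNA fragments
#'
#' A `dna_set` stores short DNA sequences (putative reading orientation,
#' uppercase) together with their identifiers and optional class labels
#' (+1 coding, -1 noncoding, `NA` unknown). Sequences containing more than
#' `max_ambiguous` fraction of non-ACGT characters are rejected: downstream
#' k-mer statistics degrade silently otherwise.
#'
#' @param id character vector of identifiers.
#' @param bases character vector of sequences (any case; IUPAC codes allowed).
#' @param label optional numeric/character labels; coerced to +1/-1
#'   (accepts `+1`/`-1`, `"coding"`/`"noncoding"`).
#' @param max_ambiguous maximum tolerated fraction of non-ACGT characters
#'   per sequence (default 0.1).
#' @return an object of class `dna_set`: a list with components `id`,
#'   `bases` (uppercase) and `label` (integer, `NA` where unknown).
#' @export
dna_set <- function(id, bases, label = NULL, max_ambiguous = 0.1) {
  id <- as.character(id)
  bases <- toupper(as.character(bases))
  if (length(id) != length(bases)) {
    stop("`id` and `bases` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(id)) {
    stop("duplicate sequence identifiers: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  empty <- !nzchar(bases)
  if (any(empty)) {
    stop("empty sequence for record(s): ", paste(id[empty], collapse = ", "),
         call. = FALSE)
  }
  bad_chars <- grepl("[^A-Z]", bases)
  if (any(bad_chars)) {
    stop("non-letter characters in record(s): ",
         paste(id[bad_chars], collapse = ", "), call. = FALSE)
  }
  n_amb <- nchar(bases) - nchar(gsub("[^ACGT]", "", bases))
  frac <- n_amb / nchar(bases)
  if (any(frac > max_ambiguous)) {
    bad <- id[frac > max_ambiguous]
    stop(sprintf("record(s) with > %.0f%% ambiguous bases rejected: %s",
                 100 * max_ambiguous, paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  label <- normalize_labels(label, n = length(id))
  structure(list(id = id, bases = bases, label = label), class = "dna_set")
}

normalize_labels <- function(label, n) {
  if (is.null(label)) return(rep(NA_integer_, n))
  if (is.character(label) || is.factor(label)) {
    label <- as.character(label)
    out <- ifelse(label %in% c("coding", "+1", "1"), 1L,
                  ifelse(label %in% c("noncoding", "non-coding", "-1"), -1L,
                         NA_integer_))
    if (any(is.na(out) & !is.na(label))) {
      stop("unrecognized label value(s): ",
           paste(unique(label[is.na(out) & !is.na(label)]), collapse = ", "),
           call. = FALSE)
    }
  } else {
    out <- as.integer(label)
    if (any(!out %in% c(-1L, 1L) & !is.na(out))) {
      stop("labels must be +1 (coding) or -1 (noncoding)", call. = FALSE)
    }
  }
  if (length(out) != n) stop("label length mismatch", call. = FALSE)
  out
}

#' @export
length.dna_set <- function(x) length(x$id)

#' @export
print.dna_set <- function(x, ...) {
  cat(sprintf("dna_set with %d sequence(s); lengths %d-%d nt; %d labelled\n",
              length(x), min(nchar(x$bases)), max(nchar(x$bases)),
              sum(!is.na(x$label))))
  invisible(x)
}

#' @export
`[.dna_set` <- function(x, i) {
  structure(list(id = x$id[i], bases = x$bases[i], label = x$label[i]),
            class = "dna_set")
}

#' Read DNA sequences from a FASTA file
#'
#' @param path path to a FASTA file (wrapped or unwrapped lines).
#' @inheritParams dna_set
#' @return a [dna_set] in file order, sequences uppercased, labels `NA`.
#' @export
read_fasta <- function(path, max_ambiguous = 0.1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(ss))
  w <- Biostrings::width(ss)
  if (any(w == 0)) {
    stop("empty sequence for record(s): ", paste(ids[w == 0], collapse = ", "),
         call. = FALSE)
  }
  dna_set(ids, as.character(ss), max_ambiguous = max_ambiguous)
}

#' Write a dna_set to FASTA
#'
#' @param x a [dna_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "dna_set"))
  ss <- Biostrings::DNAStringSet(x$bases)
  names(ss) <- x$id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read / write two-column label files
#'
#' Plain-text label files have two whitespace-separated columns:
#' sequence id and label (`+1`/`-1` or `coding`/`noncoding`).
#'
#' @param path file path.
#' @return `read_labels`: a data.frame with columns `id` and `label`
#'   (integer +1/-1).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("id", "label"))
  data.frame(id = as.character(tab$id),
             label = normalize_labels(tab$label, nrow(tab)),
             stringsAsFactors = FALSE)
}

#' @rdname read_labels
#' @param x a [dna_set] with labels, or a data.frame with `id` and `label`.
#' @export
write_labels <- function(x, path) {
  if (inherits(x, "dna_set")) x <- data.frame(id = x$id, label = x$label)
  stopifnot(all(c("id", "label") %in% names(x)))
  utils::write.table(x[, c("id", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Attach labels from a label table to a dna_set
#'
#' @param x a [dna_set].
#' @param labels data.frame as returned by [read_labels()].
#' @return `x` with labels filled in; unmatched ids raise an error.
#' @export
set_labels <- function(x, labels) {
  stopifnot(inherits(x, "dna_set"))
  idx <- match(x$id, labels$id)
  if (anyNA(idx)) {
    stop("no label for sequence(s): ",
         paste(utils::head(x$id[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  x$label <- labels$label[idx]
  x
}

#' Length classes for short sequences
#'
#' The default bins tile 60-400 nt: `[60,100)`, `[100,200)`, `[200,300)` and
#' `[300,400]`. All bins are half-open on the right except the last, which is
#' closed at 400 (matching the bracket notation of the evaluation protocol).
#'
#' @param breaks integer vector of bin edges (default `c(60,100,200,300,400)`).
#' @return a data.frame of class `length_bins` with columns `low`, `high`,
#'   `name` and `closed_top` (TRUE only for the last bin).
#' @export
length_bins <- function(breaks = c(60L, 100L, 200L, 300L, 400L)) {
  breaks <- as.integer(breaks)
  if (length(breaks) < 2 || is.unsorted(breaks, strictly = TRUE)) {
    stop("`breaks` must be strictly increasing with at least two values",
         call. = FALSE)
  }
  nb <- length(breaks) - 1L
  low <- breaks[-length(breaks)]
  high <- breaks[-1]
  name <- c(if (nb > 1) sprintf("[%d,%d)", low[-nb], high[-nb]),
            sprintf("[%d,%d]", low[nb], high[nb]))
  structure(data.frame(low = low, high = high, name = name,
                       closed_top = c(rep(FALSE, nb - 1L), TRUE),
                       stringsAsFactors = FALSE),
            class = c("length_bins", "data.frame"))
}

#' Assign sequences (or lengths) to length classes
#'
#' Boundary lengths belong to the upper bin (half-open convention), except
#' the overall maximum which belongs to the top, closed bin.
#'
#' @param x a [dna_set] or an integer vector of lengths (nt).
#' @param bins a [length_bins()] table.
#' @return character vector of bin names, one per sequence/length.
#' @export
assign_length_class <- function(x, bins = length_bins()) {
  len <- if (inherits(x, "dna_set")) nchar(x$bases) else as.integer(x)
  lo <- min(bins$low)
  hi <- max(bins$high)
  out_of_range <- len < lo | len > hi
  if (any(out_of_range)) {
    stop(sprintf("length(s) outside [%d,%d] nt: %s", lo, hi,
                 paste(utils::head(len[out_of_range], 5), collapse = ", ")),
         call. = FALSE)
  }
  # findInterval with left-closed bins; the top edge folds into the last bin
  idx <- findInterval(len, c(bins$low, hi), rightmost.closed = TRUE)
  bins$name[idx]
}
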