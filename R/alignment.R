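#' Multiple sequence alignment containers
#'
#' Alignments are stored as plain character matrices: one row per taxon
#' (rownames carry the labels), one column per alignment site, entries in
#' `{A,C,G,T,N,-}`. Most functions in the package accept anything coercible
#' by [as_alignment()].
#'
#' @param x a character matrix, a named character vector of equal-length
#'   sequences, or a [Biostrings::DNAStringSet].
#' @return a character matrix with unique rownames, class `"dna_alignment"`.
#' @export
as_alignment <- function(x) {
  if (inherits(x, "dna_alignment")) return(x)
  if (inherits(x, "DNAStringSet") || inherits(x, "XStringSet")) {
    x <- stats::setNames(as.character(x), names(x))
  }
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    lens <- nchar(x)
    if (length(unique(lens)) != 1L) {
      stop("alignment rows must all have equal length", call. = FALSE)
    }
    m <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
    rownames(m) <- names(x)
    x <- m
  }
  if (!is.matrix(x) || !is.character(x)) {
    stop("cannot interpret input as an alignment", call. = FALSE)
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("seq", seq_len(nrow(x)))
  if (anyDuplicated(rownames(x))) {
    stop("taxon labels must be unique", call. = FALSE)
  }
  x[] <- toupper(x)
  class(x) <- c("dna_alignment", class(matrix()))
  x
}

#' @rdname as_alignment
#' @param path path to a FASTA file of aligned sequences.
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  as_alignment(stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss))))
}

#' @rdname as_alignment
#' @param aln an alignment.
#' @export
write_alignment <- function(aln, path) {
  aln <- as_alignment(aln)
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(path)
}

# characters treated as missing for all site-based statistics
.gap_chars <- c("-", "N", "?")

# per-column summary used by the popgen statistics: base counts and
# gap/N counts, computed once and sliced by windows afterwards
aln_profile <- function(aln) {
  aln <- as_alignment(aln)
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) colSums(unclass(aln) == b),
                   numeric(ncol(aln)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L,
                                             dimnames = list(NULL, bases))
  gapn <- nrow(aln) - rowSums(counts)
  list(counts = counts, gapn = gapn, n = nrow(aln), length = ncol(aln))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
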