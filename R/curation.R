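#' Curate the coding genes of a plastome record
#'
#' Applies, in order, the curation rules used when preparing plastid
#' annotations for submission: genes whose spliced CDS is not a multiple
#' of 3, lacks an accepted start codon, or lacks a terminal stop codon are
#' flagged `removed_missing_start_stop`; internal stop codons are masked
#' to `NNN` and the gene flagged `internal_stop_masked`; genes annotated
#' more than once in the record are flagged `multi_copy`; genes containing
#' `N` (from the assembly or from masking) that pass the other checks are
#' flagged `contains_N`; everything else is `ok`. No gene is dropped —
#' failures become flags so downstream filters stay auditable.
#'
#' @param x a `plastome_record`, or an existing `gene_set` to re-curate
#'   (curation is idempotent).
#' @param start_codons accepted start codons; plastid genes commonly use
#'   GTG in addition to ATG.
#' @param ... passed between methods.
#' @return a tibble of class `"gene_set"` with columns `gene` (normalised
#'   name), `sequence`, `flag`, and attribute `species_id`.
#' @export
curate_cds <- function(x, start_codons = c("ATG", "GTG"), ...) {
  UseMethod("curate_cds")
}

# annotation dialects vary: match names case-insensitively and drop
# trailing locus-tag style suffixes like "_2"
normalize_gene_name <- function(x) {
  sub("_[0-9]+$", "", tolower(x))
}

stop_codons <- c("TAA", "TAG", "TGA")

curate_one <- function(seq, start_codons) {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L %% 3L != 0L || L < 6L) {
    return(list(seq = seq, flag = "removed_missing_start_stop"))
  }
  cods <- split_codons(seq)
  if (!(cods[1L] %in% start_codons) ||
      !(cods[length(cods)] %in% stop_codons)) {
    return(list(seq = seq, flag = "removed_missing_start_stop"))
  }
  internal <- cods[-length(cods)]
  bad <- which(internal %in% stop_codons)
  if (length(bad) > 0) {
    cods[bad] <- "NNN"
    return(list(seq = paste(cods, collapse = ""),
                flag = "internal_stop_masked"))
  }
  if (grepl("N", seq, fixed = TRUE)) {
    return(list(seq = seq, flag = "contains_N"))
  }
  list(seq = seq, flag = "ok")
}

#' @rdname curate_cds
#' @export
curate_cds.plastome_record <- function(x, start_codons = c("ATG", "GTG"), ...) {
  cds <- x$features[x$features$type == "CDS", ]
  fids <- unique(cds$feature_id)
  rows <- purrr::map(fids, function(fid) {
    gene <- normalize_gene_name(cds$gene[cds$feature_id == fid][1L])
    tibble::tibble(gene = gene,
                   sequence = extract_feature_seq(x, fid))
  })
  tbl <- dplyr::bind_rows(rows)
  if (nrow(tbl) == 0) {
    tbl <- tibble::tibble(gene = character(0), sequence = character(0))
  }
  curate_gene_table(tbl, x$id, start_codons)
}

#' @rdname curate_cds
#' @export
curate_cds.gene_set <- function(x, start_codons = c("ATG", "GTG"), ...) {
  out <- curate_gene_table(tibble::tibble(gene = x$gene,
                                          sequence = x$sequence),
                           attr(x, "species_id"), start_codons)
  # idempotence: a gene masked on the first pass carries N but no internal
  # stop, so a re-run would see it as contains_N; keep the original flag
  # when the sequence is unchanged
  same <- out$sequence == x$sequence[match(out$gene, x$gene)]
  was_masked <- x$flag[match(out$gene, x$gene)] == "internal_stop_masked"
  out$flag[same & was_masked & out$flag == "contains_N"] <-
    "internal_stop_masked"
  out
}

curate_gene_table <- function(tbl, species_id, start_codons) {
  cur <- purrr::map(tbl$sequence, curate_one, start_codons = start_codons)
  out <- tibble::tibble(gene = tbl$gene,
                        sequence = purrr::map_chr(cur, "seq"),
                        flag = purrr::map_chr(cur, "flag"))
  dup <- out$gene[duplicated(out$gene)]
  out$flag[out$gene %in% dup] <- "multi_copy"
  out <- dplyr::arrange(out, .data$gene)
  attr(out, "species_id") <- species_id
  class(out) <- c("gene_set", class(out))
  out
}

#' Build a gene_set directly from named sequences
#'
#' @param sequences named character vector `gene -> CDS sequence`.
#' @param species_id species label.
#' @inheritParams curate_cds
#' @export
gene_set <- function(sequences, species_id,
                     start_codons = c("ATG", "GTG")) {
  curate_gene_table(
    tibble::tibble(gene = normalize_gene_name(names(sequences)),
                   sequence = unname(sequences)),
    species_id, start_codons)
}

#' Genes shared single-copy and N-free across all species
#'
#' Returns, in deterministic alphabetical order, the genes that are
#' present exactly once in every supplied gene set (multi-copy genes and
#' genes removed by curation are treated as absent) and whose sequence
#' contains no `N` in any species.
#'
#' @param gene_sets a list of `gene_set` objects (>= 2).
#' @return a character vector of gene names; empty (with a warning) when
#'   the intersection is empty.
#' @export
shared_single_copy_genes <- function(gene_sets) {
  if (length(gene_sets) < 2L) {
    stop("need at least 2 gene sets", call. = FALSE)
  }
  eligible <- purrr::map(gene_sets, function(gs) {
    keep <- gs$flag %in% c("ok")
    gs$gene[keep]
  })
  shared <- purrr::reduce(eligible, intersect)
  shared <- sort(shared)
  if (length(shared) == 0L) {
    warning("no gene is single-copy and N-free in every species",
            call. = FALSE)
  }
  shared
}
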