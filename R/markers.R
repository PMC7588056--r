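#' Collect well-aligned blocks of an alignment
#'
#' A column is well aligned when its gap/`N` fraction is at most
#' `max_gap_fraction`. Maximal runs of well-aligned columns of length at
#' least `min_length` become blocks; shorter runs are dropped. Each block
#' carries its full Tajima's D component set, computed over the block's
#' columns under the exclude-column gap policy.
#'
#' @param aln an alignment.
#' @param min_length minimum block length in columns.
#' @param max_gap_fraction per-column gap tolerance.
#' @return a tibble of class `"aligned_blocks"`: `block_id`, `start`,
#'   `end` (0-based half-open), `length`, `gap_fraction` (cell-wise over
#'   the block), `usable_sites`, `S`, `pi_per_site`, `theta_w`, `D`,
#'   `d_defined`. Construction parameters are stored in attributes.
#' @export
collect_blocks <- function(aln, min_length = 150L, max_gap_fraction = 0.1) {
  aln <- as_alignment(aln)
  prof <- aln_profile(aln)
  good <- prof$gapn / prof$n <= max_gap_fraction
  r <- rle(good)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  if (!any(keep)) {
    warning("no block satisfies the length/gap criteria", call. = FALSE)
  }
  rows <- purrr::map2(starts[keep], ends[keep], function(s, e) {
    sub <- unclass(aln)[, s:e, drop = FALSE]
    tc <- suppressWarnings(tajimas_d(sub))
    tibble::tibble(start = s - 1L, end = e, length = e - s + 1L,
                   gap_fraction = sum(prof$gapn[s:e]) / (prof$n * (e - s + 1L)),
                   usable_sites = tc$usable_sites, S = tc$S,
                   pi_per_site = tc$pi_per_site, theta_w = tc$theta_w,
                   D = tc$D, d_defined = tc$defined)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(start = integer(0), end = integer(0),
                          length = integer(0), gap_fraction = numeric(0),
                          usable_sites = integer(0), S = integer(0),
                          pi_per_site = numeric(0), theta_w = numeric(0),
                          D = numeric(0), d_defined = logical(0))
  }
  out <- dplyr::mutate(out, block_id = dplyr::row_number(),
                       .before = 1L)
  attr(out, "params") <- list(min_length = min_length,
                              max_gap_fraction = max_gap_fraction)
  class(out) <- c("aligned_blocks", class(out))
  out
}

#' Select blocks passing the Tajima's D neutrality threshold
#'
#' Retains, in order, the blocks with a defined D strictly greater than
#' `d_threshold` (default -0.5). Blocks with undefined D are never
#' selectable. An optional symmetric upper bound (`|D| < bound` style)
#' can be enabled via `upper_threshold`.
#'
#' @param blocks a [collect_blocks()] result.
#' @param d_threshold lower D threshold (strict).
#' @param upper_threshold optional strict upper bound on D (default
#'   `NULL`, i.e. off).
#' @return the selected subset, same class, with the thresholds recorded
#'   in attributes.
#' @export
select_blocks <- function(blocks, d_threshold = -0.5,
                          upper_threshold = NULL) {
  sel <- blocks$d_defined & !is.na(blocks$D) & blocks$D > d_threshold
  if (!is.null(upper_threshold)) {
    sel <- sel & blocks$D < upper_threshold
  }
  out <- blocks[sel, ]
  attr(out, "params") <- attr(blocks, "params")
  attr(out, "d_threshold") <- d_threshold
  attr(out, "upper_threshold") <- upper_threshold
  class(out) <- unique(c("aligned_blocks", class(out)))
  out
}

#' Genotype matrix of segregating sites from selected blocks
#'
#' Concatenates the selected blocks, drops every column containing a gap
#' or `N`, keeps only segregating columns, and returns the taxa x sites
#' base-call matrix together with a selection report. Column names record
#' the source as `block<id>:<alignment column>` (0-based).
#'
#' @param aln the alignment the blocks were collected from.
#' @param selected a [select_blocks()] result (>= 1 block).
#' @return a list of class `"genotype_matrix"`: `matrix` (character,
#'   taxa x sites), `sites` (tibble `block_id`, `column`), `report` (class
#'   `"selection_report"`: `n_blocks_selected`, `total_length`,
#'   `n_segregating`, `d_threshold`, `proximal_genes`).
#' @export
build_genotype_matrix <- function(aln, selected) {
  aln <- as_alignment(aln)
  if (nrow(selected) < 1L) stop("no selected blocks", call. = FALSE)
  cols <- list(); src <- list()
  for (i in seq_len(nrow(selected))) {
    idx <- (selected$start[i] + 1L):selected$end[i]
    cols[[i]] <- idx
    src[[i]] <- tibble::tibble(block_id = selected$block_id[i],
                               column = idx - 1L)
  }
  idx <- unlist(cols)
  src <- dplyr::bind_rows(src)
  sub <- unclass(aln)[, idx, drop = FALSE]
  prof <- aln_profile(sub)
  keep <- usable_columns(prof) & column_is_segregating(prof$counts)
  if (!any(keep)) {
    stop("no segregating site in the selected blocks", call. = FALSE)
  }
  m <- sub[, keep, drop = FALSE]
  src <- src[keep, ]
  colnames(m) <- sprintf("block%d:%d", src$block_id, src$column)
  report <- structure(
    list(n_blocks_selected = nrow(selected),
         total_length = sum(selected$length),
         n_segregating = ncol(m),
         d_threshold = attr(selected, "d_threshold") %||% NA_real_,
         proximal_genes = character(0)),
    class = "selection_report")
  structure(list(matrix = m, sites = src, report = report),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d taxa x %d segregating sites from %d block(s), %d bp selected\n",
              nrow(x$matrix), ncol(x$matrix),
              x$report$n_blocks_selected, x$report$total_length))
  invisible(x)
}

#' @export
glance.selection_report <- function(x, ...) {
  tibble::tibble(n_blocks_selected = x$n_blocks_selected,
                 total_length = x$total_length,
                 n_segregating = x$n_segregating,
                 d_threshold = x$d_threshold)
}

#' Genes proximal to the selected blocks
#'
#' Maps each selected block into reference coordinates through a
#' column-to-reference projection and reports the annotated genes
#' overlapping or lying within `max_distance` of any block, deduplicated
#' and ordered by genomic position. The projection is an integer vector
#' with one entry per alignment column giving the 0-based reference
#' position (NA where the reference is gapped); pass
#' `projection = "identity"` when alignment columns are reference
#' positions already.
#'
#' @param selected a [select_blocks()] result.
#' @param annotation a data frame with columns `gene`, `start`, `end`
#'   (0-based half-open reference coordinates), e.g. derived from a
#'   `plastome_record`'s features.
#' @param projection integer vector (length = alignment columns) or
#'   `"identity"`.
#' @param max_distance maximum gap between block and gene (bp).
#' @return a character vector of gene names.
#' @export
proximal_genes <- function(selected, annotation, projection,
                           max_distance = 1000L) {
  if (missing(projection) || is.null(projection)) {
    stop("a column-to-reference projection map is required", call. = FALSE)
  }
  if (inherits(annotation, "plastome_record")) {
    annotation <- annotation$features |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(start = min(.data$start), end = max(.data$end),
                       .groups = "drop")
  }
  hits <- list()
  for (i in seq_len(nrow(selected))) {
    cols <- (selected$start[i] + 1L):selected$end[i]
    ref <- if (identical(projection, "identity")) cols - 1L
           else projection[cols]
    ref <- ref[!is.na(ref)]
    if (length(ref) == 0L) next
    lo <- min(ref) - max_distance
    hi <- max(ref) + max_distance
    sel <- annotation$end > lo & annotation$start < hi
    hits[[i]] <- annotation[sel, ]
  }
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0L) return(character(0))
  out <- dplyr::distinct(out, .data$gene, .keep_all = TRUE)
  out <- dplyr::arrange(out, .data$start)
  out$gene
}

#' Write selected blocks as BED
#'
#' @param blocks an `aligned_blocks` tibble.
#' @param path output path.
#' @param chrom BED chromosome name (alignment-column space).
#' @export
write_blocks_bed <- function(blocks, path, chrom = "alignment") {
  utils::write.table(
    data.frame(chrom = chrom, start = blocks$start, end = blocks$end,
               name = sprintf("block%d", blocks$block_id),
               score = ifelse(blocks$d_defined,
                              sprintf("%.4f", blocks$D), ".")),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix as TSV (taxa rows, site columns)
#'
#' @param gm a [build_genotype_matrix()] result.
#' @param path output path.
#' @export
write_genotype_matrix <- function(gm, path) {
  df <- as.data.frame(gm$matrix)
  df <- cbind(taxon = rownames(gm$matrix), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
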