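# Quadripartite (LSC / IRb / SSC / IRa) structure detection.
#
# The two IR copies are exact reverse complements, so the problem is to
# find the longest pair of disjoint, exactly reverse-complementary
# repeats on the circular sequence. A k-mer seed-and-extend search is
# used: every k-mer is hashed, seeds pair a k-mer with an occurrence of
# its reverse complement, and each seed is extended maximally in both
# directions on the doubled sequence. All seeds of one repeat pair share
# the invariant (start_a + end_b) mod L, which lets extensions be
# deduplicated cheaply.

# extend an exact reverse-complement match seeded at (a, b, k) on the
# doubled sequence; coordinates 0-based on the original circle
extend_ir_seed <- function(s2, L, a, b, k, comp) {
  # left of a pairs with right of b; right of a with left of b
  left <- 0L
  while (left < L %/% 2) {
    pa <- a - left - 1L; pb <- b + k + left
    if (pa < 0) pa <- pa + L
    if (pb >= 2 * L - 1L) break
    if (substr(s2, pa + 1L, pa + 1L) !=
        comp[substr(s2, pb + 1L, pb + 1L)]) break
    left <- left + 1L
  }
  right <- 0L
  while (right < L %/% 2) {
    pa <- a + k + right; pb <- b - right - 1L
    if (pb < 0) pb <- pb + L
    if (pa >= 2 * L - 1L) break
    if (substr(s2, pa + 1L, pa + 1L) !=
        comp[substr(s2, pb + 1L, pb + 1L)]) break
    right <- right + 1L
  }
  len <- k + left + right
  list(a = (a - left) %% L, b = (b - right) %% L, len = min(len, L %/% 2))
}

# do circular intervals [s1, s1+l1) and [s2, s2+l2) overlap on a circle
# of size L?
circ_overlap <- function(s1, l1, s2, l2, L) {
  cols1 <- (s1 + seq_len(l1) - 1L) %% L
  cols2 <- (s2 + seq_len(l2) - 1L) %% L
  length(intersect(cols1, cols2)) > 0
}

#' Detect the quadripartite structure of a plastome
#'
#' Finds the longest pair of disjoint, exactly reverse-complementary
#' repeats of length at least `min_ir` on the circular sequence and labels
#' the longer single-copy interval between them LSC and the shorter SSC.
#' Following the conventional orientation, IRb is the repeat copy that
#' follows the LSC. Among equal-length maximal repeat pairs the pair
#' minimising the LSC start is chosen, so the result is deterministic.
#'
#' @param x a `plastome_record` or a DNA sequence string; treated as
#'   circular.
#' @param min_ir minimum IR length (bp); sequence must be >= `4 * min_ir`.
#' @return a list of class `"quadripartite"` with elements `lsc`, `irb`,
#'   `ssc`, `ira`, each `c(start, end)` 0-based half-open on the circular
#'   sequence (`end` may exceed the length to denote wrap-around), plus
#'   `genome_length`.
#' @export
detect_quadripartite <- function(x, min_ir = 1000L) {
  seq <- if (inherits(x, "plastome_record")) x$sequence else toupper(x)
  L <- nchar(seq)
  if (L < 4L * min_ir) {
    stop("sequence shorter than 4 * min_ir", call. = FALSE)
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  s2 <- paste0(seq, substr(seq, 1L, L - 1L))
  k <- min(min_ir, 24L)
  starts <- seq_len(L)  # 1-based starts of k-mers on the circle
  kmers <- substring(s2, starts, starts + k - 1L)
  rckmers <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  pos_by_kmer <- split(seq_len(L) - 1L, kmers)  # 0-based positions

  seen <- new.env(parent = emptyenv())
  best <- NULL
  for (a in seq_len(L) - 1L) {
    mates <- pos_by_kmer[[rckmers[a + 1L]]]
    if (is.null(mates)) next
    for (b in mates) {
      if (b == a) next
      key <- as.character((a + b + k) %% L)
      if (!is.null(seen[[key]])) next
      ext <- extend_ir_seed(s2, L, a, b, k, comp)
      seen[[key]] <- TRUE
      if (ext$len < min_ir) next
      # the two copies of the pair must be disjoint on the circle
      if (circ_overlap(ext$a, ext$len, ext$b, ext$len, L)) next
      cand <- ext
      if (is.null(best) || cand$len > best$len ||
          (cand$len == best$len && min(cand$a, cand$b) < min(best$a, best$b))) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    stop("no inverted repeat of length >= min_ir found", call. = FALSE)
  }
  # order the two copies along the circle and carve the single-copy gaps
  p <- best$a; q <- best$b; m <- best$len
  gap_after <- function(s_end, nxt_start) (nxt_start - s_end) %% L
  g1 <- gap_after((p + m) %% L, q)   # gap from end of copy at p to copy at q
  g2 <- gap_after((q + m) %% L, p)
  if (g1 >= g2) {
    # LSC is the gap following copy p; walking the circle from the LSC
    # the next repeat copy (at q) is IRb, then SSC, then IRa (at p)
    lsc_start <- (p + m) %% L; lsc_len <- g1
    ssc_start <- (q + m) %% L; ssc_len <- g2
    irb_start <- q; ira_start <- p
  } else {
    lsc_start <- (q + m) %% L; lsc_len <- g2
    ssc_start <- (p + m) %% L; ssc_len <- g1
    irb_start <- p; ira_start <- q
  }
  iv <- function(s, l) c(start = s, end = s + l)
  structure(list(lsc = iv(lsc_start, lsc_len), irb = iv(irb_start, m),
                 ssc = iv(ssc_start, ssc_len), ira = iv(ira_start, m),
                 genome_length = L),
            class = "quadripartite")
}

#' @export
print.quadripartite <- function(x, ...) {
  for (r in c("lsc", "irb", "ssc", "ira")) {
    cat(sprintf("%s: [%d, %d)  (%d bp)\n", toupper(r), x[[r]]["start"],
                x[[r]]["end"], x[[r]]["end"] - x[[r]]["start"]))
  }
  invisible(x)
}

#' Write quadripartite intervals as BED
#'
#' @param qs a [detect_quadripartite()] result.
#' @param path output path; intervals wrapping the origin are split into
#'   two BED lines.
#' @param chrom chromosome name for the BED records.
#' @export
write_quadripartite_bed <- function(qs, path, chrom = "plastome") {
  L <- qs$genome_length
  rows <- purrr::imap(qs[c("lsc", "irb", "ssc", "ira")], function(iv, nm) {
    s <- iv["start"]; e <- iv["end"]
    if (e <= L) {
      data.frame(chrom = chrom, start = s, end = e, name = toupper(nm))
    } else {
      rbind(data.frame(chrom = chrom, start = s, end = L, name = toupper(nm)),
            data.frame(chrom = chrom, start = 0, end = e - L,
                       name = toupper(nm)))
    }
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Summarise plastome assemblies (per-species lengths plus a mean row)
#'
#' Either pass a prebuilt table of per-species lengths (columns `species`,
#' `genome_bp`, `lsc_bp`, `irb_bp`, `ssc_bp`, `ira_bp`, optionally gene
#' counts), or parallel lists of records, structures and gene sets from
#' which the table is derived. A `Mean (bp)` row with two-decimal rounding
#' is appended, matching the layout of published assembly summaries.
#'
#' @param records a data frame as above, or a list of `plastome_record`s.
#' @param structures list of [detect_quadripartite()] results (parallel to
#'   `records`; required when `records` is a list).
#' @param gene_sets optional parallel list of `gene_set`s, adding an
#'   `n_genes` column.
#' @return a tibble with one row per species plus the mean row.
#' @export
summarize_assemblies <- function(records, structures = NULL,
                                 gene_sets = NULL) {
  if (is.data.frame(records)) {
    tbl <- tibble::as_tibble(records)
  } else {
    if (is.null(structures) || length(structures) != length(records)) {
      stop("records and structures must be parallel lists", call. = FALSE)
    }
    if (!is.null(gene_sets) && length(gene_sets) != length(records)) {
      stop("gene_sets must be parallel to records", call. = FALSE)
    }
    tbl <- dplyr::bind_rows(purrr::map(seq_along(records), function(i) {
      r <- records[[i]]; q <- structures[[i]]
      len <- function(iv) unname(iv["end"] - iv["start"])
      row <- tibble::tibble(species = r$id, genome_bp = r$length,
                            lsc_bp = len(q$lsc), irb_bp = len(q$irb),
                            ssc_bp = len(q$ssc), ira_bp = len(q$ira))
      if (!is.null(gene_sets)) {
        row$n_genes <- sum(gene_sets[[i]]$flag != "removed_missing_start_stop")
      }
      row
    }))
  }
  num_cols <- names(tbl)[vapply(tbl, is.numeric, logical(1))]
  mean_row <- tbl[1L, ]
  mean_row[["species"]] <- "Mean (bp)"
  for (nc in num_cols) mean_row[[nc]] <- round(mean(tbl[[nc]]), 2)
  dplyr::bind_rows(tbl, mean_row)
}
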