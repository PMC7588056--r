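#' Pair up codons of two codon-aligned sequences
#'
#' Codon pairs containing a gap character, an `N`, or a stop codon in
#' either member are dropped; sequence lengths must be equal and divisible
#' by 3 (frame-shifted input is rejected).
#'
#' @param gene_a,gene_b codon-aligned DNA strings.
#' @return a tibble with columns `codon_a`, `codon_b`.
#' @export
pair_codons <- function(gene_a, gene_b) {
  if (nchar(gene_a) != nchar(gene_b)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  ca <- split_codons(toupper(gene_a))
  cb <- split_codons(toupper(gene_b))
  bad <- grepl("[-N?]", ca) | grepl("[-N?]", cb) |
    ca %in% stop_codons | cb %in% stop_codons
  tibble::tibble(codon_a = ca[!bad], codon_b = cb[!bad])
}

#' Nei-Gojobori (1986) synonymous and nonsynonymous rates for a codon pair list
#'
#' Site counts: the synonymous site count of a codon is the expected
#' fraction of its 9 possible single-nucleotide changes that are
#' synonymous (changes to stop codons count as nonsynonymous); per pair
#' the counts of the two codons are averaged. Difference counts: codon
#' pairs differing at several positions are averaged over all minimal
#' mutational pathways, excluding pathways through stop codons. Rates are
#' Jukes-Cantor corrected: `Ks = -(3/4) ln(1 - (4/3) ps)`; the pair is
#' flagged invalid when `ps >= 3/4` (or `pn >= 3/4`), where the
#' correction is undefined.
#'
#' @param pairs a tibble from [pair_codons()], or two sequences given as
#'   `pairs` and `gene_b`.
#' @param gene_b optional second sequence (then `pairs` is the first).
#' @return a one-row tibble of class `"ks_result"`: `n_codons`,
#'   `syn_sites`, `nonsyn_sites`, `syn_diffs`, `nonsyn_diffs`, `ps`, `pn`,
#'   `ks`, `ka`, `valid`.
#' @export
ng86_ks <- function(pairs, gene_b = NULL) {
  if (!is.null(gene_b)) pairs <- pair_codons(pairs, gene_b)
  if (nrow(pairs) < 1L) stop("no comparable codon pairs", call. = FALSE)
  tab <- codon_tables()
  pm <- pair_count_matrices()
  ia <- match(pairs$codon_a, tab$codons)
  ib <- match(pairs$codon_b, tab$codons)
  syn_sites <- sum((tab$syn_sites[ia] + tab$syn_sites[ib]) / 2)
  nonsyn_sites <- sum((tab$nonsyn_sites[ia] + tab$nonsyn_sites[ib]) / 2)
  idx <- cbind(ia, ib)
  syn_diffs <- sum(pm$Sd[idx])
  nonsyn_diffs <- sum(pm$Nd[idx])
  ps <- if (syn_sites > 0) syn_diffs / syn_sites else 0
  pn <- if (nonsyn_sites > 0) nonsyn_diffs / nonsyn_sites else 0
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  valid <- ps < 0.75 && pn < 0.75
  out <- tibble::tibble(
    n_codons = nrow(pairs), syn_sites = syn_sites,
    nonsyn_sites = nonsyn_sites, syn_diffs = syn_diffs,
    nonsyn_diffs = nonsyn_diffs, ps = ps, pn = pn,
    ks = if (ps < 0.75) jc(ps) else NA_real_,
    ka = if (pn < 0.75) jc(pn) else NA_real_,
    valid = valid)
  class(out) <- c("ks_result", class(out))
  out
}

#' Modal value of a Ks distribution
#'
#' `histogram`: the midpoint of the highest-count bin on a grid of width
#' `binwidth` anchored at 0, taking the leftmost bin on ties. `kde`: the
#' argmax of a Gaussian kernel density evaluated on a fixed 512-point grid
#' spanning `[0, max(values)]`; the default bandwidth is Terrell's
#' oversmoothing rule `1.144 * sd * n^(-1/5)`, appropriate for locating
#' the single peak of a unimodal distribution from a few dozen values
#' (per-gene Ks distributions typically hold ~57 points, where an
#' undersmoothed mode estimate is dominated by sampling noise).
#'
#' @param values numeric Ks values (invalid/`NA` entries are dropped).
#' @param method `"histogram"` (default) or `"kde"`.
#' @param binwidth histogram bin width in Ks units.
#' @param bandwidth optional KDE bandwidth override.
#' @return the modal Ks value.
#' @export
modal_ks <- function(values, method = c("histogram", "kde"),
                     binwidth = 0.005, bandwidth = NULL) {
  method <- match.arg(method)
  values <- unname(values[is.finite(values)])
  if (length(values) == 0L) stop("no finite Ks values", call. = FALSE)
  if (length(unique(values)) == 1L) return(values[1L])
  if (method == "histogram") {
    bins <- floor(values / binwidth)
    tb <- table(bins)
    top <- as.numeric(names(tb)[tb == max(tb)])
    (min(top) + 0.5) * binwidth
  } else {
    if (length(values) < 5L) {
      stop("kde modal extraction needs >= 5 values", call. = FALSE)
    }
    if (is.null(bandwidth)) {
      bandwidth <- 1.144 * stats::sd(values) * length(values)^(-1 / 5)
    }
    d <- stats::density(values, bw = bandwidth, from = 0, to = max(values),
                        n = 512L)
    d$x[which.max(d$y)]
  }
}

# ---- vectorised NG86 fast path -------------------------------------------
#
# Gene sequences are compiled once into codon-index vectors (1..64, NA for
# codons containing gaps/N); per pair, Sd/Nd/site sums reduce to table
# lookups, which keeps all-vs-all modal-Ks matrices cheap.

codon_index <- function(seq) {
  tab <- codon_tables()
  idx <- match(split_codons(toupper(seq)), tab$codons)
  idx
}

compile_gene_profiles <- function(gene_sets) {
  purrr::map(gene_sets, function(genes) purrr::map(genes, codon_index))
}

# numeric-only NG86 for one precompiled gene pair; returns c(ks, valid)
ks_pair_core <- function(ia, ib) {
  tab <- codon_tables()
  pm <- pair_count_matrices()
  keep <- !is.na(ia) & !is.na(ib) & !tab$is_stop[ia] & !tab$is_stop[ib]
  if (!any(keep)) return(c(NA_real_, 0))
  ia <- ia[keep]; ib <- ib[keep]
  syn_sites <- sum(tab$syn_sites[ia] + tab$syn_sites[ib]) / 2
  syn_diffs <- sum(pm$Sd[cbind(ia, ib)])
  ps <- if (syn_sites > 0) syn_diffs / syn_sites else 0
  if (ps >= 0.75) return(c(NA_real_, 0))
  c(-0.75 * log(1 - 4 * ps / 3), 1)
}

#' Ks distribution between two species over shared orthologous genes
#'
#' @param genes_a,genes_b named character vectors `gene -> codon-aligned
#'   sequence` (e.g. entries of the `gene_sets` element of
#'   [evolve_codon_genes()], or `sequence` columns of curated gene sets).
#' @param shared gene names present in both; defaults to the intersection.
#' @param species_pair optional pair of labels for reporting.
#' @inheritParams modal_ks
#' @return a list of class `"ks_distribution"`: `species_pair`, `values`
#'   (tibble `gene`, `ks`, `valid`), `modal_value`, `n_invalid`.
#' @export
pairwise_ks_distribution <- function(genes_a, genes_b, shared = NULL,
                                     species_pair = c("a", "b"),
                                     method = "histogram",
                                     binwidth = 0.005) {
  if (is.null(shared)) shared <- intersect(names(genes_a), names(genes_b))
  if (!all(shared %in% names(genes_a)) || !all(shared %in% names(genes_b))) {
    stop("shared genes missing from a gene set", call. = FALSE)
  }
  core <- vapply(shared, function(g) {
    ks_pair_core(codon_index(genes_a[[g]]), codon_index(genes_b[[g]]))
  }, numeric(2))
  vals <- tibble::tibble(gene = shared, ks = core[1L, ],
                         valid = core[2L, ] == 1)
  ok <- vals$valid & is.finite(vals$ks)
  n_invalid <- sum(!ok)
  if (n_invalid > 0) {
    message(sprintf("%d of %d gene pair(s) excluded (saturated or invalid)",
                    n_invalid, nrow(vals)))
  }
  if (!any(ok)) stop("empty Ks distribution: no valid gene pair",
                     call. = FALSE)
  structure(list(species_pair = species_pair,
                 values = vals,
                 modal_value = modal_ks(vals$ks[ok], method = method,
                                        binwidth = binwidth),
                 n_invalid = n_invalid),
            class = "ks_distribution")
}

#' All-vs-all modal-Ks divergence matrix
#'
#' Computes the modal Ks for every unordered species pair and reports each
#' taxon's nearest neighbor (smallest modal Ks), the quantity used to
#' flag close species pairs.
#'
#' @param gene_sets named list: species -> named character vector
#'   `gene -> sequence`.
#' @param shared gene names to use; defaults to the intersection over all
#'   species.
#' @inheritParams modal_ks
#' @return a list of class `"ks_matrix"`: `taxa`, `modal` (symmetric
#'   matrix, `NA` diagonal treated as 0), `nearest` (tibble `taxon`,
#'   `nearest`, `modal_ks`).
#' @export
ks_distance_matrix <- function(gene_sets, shared = NULL,
                               method = "kde", binwidth = 0.005) {
  taxa <- names(gene_sets)
  if (length(taxa) < 3L) stop("need >= 3 taxa", call. = FALSE)
  if (is.null(shared)) {
    shared <- purrr::reduce(purrr::map(gene_sets, names), intersect)
  }
  k <- length(taxa)
  modal <- matrix(0, k, k, dimnames = list(taxa, taxa))
  prof <- compile_gene_profiles(purrr::map(gene_sets, function(g) g[shared]))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      core <- vapply(shared, function(g) {
        ks_pair_core(prof[[i]][[g]], prof[[j]][[g]])
      }, numeric(2))
      ok <- core[2L, ] == 1 & is.finite(core[1L, ])
      md <- if (any(ok)) {
        modal_ks(core[1L, ok], method = method, binwidth = binwidth)
      } else NA_real_
      modal[i, j] <- modal[j, i] <- md
    }
  }
  nearest <- purrr::map(seq_len(k), function(i) {
    d <- modal[i, -i]
    tibble::tibble(taxon = taxa[i], nearest = names(d)[which.min(d)],
                   modal_ks = min(d, na.rm = TRUE))
  })
  structure(list(taxa = taxa, modal = modal,
                 nearest = dplyr::bind_rows(nearest)),
            class = "ks_matrix")
}

#' @export
print.ks_matrix <- function(x, ...) {
  cat(sprintf("<ks_matrix> %d taxa; modal Ks range [%.4g, %.4g]\n",
              length(x$taxa), min(x$modal[upper.tri(x$modal)]),
              max(x$modal[upper.tri(x$modal)])))
  invisible(x)
}

#' @export
tidy.ks_matrix <- function(x, ...) {
  ut <- which(upper.tri(x$modal), arr.ind = TRUE)
  tibble::tibble(taxon_a = x$taxa[ut[, 1L]], taxon_b = x$taxa[ut[, 2L]],
                 modal_ks = x$modal[ut])
}

#' Triangle heatmap of modal pairwise Ks values
#'
#' @param object a [ks_distance_matrix()] result.
#' @param ... ignored.
#' @export
autoplot.ks_matrix <- function(object, ...) {
  df <- tidy.ks_matrix(object) |>
    dplyr::mutate(taxon_a = factor(.data$taxon_a, levels = object$taxa),
                  taxon_b = factor(.data$taxon_b, levels = object$taxa))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$taxon_b, y = .data$taxon_a,
                                   fill = .data$modal_ks)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "modal Ks") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1))
}

#' Write the modal-Ks matrix as a triangular TSV
#'
#' @param x a `ks_matrix`.
#' @param path output path.
#' @export
write_ks_matrix <- function(x, path) {
  m <- x$modal
  m[upper.tri(m, diag = TRUE)] <- NA
  df <- as.data.frame(m)
  df <- cbind(taxon = rownames(m), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
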