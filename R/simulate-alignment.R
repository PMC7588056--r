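# tips subtended by every edge of a phylo, as row indices into the
# alignment; terminal flag per edge
edge_clades <- function(tree) {
  n_tip <- length(tree$tip.label)
  edges <- tree$edge
  below <- vector("list", max(edges))
  # accumulate tips below each node by postorder traversal
  for (i in seq_len(n_tip)) below[[i]] <- i
  for (e in ape::postorder(tree)) {
    p <- edges[e, 1L]; ch <- edges[e, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  clades <- lapply(edges[, 2L], function(nd) below[[nd]])
  sizes <- lengths(clades)
  list(clades = clades,
       lengths = tree$edge.length,
       terminal = edges[, 2L] <= n_tip,
       internal = sizes >= 2L & sizes <= n_tip - 2L)
}

#' Evolve a plastome-like alignment with labelled selection regimes
#'
#' Starting from a random root sequence, mutations are dropped onto the
#' tree region by region. In `neutral` regions a fraction `internal_bias`
#' of mutations is placed branch-length-proportionally on internal
#' branches (the rest over all branches), so variants are clade-shared
#' and at intermediate frequency, holding the site-frequency spectrum at
#' Tajima-neutral expectations (D near 0) even though the outgroup's long
#' pendant edge is present. In `constrained` regions a fraction
#' `terminal_bias` of mutations is forced onto terminal branches, creating
#' the singleton excess that drives Tajima's D strongly negative. Each
#' mutation rewrites one column for all taxa below the chosen branch.
#'
#' The per-region mutation count is Poisson with mean
#' `region length x rate` (`rate` = expected mutations per column over the
#' whole tree). The alignment is emitted gap-free unless `gap_rate > 0`
#' (random gappy columns) or `boundary_gap > 0` (runs of all-gap columns at
#' region joins, which lets gap-density block collection recover the region
#' decomposition).
#'
#' @param tree a [simulate_species_tree()] result (any `phylo` works).
#' @param plan a [region_plan()].
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param gap_rate per-column probability of injecting gaps into a random
#'   subset of taxa (exercises gap-handling; default 0).
#' @param boundary_gap number of all-gap columns carved out of the end of
#'   every region except the last (default 0).
#' @return a list of class `"sim_alignment"`: `alignment` (character
#'   matrix), `truth` (list: `tree`, `region_labels` per column,
#'   `regions` tibble with 0-based half-open coordinates, `seed`).
#' @export
evolve_alignment <- function(tree, plan, seed, gap_rate = 0,
                             boundary_gap = 0L) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 3L) {
    stop("tree must have >= 3 taxa", call. = FALSE)
  }
  if (all(tree$edge.length == 0)) {
    stop("degenerate tree: every branch length is zero", call. = FALSE)
  }
  tb <- attr(plan, "terminal_bias")
  if (is.null(tb)) tb <- 0.95
  ib <- attr(plan, "internal_bias")
  if (is.null(ib)) ib <- 0.75
  L <- sum(plan$length)
  ec <- edge_clades(tree)
  taxa <- tree$tip.label
  n <- length(taxa)
  bases <- c("A", "C", "G", "T")

  with_seed(seed, {
    root <- sample(bases, L, replace = TRUE)
    aln <- matrix(rep(root, each = n), nrow = n,
                  dimnames = list(taxa, NULL))
    w_len <- ec$lengths / sum(ec$lengths)
    term_idx <- which(ec$terminal)
    w_int <- ifelse(ec$internal, ec$lengths, 0)
    has_internal <- sum(w_int) > 0
    if (has_internal) w_int <- w_int / sum(w_int)
    offset <- 0L
    labels <- character(L)
    for (r in seq_len(nrow(plan))) {
      len <- plan$length[r]
      regime <- plan$regime[r]
      labels[(offset + 1L):(offset + len)] <- regime
      n_mut <- stats::rpois(1L, len * plan$rate[r])
      if (n_mut > 0) {
        cols <- offset + sample.int(len, n_mut, replace = TRUE)
        if (regime == "constrained") {
          on_term <- stats::runif(n_mut) < tb
          edges <- integer(n_mut)
          if (any(on_term)) {
            edges[on_term] <- sample(term_idx, sum(on_term), replace = TRUE)
          }
          if (any(!on_term)) {
            edges[!on_term] <- sample.int(length(w_len), sum(!on_term),
                                          replace = TRUE, prob = w_len)
          }
        } else {
          on_int <- has_internal & stats::runif(n_mut) < ib
          edges <- integer(n_mut)
          if (any(on_int)) {
            edges[on_int] <- sample.int(length(w_len), sum(on_int),
                                        replace = TRUE, prob = w_int)
          }
          if (any(!on_int)) {
            edges[!on_int] <- sample.int(length(w_len), sum(!on_int),
                                         replace = TRUE, prob = w_len)
          }
        }
        for (m in seq_len(n_mut)) {
          clade <- ec$clades[[edges[m]]]
          cur <- aln[clade[1L], cols[m]]
          aln[clade, cols[m]] <- sample(setdiff(bases, cur), 1L)
        }
      }
      offset <- offset + len
    }
    regions <- tibble::tibble(
      start = cumsum(c(0L, plan$length[-nrow(plan)])),
      end = cumsum(plan$length),
      regime = plan$regime)
    if (boundary_gap > 0L && nrow(plan) > 1L) {
      for (r in seq_len(nrow(plan) - 1L)) {
        e <- regions$end[r]
        idx <- (e - boundary_gap + 1L):e
        aln[, idx] <- "-"
        labels[idx] <- "boundary"
      }
    }
    if (gap_rate > 0) {
      gappy <- which(stats::runif(L) < gap_rate)
      for (g in gappy) {
        k <- sample.int(n - 1L, 1L)
        aln[sample.int(n, k), g] <- "-"
      }
    }
    structure(
      list(alignment = as_alignment(aln),
           truth = list(tree = tree, region_labels = labels,
                        regions = regions, seed = seed)),
      class = "sim_alignment")
  })
}

#' Write simulation truth as JSON (run-length encoded labels) and BED
#'
#' @param sim an [evolve_alignment()] result.
#' @param json_path,bed_path output paths (either may be `NULL`).
#' @export
write_simulation_truth <- function(sim, json_path = NULL, bed_path = NULL) {
  stopifnot(inherits(sim, "sim_alignment"))
  if (!is.null(json_path)) {
    r <- rle(sim$truth$region_labels)
    jsonlite::write_json(
      list(seed = sim$truth$seed,
           newick = ape::write.tree(sim$truth$tree),
           region_rle = list(lengths = r$lengths, values = r$values)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(bed_path)) {
    bed <- sim$truth$regions
    utils::write.table(
      data.frame(chrom = "alignment", start = bed$start, end = bed$end,
                 name = bed$regime),
      bed_path, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
  }
  invisible(sim)
}
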