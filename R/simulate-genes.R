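#' Evolve orthologous codon genes along a species tree
#'
#' Each gene starts from a random stop-free codon sequence at the root and
#' evolves down the tree by single-nucleotide codon substitutions with
#' separate synonymous and nonsynonymous rates: a specific synonymous
#' neighbor change occurs at rate `syn_rate/3` per unit branch length (so a
#' synonymous site accumulates `syn_rate` expected changes per unit), a
#' nonsynonymous one at `nonsyn_rate/3`, and changes into stop codons never
#' occur. Expected pairwise Ks between two taxa therefore grows with their
#' path length on the tree, which is what the downstream modal-Ks
#' classification exploits.
#'
#' @param tree a `phylo`; branch lengths in substitutions/site.
#' @param n_genes number of orthologous genes to emit.
#' @param syn_rate expected synonymous substitutions per synonymous site
#'   per unit branch length.
#' @param nonsyn_rate likewise for nonsynonymous sites.
#' @param gene_length gene length in codons (>= 30).
#' @param seed integer seed; identical seeds give identical gene sets.
#' @return a list of class `"sim_genes"`: `gene_sets` (named list, one
#'   named character vector `gene -> sequence` per taxon), `tree`, `seed`,
#'   and `saturated_pairs` (tibble of taxon pairs whose expected raw
#'   synonymous difference proportion exceeds 0.74, where the Jukes-Cantor
#'   correction degenerates; a warning is raised when any exist).
#' @export
evolve_codon_genes <- function(tree, n_genes, syn_rate, nonsyn_rate,
                               gene_length, seed) {
  stopifnot(inherits(tree, "phylo"))
  if (gene_length < 30L) stop("gene_length must be >= 30 codons", call. = FALSE)
  if (syn_rate < 0 || nonsyn_rate < 0) stop("rates must be >= 0", call. = FALSE)
  tab <- codon_tables()
  ok_codons <- which(!tab$is_stop)
  # per-codon total event rate per unit branch length
  lam <- vapply(seq_len(64L), function(i) {
    if (tab$is_stop[i]) return(0)
    sum(ifelse(tab$nbr_stop[[i]], 0,
               ifelse(tab$nbr_syn[[i]], syn_rate, nonsyn_rate))) / 3
  }, numeric(1))

  mutate_branch <- function(codons, t) {
    if (t <= 0) return(codons)
    k <- stats::rpois(length(codons), lam[codons] * t)
    hot <- which(k > 0)
    for (h in hot) {
      for (rep in seq_len(k[h])) {
        i <- codons[h]
        w <- ifelse(tab$nbr_stop[[i]], 0,
                    ifelse(tab$nbr_syn[[i]], syn_rate, nonsyn_rate))
        if (sum(w) == 0) break
        codons[h] <- sample(tab$nbr[[i]], 1L, prob = w)
      }
    }
    codons
  }

  # expected raw synonymous difference proportion per pair, to flag
  # saturation of the Jukes-Cantor correction
  pd <- stats::cophenetic(tree)
  exp_ps <- 0.75 * (1 - exp(-4 / 3 * syn_rate * pd))
  sat <- which(exp_ps > 0.74 & upper.tri(exp_ps), arr.ind = TRUE)
  saturated <- tibble::tibble(taxon_a = rownames(pd)[sat[, 1L]],
                              taxon_b = colnames(pd)[sat[, 2L]])
  if (nrow(saturated) > 0) {
    warning(sprintf(
      "%d taxon pair(s) have expected synonymous divergence beyond the JC correction domain (ps > 0.74)",
      nrow(saturated)), call. = FALSE)
  }

  taxa <- tree$tip.label
  edges <- tree$edge
  root <- length(taxa) + 1L
  preord <- rev(ape::postorder(tree))

  with_seed(seed, {
    gene_sets <- stats::setNames(
      replicate(length(taxa), character(0), simplify = FALSE), taxa)
    gene_names <- sprintf("gene%03d", seq_len(n_genes))
    for (g in seq_len(n_genes)) {
      node_seq <- vector("list", max(edges))
      node_seq[[root]] <- sample(ok_codons, gene_length, replace = TRUE)
      for (e in preord) {
        p <- edges[e, 1L]; ch <- edges[e, 2L]
        node_seq[[ch]] <- mutate_branch(node_seq[[p]], tree$edge.length[e])
      }
      for (ti in seq_along(taxa)) {
        seq_str <- paste(tab$codons[node_seq[[ti]]], collapse = "")
        gene_sets[[ti]][gene_names[g]] <- seq_str
      }
    }
    structure(list(gene_sets = gene_sets, tree = tree, seed = seed,
                   saturated_pairs = saturated),
              class = "sim_genes")
  })
}

#' Write simulated gene sets as per-gene FASTA files
#'
#' @param sim an [evolve_codon_genes()] result.
#' @param dir output directory (one FASTA per gene, all taxa in each).
#' @export
write_gene_fastas <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_genes"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gene_names <- names(sim$gene_sets[[1L]])
  for (g in gene_names) {
    lines <- unlist(purrr::imap(sim$gene_sets, function(genes, taxon) {
      c(paste0(">", taxon), genes[[g]])
    }))
    writeLines(lines, file.path(dir, paste0(g, ".fasta")))
  }
  invisible(dir)
}
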