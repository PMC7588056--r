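#' Tamura-Nei (1993) pairwise distance with components
#'
#' Computes the closed-form TN93 distance from the two transition
#' proportions (`P1` within purines, `P2` within pyrimidines), the
#' transversion proportion `Q`, and the base frequencies pooled over the
#' two sequences. Positions where either sequence carries a gap, `N` or
#' `?` are deleted pairwise. When a logarithm argument is non-positive
#' (saturation) the distance is set to `saturation_cap` and flagged.
#'
#' @param seq_a,seq_b DNA strings or character vectors of equal length.
#' @param saturation_cap distance reported for saturated pairs.
#' @return a list of class `"tn93"`: `distance`, `saturated`, and
#'   `components` (list: `P1`, `P2`, `Q`, `gA`, `gC`, `gG`, `gT`, `gR`,
#'   `gY`, `k1`, `k2`, `usable_sites`).
#' @export
tn93_distance <- function(seq_a, seq_b, saturation_cap = 5) {
  a <- if (length(seq_a) == 1L) strsplit(toupper(seq_a), "")[[1L]] else toupper(seq_a)
  b <- if (length(seq_b) == 1L) strsplit(toupper(seq_b), "")[[1L]] else toupper(seq_b)
  if (length(a) != length(b)) stop("sequences must have equal length",
                                   call. = FALSE)
  use <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(use)) stop("no usable site after pairwise deletion", call. = FALSE)
  a <- a[use]; b <- b[use]
  n <- length(a)
  pooled <- c(a, b)
  g <- c(gA = mean(pooled == "A"), gC = mean(pooled == "C"),
         gG = mean(pooled == "G"), gT = mean(pooled == "T"))
  gR <- g["gA"] + g["gG"]; gY <- g["gC"] + g["gT"]
  diff <- a != b
  pur <- c("A", "G")
  P1 <- mean(diff & a %in% pur & b %in% pur)               # A<->G
  P2 <- mean(diff & !(a %in% pur) & !(b %in% pur))         # C<->T
  Q <- mean(diff & xor(a %in% pur, b %in% pur))            # transversions
  # degenerate frequency classes (an absent purine or pyrimidine) zero
  # out the corresponding transition term
  k1 <- if (gR > 0) 2 * g["gA"] * g["gG"] / gR else 0
  k2 <- if (gY > 0) 2 * g["gC"] * g["gT"] / gY else 0
  k3 <- 2 * (gR * gY -
               (if (gR > 0) g["gA"] * g["gG"] * gY / gR else 0) -
               (if (gY > 0) g["gC"] * g["gT"] * gR / gY else 0))
  w1 <- if (k1 > 0) 1 - P1 / k1 - Q / (2 * gR) else 1
  w2 <- if (k2 > 0) 1 - P2 / k2 - Q / (2 * gY) else 1
  w3 <- if (Q == 0) 1
        else if (gR * gY > 0) 1 - Q / (2 * gR * gY) else 0
  saturated <- w1 <= 0 || w2 <= 0 || w3 <= 0 ||
    (k1 == 0 && P1 > 0) || (k2 == 0 && P2 > 0)
  d <- if (saturated) saturation_cap else {
    -(if (k1 > 0) k1 * log(w1) else 0) -
      (if (k2 > 0) k2 * log(w2) else 0) -
      (if (w3 < 1) k3 * log(w3) else 0)
  }
  structure(list(distance = unname(d), saturated = saturated,
                 components = as.list(c(P1 = P1, P2 = P2, Q = Q, g,
                                        gR = unname(gR), gY = unname(gY),
                                        k1 = unname(k1), k2 = unname(k2),
                                        usable_sites = n))),
            class = "tn93")
}

#' TN93 distance matrix of an alignment
#'
#' @param aln an alignment ([as_alignment()]).
#' @inheritParams tn93_distance
#' @return a symmetric numeric matrix with zero diagonal; saturated pairs
#'   carry the cap and are listed in attribute `saturated_pairs`.
#' @export
tn93_distance_matrix <- function(aln, saturation_cap = 5) {
  aln <- as_alignment(aln)
  taxa <- rownames(aln)
  k <- nrow(aln)
  d <- matrix(0, k, k, dimnames = list(taxa, taxa))
  sat <- list()
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      r <- tn93_distance(aln[i, ], aln[j, ], saturation_cap)
      d[i, j] <- d[j, i] <- r$distance
      if (r$saturated) sat[[length(sat) + 1L]] <- c(taxa[i], taxa[j])
    }
  }
  attr(d, "saturated_pairs") <- sat
  d
}

#' Hamming (p-) distance matrix of a genotype matrix
#'
#' Proportion of differing sites per taxon pair over the genotype-matrix
#' columns.
#'
#' @param gm a genotype matrix (character matrix taxa x sites, e.g. from
#'   [build_genotype_matrix()]).
#' @return a symmetric numeric matrix with zero diagonal.
#' @export
hamming_distance_matrix <- function(gm) {
  m <- if (is.list(gm) && !is.null(gm$matrix)) gm$matrix else gm
  if (nrow(m) < 2L) stop("need >= 2 taxa", call. = FALSE)
  k <- nrow(m)
  d <- matrix(0, k, k, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      d[i, j] <- d[j, i] <- mean(m[i, ] != m[j, ])
    }
  }
  d
}

#' Neighbor-joining tree (deterministic wrapper)
#'
#' Canonical NJ agglomeration on a distance matrix. Taxa are sorted
#' lexicographically before agglomeration so ties resolve reproducibly,
#' and negative branch lengths are clamped to zero with the total clamped
#' deficit recorded in attribute `clamped_deficit`.
#'
#' @param dm symmetric distance matrix with taxon dimnames.
#' @return an unrooted `phylo`.
#' @export
neighbor_joining <- function(dm) {
  check_dist_matrix(dm, min_taxa = 3L)
  ord <- order(rownames(dm))
  dm <- dm[ord, ord]
  tr <- ape::nj(stats::as.dist(dm))
  neg <- tr$edge.length < 0
  deficit <- sum(-tr$edge.length[neg])
  if (deficit > 0) tr$edge.length[neg] <- 0
  attr(tr, "clamped_deficit") <- deficit
  tr
}

#' UPGMA (average-linkage) dendrogram
#'
#' Average-linkage hierarchical clustering of the distance matrix,
#' returned as a rooted ultrametric `phylo` (node heights are half the
#' cophenetic distances). Taxa are sorted lexicographically first for
#' reproducible tie-breaking.
#'
#' @inheritParams neighbor_joining
#' @return a rooted ultrametric `phylo`.
#' @export
upgma <- function(dm) {
  check_dist_matrix(dm, min_taxa = 2L)
  ord <- order(rownames(dm))
  dm <- dm[ord, ord]
  hc <- stats::hclust(stats::as.dist(dm), method = "average")
  # as.phylo.hclust already halves merge heights, giving root-to-tip
  # height d/2 for two taxa at distance d
  ape::as.phylo(hc)
}

check_dist_matrix <- function(dm, min_taxa) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) {
    stop("distance matrix must be square", call. = FALSE)
  }
  if (nrow(dm) < min_taxa) {
    stop(sprintf("need >= %d taxa", min_taxa), call. = FALSE)
  }
  if (any(!is.finite(dm))) {
    stop("distance matrix contains non-finite entries", call. = FALSE)
  }
  if (is.null(rownames(dm))) {
    stop("distance matrix needs taxon dimnames", call. = FALSE)
  }
  invisible(dm)
}

# non-trivial bipartitions of an unrooted tree, keyed canonically by the
# sorted side not containing the alphabetically first taxon
bipartition_keys <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  ref <- tips[1L]
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  keys <- character(0)
  for (p in parts) {
    side <- labs[p]
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) >= 2L && length(side) <= length(tips) - 2L) {
      keys <- c(keys, paste(sort(side), collapse = "|"))
    }
  }
  unique(keys)
}

#' Site-resampling bootstrap supports for a genotype-matrix tree
#'
#' Builds the point-estimate tree from the full matrix, then resamples
#' matrix columns with replacement `n_reps` times, rebuilds a tree per
#' replicate, and reports for each internal edge of the point tree the
#' percentage of replicates containing the same bipartition. Each
#' replicate draws from its own seed derived from the master seed, so
#' increasing `n_reps` never reshuffles earlier replicates.
#'
#' @param gm a genotype matrix (or a [build_genotype_matrix()] result).
#' @param builder `"nj"` or `"upgma"`.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed master integer seed.
#' @return the point-estimate `phylo` with `node.label` holding the
#'   support percentages (root label empty) and attribute `supports`, a
#'   tibble of bipartition keys and percentages. Single-site matrices are
#'   flagged via attribute `low_information`.
#' @export
bootstrap_support <- function(gm, builder = c("nj", "upgma"), n_reps = 1000L,
                              seed = 1L) {
  builder <- match.arg(builder)
  m <- if (is.list(gm) && !is.null(gm$matrix)) gm$matrix else gm
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  m <- m[, order(colnames(m) %||% seq_len(ncol(m))), drop = FALSE]
  build <- function(mm) {
    d <- hamming_distance_matrix(mm)
    if (builder == "nj") neighbor_joining(d) else upgma(d)
  }
  point <- build(m)
  keys <- bipartition_keys(point)
  hits <- stats::setNames(numeric(length(keys)), keys)
  for (r in seq_len(n_reps)) {
    rep_seed <- (as.numeric(seed) + r * 1664525) %% 2147483647
    cols <- with_seed(rep_seed, sample.int(ncol(m), ncol(m), replace = TRUE))
    bt <- build(m[, cols, drop = FALSE])
    bk <- bipartition_keys(bt)
    hit <- keys %in% bk
    hits[hit] <- hits[hit] + 1
  }
  supports <- tibble::tibble(bipartition = keys,
                             support = 100 * hits / n_reps)
  # attach supports to internal nodes of the point tree
  point$node.label <- rep("", point$Nnode)
  tips <- sort(point$tip.label)
  ref <- tips[1L]
  parts <- ape::prop.part(point)
  labs <- attr(parts, "labels")
  for (i in seq_along(parts)) {
    side <- labs[parts[[i]]]
    if (ref %in% side) side <- setdiff(tips, side)
    key <- paste(sort(side), collapse = "|")
    j <- match(key, keys)
    if (!is.na(j)) {
      point$node.label[i] <- format(round(supports$support[j], 1))
    }
  }
  attr(point, "supports") <- supports
  if (ncol(m) == 1L) {
    attr(point, "low_information") <- TRUE
    warning("single-site matrix: bootstrap supports carry little information",
            call. = FALSE)
  }
  point
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric-difference count of non-trivial unrooted bipartitions, plus
#' the count normalised by the maximum possible `2(n-3)`.
#'
#' @param t1,t2 `phylo` objects on identical leaf sets.
#' @return a list with `rf` (count) and `normalized` (in `[0,1]`).
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees must share an identical leaf set", call. = FALSE)
  }
  rf <- phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2))
  n <- length(t1$tip.label)
  maxrf <- 2 * (n - 3)
  list(rf = rf, normalized = if (maxrf > 0) rf / maxrf else 0)
}

#' Read / write newick trees
#'
#' Thin wrappers with explicit format errors; round trips preserve
#' topology, branch lengths and internal-node support labels.
#'
#' @param path file path.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) stop("malformed newick in ", path, call. = FALSE)
  tr
}

#' @rdname read_newick
#' @param tree a `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
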