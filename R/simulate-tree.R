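# Seeded random draws without touching the caller's global RNG stream:
# save and restore .Random.seed around every simulator entry point.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# recursive ultrametric newick over a label set: random bifurcations with
# split heights drawn uniformly below the parent height
random_clade_newick <- function(labels, height) {
  if (length(labels) == 1L) {
    return(list(str = labels, h = 0))
  }
  k <- sample.int(length(labels) - 1L, 1L)
  left <- sample(labels)
  a <- left[seq_len(k)]
  b <- left[-seq_len(k)]
  split_h <- height * stats::runif(1L, 0.3, 0.9)
  na <- random_clade_newick(a, split_h)
  nb <- random_clade_newick(b, split_h)
  str <- sprintf("(%s:%.8f,%s:%.8f)", na$str, split_h - na$h,
                 nb$str, split_h - nb$h)
  list(str = str, h = split_h)
}

#' Simulate a clade-structured species tree
#'
#' Builds a binary, ultrametric ingroup tree with `n_clades` monophyletic
#' clades joined by a random backbone, and attaches a single outgroup at
#' the root. Branch lengths are in expected substitutions per site;
#' `depth` is the root-to-tip height of the ingroup. The outgroup branch is
#' made 1.5x the ingroup depth so that it is unambiguously the most
#' divergent taxon, as for a typical confamilial outgroup.
#'
#' @param n_ingroup number of ingroup taxa (>= n_clades).
#' @param n_clades number of monophyletic ingroup clades (>= 1).
#' @param depth ingroup root-to-tip height, substitutions/site (> 0).
#' @param seed integer seed; identical seeds give identical newick strings.
#' @return an [ape::phylo] with extra class `"species_tree"` and
#'   attributes: `outgroup` (label), `clades` (list of tip-label vectors),
#'   `newick` (the exact string), `seed`.
#' @export
simulate_species_tree <- function(n_ingroup, n_clades, depth, seed) {
  if (n_clades < 1L || n_ingroup < n_clades) {
    stop("need n_ingroup >= n_clades >= 1", call. = FALSE)
  }
  if (depth <= 0) stop("depth must be > 0", call. = FALSE)
  with_seed(seed, {
    tips <- sprintf("t%02d", seq_len(n_ingroup))
    sizes <- rep(n_ingroup %/% n_clades, n_clades)
    extra <- n_ingroup %% n_clades
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    clades <- split(tips, rep(seq_len(n_clades), times = sizes))
    # clades coalesce below 45% of the depth; the backbone above it, so
    # clade monophyly survives moderate branch-length noise downstream
    clade_parts <- purrr::map(clades, function(cl) {
      random_clade_newick(cl, height = depth * 0.45)
    })
    if (n_clades == 1L) {
      ing <- clade_parts[[1L]]
      ing_str <- ing$str
      ing_h <- ing$h
      if (n_ingroup == 1L) {
        ing_str <- tips
        ing_h <- 0
      }
    } else {
      backbone <- random_clade_newick(sprintf("C%d", seq_len(n_clades)),
                                      height = depth)
      # backbone splits must sit above the clade crowns: rescale into
      # [0.5*depth, depth] by flooring at half depth
      ing_str <- backbone$str
      ing_h <- backbone$h
      for (i in seq_len(n_clades)) {
        stub <- sprintf("C%d:([0-9.]+)", i)
        m <- regmatches(ing_str, regexec(stub, ing_str))[[1L]]
        stub_edge <- as.numeric(m[2L])
        # tip stub sat at height 0; clade crown sits at clade_parts height
        new_edge <- stub_edge - clade_parts[[i]]$h
        if (new_edge <= 0) new_edge <- stub_edge * 0.1
        ing_str <- sub(sprintf("C%d:[0-9.]+", i),
                       sprintf("%s:%.8f", clade_parts[[i]]$str, new_edge),
                       ing_str)
      }
    }
    out_label <- "OUT"
    newick <- sprintf("(%s:%.8f,%s:%.8f);", ing_str,
                      depth - ing_h + 0.5 * depth, out_label, 1.5 * depth)
    tree <- ape::read.tree(text = newick)
    attr(tree, "outgroup") <- out_label
    attr(tree, "clades") <- unname(clades)
    attr(tree, "newick") <- newick
    attr(tree, "seed") <- seed
    class(tree) <- c("species_tree", "phylo")
    tree
  })
}

#' Region plan for the plastome alignment simulator
#'
#' Describes, left to right, the regions of the simulated alignment: each
#' has a length (bp), a regime (`"constrained"` regions push mutations onto
#' terminal branches, producing a rare-allele excess and strongly negative
#' Tajima's D; `"neutral"` regions place mutations proportionally to branch
#' length, leaving clade-informative intermediate-frequency variants), and
#' a mutation rate (expected mutations per column over the whole tree).
#'
#' @param lengths integer vector of region lengths (bp, >= 1).
#' @param regimes character vector, `"neutral"` or `"constrained"`.
#' @param rates per-region expected mutations per column (>= 0).
#' @param terminal_bias fraction in `[0,1]` of constrained-region mutations
#'   forced onto terminal branches.
#' @param internal_bias fraction in `[0,1]` of neutral-region mutations
#'   placed on internal branches (branch-length-proportionally among
#'   edges subtending 2..n-2 tips); the remainder is branch-length-
#'   proportional over all edges. The default 0.75 equates the expected
#'   per-mutation pairwise-difference contribution with Watterson's
#'   expectation on trees of the [simulate_species_tree()] shape, so
#'   neutral regions sit at Tajima's D near 0 even with the outgroup
#'   included.
#' @return a tibble of class `"region_plan"` with attributes
#'   `terminal_bias` and `internal_bias`.
#' @export
region_plan <- function(lengths, regimes, rates, terminal_bias = 0.95,
                        internal_bias = 0.75) {
  stopifnot(length(lengths) == length(regimes),
            length(lengths) == length(rates))
  if (any(lengths < 1)) stop("region lengths must be >= 1", call. = FALSE)
  if (any(rates < 0)) stop("rates must be >= 0", call. = FALSE)
  if (terminal_bias < 0 || terminal_bias > 1) {
    stop("terminal_bias must lie in [0,1]", call. = FALSE)
  }
  if (internal_bias < 0 || internal_bias > 1) {
    stop("internal_bias must lie in [0,1]", call. = FALSE)
  }
  regimes <- match.arg(regimes, c("neutral", "constrained"),
                       several.ok = TRUE)
  out <- tibble::tibble(length = as.integer(lengths), regime = regimes,
                        rate = as.numeric(rates))
  attr(out, "terminal_bias") <- terminal_bias
  attr(out, "internal_bias") <- internal_bias
  class(out) <- c("region_plan", class(out))
  out
}

#' Default two-regime plan: constrained background, interspersed neutral islands
#'
#' Lays out `n_neutral` neutral regions separated by constrained stretches,
#' mirroring a plastome in which most of the sequence is under purifying
#' pressure (or outgroup-skewed) and a minority of short regions retains a
#' neutral frequency spectrum.
#'
#' @param alignment_length total alignment length (bp).
#' @param neutral_fraction fraction of columns in neutral regions.
#' @param n_neutral number of neutral islands.
#' @param constrained_rate,neutral_rate expected mutations/column.
#' @inheritParams region_plan
#' @export
default_region_plan <- function(alignment_length = 50000L,
                                neutral_fraction = 0.2,
                                n_neutral = 5L,
                                constrained_rate = 0.08,
                                neutral_rate = 0.05,
                                terminal_bias = 0.95,
                                internal_bias = 0.75) {
  n_len <- floor(alignment_length * neutral_fraction / n_neutral)
  c_total <- alignment_length - n_len * n_neutral
  c_len <- floor(c_total / (n_neutral + 1L))
  lengths <- integer(0); regimes <- character(0)
  for (i in seq_len(n_neutral)) {
    lengths <- c(lengths, c_len, n_len)
    regimes <- c(regimes, "constrained", "neutral")
  }
  lengths <- c(lengths, alignment_length - sum(lengths))
  regimes <- c(regimes, "constrained")
  rates <- ifelse(regimes == "neutral", neutral_rate, constrained_rate)
  region_plan(lengths, regimes, rates, terminal_bias, internal_bias)
}
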