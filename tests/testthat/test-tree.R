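test_that("TN93 distance: identity, ape agreement, JC reduction", {
  expect_equal(tn93_distance("ACGTACGT", "ACGTACGT")$distance, 0)

  # gap-free random pairs against the reference implementation in ape
  # (with gaps, ape pools base frequencies over all sites while this
  # implementation pools over pairwise-complete sites, so gapped pairs
  # are checked against the direct-formula oracle instead)
  set.seed(31)
  for (i in 1:20) {
    gapped <- i %% 2 == 0
    m <- random_alignment(2, 800, gap_prob = ifelse(gapped, 0.02, 0))
    keep <- m[1, ] != "-" & m[2, ] != "-"
    m[2, keep] <- ifelse(runif(sum(keep)) < 0.85, m[1, keep], m[2, keep])
    mine <- tn93_distance(m[1, ], m[2, ])
    if (gapped) {
      expect_equal(mine$distance, oracle_tn93(m[1, ], m[2, ]),
                   tolerance = 1e-9)
    } else {
      ref <- ape::dist.dna(ape::as.DNAbin(m), model = "TN93",
                           pairwise.deletion = TRUE)
      expect_equal(mine$distance, as.numeric(ref), tolerance = 1e-9)
    }
  }

  # balanced substitution pattern with equal frequencies reduces to JC:
  # 1200 sites, 300 of each base; 40 transitions within purines, 40 within
  # pyrimidines, 160 transversions (the JC 1:1:4 ratio), frequencies kept
  # uniform by symmetric swaps
  a <- rep(c("A", "C", "G", "T"), each = 300)
  b <- a
  b[1:20] <- "G";    b[301:320] <- "T"     # 20 A->G, 20 C->T
  b[601:620] <- "A"; b[901:920] <- "C"     # 20 G->A, 20 T->C
  b[21:40] <- "C";   b[321:340] <- "A"     # A<->C transversions
  b[621:640] <- "T"; b[921:940] <- "G"     # G<->T
  b[41:60] <- "T";   b[941:960] <- "A"     # A<->T
  b[641:660] <- "C"; b[341:360] <- "G"     # G<->C
  p <- mean(a != b)
  expect_equal(p, 0.2)
  jc <- -0.75 * log(1 - 4 * p / 3)
  expect_equal(tn93_distance(a, b)$distance, jc, tolerance = 1e-6)

  comp <- tn93_distance(a, b)$components
  expect_equal(comp$P1 + comp$P2 + comp$Q, p, tolerance = 1e-12)
  expect_equal(comp$gA + comp$gC + comp$gG + comp$gT, 1, tolerance = 1e-12)
})

test_that("TN93 flags saturated pairs at the declared cap", {
  a <- rep(c("A", "G"), 50)
  b <- rep(c("G", "A"), 50)  # all sites transition-different
  r <- tn93_distance(a, b, saturation_cap = 5)
  expect_true(r$saturated)
  expect_equal(r$distance, 5)
})

test_that("hamming distances match exhaustive pair enumeration", {
  gm <- rbind(a = strsplit("AAAACCCCGGGG", "")[[1]],
              b = strsplit("AAAACCCCGGGT", "")[[1]])
  gm[2, 1:2] <- "T"
  expect_equal(hamming_distance_matrix(gm)["a", "b"], 3 / 12)

  set.seed(9)
  for (i in 1:10) {
    m <- random_alignment(8, 20)
    d <- hamming_distance_matrix(m)
    for (p in 1:7) for (q in (p + 1):8) {
      expect_equal(d[p, q], mean(m[p, ] != m[q, ]))
    }
    expect_identical(d, t(d))
    expect_true(all(diag(d) == 0))
  }
})

test_that("NJ recovers additive matrices exactly and is order-invariant", {
  # 3 taxa: closed-form three-point branch lengths
  d3 <- matrix(c(0, .3, .5, .3, 0, .4, .5, .4, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- neighbor_joining(d3)
  expect_equal(length(t3$tip.label), 3L)
  h <- function(tr, tip) tr$edge.length[tr$edge[, 2] ==
                                          which(tr$tip.label == tip)]
  expect_equal(h(t3, "a"), (0.3 + 0.5 - 0.4) / 2)
  expect_equal(h(t3, "b"), (0.3 + 0.4 - 0.5) / 2)
  expect_equal(h(t3, "c"), (0.5 + 0.4 - 0.3) / 2)

  set.seed(41)
  for (i in 1:50) {
    n <- sample(4:10, 1)
    tr <- ape::rtree(n)
    dm <- stats::cophenetic(tr)
    nj1 <- neighbor_joining(dm)
    expect_equal(robinson_foulds(nj1, tr)$rf, 0)
    perm <- sample(n)
    nj2 <- neighbor_joining(dm[perm, perm])
    expect_equal(robinson_foulds(nj1, nj2)$rf, 0)
  }
})

test_that("NJ clamps negative branch lengths and validates input", {
  d <- matrix(c(0, 1, 10, 1, 0, 1, 10, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
  d[1, 2] <- NA; d[2, 1] <- NA
  expect_error(neighbor_joining(d), "non-finite")
})

test_that("UPGMA returns ultrametric trees and exact heights", {
  d2 <- matrix(c(0, .4, .4, 0), 2, 2, dimnames = list(c("a", "b"),
                                                      c("a", "b")))
  t2 <- upgma(d2)
  expect_equal(sort(t2$edge.length), c(0.2, 0.2))

  # ultrametric 4-taxon matrix: ((a,b),(c,d)) with heights .1 and .3
  dm <- matrix(.6, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(dm) <- 0
  dm["a", "b"] <- dm["b", "a"] <- .2
  dm["c", "d"] <- dm["d", "c"] <- .2
  t4 <- upgma(dm)
  expect_equal(robinson_foulds(t4, ape::read.tree(text = "((a,b),(c,d));"))$rf,
               0)
  expect_true(ape::is.ultrametric(t4, tol = 1e-9))

  set.seed(13)
  m <- random_alignment(6, 30)
  expect_true(ape::is.ultrametric(upgma(hamming_distance_matrix(m)),
                                  tol = 1e-9))
})

test_that("Robinson-Foulds agrees with the bipartition-set oracle", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(robinson_foulds(t1, t1)$rf, 0)
  r <- robinson_foulds(t1, t2)
  expect_equal(r$rf, 2)
  expect_equal(r$normalized, 1)

  cat6 <- ape::read.tree(text = "(a,(b,(c,(d,(e,f)))));")
  bal6 <- ape::read.tree(text = "((a,(b,c)),(d,(e,f)));")
  expect_equal(robinson_foulds(cat6, bal6)$rf, oracle_rf(cat6, bal6))

  set.seed(3)
  for (i in 1:20) {
    x <- ape::rtree(8); y <- ape::rtree(8)
    expect_equal(robinson_foulds(x, y)$rf, oracle_rf(x, y))
  }

  t3 <- ape::read.tree(text = "((a,b),(c,e));")
  expect_error(robinson_foulds(t1, t3), "leaf set")
})

test_that("bootstrap supports are deterministic and calibrated", {
  # perfectly clade-consistent matrix: every site splits {a,b} vs {c,d}
  gm <- rbind(a = rep("A", 8), b = rep("A", 8),
              c = rep("G", 8), d = rep("G", 8))
  gm[3:4, 5:8] <- "T"  # second allele pattern, same split
  bt <- suppressWarnings(bootstrap_support(gm, "nj", n_reps = 50, seed = 3))
  sup <- attr(bt, "supports")
  expect_true(all(sup$support == 100))

  set.seed(99)
  m <- random_alignment(6, 12)
  b1 <- bootstrap_support(m, "nj", n_reps = 20, seed = 11)
  b2 <- bootstrap_support(m, "nj", n_reps = 20, seed = 11)
  expect_identical(attr(b1, "supports"), attr(b2, "supports"))

  single <- bootstrap_support(m, "nj", n_reps = 1, seed = 2)
  expect_true(all(attr(single, "supports")$support %in% c(0, 100)))
})

test_that("newick I/O round-trips topology, lengths and supports", {
  tr <- ape::rtree(17)
  path <- tempfile(fileext = ".nwk")
  write_newick(tr, path)
  back <- read_newick(path)
  expect_equal(robinson_foulds(tr, back)$rf, 0)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-9)

  tr$node.label <- as.character(seq_len(tr$Nnode))
  write_newick(tr, path)
  expect_identical(read_newick(path)$node.label, tr$node.label)

  bad <- tempfile(fileext = ".nwk")
  writeLines("((a,b,(c);", bad)
  expect_error(read_newick(bad), "malformed")

  simple <- tempfile(fileext = ".nwk")
  writeLines("((A,B),(C,D));", simple)
  expect_equal(length(read_newick(simple)$tip.label), 4L)
})
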