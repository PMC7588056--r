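make_record <- function(id, sequence, features = list()) {
  path <- tempfile(fileext = ".gb")
  writeLines(genbank_fixture(id, sequence, features), path)
  read_genbank_plastome(path)
}

test_that("GenBank parsing handles simple and spliced features", {
  rec <- make_record("TEST1", "ATGAAATAAGGGCC",
                     list(list(type = "CDS", location = "1..9",
                               gene = "psbA")))
  expect_s3_class(rec, "plastome_record")
  expect_equal(rec$length, 14L)
  f <- rec$features
  expect_equal(nrow(f), 1L)
  expect_equal(unname(f$start), 0)
  expect_equal(unname(f$end), 9)
  expect_equal(f$strand, "+")

  # join on the minus strand: spliced extraction reverse-complements the
  # concatenation of the intervals
  seq12 <- "TTACATGGGTCA"
  rec2 <- make_record("TEST2", seq12,
                      list(list(type = "CDS",
                                location = "complement(join(1..6,10..12))",
                                gene = "matK")))
  f2 <- rec2$features
  expect_equal(nrow(f2), 2L)
  expect_equal(unname(f2$start), c(0, 9))
  expect_equal(unname(f2$end), c(6, 12))
  expect_equal(unique(f2$strand), "-")
  spliced <- plastidscan:::extract_feature_seq(rec2, 1L)
  manual <- paste0(substr(seq12, 1, 6), substr(seq12, 10, 12))
  expect_identical(spliced,
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(manual))))
})

test_that("FASTA input is rejected as a format error", {
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">seq1", "ACGTACGT"), path)
  expect_error(read_genbank_plastome(path), "GenBank")
})

test_that("records round-trip through write/read bit-exactly", {
  rec <- make_record("RT1", paste(rep("ACGTTGCA", 30), collapse = ""),
                     list(list(type = "CDS", location = "1..9", gene = "a"),
                          list(type = "CDS",
                               location = "complement(join(13..18,22..27))",
                               gene = "b"),
                          list(type = "tRNA", location = "31..40",
                               gene = "trnG-UCC")))
  path <- tempfile(fileext = ".gb")
  write_genbank_plastome(rec, path)
  back <- read_genbank_plastome(path)
  expect_identical(back$sequence, rec$sequence)
  expect_identical(back$id, rec$id)
  expect_equal(as.data.frame(back$features), as.data.frame(rec$features))
})

test_that("CDS curation masks internal stops and removes broken genes", {
  gs <- gene_set(c(good = "ATGAAATAA",
                   internal = "ATGTAAAAATAA",
                   nostop = "ATGAAA",
                   offframe = "ATGAAAT",
                   gtg_start = "GTGAAATAA",
                   has_n = "ATGANATAA"), species_id = "sp1")
  flag <- setNames(gs$flag, gs$gene)
  expect_equal(unname(flag["good"]), "ok")
  expect_equal(unname(flag["internal"]), "internal_stop_masked")
  expect_identical(gs$sequence[gs$gene == "internal"], "ATGNNNAAATAA")
  expect_equal(unname(flag["nostop"]), "removed_missing_start_stop")
  expect_equal(unname(flag["offframe"]), "removed_missing_start_stop")
  expect_equal(unname(flag["gtg_start"]), "ok")
  expect_equal(unname(flag["has_n"]), "contains_N")
})

test_that("curation is idempotent on an already-curated gene set", {
  gs <- gene_set(c(a = "ATGAAATAA", b = "ATGTAAAAATAA", c = "ATGAAA"),
                 species_id = "sp1")
  twice <- curate_cds(gs)
  expect_equal(twice$sequence, gs$sequence)
  expect_equal(twice$flag, gs$flag)
})

test_that("shared single-copy N-free gene filtering", {
  s1 <- gene_set(c(matK = "ATGAAATAA", psbA = "ATGCCCTAA"), "sp1")
  s2 <- gene_set(c(matK = "ATGAAATAA", psbA = "ATGCCCTAA",
                   psbA_2 = "ATGCCGTAA"), "sp2")  # duplicated psbA
  expect_equal(shared_single_copy_genes(list(s1, s2)), "matk")

  s3 <- gene_set(c(matK = "ATGANATAA"), "sp3")   # contains N
  expect_warning(out <- shared_single_copy_genes(list(s1, s3)),
                 "no gene")
  expect_length(out, 0L)
  expect_error(shared_single_copy_genes(list(s1)), "at least 2")
})

test_that("quadripartite detection recovers constructed boundaries", {
  set.seed(21)
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  # single-copy flanks end/start with a base that cannot pair with the
  # opposite IR boundary, so the planted repeat cannot extend by chance
  ir <- paste0("G", rand(118), "G")
  lsc <- paste0("A", rand(797), "AA")
  ssc <- paste0("AA", rand(196), "AA")
  genome <- paste0(lsc, ir, ssc, rc(ir))  # 1240 bp
  L <- nchar(genome)
  qs <- detect_quadripartite(genome, min_ir = 50)
  lens <- sapply(qs[c("lsc", "irb", "ssc", "ira")],
                 function(iv) unname(iv["end"] - iv["start"]))
  expect_equal(unname(lens), c(800, 120, 200, 120))
  expect_equal(unname(qs$lsc["start"] %% L), 0)
  # the two IR copies are exact reverse complements
  sub <- function(iv) {
    s <- iv["start"] %% L
    substr(paste0(genome, genome), s + 1, s + unname(iv["end"] - iv["start"]))
  }
  expect_identical(sub(qs$irb), rc(sub(qs$ira)))

  no_ir <- rand(600)
  expect_error(detect_quadripartite(no_ir, min_ir = 50), "no inverted repeat")
})

test_that("quadripartite detection is invariant under circular rotation", {
  set.seed(8)
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  ir <- rand(30)
  genome <- paste0(rand(100), ir, rand(40), rc(ir))  # 200 bp toy
  base <- detect_quadripartite(genome, min_ir = 25)
  base_lens <- sapply(base[c("lsc", "irb", "ssc", "ira")],
                      function(iv) unname(iv["end"] - iv["start"]))
  for (rot in seq(0, 199, by = 13)) {
    g2 <- paste0(substr(genome, rot + 1, 200), substr(genome, 1, rot))
    qs <- detect_quadripartite(g2, min_ir = 25)
    lens <- sapply(qs[c("lsc", "irb", "ssc", "ira")],
                   function(iv) unname(iv["end"] - iv["start"]))
    expect_equal(lens, base_lens)
  }
})

test_that("assembly summaries append a two-decimal mean row", {
  tbl <- tibble::tibble(species = c("s1", "s2", "s3"),
                        genome_bp = c(150000, 151000, 152500),
                        lsc_bp = c(82000, 82100, 82550))
  out <- summarize_assemblies(tbl)
  expect_equal(nrow(out), 4L)
  expect_equal(out$species[4], "Mean (bp)")
  expect_equal(out$genome_bp[4], round(mean(tbl$genome_bp), 2))
  expect_equal(out$lsc_bp[4], round(mean(tbl$lsc_bp), 2))

  one <- summarize_assemblies(tibble::tibble(species = "x",
                                             genome_bp = 1234))
  expect_equal(one$genome_bp[2], 1234)
})
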