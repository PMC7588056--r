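test_that("block collection splits on gap-dense stretches", {
  set.seed(2)
  m <- random_alignment(6, 600)
  one <- collect_blocks(m, min_length = 100, max_gap_fraction = 0.1)
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start, one$end), c(0L, 600L))

  m2 <- m
  m2[, 301:350] <- "-"
  two <- collect_blocks(m2, min_length = 100, max_gap_fraction = 0.1)
  expect_equal(nrow(two), 2L)
  expect_equal(two$start, c(0L, 350L))
  expect_equal(two$end, c(300L, 600L))
  expect_true(all(two$d_defined))

  expect_warning(none <- collect_blocks(m2[, 290:360], min_length = 100),
                 "no block")
  expect_equal(nrow(none), 0L)
})

test_that("block boundaries track truth region joins marked by gaps", {
  tr <- simulate_species_tree(8, 2, 0.05, seed = 4)
  plan <- default_region_plan(6000, 0.25, 2)
  sim <- evolve_alignment(tr, plan, seed = 5, boundary_gap = 12)
  bl <- collect_blocks(sim$alignment, min_length = 150,
                       max_gap_fraction = 0.1)
  truth_edges <- sort(unique(c(sim$truth$regions$start,
                               sim$truth$regions$end)))
  for (i in seq_len(nrow(bl))) {
    expect_true(min(abs(truth_edges - bl$start[i])) <= 12)
    expect_true(min(abs(truth_edges - bl$end[i])) <= 12)
  }
})

fake_blocks <- function(D) {
  out <- tibble::tibble(block_id = seq_along(D),
                        start = (seq_along(D) - 1L) * 100L,
                        end = seq_along(D) * 100L,
                        length = 100L, gap_fraction = 0,
                        usable_sites = 100L, S = 10L,
                        pi_per_site = 0.01, theta_w = 3,
                        D = D, d_defined = !is.na(D))
  class(out) <- c("aligned_blocks", class(out))
  out
}

test_that("selection applies a strict lower threshold on D", {
  bl <- fake_blocks(c(-1.2, -0.4, 0.1))
  sel <- select_blocks(bl, d_threshold = -0.5)
  expect_equal(sel$block_id, c(2L, 3L))

  none <- select_blocks(fake_blocks(c(NA_real_, NA_real_)))
  expect_equal(nrow(none), 0L)

  # boundary is strict: D exactly at the threshold is not selected
  expect_equal(nrow(select_blocks(fake_blocks(-0.5), -0.5)), 0L)

  # optional symmetric upper bound
  both <- select_blocks(fake_blocks(c(-0.2, 0.7)), -0.5,
                        upper_threshold = 0.5)
  expect_equal(both$block_id, 1L)
})

test_that("lowering the threshold never removes a selected block", {
  set.seed(77)
  d_vals <- runif(30, -3, 1)
  bl <- fake_blocks(d_vals)
  for (thr in c(0, -0.5, -1, -2)) {
    hi <- select_blocks(bl, thr)
    lo <- select_blocks(bl, thr - 0.7)
    expect_true(all(hi$block_id %in% lo$block_id))
  }
})

test_that("genotype matrix keeps only clean segregating columns", {
  m <- matrix("A", 17, 300, dimnames = list(sprintf("t%02d", 1:17), NULL))
  m[1, 50] <- "G"                      # one segregating site
  m[3, 120] <- "-"                     # gap column must be excluded
  m[4, 120] <- "T"
  bl <- collect_blocks(m, min_length = 100, max_gap_fraction = 0.2)
  sel <- select_blocks(bl, d_threshold = -5)
  gm <- build_genotype_matrix(m, sel)
  expect_equal(dim(gm$matrix), c(17L, 1L))
  expect_equal(gm$sites$column, 49L)
  expect_equal(gm$report$n_segregating, 1L)
  expect_equal(gm$report$total_length, sum(sel$length))

  flat <- matrix("C", 6, 200, dimnames = list(letters[1:6], NULL))
  blf <- collect_blocks(flat, min_length = 100)
  expect_error(build_genotype_matrix(flat, select_blocks(blf, -5)),
               "no segregating|no selected")
})

test_that("report accounting is re-derivable from the BED output", {
  tr <- simulate_species_tree(10, 2, 0.05, seed = 9)
  sim <- evolve_alignment(tr, default_region_plan(8000, 0.2, 2), seed = 10,
                          boundary_gap = 15)
  sel <- select_blocks(collect_blocks(sim$alignment))
  gm <- build_genotype_matrix(sim$alignment, sel)
  bed <- tempfile(fileext = ".bed")
  write_blocks_bed(sel, bed)
  b <- read.table(bed, sep = "\t")
  expect_equal(sum(b$V3 - b$V2), gm$report$total_length)
  expect_equal(gm$report$n_segregating, ncol(gm$matrix))
})

test_that("proximal genes respect the distance cutoff and ordering", {
  ann <- tibble::tibble(gene = c("matK", "psbI", "ndhD"),
                        start = c(1000, 5000, 40000),
                        end = c(2500, 5400, 41500))
  sel <- fake_blocks(c(0, 0.2))
  sel$start <- c(2000L, 4000L); sel$end <- c(2200L, 4400L)
  hits <- proximal_genes(sel, ann, projection = "identity",
                         max_distance = 1000)
  expect_equal(hits, c("matK", "psbI"))

  far <- fake_blocks(0.1)
  far$start <- 20000L; far$end <- 20500L
  expect_length(proximal_genes(far, ann, projection = "identity",
                               max_distance = 1000), 0L)
  expect_error(proximal_genes(sel, ann), "projection")

  # explicit projection map: block columns all map 10 kb downstream
  proj <- seq_len(4400) + 39000
  shifted <- proximal_genes(sel, ann, projection = proj,
                            max_distance = 500)
  expect_equal(shifted, "ndhD")
})

test_that("selected sites recapitulate the true topology; constrained sites do not", {
  rf_sel <- integer(0); rf_con <- integer(0)
  for (s in 1:6) {
    tr <- simulate_species_tree(16, 4, 0.05, seed = s)
    sim <- evolve_alignment(tr, default_region_plan(30000, 0.2, 5),
                            seed = s + 600, boundary_gap = 20)
    sel <- select_blocks(collect_blocks(sim$alignment))
    gm <- build_genotype_matrix(sim$alignment, sel)
    t_sel <- neighbor_joining(hamming_distance_matrix(gm))
    rf_sel <- c(rf_sel, robinson_foulds(t_sel, tr)$rf)

    # equal-length sample of constrained-regime columns
    lab <- sim$truth$region_labels
    con_cols <- which(lab == "constrained")[seq_len(gm$report$total_length)]
    con_aln <- sim$alignment[, con_cols]
    bl_con <- fake_blocks(0)
    bl_con$start <- 0L; bl_con$end <- ncol(con_aln)
    bl_con$length <- ncol(con_aln)
    gm_con <- build_genotype_matrix(con_aln, bl_con)
    t_con <- neighbor_joining(hamming_distance_matrix(gm_con))
    rf_con <- c(rf_con, robinson_foulds(t_con, tr)$rf)
  }
  expect_gte(mean(rf_sel == 0), 0.8)
  expect_gt(mean(rf_con > 0), 0.5)
})
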