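pipeline_defaults <- function() {
  list(
    mode = "synthetic",
    out_dir = NULL,
    seed = 1L,
    # synthetic-mode simulation parameters
    n_ingroup = 16L, n_clades = 4L, depth = 0.05,
    alignment_length = 50000L, neutral_fraction = 0.2, n_neutral = 5L,
    constrained_rate = 0.08, neutral_rate = 0.05, terminal_bias = 0.95,
    boundary_gap = 20L, gap_rate = 0,
    n_genes = 57L, gene_length = 300L, syn_rate = 2, nonsyn_rate = 0.4,
    # scan / selection parameters
    window = 500L, step = 100L, max_gap_fraction = 0.2, min_usable = 100L,
    min_block_length = 150L, block_max_gap_fraction = 0.1,
    d_threshold = -0.5, upper_threshold = NULL,
    # trees
    tree_builder = "nj", n_bootstrap = 1000L,
    # Ks
    ks_method = "kde", ks_binwidth = 0.005,
    # real-mode inputs
    alignment_fasta = NULL, genbank_dir = NULL, gene_fasta_dir = NULL,
    reference_newick = NULL
  )
}

#' Validate and normalise a pipeline configuration
#'
#' Accepts a YAML file path or a named list; fills in defaults, rejects
#' unknown keys, and checks ranges, reporting every violation at once.
#'
#' @param config path to a YAML file, or a named list.
#' @return a list of class `"pipeline_config"` with every key populated.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  problems <- character(0)
  if (length(unknown) > 0) {
    problems <- c(problems, paste0("unknown key(s): ",
                                   paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config[intersect(names(config),
                                                      names(defaults))])
  num_ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk <- function(cond, msg) if (!cond) problems <<- c(problems, msg)
  chk(cfg$mode %in% c("synthetic", "real"),
      "mode must be 'synthetic' or 'real'")
  for (key in c("seed", "n_ingroup", "n_clades", "depth",
                "alignment_length", "neutral_fraction", "n_neutral",
                "constrained_rate", "neutral_rate", "terminal_bias",
                "boundary_gap", "gap_rate", "n_genes", "gene_length",
                "syn_rate", "nonsyn_rate", "window", "step",
                "max_gap_fraction", "min_usable", "min_block_length",
                "block_max_gap_fraction", "d_threshold", "n_bootstrap",
                "ks_binwidth")) {
    chk(num_ok(cfg[[key]]), paste0(key, " must be a finite number"))
  }
  if (num_ok(cfg$max_gap_fraction)) {
    chk(cfg$max_gap_fraction >= 0 && cfg$max_gap_fraction <= 1,
        "max_gap_fraction must lie in [0,1]")
  }
  if (num_ok(cfg$block_max_gap_fraction)) {
    chk(cfg$block_max_gap_fraction >= 0 && cfg$block_max_gap_fraction <= 1,
        "block_max_gap_fraction must lie in [0,1]")
  }
  if (num_ok(cfg$terminal_bias)) {
    chk(cfg$terminal_bias >= 0 && cfg$terminal_bias <= 1,
        "terminal_bias must lie in [0,1]")
  }
  if (num_ok(cfg$neutral_fraction)) {
    chk(cfg$neutral_fraction > 0 && cfg$neutral_fraction < 1,
        "neutral_fraction must lie in (0,1)")
  }
  if (num_ok(cfg$window) && num_ok(cfg$step)) {
    chk(cfg$window >= cfg$step && cfg$step >= 1,
        "need window >= step >= 1")
  }
  chk(cfg$tree_builder %in% c("nj", "upgma"),
      "tree_builder must be 'nj' or 'upgma'")
  chk(cfg$ks_method %in% c("histogram", "kde"),
      "ks_method must be 'histogram' or 'kde'")
  if (length(problems) > 0) {
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

stage_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

run_stage <- function(stage, expr) {
  tryCatch(force(expr), error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full marker-discovery pipeline
#'
#' Synthetic mode: simulates a clade-structured species tree, a
#' two-regime plastome alignment and orthologous codon genes, then scans,
#' selects neutral blocks, builds the genotype matrix and trees, compares
#' against the true tree, and classifies taxa by modal Ks. Real mode:
#' consumes a whole-plastome alignment FASTA (plus optional codon-gene
#' FASTAs, GenBank records and a reference newick) and runs the same
#' downstream stages. Intermediate artifacts (window TSV, blocks BED,
#' genotype TSV, newick trees, report JSON) are persisted to `out_dir`
#' when one is configured.
#'
#' @param config a [validate_config()] result, a path, or a list.
#' @return a list of class `"run_report"`; see [glance.run_report()].
#' @export
run_pipeline <- function(config = list()) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  out_dir <- config$out_dir
  persist <- !is.null(out_dir)
  if (persist && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  truth <- NULL; ref_tree <- NULL; gene_sets <- NULL
  if (config$mode == "synthetic") {
    sim <- run_stage("simulate", {
      tree <- simulate_species_tree(config$n_ingroup, config$n_clades,
                                    config$depth, config$seed)
      plan <- default_region_plan(config$alignment_length,
                                  config$neutral_fraction, config$n_neutral,
                                  config$constrained_rate,
                                  config$neutral_rate, config$terminal_bias)
      evolve_alignment(tree, plan, seed = config$seed + 1,
                       gap_rate = config$gap_rate,
                       boundary_gap = config$boundary_gap)
    })
    aln <- sim$alignment
    truth <- sim$truth
    ref_tree <- truth$tree
    stage_msg("simulate", "alignment %d taxa x %d columns",
              nrow(aln), ncol(aln))
    if (config$n_genes > 0) {
      genes <- run_stage("simulate_genes", {
        evolve_codon_genes(truth$tree, config$n_genes, config$syn_rate,
                           config$nonsyn_rate, config$gene_length,
                           seed = config$seed + 2)
      })
      gene_sets <- genes$gene_sets
    }
    if (persist) {
      write_alignment(aln, file.path(out_dir, "alignment.fasta"))
      write_newick(ref_tree, file.path(out_dir, "true_tree.nwk"))
      write_simulation_truth(sim,
                             json_path = file.path(out_dir, "truth.json"),
                             bed_path = file.path(out_dir, "truth.bed"))
    }
  } else {
    if (is.null(config$alignment_fasta)) {
      stop("real mode requires alignment_fasta", call. = FALSE)
    }
    aln <- run_stage("load", read_alignment(config$alignment_fasta))
    stage_msg("load", "alignment %d taxa x %d columns", nrow(aln), ncol(aln))
    if (!is.null(config$reference_newick)) {
      ref_tree <- run_stage("load", read_newick(config$reference_newick))
    }
    if (!is.null(config$gene_fasta_dir)) {
      gene_sets <- run_stage("load", read_gene_fasta_dir(config$gene_fasta_dir))
    } else if (!is.null(config$genbank_dir)) {
      gene_sets <- run_stage("curate", {
        paths <- list.files(config$genbank_dir, full.names = TRUE)
        sets <- purrr::map(paths, function(p) {
          curate_cds(read_genbank_plastome(p))
        })
        shared <- shared_single_copy_genes(sets)
        purrr::map(stats::setNames(sets, purrr::map_chr(sets, attr,
                                                        "species_id")),
                   function(gs) {
                     stats::setNames(gs$sequence, gs$gene)[shared]
                   })
      })
    } else {
      warning("no gene inputs configured: Ks stage skipped", call. = FALSE)
    }
  }

  scan <- run_stage("scan", {
    window_scan(aln, window = config$window, step = config$step,
                max_gap_fraction = config$max_gap_fraction,
                min_usable = config$min_usable)
  })
  stage_msg("scan", "%d windows (%d usable)", nrow(scan),
            sum(scan$flag == "ok"))
  if (persist) write_window_scan(scan, file.path(out_dir, "windows.tsv"))

  blocks <- run_stage("select", {
    collect_blocks(aln, min_length = config$min_block_length,
                   max_gap_fraction = config$block_max_gap_fraction)
  })
  selected <- run_stage("select", {
    select_blocks(blocks, d_threshold = config$d_threshold,
                  upper_threshold = config$upper_threshold)
  })
  stage_msg("select", "%d of %d blocks pass D > %g", nrow(selected),
            nrow(blocks), config$d_threshold)
  if (persist) {
    write_blocks_bed(blocks, file.path(out_dir, "blocks_all.bed"))
    write_blocks_bed(selected, file.path(out_dir, "blocks_selected.bed"))
  }

  gm <- run_stage("genotype", build_genotype_matrix(aln, selected))
  stage_msg("genotype", "%d segregating sites over %d bp",
            gm$report$n_segregating, gm$report$total_length)
  if (persist) write_genotype_matrix(gm, file.path(out_dir, "genotype.tsv"))

  marker_tree <- run_stage("tree", {
    if (config$n_bootstrap > 0) {
      bootstrap_support(gm, builder = config$tree_builder,
                        n_reps = config$n_bootstrap, seed = config$seed)
    } else {
      d <- hamming_distance_matrix(gm)
      if (config$tree_builder == "nj") neighbor_joining(d) else upgma(d)
    }
  })
  upgma_tree <- run_stage("tree", upgma(hamming_distance_matrix(gm)))
  if (persist) {
    write_newick(marker_tree, file.path(out_dir, "marker_tree.nwk"))
    write_newick(upgma_tree, file.path(out_dir, "genotype_upgma.nwk"))
  }

  rf <- NULL
  if (!is.null(ref_tree)) {
    rf <- run_stage("compare", robinson_foulds(marker_tree, ref_tree))
    stage_msg("compare", "RF to reference tree = %d (normalized %.3f)",
              rf$rf, rf$normalized)
  }

  ksm <- NULL
  if (!is.null(gene_sets) && length(gene_sets) >= 3L) {
    ksm <- run_stage("ks", {
      suppressMessages(ks_distance_matrix(gene_sets,
                                          method = config$ks_method,
                                          binwidth = config$ks_binwidth))
    })
    if (persist) write_ks_matrix(ksm, file.path(out_dir, "ks_matrix.tsv"))
  }

  recovery <- NULL
  if (!is.null(truth)) {
    lab <- truth$region_labels[gm$sites$column + 1L]
    recovery <- list(
      neutral_column_fraction = mean(lab == "neutral"),
      selected_blocks = nrow(selected))
  }

  report <- structure(list(
    config = unclass(config),
    version = as.character(utils::packageVersion("plastidscan")),
    n_taxa = nrow(aln), alignment_length = ncol(aln),
    n_windows = nrow(scan), n_blocks = nrow(blocks),
    n_blocks_selected = nrow(selected),
    selection = gm$report,
    rf = rf,
    nearest = if (!is.null(ksm)) ksm$nearest else NULL,
    recovery = recovery,
    elapsed = proc.time()[["elapsed"]] - t0),
    class = "run_report")
  if (persist) {
    jsonlite::write_json(
      report_as_list(report), file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
  }
  report
}

report_as_list <- function(report) {
  out <- unclass(report)
  out$selection <- unclass(out$selection)
  if (!is.null(out$nearest)) out$nearest <- as.data.frame(out$nearest)
  out$config <- out$config[!vapply(out$config, is.null, logical(1))]
  # timings and output paths excluded so reruns are byte-identical
  out$config$out_dir <- NULL
  out$elapsed <- NULL
  out
}

read_gene_fasta_dir <- function(dir) {
  paths <- list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  sets <- list()
  for (p in paths) {
    gene <- sub("\\.(fa|fasta)$", "", basename(p))
    ss <- Biostrings::readBStringSet(p)
    for (i in seq_along(ss)) {
      taxon <- sub("\\s.*$", "", names(ss)[i])
      sets[[taxon]][gene] <- as.character(ss[[i]])
    }
  }
  sets
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d taxa, %d columns\n", x$n_taxa,
              x$alignment_length))
  cat(sprintf("  blocks: %d collected, %d selected (%d bp, %d segregating sites)\n",
              x$n_blocks, x$n_blocks_selected, x$selection$total_length,
              x$selection$n_segregating))
  if (!is.null(x$rf)) {
    cat(sprintf("  RF to reference tree: %d (normalized %.3f)\n",
                x$rf$rf, x$rf$normalized))
  }
  if (!is.null(x$recovery)) {
    cat(sprintf("  truth-neutral fraction of selected sites: %.3f\n",
                x$recovery$neutral_column_fraction))
  }
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x a [run_pipeline()] result.
#' @param ... ignored.
#' @export
glance.run_report <- function(x, ...) {
  tibble::tibble(
    n_taxa = x$n_taxa, alignment_length = x$alignment_length,
    n_blocks = x$n_blocks, n_blocks_selected = x$n_blocks_selected,
    total_length = x$selection$total_length,
    n_segregating = x$selection$n_segregating,
    rf = if (!is.null(x$rf)) x$rf$rf else NA_integer_,
    neutral_column_fraction = if (!is.null(x$recovery))
      x$recovery$neutral_column_fraction else NA_real_)
}
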