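# Minimal GenBank flat-file reader for plastid genome records.
#
# Coordinates are converted to 0-based half-open at the parsing boundary
# and stay that way throughout the package; the 1-based closed GenBank
# convention exists only in this file.

parse_location <- function(loc) {
  loc <- gsub("[<>]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  }
  parts <- strsplit(loc, ",")[[1L]]
  ivs <- lapply(parts, function(p) {
    p <- gsub("complement\\(|\\)", "", p)
    nums <- as.numeric(strsplit(p, "\\.\\.")[[1L]])
    if (any(is.na(nums))) return(NULL)
    if (length(nums) == 1L) nums <- c(nums, nums)
    c(start = nums[1L] - 1, end = nums[2L])  # to 0-based half-open
  })
  if (any(vapply(ivs, is.null, logical(1)))) return(NULL)
  list(strand = strand, intervals = do.call(rbind, ivs))
}

#' Read a plastid genome record from a GenBank flat file
#'
#' Parses the LOCUS line, the CDS/tRNA/rRNA features (including
#' multi-interval `join(...)` and `complement(...)` locations) and the
#' ORIGIN sequence. Unparseable features are logged via a message and
#' skipped; a file with no sequence (e.g. plain FASTA) is a format error.
#'
#' @param path path to a GenBank flat file.
#' @return an object of class `"plastome_record"`: a list with `id`,
#'   `sequence` (uppercase string), `length`, and `features` (tibble:
#'   `feature_id`, `gene`, `type`, `strand`, `part`, `start`, `end`;
#'   coordinates 0-based half-open).
#' @export
read_genbank_plastome <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^LOCUS", lines)) || !any(grepl("^ORIGIN", lines))) {
    stop("not a GenBank flat file (missing LOCUS/ORIGIN)", call. = FALSE)
  }
  locus <- lines[grepl("^LOCUS", lines)][1L]
  id <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1L]][1L]

  ori <- which(grepl("^ORIGIN", lines))[1L]
  seq_lines <- lines[(ori + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) {
    stop("GenBank record has an empty sequence", call. = FALSE)
  }

  feat_start <- which(grepl("^FEATURES", lines))
  feats <- tibble::tibble(feature_id = integer(0), gene = character(0),
                          type = character(0), strand = character(0),
                          part = integer(0), start = numeric(0),
                          end = numeric(0))
  if (length(feat_start) > 0) {
    block <- lines[(feat_start[1L] + 1L):(ori - 1L)]
    # a feature header is 5 spaces + key + location (location may wrap)
    is_hdr <- grepl("^ {5}\\S", block)
    hdr_idx <- which(is_hdr)
    fid <- 0L
    rows <- list()
    for (hi in seq_along(hdr_idx)) {
      i <- hdr_idx[hi]
      key <- strsplit(trimws(block[i]), "\\s+")[[1L]]
      type <- key[1L]
      if (!type %in% c("CDS", "tRNA", "rRNA")) next
      loc <- paste(key[-1L], collapse = "")
      j <- i + 1L
      lim <- if (hi < length(hdr_idx)) hdr_idx[hi + 1L] - 1L else length(block)
      while (j <= lim && !grepl("^ {21}/", block[j])) {
        loc <- paste0(loc, trimws(block[j])); j <- j + 1L
      }
      quals <- block[j:lim][grepl("^ {21}/", block[j:lim])]
      gene <- sub('^.*?/gene="?([^"]*)"?.*$', "\\1",
                  quals[grepl("/gene", quals)][1L])
      if (length(gene) == 0L || is.na(gene)) {
        gene <- sub('^.*?/product="?([^"]*)"?.*$', "\\1",
                    quals[grepl("/product", quals)][1L])
      }
      if (length(gene) == 0L || is.na(gene)) gene <- paste0("feature", hi)
      pl <- parse_location(loc)
      if (is.null(pl)) {
        message("skipping unparseable feature location: ", loc)
        next
      }
      if (any(pl$intervals[, "start"] < 0) ||
          any(pl$intervals[, "end"] > nchar(sequence))) {
        message("skipping out-of-range feature: ", loc)
        next
      }
      fid <- fid + 1L
      rows[[fid]] <- tibble::tibble(
        feature_id = fid, gene = gene, type = type, strand = pl$strand,
        part = seq_len(nrow(pl$intervals)),
        start = pl$intervals[, "start"], end = pl$intervals[, "end"])
    }
    if (length(rows) > 0) feats <- dplyr::bind_rows(rows)
  }
  structure(list(id = id, sequence = sequence, length = nchar(sequence),
                 features = feats),
            class = "plastome_record")
}

#' @export
print.plastome_record <- function(x, ...) {
  cat(sprintf("<plastome_record> %s: %d bp, %d feature(s)\n",
              x$id, x$length, length(unique(x$features$feature_id))))
  invisible(x)
}

#' Write a plastome record back to a GenBank flat file
#'
#' Emits the minimal subset of the format that [read_genbank_plastome()]
#' consumes, so that a write/read round trip preserves the id, sequence
#' and every feature interval bit-exactly.
#'
#' @param record a `plastome_record`.
#' @param path output path.
#' @export
write_genbank_plastome <- function(record, path) {
  stopifnot(inherits(record, "plastome_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     circular PLN",
                     record$id, record$length), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  f <- record$features
  for (fid in unique(f$feature_id)) {
    ff <- f[f$feature_id == fid, ]
    segs <- sprintf("%d..%d", ff$start + 1, ff$end)
    loc <- if (length(segs) > 1L) sprintf("join(%s)", paste(segs, collapse = ","))
           else segs
    if (ff$strand[1L] == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-16s%s", ff$type[1L], loc), con)
    writeLines(sprintf('                     /gene="%s"', ff$gene[1L]), con)
  }
  writeLines("ORIGIN", con)
  s <- record$sequence
  for (i in seq(1L, nchar(s), 60L)) {
    writeLines(sprintf("%9d %s", i,
                       tolower(substr(s, i, min(i + 59L, nchar(s))))), con)
  }
  writeLines("//", con)
  invisible(path)
}

# spliced, strand-resolved CDS extraction: concatenate the intervals in
# file order, then reverse-complement the concatenation on '-' strand
extract_feature_seq <- function(record, fid) {
  ff <- record$features[record$features$feature_id == fid, ]
  parts <- vapply(seq_len(nrow(ff)), function(i) {
    substr(record$sequence, ff$start[i] + 1L, ff$end[i])
  }, character(1))
  s <- paste(parts, collapse = "")
  if (ff$strand[1L] == "-") s <- revcomp(s)
  s
}
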