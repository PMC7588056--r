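# Codon-level lookup tables for the NG86 machinery and the codon-gene
# simulator. Built once per session and cached.
#
# Conventions (standard genetic code throughout):
#   - synonymous-site fraction of a codon position = (# of the 3 possible
#     single-nucleotide changes at that position that preserve the amino
#     acid) / 3; changes creating a stop codon count as nonsynonymous;
#   - for codon pairs differing at d positions, Sd/Nd are averaged over
#     the d! minimal mutational pathways, excluding pathways that pass
#     through a stop codon (if every pathway is blocked, all are used).
.codon_cache <- new.env(parent = emptyenv())

codon_tables <- function() {
  if (!is.null(.codon_cache$tab)) return(.codon_cache$tab)
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- sort(codons)
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  is_stop <- aa == "*"

  nbr <- vector("list", 64L)        # neighbor codon indices (9 per codon)
  nbr_syn <- vector("list", 64L)    # TRUE if neighbor change is synonymous
  nbr_stop <- vector("list", 64L)   # TRUE if neighbor is a stop codon
  syn_sites <- numeric(64L)
  for (i in seq_len(64L)) {
    cd <- strsplit(codons[i], "")[[1L]]
    nb <- character(0); sy <- logical(0); st <- logical(0)
    for (pos in 1:3) {
      for (b in setdiff(bases, cd[pos])) {
        alt <- cd; alt[pos] <- b
        alt <- paste(alt, collapse = "")
        nb <- c(nb, alt)
        sy <- c(sy, identical(gc[[alt]], aa[i]) && gc[[alt]] != "*")
        st <- c(st, gc[[alt]] == "*")
      }
    }
    nbr[[i]] <- match(nb, codons)
    nbr_syn[[i]] <- sy
    nbr_stop[[i]] <- st
    syn_sites[i] <- sum(sy) / 3
  }

  tab <- list(codons = codons, aa = aa, is_stop = is_stop,
              nbr = nbr, nbr_syn = nbr_syn, nbr_stop = nbr_stop,
              syn_sites = syn_sites, nonsyn_sites = 3 - syn_sites)
  .codon_cache$tab <- tab
  tab
}

# classify a single codon step a -> b (differing at exactly one position):
# c(syn, nonsyn) as 0/1
step_class <- function(a, b, gc) {
  if (gc[[a]] == gc[[b]] && gc[[a]] != "*") c(1, 0) else c(0, 1)
}

# Sd/Nd for one codon pair by enumeration of minimal pathways
pair_path_counts <- function(ca, cb) {
  gc <- Biostrings::GENETIC_CODE
  pa <- strsplit(ca, "")[[1L]]
  pb <- strsplit(cb, "")[[1L]]
  diff_pos <- which(pa != pb)
  d <- length(diff_pos)
  if (d == 0L) return(c(Sd = 0, Nd = 0))
  orders <- if (d == 1L) list(diff_pos) else {
    perms <- function(v) {
      if (length(v) == 1L) return(list(v))
      out <- list()
      for (i in seq_along(v)) {
        for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
      }
      out
    }
    perms(diff_pos)
  }
  acc <- list()
  for (ord in orders) {
    cur <- pa; sd <- 0; nd <- 0; blocked <- FALSE
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- pb[pos]
      a_cd <- paste(cur, collapse = ""); b_cd <- paste(nxt, collapse = "")
      if (gc[[b_cd]] == "*" && b_cd != cb) blocked <- TRUE
      cls <- step_class(a_cd, b_cd, gc)
      sd <- sd + cls[1L]; nd <- nd + cls[2L]
      cur <- nxt
    }
    acc[[length(acc) + 1L]] <- c(sd, nd, blocked)
  }
  m <- do.call(rbind, acc)
  keep <- m[, 3L] == 0
  if (!any(keep)) keep <- rep(TRUE, nrow(m))
  c(Sd = mean(m[keep, 1L]), Nd = mean(m[keep, 2L]))
}

# 64x64 cached Sd/Nd matrices (pairs involving stop codons are NA; those
# pairs are dropped by pair_codons upstream)
pair_count_matrices <- function() {
  if (!is.null(.codon_cache$pairmat)) return(.codon_cache$pairmat)
  tab <- codon_tables()
  k <- 64L
  Sd <- matrix(NA_real_, k, k, dimnames = list(tab$codons, tab$codons))
  Nd <- Sd
  for (i in seq_len(k)) {
    if (tab$is_stop[i]) next
    for (j in seq_len(k)) {
      if (tab$is_stop[j]) next
      if (j < i) { Sd[i, j] <- Sd[j, i]; Nd[i, j] <- Nd[j, i]; next }
      cnt <- pair_path_counts(tab$codons[i], tab$codons[j])
      Sd[i, j] <- cnt[["Sd"]]; Nd[i, j] <- cnt[["Nd"]]
    }
  }
  .codon_cache$pairmat <- list(Sd = Sd, Nd = Nd)
  .codon_cache$pairmat
}

split_codons <- function(seq) {
  L <- nchar(seq)
  if (L %% 3L != 0L) {
    stop("sequence length not divisible by 3", call. = FALSE)
  }
  substring(seq, seq(1L, L, 3L), seq(3L, L, 3L))
}
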