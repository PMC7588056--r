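# Independent oracles used to cross-check the package implementations.
# These are written from the defining formulas / by exhaustive
# enumeration, deliberately not sharing code with the package internals.

# --- Tajima's D from the direct formula, pi by exhaustive pair counting ---
oracle_tajima <- function(m) {
  keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  S <- sum(apply(m, 2, function(col) length(unique(col)) > 1))
  pr <- utils::combn(n, 2)
  pi_count <- sum(apply(pr, 2, function(p) sum(m[p[1], ] != m[p[2], ]))) /
    ncol(pr)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  vd <- e1 * S + e2 * S * (S - 1)
  list(S = S, pi = pi_count, theta = S / a1,
       D = if (S > 0 && vd > 0) (pi_count - S / a1) / sqrt(vd) else NA_real_,
       usable = ncol(m))
}

oracle_pi_per_site <- function(m) {
  o <- oracle_tajima(m)
  o$pi / o$usable
}

# --- NG86 pathway enumeration by recursion over remaining positions -------
oracle_ng86_path <- function(ca, cb) {
  gc <- Biostrings::GENETIC_CODE
  pa <- strsplit(ca, "")[[1]]
  pb <- strsplit(cb, "")[[1]]
  walk <- function(cur, remaining) {
    # returns matrix of c(sd, nd, blocked) over all orderings
    if (length(remaining) == 0) return(matrix(c(0, 0, 0), nrow = 1))
    out <- NULL
    for (pos in remaining) {
      nxt <- cur
      nxt[pos] <- pb[pos]
      from <- paste(cur, collapse = "")
      to <- paste(nxt, collapse = "")
      syn <- gc[[from]] == gc[[to]] && gc[[to]] != "*"
      blocked <- gc[[to]] == "*" && length(remaining) > 1
      rest <- walk(nxt, setdiff(remaining, pos))
      rest[, 1] <- rest[, 1] + as.numeric(syn)
      rest[, 2] <- rest[, 2] + as.numeric(!syn)
      rest[, 3] <- pmax(rest[, 3], as.numeric(blocked))
      out <- rbind(out, rest)
    }
    out
  }
  m <- walk(pa, which(pa != pb))
  keep <- m[, 3] == 0
  if (!any(keep)) keep <- rep(TRUE, nrow(m))
  c(Sd = mean(m[keep, 1]), Nd = mean(m[keep, 2]))
}

# --- Robinson-Foulds by explicit bipartition sets -------------------------
oracle_rf <- function(t1, t2) {
  splits <- function(tr) {
    tr <- ape::unroot(tr)
    tips <- sort(tr$tip.label)
    pp <- ape::prop.part(tr)
    labs <- attr(pp, "labels")
    out <- character(0)
    for (p in pp) {
      side <- labs[p]
      if (tips[1] %in% side) side <- setdiff(tips, side)
      if (length(side) >= 2 && length(side) <= length(tips) - 2) {
        out <- c(out, paste(sort(side), collapse = "|"))
      }
    }
    unique(out)
  }
  s1 <- splits(t1); s2 <- splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# --- TN93 from the published closed form, written independently ----------
oracle_tn93 <- function(x, y) {
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  x <- x[ok]; y <- y[ok]
  f <- table(factor(c(x, y), levels = c("A", "C", "G", "T"))) /
    (2 * length(x))
  gA <- f[["A"]]; gC <- f[["C"]]; gG <- f[["G"]]; gT <- f[["T"]]
  gR <- gA + gG; gY <- gC + gT
  P1 <- mean((x == "A" & y == "G") | (x == "G" & y == "A"))
  P2 <- mean((x == "C" & y == "T") | (x == "T" & y == "C"))
  Q <- mean(x != y) - P1 - P2
  -2 * gA * gG / gR * log(1 - gR * P1 / (2 * gA * gG) - Q / (2 * gR)) -
    2 * gT * gC / gY * log(1 - gY * P2 / (2 * gT * gC) - Q / (2 * gY)) -
    2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY) *
      log(1 - Q / (2 * gR * gY))
}

# --- small random fixtures ------------------------------------------------
random_alignment <- function(n, len, gap_prob = 0) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n, dimnames = list(paste0("t", seq_len(n)), NULL))
  if (gap_prob > 0) {
    g <- runif(n * len) < gap_prob
    m[g] <- "-"
  }
  m
}

sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all64 <- sort(as.vector(outer(outer(b, b, paste0), b, paste0)))
  all64[Biostrings::GENETIC_CODE[all64] != "*"]
}

# minimal GenBank flat-file text, built in code
genbank_fixture <- function(id, sequence, features = list()) {
  lines <- c(sprintf("LOCUS       %s %d bp    DNA     circular PLN",
                     id, nchar(sequence)),
             "FEATURES             Location/Qualifiers")
  for (f in features) {
    lines <- c(lines,
               sprintf("     %-16s%s", f$type, f$location),
               sprintf('                     /gene="%s"', f$gene))
  }
  lines <- c(lines, "ORIGIN")
  for (i in seq(1, nchar(sequence), 60)) {
    lines <- c(lines, sprintf("%9d %s", i,
                              tolower(substr(sequence, i,
                                             min(i + 59, nchar(sequence))))))
  }
  c(lines, "//")
}
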