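#' Constants of Tajima's D
#'
#' The dimensionless constants `a1, a2, b1, b2, c1, c2, e1, e2` that enter
#' the variance normalisation of Tajima's D for a sample of `n` sequences.
#'
#' @param n number of sequences (>= 2).
#' @return a named list of the eight constants.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

# which columns are usable under the exclude_column gap policy
usable_columns <- function(prof) prof$gapn == 0

# per-column mean pairwise difference count, for usable columns with all
# n rows present: choose(n,2) minus matched pairs, divided by choose(n,2)
# happens later; here we return raw pairwise-difference counts per column
column_pair_diffs <- function(counts) {
  n_col <- rowSums(counts)
  (n_col * (n_col - 1) - rowSums(counts * (counts - 1))) / 2
}

column_is_segregating <- function(counts) rowSums(counts > 0) >= 2

#' Segregating sites of an alignment
#'
#' A site is segregating when at least two distinct bases among `{A,C,G,T}`
#' are present in its column. Under the default `exclude_column` policy any
#' column containing a gap (`-`), `N` or `?` is skipped entirely (the
#' convention of counting sites "excluding gaps"); under `pairwise` the
#' missing entries are ignored but the remaining bases in the column still
#' count.
#'
#' @param aln an alignment (see [as_alignment()]).
#' @param gap_policy `"exclude_column"` (default) or `"pairwise"`.
#' @return a list with `S` (count) and `site_indices` (1-based column
#'   indices of the segregating sites).
#' @export
segregating_sites <- function(aln, gap_policy = c("exclude_column", "pairwise")) {
  gap_policy <- match.arg(gap_policy)
  aln <- as_alignment(aln)
  if (nrow(aln) < 2L) stop("need at least 2 sequences", call. = FALSE)
  prof <- aln_profile(aln)
  seg <- column_is_segregating(prof$counts)
  if (gap_policy == "exclude_column") seg <- seg & usable_columns(prof)
  list(S = sum(seg), site_indices = which(seg))
}

#' Nucleotide diversity (pi) per site
#'
#' Mean pairwise difference proportion among all `choose(n, 2)` sequence
#' pairs. Under `exclude_column` the denominator is the number of fully
#' ungapped columns; under `pairwise` every pair uses its own usable sites.
#'
#' @inheritParams segregating_sites
#' @return per-site diversity; `NA` (with a warning) when no usable sites
#'   remain.
#' @export
nucleotide_diversity <- function(aln, gap_policy = c("exclude_column", "pairwise")) {
  gap_policy <- match.arg(gap_policy)
  aln <- as_alignment(aln)
  if (nrow(aln) < 2L) stop("need at least 2 sequences", call. = FALSE)
  if (gap_policy == "exclude_column") {
    prof <- aln_profile(aln)
    use <- usable_columns(prof)
    if (!any(use)) {
      warning("no usable (gap-free) columns; pi undefined", call. = FALSE)
      return(NA_real_)
    }
    n <- prof$n
    pd <- column_pair_diffs(prof$counts[use, , drop = FALSE])
    sum(pd) / choose(n, 2) / sum(use)
  } else {
    m <- unclass(aln)
    ok <- !(m %in% .gap_chars)
    dim(ok) <- dim(m)
    n <- nrow(m)
    pairs <- utils::combn(n, 2)
    per_pair <- apply(pairs, 2L, function(p) {
      use <- ok[p[1], ] & ok[p[2], ]
      if (!any(use)) return(NA_real_)
      mean(m[p[1], use] != m[p[2], use])
    })
    if (all(is.na(per_pair))) {
      warning("no pair shares a usable site; pi undefined", call. = FALSE)
      return(NA_real_)
    }
    mean(per_pair, na.rm = TRUE)
  }
}

#' Tajima's D with all intermediate components
#'
#' Computes `D = (pi - S/a1) / sqrt(e1*S + e2*S*(S-1))` where `pi` is the
#' mean pairwise difference *count* and `S` the segregating-site count,
#' both over gap-free columns (default policy). All constants and
#' intermediate quantities are returned for auditability. `D` is flagged
#' undefined (not zero) when `S = 0`.
#'
#' @inheritParams segregating_sites
#' @return an object of class `"tajima_components"`: a list with `n`, `S`,
#'   `pi` (count units), `pi_per_site`, `theta_w`, the constants
#'   `a1..e2`, `var_d`, `D`, `defined`, and `usable_sites`.
#' @export
tajimas_d <- function(aln, gap_policy = c("exclude_column", "pairwise")) {
  gap_policy <- match.arg(gap_policy)
  aln <- as_alignment(aln)
  n <- nrow(aln)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  low_n <- n < 4L
  prof <- aln_profile(aln)
  use <- if (gap_policy == "exclude_column") usable_columns(prof)
         else rep(TRUE, prof$length)
  counts <- prof$counts[use, , drop = FALSE]
  S <- sum(column_is_segregating(counts))
  pd <- column_pair_diffs(counts)
  # pairwise policy: columns with missing rows still contribute their
  # observed pairs; denominator stays choose(n,2) as in standard practice
  pi_count <- sum(pd) / choose(n, 2)
  k <- tajima_constants(n)
  theta_w <- S / k$a1
  var_d <- k$e1 * S + k$e2 * S * (S - 1)
  defined <- S > 0 && var_d > 0
  D <- if (defined) (pi_count - theta_w) / sqrt(var_d) else NA_real_
  out <- c(list(n = n, S = S, pi = pi_count,
                pi_per_site = if (sum(use) > 0) pi_count / sum(use) else NA_real_,
                theta_w = theta_w),
           k,
           list(var_d = var_d, D = D, defined = defined,
                usable_sites = sum(use), low_n = low_n))
  if (low_n) warning("fewer than 4 sequences: D is poorly behaved",
                     call. = FALSE)
  structure(out, class = "tajima_components")
}

#' @export
print.tajima_components <- function(x, ...) {
  cat(sprintf("Tajima's D components (n = %d, usable sites = %d)\n",
              x$n, x$usable_sites))
  cat(sprintf("  S = %d, pi = %.6g, theta_w = %.6g\n", x$S, x$pi, x$theta_w))
  if (x$defined) cat(sprintf("  D = %.6f\n", x$D))
  else cat("  D undefined (S = 0)\n")
  invisible(x)
}

#' @export
glance.tajima_components <- function(x, ...) {
  tibble::tibble(n = x$n, S = x$S, pi = x$pi, pi_per_site = x$pi_per_site,
                 theta_w = x$theta_w, var_d = x$var_d, D = x$D,
                 defined = x$defined, usable_sites = x$usable_sites)
}

#' Sliding-window scan of diversity and Tajima's D
#'
#' Slides a window along the alignment and reports, per window, the
#' cell-wise gap fraction, the number of usable (fully ungapped) columns,
#' the segregating-site count, per-site pi and Tajima's D. Windows that are
#' too gappy or too short on usable sites are emitted with their statistics
#' flagged unavailable rather than silently dropped, so the scan always
#' tiles the alignment.
#'
#' @param aln an alignment.
#' @param window,step window width and stride, in alignment columns;
#'   `window >= step >= 1`.
#' @param max_gap_fraction windows whose fraction of gap/`N` cells exceeds
#'   this are flagged `"gappy"`.
#' @param min_usable minimum number of usable columns for the statistics to
#'   be reported.
#' @return a tibble of class `"window_scan"` with columns `start`, `end`
#'   (0-based half-open), `gap_fraction`, `usable_sites`, `S`,
#'   `pi_per_site`, `D`, `flag` (`"ok"`, `"gappy"`, `"short"`, or
#'   `"d_undefined"`). Scan parameters are kept in attributes.
#' @export
window_scan <- function(aln, window = 500L, step = 100L,
                        max_gap_fraction = 0.2, min_usable = 100L) {
  aln <- as_alignment(aln)
  if (step < 1L || window < step) {
    stop("need window >= step >= 1", call. = FALSE)
  }
  L <- ncol(aln)
  if (window > L) {
    warning("window wider than alignment; emitting one truncated window",
            call. = FALSE)
    window <- L
  }
  prof <- aln_profile(aln)
  use <- usable_columns(prof)
  pd <- column_pair_diffs(prof$counts)
  seg <- column_is_segregating(prof$counts)
  n <- prof$n
  starts <- seq.int(0L, L - window, by = step)
  k <- tajima_constants(n)

  rows <- purrr::map(starts, function(s) {
    idx <- (s + 1L):(s + window)
    gap_fraction <- sum(prof$gapn[idx]) / (n * window)
    u <- use[idx]
    usable <- sum(u)
    flag <- "ok"
    S <- NA_integer_; pps <- NA_real_; D <- NA_real_
    if (gap_fraction > max_gap_fraction) {
      flag <- "gappy"
    } else if (usable < min_usable) {
      flag <- "short"
    } else {
      S <- sum(seg[idx] & u)
      pi_count <- sum(pd[idx][u]) / choose(n, 2)
      pps <- pi_count / usable
      var_d <- k$e1 * S + k$e2 * S * (S - 1)
      if (S > 0 && var_d > 0) {
        D <- (pi_count - S / k$a1) / sqrt(var_d)
      } else {
        flag <- "d_undefined"
      }
    }
    tibble::tibble(start = s, end = s + window, gap_fraction = gap_fraction,
                   usable_sites = usable, S = S, pi_per_site = pps,
                   D = D, flag = flag)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "params") <- list(window = window, step = step,
                              max_gap_fraction = max_gap_fraction,
                              min_usable = min_usable, n_taxa = n,
                              alignment_length = L)
  class(out) <- c("window_scan", class(out))
  out
}

#' Plot a window scan as paired pi / Tajima's D tracks
#'
#' @param object a [window_scan()] result.
#' @param d_threshold horizontal guide drawn on the D panel.
#' @param ... ignored.
#' @return a ggplot object with two facetted tracks.
#' @export
autoplot.window_scan <- function(object, d_threshold = -0.5, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(.data$flag %in% c("ok")) |>
    dplyr::mutate(mid = (.data$start + .data$end) / 2) |>
    tidyr::pivot_longer(c("pi_per_site", "D"), names_to = "stat",
                        values_to = "value") |>
    dplyr::mutate(stat = factor(.data$stat, levels = c("pi_per_site", "D"),
                                labels = c("diversity (pi)", "Tajima's D")))
  guide <- tibble::tibble(stat = factor("Tajima's D",
                                        levels = c("diversity (pi)", "Tajima's D")),
                          y = d_threshold)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(data = guide, ggplot2::aes(yintercept = .data$y),
                        linetype = 2, colour = "red") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$stat), scales = "free_y") +
    ggplot2::labs(x = "alignment position (columns)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Write a window scan to TSV
#'
#' Parameters are recorded as `#`-prefixed header lines above the table.
#'
#' @param x a [window_scan()] result.
#' @param path output file.
#' @export
write_window_scan <- function(x, path) {
  p <- attr(x, "params")
  hdr <- sprintf("# window=%d step=%d max_gap_fraction=%g min_usable=%d",
                 p$window, p$step, p$max_gap_fraction, p$min_usable)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(tibble::as_tibble(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
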