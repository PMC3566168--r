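#' Count amino-acid pairs around candidate sites
#'
#' Enumerates, over all windows, every ordered pair of residues at two
#' distinct non-centre offsets `(i < j)` within the window, and counts for
#' each observed (offset, residue, offset, residue) combination the number
#' of windows containing it (`n`) and the number of positive windows
#' containing it (`x`). Counting is per-window membership (0/1), not
#' occurrence multiplicity; padding `X` never matches; pairs never observed
#' are absent.
#'
#' @param windows Character matrix of window contexts, one row per window
#'   and `2w + 1` columns (from [site_window_matrix()]), all sharing the
#'   same centre residue type.
#' @param labels Binary vector (1 = binding) aligned with the rows.
#' @return A `saap_catalog`: `data.frame` with columns `offset1`, `aa1`,
#'   `offset2`, `aa2`, `n`, `x`, plus attributes `N` (number of windows)
#'   and `M` (number of positive windows).
#' @export
enumerate_pairs <- function(windows, labels) {
  if (!is.matrix(windows)) .stopf("windows must be a character matrix")
  L <- ncol(windows)
  if (L %% 2L != 1L) .stopf("window width must be odd")
  w <- (L - 1L) %/% 2L
  centre <- windows[, w + 1L]
  if (length(unique(centre)) > 1L)
    .stopf("mixed centre residue types: %s", paste(unique(centre), collapse = ", "))
  labels <- as.integer(labels)
  pos <- labels == 1L
  offsets <- setdiff(seq.int(-w, w), 0L)
  out <- vector("list", length(offsets) * (length(offsets) - 1L) / 2L)
  k <- 0L
  for (a in seq_along(offsets)) {
    for (b in seq_along(offsets)) {
      if (b <= a) next
      o1 <- offsets[a]; o2 <- offsets[b]
      c1 <- windows[, o1 + w + 1L]
      c2 <- windows[, o2 + w + 1L]
      ok <- c1 != PAD_CHAR & c2 != PAD_CHAR
      if (!any(ok)) next
      key <- paste0(c1[ok], c2[ok])
      t_all <- table(key)
      t_pos <- table(key[pos[ok]])
      aa <- names(t_all)
      x <- as.integer(t_pos[aa])
      x[is.na(x)] <- 0L
      k <- k + 1L
      out[[k]] <- data.frame(offset1 = o1, aa1 = substr(aa, 1L, 1L),
                             offset2 = o2, aa2 = substr(aa, 2L, 2L),
                             n = as.integer(t_all), x = x,
                             stringsAsFactors = FALSE)
    }
  }
  cat_df <- do.call(rbind, out[seq_len(k)])
  if (is.null(cat_df))
    cat_df <- data.frame(offset1 = integer(0), aa1 = character(0),
                         offset2 = integer(0), aa2 = character(0),
                         n = integer(0), x = integer(0), stringsAsFactors = FALSE)
  rownames(cat_df) <- NULL
  structure(cat_df, N = nrow(windows), M = sum(pos), w = w,
            class = c("saap_catalog", "data.frame"))
}

check_hyper_args <- function(N, M, n, x) {
  if (any(N < 0L | M < 0L | M > N)) .stopf("require 0 <= M <= N")
  if (any(n < 0L | n > N)) .stopf("require 0 <= n <= N")
  if (any(x < 0L | x > n | x > M | (n - x) > (N - M)))
    .stopf("x out of the hypergeometric support for (N, M, n)")
  invisible(NULL)
}

#' Hypergeometric point probability
#'
#' Probability that a uniformly drawn subset of `n` windows out of `N`
#' (of which `M` are positive) contains exactly `x` positives:
#' `C(M, x) C(N - M, n - x) / C(N, n)`. Vectorised; evaluated through the
#' numerically stable log-space routine in [stats::dhyper()].
#'
#' @param N Total number of windows.
#' @param M Number of positive windows.
#' @param n Number of windows containing the pair.
#' @param x Number of positive windows containing the pair.
#' @return Point probability in `[0, 1]`.
#' @export
hypergeom_pmf <- function(N, M, n, x) {
  check_hyper_args(N, M, n, x)
  stats::dhyper(x, M, N - M, n)
}

#' Enrichment p-value for an amino-acid pair
#'
#' Upper-tail probability `P(X >= x)` under the hypergeometric null — the
#' chance that a pair present in `n` of `N` windows lands in at least `x`
#' of the `M` positive windows by the draw alone. `type = "point"` returns
#' the point-mass probability instead.
#'
#' @inheritParams hypergeom_pmf
#' @param type `"tail"` (default, enrichment test) or `"point"`.
#' @return p-value in `(0, 1]`.
#' @export
saap_pvalue <- function(N, M, n, x, type = c("tail", "point")) {
  type <- match.arg(type)
  check_hyper_args(N, M, n, x)
  if (type == "point") return(hypergeom_pmf(N, M, n, x))
  stats::phyper(x - 1, M, N - M, n, lower.tail = FALSE)
}

#' Rank significant amino-acid pairs
#'
#' Computes the enrichment p-value for every counted pair, keeps those with
#' `p < alpha`, and orders them by ascending p-value with a deterministic
#' lexicographic tie-break on `(offset1, aa1, offset2, aa2)`.
#'
#' @param catalog A `saap_catalog` from [enumerate_pairs()].
#' @param alpha Significance level (default 0.05).
#' @param type p-value type passed to [saap_pvalue()].
#' @return The filtered, ranked `saap_catalog` with a `p_value` column.
#' @export
rank_saaps <- function(catalog, alpha = 0.05, type = c("tail", "point")) {
  type <- match.arg(type)
  N <- attr(catalog, "N"); M <- attr(catalog, "M")
  if (nrow(catalog)) {
    catalog$p_value <- saap_pvalue(N, M, catalog$n, catalog$x, type = type)
    # alpha >= 1 keeps everything, including pairs at the p = 1 boundary
    keep <- if (alpha >= 1) rep(TRUE, nrow(catalog)) else catalog$p_value < alpha
    catalog <- catalog[keep, , drop = FALSE]
    ord <- order(catalog$p_value, catalog$offset1, catalog$aa1,
                 catalog$offset2, catalog$aa2)
    catalog <- catalog[ord, , drop = FALSE]
    rownames(catalog) <- NULL
  } else {
    catalog$p_value <- numeric(0)
  }
  structure(catalog, N = N, M = M, w = attr(catalog, "w"),
            class = c("saap_catalog", "data.frame"))
}

#' Mine significant amino-acid pairs from labelled sites
#'
#' Convenience wrapper: window extraction, pair counting
#' ([enumerate_pairs()]) and ranking ([rank_saaps()]) in one step.
#'
#' @param records Named list of [protein_record()] objects.
#' @param sites Site table (single residue type) from [extract_sites()].
#' @param alpha Significance level.
#' @param w Flank width.
#' @param type p-value type; see [saap_pvalue()].
#' @return Ranked `saap_catalog`.
#' @export
mine_saaps <- function(records, sites, alpha = 0.05, w = 6L,
                       type = c("tail", "point")) {
  wm <- site_window_matrix(records, sites, w = w)
  rank_saaps(enumerate_pairs(wm, sites$label == "binding"),
             alpha = alpha, type = match.arg(type))
}

#' Binary SAAP indicator features for windows
#'
#' Column `k` is 1 for a window containing catalog pair `k` (both residues
#' at their offsets), 0 otherwise.
#'
#' @param windows Character window matrix from [site_window_matrix()].
#' @param catalog Ranked `saap_catalog`.
#' @return Integer 0/1 matrix with `nrow(windows)` rows and one column per
#'   catalog pair, named like `"-4C|+1P"`.
#' @export
encode_saap_indicators <- function(windows, catalog) {
  w <- (ncol(windows) - 1L) %/% 2L
  k <- nrow(catalog)
  out <- matrix(0L, nrow = nrow(windows), ncol = k)
  for (j in seq_len(k)) {
    out[, j] <- as.integer(
      windows[, catalog$offset1[j] + w + 1L] == catalog$aa1[j] &
      windows[, catalog$offset2[j] + w + 1L] == catalog$aa2[j])
  }
  colnames(out) <- saap_names(catalog)
  out
}

saap_names <- function(catalog) {
  if (!nrow(catalog)) return(character(0))
  sprintf("%+d%s|%+d%s", catalog$offset1, catalog$aa1,
          catalog$offset2, catalog$aa2)
}

#' Write / read a SAAP catalog as headered TSV
#'
#' Offsets are signed integers; p-values are written in scientific
#' notation. The `N`/`M` totals travel in `# N=` / `# M=` comment lines so
#' a round-trip preserves the catalog exactly.
#'
#' @param catalog A `saap_catalog`.
#' @param path File path.
#' @return `path` (write) or the catalog (read).
#' @export
write_saap_catalog <- function(catalog, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# N=%d M=%d w=%d", attr(catalog, "N"), attr(catalog, "M"),
                     attr(catalog, "w")), con)
  df <- as.data.frame(catalog)
  if ("p_value" %in% names(df)) df$p_value <- sprintf("%.6E", df$p_value)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_saap_catalog
#' @export
read_saap_catalog <- function(path) {
  header <- readLines(path, n = 1L)
  meta <- as.integer(regmatches(header, gregexpr("[0-9]+", header))[[1]])
  df <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  if ("p_value" %in% names(df)) df$p_value <- as.numeric(df$p_value)
  structure(df, N = meta[1], M = meta[2], w = meta[3],
            class = c("saap_catalog", "data.frame"))
}
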