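#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the position-specific scoring matrix written by PSI-BLAST's
#' `-out_ascii_pssm` option: header lines, then one row per sequence
#' position carrying the position index, the residue letter, 20 log-odds
#' columns and (optionally) 20 weighted-percentage columns plus trailing
#' statistics. Only the first 20 numeric columns are kept.
#'
#' @param path Path to the ASCII PSSM file.
#' @param id Optional protein accession to record in the profile.
#' @return Object of class `pssm_profile`: list with `id`, `residues`
#'   (character vector, one per position) and `scores` (numeric matrix,
#'   one row per position, 20 columns named in PSI-BLAST order).
#' @export
parse_psiblast_pssm <- function(path, id = NULL) {
  if (!file.exists(path)) .stopf("PSSM file not found: %s", path)
  lines <- readLines(path)
  is_row <- grepl("^\\s*[0-9]+\\s+[A-Za-z]\\s", lines)
  if (!any(is_row)) .stopf("no PSSM rows found in %s", path)
  idx <- which(is_row)
  # rows are contiguous; anything after the first gap is footer statistics
  if (length(idx) > 1L) idx <- idx[seq_len(which.max(c(diff(idx) > 1L, TRUE)))]
  n <- length(idx)
  scores <- matrix(NA_real_, nrow = n, ncol = 20L, dimnames = list(NULL, AA_ORDER))
  residues <- character(n)
  positions <- integer(n)
  for (k in seq_len(n)) {
    ln <- idx[k]
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 22L)
      .stopf("%s line %d: expected at least 22 fields, found %d", path, ln, length(tok))
    vals <- suppressWarnings(as.numeric(tok[3:22]))
    if (anyNA(vals))
      .stopf("%s line %d: non-numeric score column", path, ln)
    positions[k] <- as.integer(tok[1])
    residues[k] <- toupper(tok[2])
    scores[k, ] <- vals
  }
  if (!all(positions == seq_len(n)))
    .stopf("%s: PSSM positions are not consecutive from 1", path)
  structure(list(id = id, residues = residues, scores = scores),
            class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat(sprintf("<pssm_profile> %s: %d positions x 20 scores\n",
              if (is.null(x$id)) "?" else x$id, nrow(x$scores)))
  invisible(x)
}

# check a profile against its record; returns the profile invisibly
check_profile <- function(profile, record) {
  n <- nchar(record$sequence)
  if (nrow(profile$scores) != n)
    .stopf("profile for '%s' has %d rows but sequence has %d residues",
           record$id, nrow(profile$scores), n)
  seq_chars <- strsplit(record$sequence, "", fixed = TRUE)[[1]]
  cmp <- seq_chars != PAD_CHAR & profile$residues != seq_chars
  if (any(cmp))
    .stopf("profile for '%s' disagrees with sequence at position(s) %s",
           record$id, paste(utils::head(which(cmp), 5L), collapse = ", "))
  invisible(profile)
}

#' Squash a PSSM log-odds score into (0, 1)
#'
#' The logistic transform `1 / (1 + exp(-x))`, the standard squashing used
#' when profile log-odds scores feed a fixed-range feature vector. Strictly
#' increasing, with `scale_pssm_value(0) == 0.5`.
#'
#' @param x Numeric vector of log-odds scores.
#' @return Values strictly inside `(0, 1)`.
#' @export
scale_pssm_value <- function(x) {
  if (any(!is.finite(x))) .stopf("non-finite PSSM score")
  stats::plogis(x)
}

# substitution matrices in PSI-BLAST order, min-max rescaled to [0,1]
# over the 20x20 block so all encodings share the feature range
.subst_cache <- new.env(parent = emptyenv())

scaled_substitution_matrix <- function(name = c("BLOSUM62", "PAM250")) {
  name <- match.arg(name)
  if (!is.null(.subst_cache[[name]])) return(.subst_cache[[name]])
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  m <- e[[name]][AA_ORDER, AA_ORDER]
  m <- (m - min(m)) / (max(m) - min(m))
  .subst_cache[[name]] <- m
  m
}

#' Encode a residue window as a numeric feature vector
#'
#' Each of the `2w + 1` window positions contributes a row of 20 values in
#' PSI-BLAST column order, concatenated left to right into a vector of
#' length `(2w + 1) * 20` (260 at the default window of 13):
#'
#' * `"AA"` — one-hot indicator of the residue identity;
#' * `"BLOSUM62"` / `"PAM250"` — the residue's substitution-matrix row,
#'   min-max rescaled to `[0, 1]` over the whole 20x20 matrix;
#' * `"PSSM"` — the logistic-scaled profile row of the corresponding
#'   sequence position (requires `profile`).
#'
#' Terminal padding positions (`X`) contribute an all-zero row under every
#' encoding.
#'
#' @param window A `site_window` from [extract_window()].
#' @param encoding One of `"AA"`, `"BLOSUM62"`, `"PAM250"`, `"PSSM"`.
#' @param profile A `pssm_profile` for the window's protein (PSSM only).
#' @param scale_fun Squashing function applied to raw PSSM scores
#'   (default [scale_pssm_value()], the logistic; replaceable as a hook).
#' @return Numeric vector of length `(2w + 1) * 20`.
#' @export
encode_window <- function(window, encoding = c("AA", "BLOSUM62", "PAM250", "PSSM"),
                          profile = NULL, scale_fun = scale_pssm_value) {
  encoding <- match.arg(encoding)
  chars <- strsplit(window$context, "", fixed = TRUE)[[1]]
  L <- length(chars)
  out <- matrix(0, nrow = L, ncol = 20L)
  real <- chars != PAD_CHAR
  if (encoding == "AA") {
    cols <- match(chars[real], AA_ORDER)
    out[cbind(which(real), cols)] <- 1
  } else if (encoding %in% c("BLOSUM62", "PAM250")) {
    m <- scaled_substitution_matrix(encoding)
    out[real, ] <- m[chars[real], , drop = FALSE]
  } else {
    if (is.null(profile)) .stopf("PSSM encoding requires a profile")
    pos <- window$position + (seq_len(L) - 1L) - window$w
    inside <- pos >= 1L & pos <= nrow(profile$scores)
    if (any(real & !inside))
      .stopf("window for %s:%d extends beyond its profile",
             window$protein_id, window$position)
    out[real, ] <- scale_fun(profile$scores[pos[real], , drop = FALSE])
  }
  as.vector(t(out))
}

#' Encode a table of candidate sites as a feature matrix
#'
#' Base window features under one encoding, optionally extended by binary
#' indicator columns for a ranked SAAP catalog (see [mine_saaps()]). Row
#' order equals site order; labels are 1 for binding sites and 0 otherwise.
#'
#' @param records Named list of [protein_record()] objects.
#' @param sites Site table from [extract_sites()] (single residue type).
#' @param encoding Encoding tag; see [encode_window()].
#' @param profiles Named list of `pssm_profile` objects keyed by protein id
#'   (required for `"PSSM"`).
#' @param saaps Optional `saap_catalog`; its pairs are appended as binary
#'   indicator columns in catalog order.
#' @param w Flank width (default 6).
#' @return List with `x` (numeric matrix, `nrow(sites)` rows) and `y`
#'   (integer vector of 0/1 labels).
#' @export
encode_dataset <- function(records, sites, encoding = "PSSM", profiles = NULL,
                           saaps = NULL, w = 6L) {
  encoding <- match.arg(encoding, c("AA", "BLOSUM62", "PAM250", "PSSM"))
  if (inherits(records, "protein_record")) records <- list(records)
  ids <- vapply(records, function(r) r$id, character(1))
  names(records) <- ids
  d <- (2L * w + 1L) * 20L
  n <- nrow(sites)
  y <- as.integer(sites$label == "binding")
  if (n == 0L) {
    x <- matrix(numeric(0), nrow = 0L, ncol = d + if (is.null(saaps)) 0L else nrow(saaps))
    return(list(x = x, y = integer(0)))
  }
  if (encoding == "PSSM") {
    if (is.null(profiles)) .stopf("PSSM encoding requires profiles")
    for (pid in unique(sites$protein_id)) {
      if (is.null(profiles[[pid]]))
        .stopf("no PSSM profile supplied for protein '%s'", pid)
      check_profile(profiles[[pid]], records[[pid]])
    }
  }
  x <- matrix(0, nrow = n, ncol = d)
  for (i in seq_len(n)) {
    rec <- records[[sites$protein_id[i]]]
    if (is.null(rec)) .stopf("site %d refers to unknown protein '%s'", i, sites$protein_id[i])
    win <- extract_window(rec, sites$position[i], w = w)
    x[i, ] <- encode_window(win, encoding,
                            profile = profiles[[sites$protein_id[i]]])
  }
  rownames(x) <- paste(sites$protein_id, sites$position, sep = ":")
  if (!is.null(saaps) && nrow(saaps) > 0L) {
    wm <- site_window_matrix(records, sites, w = w)
    x <- cbind(x, encode_saap_indicators(wm, saaps))
  }
  list(x = x, y = y)
}

#' Export a feature matrix as headered TSV
#'
#' @param x Feature matrix (e.g. from [encode_dataset()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  colnames(x) <- if (is.null(colnames(x))) paste0("f", seq_len(ncol(x))) else colnames(x)
  utils::write.table(data.frame(site = rownames(x), x, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
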