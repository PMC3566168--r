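#' Construct a protein record
#'
#' A `protein_record` holds one amino-acid sequence together with its
#' annotated metal-binding positions. Binding positions must point at
#' cysteine (C) or histidine (H); the method is defined only for these two
#' ligand residues.
#'
#' @param id Accession string (unique within a set).
#' @param sequence Amino-acid sequence; upper-cased on input. Letters outside
#'   the 20-residue alphabet (`B`, `Z`, `U`, `J`, `O`, `X`, ...) are mapped to
#'   `X`.
#' @param binding_sites Optional `data.frame` with columns `position`
#'   (1-based), and `metal` (`"Fe"`, `"Cu"`, or `"other"`).
#' @return An object of class `protein_record` with fields `id`, `sequence`
#'   and `binding_sites`.
#' @export
protein_record <- function(id, sequence, binding_sites = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    .stopf("protein id must be a non-empty string")
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) .stopf("zero-length sequence for '%s'", id)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  nonstd <- !(chars %in% AA_ORDER)   # includes literal X: not a real residue
  if (any(nonstd)) chars[nonstd] <- PAD_CHAR
  sequence <- paste(chars, collapse = "")
  if (is.null(binding_sites)) {
    binding_sites <- data.frame(position = integer(0), metal = character(0),
                                stringsAsFactors = FALSE)
  }
  rec <- structure(list(id = id, sequence = sequence,
                        binding_sites = binding_sites,
                        n_nonstandard = sum(nonstd)),
                   class = "protein_record")
  validate_protein_record(rec)
}

validate_protein_record <- function(rec) {
  bs <- rec$binding_sites
  n <- nchar(rec$sequence)
  if (nrow(bs)) {
    if (any(bs$position < 1L | bs$position > n))
      .stopf("binding position out of range [1,%d] for '%s'", n, rec$id)
    res <- substring(rec$sequence, bs$position, bs$position)
    bad <- !(res %in% c("C", "H"))
    if (any(bad)) {
      .warnf("'%s': skipping %d annotated site(s) whose residue is not C/H (position %s)",
             rec$id, sum(bad), paste(bs$position[bad], collapse = ", "))
      rec$binding_sites <- bs[!bad, , drop = FALSE]
    }
  }
  rec
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s: %d aa, %d annotated binding site(s)\n",
              x$id, nchar(x$sequence), nrow(x$binding_sites)))
  invisible(x)
}

#' Read a multi-entry FASTA file into protein records
#'
#' Sequences are upper-cased; letters outside the 20-residue alphabet are
#' mapped to the padding/unknown symbol `X` and counted in the load report
#' (attribute `"load_report"`, a character vector of log lines). Binding-site
#' annotations are left empty; attach them with [read_annotations()].
#'
#' @param path Path to a FASTA file.
#' @return Named list of [protein_record()] objects, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) .stopf("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) .stopf("empty FASTA file: %s", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) .stopf("duplicate FASTA id(s): %s", paste(unique(dup), collapse = ", "))
  seqs <- as.character(set)
  if (any(!nzchar(seqs)))
    .stopf("zero-length sequence for id(s): %s", paste(ids[!nzchar(seqs)], collapse = ", "))
  recs <- lapply(seq_along(ids), function(i) protein_record(ids[i], seqs[i]))
  names(recs) <- ids
  report <- character(0)
  for (r in recs) {
    if (r$n_nonstandard > 0L)
      report <- c(report, sprintf("%s: %d non-standard letter(s) mapped to X",
                                  r$id, r$n_nonstandard))
  }
  attr(recs, "load_report") <- report
  recs
}

#' Write protein records to a FASTA file
#'
#' @param records List of [protein_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  seqs <- vapply(records, function(r) r$sequence, character(1))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- vapply(records, function(r) r$id, character(1))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Attach binding-site annotations from a TSV file
#'
#' The file must be tab-separated with header columns `protein_id`,
#' `position`, `residue`, `metal` (1-based positions, UniProt convention).
#' Rows whose stated residue disagrees with the sequence are rejected with a
#' per-row warning; rows pointing at residues other than C/H are skipped.
#' Unknown protein ids and out-of-range positions are errors.
#'
#' @param path Path to the annotation TSV.
#' @param records Named list of [protein_record()] objects to annotate.
#' @return `records` with `binding_sites` populated.
#' @export
read_annotations <- function(path, records) {
  if (!file.exists(path)) .stopf("annotation file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, sep = "\t")
  need <- c("protein_id", "position", "residue", "metal")
  miss <- setdiff(need, names(tab))
  if (length(miss)) .stopf("annotation TSV missing column(s): %s", paste(miss, collapse = ", "))
  ids <- vapply(records, function(r) r$id, character(1))
  unknown <- setdiff(unique(tab$protein_id), ids)
  if (length(unknown)) .stopf("annotation refers to unknown protein id(s): %s",
                              paste(unknown, collapse = ", "))
  tab$position <- as.integer(tab$position)
  for (i in seq_along(records)) {
    rec <- records[[i]]
    rows <- tab[tab$protein_id == rec$id, , drop = FALSE]
    if (!nrow(rows)) next
    n <- nchar(rec$sequence)
    if (any(rows$position < 1L | rows$position > n))
      .stopf("'%s': annotated position out of range [1,%d]: %s", rec$id, n,
             paste(rows$position[rows$position < 1L | rows$position > n], collapse = ", "))
    seq_res <- substring(rec$sequence, rows$position, rows$position)
    mismatch <- toupper(rows$residue) != seq_res
    if (any(mismatch)) {
      .warnf("'%s': rejecting %d row(s) whose residue disagrees with the sequence (position %s)",
             rec$id, sum(mismatch), paste(rows$position[mismatch], collapse = ", "))
      rows <- rows[!mismatch, , drop = FALSE]
    }
    rec$binding_sites <- data.frame(position = rows$position,
                                    metal = .canon_metal(rows$metal),
                                    stringsAsFactors = FALSE)
    records[[i]] <- validate_protein_record(rec)
  }
  records
}

#' Write binding-site annotations to a TSV file
#'
#' @param records Named list of annotated [protein_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(records, path) {
  rows <- lapply(records, function(r) {
    if (!nrow(r$binding_sites)) return(NULL)
    data.frame(protein_id = r$id,
               position = r$binding_sites$position,
               residue = substring(r$sequence, r$binding_sites$position,
                                   r$binding_sites$position),
               metal = r$binding_sites$metal,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(protein_id = character(0), position = integer(0),
                      residue = character(0), metal = character(0))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Enumerate candidate residue sites
#'
#' Lists every cysteine and histidine in each record, labelled `"binding"`
#' when annotated and `"non-binding"` otherwise, ordered by record then
#' position. The negative class for a given model is the non-binding residues
#' of the *same* amino-acid type as the target (use `residue` to restrict).
#'
#' @param records A [protein_record()] or list of them.
#' @param residue Optional restriction to `"C"` or `"H"`.
#' @return `data.frame` with columns `protein_id`, `position`, `residue`,
#'   `label`, `metal`.
#' @export
extract_sites <- function(records, residue = NULL) {
  if (inherits(records, "protein_record")) records <- list(records)
  out <- lapply(records, function(rec) {
    chars <- strsplit(rec$sequence, "", fixed = TRUE)[[1]]
    pos <- which(chars %in% c("C", "H"))
    if (!length(pos))
      return(data.frame(protein_id = character(0), position = integer(0),
                        residue = character(0), label = character(0),
                        metal = character(0), stringsAsFactors = FALSE))
    bs <- rec$binding_sites
    lab <- ifelse(pos %in% bs$position, "binding", "non-binding")
    metal <- rep(NA_character_, length(pos))
    m <- match(pos, bs$position)
    metal[!is.na(m)] <- bs$metal[m[!is.na(m)]]
    data.frame(protein_id = rec$id, position = pos, residue = chars[pos],
               label = lab, metal = metal, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  if (!is.null(residue)) {
    residue <- match.arg(residue, c("C", "H"))
    tab <- tab[tab$residue == residue, , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' Extract the sequence window centred on a candidate residue
#'
#' Returns the `2w + 1`-residue context around `position`; positions falling
#' outside the sequence are filled with the padding symbol `X`, which can
#' only ever appear as a contiguous prefix and/or suffix.
#'
#' @param record A [protein_record()].
#' @param position 1-based position within the sequence.
#' @param w Flank width on each side of the centre (default 6, i.e. a
#'   13-residue window).
#' @return Object of class `site_window`: list with `protein_id`, `position`,
#'   `residue`, `context` (string of length `2w+1`) and `w`.
#' @export
extract_window <- function(record, position, w = 6L) {
  n <- nchar(record$sequence)
  position <- as.integer(position)
  if (position < 1L || position > n)
    .stopf("'%s': window position %d out of range [1,%d]", record$id, position, n)
  lo <- position - w
  hi <- position + w
  left <- strrep(PAD_CHAR, max(0L, 1L - lo))
  right <- strrep(PAD_CHAR, max(0L, hi - n))
  core <- substring(record$sequence, max(1L, lo), min(n, hi))
  structure(list(protein_id = record$id, position = position,
                 residue = substring(record$sequence, position, position),
                 context = paste0(left, core, right), w = as.integer(w)),
            class = "site_window")
}

#' @export
print.site_window <- function(x, ...) {
  cat(sprintf("<site_window> %s:%d (%s) %s\n", x$protein_id, x$position,
              x$residue, x$context))
  invisible(x)
}

# n x (2w+1) character matrix of window contexts for a site table;
# the workhorse behind encoders and SAAP counting.
site_window_matrix <- function(records, sites, w = 6L) {
  if (inherits(records, "protein_record")) records <- list(records)
  ids <- vapply(records, function(r) r$id, character(1))
  names(records) <- ids
  n <- nrow(sites)
  out <- matrix(PAD_CHAR, nrow = n, ncol = 2L * w + 1L)
  for (i in seq_len(n)) {
    rec <- records[[sites$protein_id[i]]]
    if (is.null(rec)) .stopf("site refers to unknown protein id '%s'", sites$protein_id[i])
    win <- extract_window(rec, sites$position[i], w = w)
    out[i, ] <- strsplit(win$context, "", fixed = TRUE)[[1]]
  }
  rownames(out) <- paste(sites$protein_id, sites$position, sep = ":")
  out
}
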