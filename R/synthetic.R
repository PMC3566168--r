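#' Configuration for the synthetic dataset generator
#'
#' Describes a synthetic study: proteins drawn from a background residue
#' distribution, a fixed number of positive (metal-binding) and negative
#' (non-binding) candidate sites of one residue type, residue pairs planted
#' around positive centres with a stated enrichment, and per-protein PSSM
#' profiles whose rows deviate from background near positive centres with a
#' strength controlled by `pssm_signal`.
#'
#' @param n_proteins Number of proteins.
#' @param length_range `(min, max)` sequence lengths.
#' @param center_residue `"C"` or `"H"`.
#' @param n_positive,n_negative Numbers of designed positive/negative sites.
#' @param planted_pairs `data.frame` with columns `offset1`, `aa1`,
#'   `offset2`, `aa2`, `enrichment` (probability the pair is written into a
#'   positive window) and `background` (same for designed negative
#'   windows). Offsets are centre-relative in `[-w, w]` excluding 0.
#' @param pssm_signal Non-negative real; 0 gives class-uninformative
#'   profiles, larger values peak profile rows near positive centres.
#' @param decoy_rate Fraction of designed negative sites that are
#'   "conserved decoys": non-binding residues whose profile neighbourhood
#'   is as conserved as a binding site's (emulating structural cysteines
#'   and histidines, e.g. disulfide partners, which make profile features
#'   alone imperfect). Decoys carry planted pairs only at the background
#'   rate, so pair features disambiguate them.
#' @param profile_depth Number of pseudo-observations per profile column
#'   (sampling noise of the simulated profile).
#' @param background_freqs Length-20 residue probabilities in the standard
#'   column order (default uniform).
#' @param w Flank width.
#' @param seed Integer seed; every generated artefact is a deterministic
#'   function of it.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 44L, length_range = c(100L, 200L),
                         center_residue = c("C", "H"),
                         n_positive = 80L, n_negative = 280L,
                         planted_pairs = data.frame(
                           offset1 = -4L, aa1 = "C", offset2 = 1L, aa2 = "P",
                           enrichment = 0.8, background = 0.05,
                           stringsAsFactors = FALSE),
                         pssm_signal = 2, decoy_rate = 0.18,
                         profile_depth = 25L,
                         background_freqs = rep(1 / 20, 20),
                         w = 6L, seed = 1L) {
  center_residue <- match.arg(center_residue)
  if (any(planted_pairs$enrichment < planted_pairs$background))
    .stopf("planted pair enrichment must be >= background")
  if (any(planted_pairs$enrichment > 1 | planted_pairs$background < 0))
    .stopf("planted pair probabilities must lie in [0, 1]")
  if (any(planted_pairs$offset1 == 0L | planted_pairs$offset2 == 0L) ||
      any(abs(c(planted_pairs$offset1, planted_pairs$offset2)) > w))
    .stopf("planted pair offsets must be non-zero and within [-w, w]")
  if (pssm_signal < 0) .stopf("pssm_signal must be non-negative")
  if (decoy_rate < 0 || decoy_rate > 1) .stopf("decoy_rate must lie in [0, 1]")
  if (abs(sum(background_freqs) - 1) > 1e-8 || length(background_freqs) != 20L)
    .stopf("background_freqs must be 20 probabilities summing to 1")
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 center_residue = center_residue,
                 n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative),
                 planted_pairs = planted_pairs,
                 pssm_signal = pssm_signal,
                 decoy_rate = decoy_rate,
                 profile_depth = as.integer(profile_depth),
                 background_freqs = background_freqs,
                 w = as.integer(w), seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic annotated dataset with PSSM profiles
#'
#' Sequences are drawn i.i.d. from the background distribution; candidate
#' site centres are placed on non-overlapping window slots and assigned to
#' the positive or negative class; planted pairs are written into windows
#' with their class-specific probabilities. Profile rows carry a baseline
#' conservation level (Beta-distributed) raised near positive centres
#' according to `pssm_signal`, are sampled with multinomial noise at
#' `profile_depth`, and converted to integer log-odds scores against the
#' background — so `pssm_signal = 0` yields profiles with realistic noise
#' but no class information.
#'
#' @param config A [synth_config()].
#' @return List with `records` (annotated [protein_record()]s), `profiles`
#'   (named list of `pssm_profile`), `sites` (the designed ground-truth
#'   site table: `protein_id`, `position`, `residue`, `label`), `planted`
#'   (one row per realised planting decision) and `config`.
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  w <- config$w
  spacing <- 2L * w + 2L
  lens <- sample(seq(config$length_range[1], config$length_range[2]),
                 config$n_proteins, replace = TRUE)
  ids <- sprintf("SYN%03d", seq_len(config$n_proteins))
  seqs <- lapply(lens, function(L)
    sample(AA_ORDER, L, replace = TRUE, prob = config$background_freqs))
  slots <- do.call(rbind, lapply(seq_along(ids), function(i) {
    pos <- seq.int(w + 1L, lens[i] - w, by = spacing)
    if (!length(pos)) return(NULL)
    data.frame(protein = i, position = pos)
  }))
  need <- config$n_positive + config$n_negative
  if (is.null(slots) || nrow(slots) < need)
    .stopf("infeasible placement: %d site slots available but %d sites requested",
           if (is.null(slots)) 0L else nrow(slots), need)
  slots <- slots[sample(nrow(slots)), , drop = FALSE]
  slots <- slots[seq_len(need), , drop = FALSE]
  slots$label <- rep(c("binding", "non-binding"),
                     c(config$n_positive, config$n_negative))
  slots$decoy <- slots$label == "non-binding" &
    stats::runif(nrow(slots)) < config$decoy_rate
  # fix the centre residue at every designed site
  for (r in seq_len(nrow(slots)))
    seqs[[slots$protein[r]]][slots$position[r]] <- config$center_residue
  # plant pairs with class-specific probabilities
  planted <- list()
  pp <- config$planted_pairs
  for (r in seq_len(nrow(slots))) {
    prob_col <- if (slots$label[r] == "binding") "enrichment" else "background"
    for (j in seq_len(nrow(pp))) {
      if (stats::runif(1) < pp[[prob_col]][j]) {
        i <- slots$protein[r]; pos <- slots$position[r]
        seqs[[i]][pos + pp$offset1[j]] <- pp$aa1[j]
        seqs[[i]][pos + pp$offset2[j]] <- pp$aa2[j]
        planted[[length(planted) + 1L]] <-
          data.frame(protein_id = ids[i], position = pos, pair = j,
                     label = slots$label[r], stringsAsFactors = FALSE)
      }
    }
  }
  planted <- if (length(planted)) do.call(rbind, planted) else
    data.frame(protein_id = character(0), position = integer(0),
               pair = integer(0), label = character(0))
  # conservation profile: Beta baseline everywhere, raised within +/-1 of
  # positive centres by the signal strength
  records <- list()
  profiles <- list()
  bg <- config$background_freqs
  for (i in seq_along(ids)) {
    chars <- seqs[[i]]
    L <- lens[i]
    cons <- stats::rbeta(L, 1, 4)
    pos_centres <- slots$position[slots$protein == i &
                                    (slots$label == "binding" | slots$decoy)]
    hot <- unique(pmin(pmax(rep(pos_centres, each = 3L) + (-1L:1L), 1L), L))
    cons[hot] <- 1 - (1 - cons[hot]) * exp(-config$pssm_signal)
    scores <- matrix(0, nrow = L, ncol = 20L, dimnames = list(NULL, AA_ORDER))
    depth <- config$profile_depth
    for (t in seq_len(L)) {
      q <- (1 - cons[t]) * bg
      q[match(chars[t], AA_ORDER)] <- q[match(chars[t], AA_ORDER)] + cons[t]
      counts <- stats::rmultinom(1L, depth, q)[, 1]
      phat <- (counts + 5 * bg) / (depth + 5)
      scores[t, ] <- pmax(-10, pmin(13, round(2 * log(phat / bg))))
    }
    rec <- protein_record(ids[i], paste(chars, collapse = ""))
    bs <- slots[slots$protein == i & slots$label == "binding", , drop = FALSE]
    if (nrow(bs))
      rec$binding_sites <- data.frame(position = sort(bs$position),
                                      metal = "Fe", stringsAsFactors = FALSE)
    records[[ids[i]]] <- rec
    profiles[[ids[i]]] <- structure(list(id = ids[i], residues = chars,
                                         scores = scores),
                                    class = "pssm_profile")
  }
  sites <- data.frame(protein_id = ids[slots$protein],
                      position = slots$position,
                      residue = config$center_residue,
                      label = slots$label, decoy = slots$decoy,
                      stringsAsFactors = FALSE)
  ord <- order(match(sites$protein_id, ids), sites$position)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  list(records = records, profiles = profiles, sites = sites,
       planted = planted, config = config)
}

#' Write a PSI-BLAST-dialect ASCII PSSM fixture
#'
#' Emits the header, per-position rows (position, residue, 20 integer
#' log-odds, 20 placeholder percentage columns, information and weight
#' columns) and footer statistics of the `-out_ascii_pssm` dialect, such
#' that [parse_psiblast_pssm()] recovers exactly the intended matrix.
#'
#' @param residues Character vector of sequence residues.
#' @param scores Integer matrix, `length(residues)` rows by 20 columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
make_fixture_pssm <- function(residues, scores, path) {
  stopifnot(nrow(scores) == length(residues), ncol(scores) == 20L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
               paste0("            ", paste(sprintf("%3s", c(AA_ORDER, AA_ORDER)), collapse = ""))),
             con)
  for (t in seq_along(residues)) {
    writeLines(paste0(sprintf("%5d %s  ", t, residues[t]),
                      paste(sprintf("%3d", scores[t, ]), collapse = " "),
                      "  ",
                      paste(sprintf("%3d", rep(0L, 20L)), collapse = " "),
                      sprintf("  %4.2f %8.2f", 0, 0)),
               con)
  }
  writeLines(c("", "                      K         Lambda",
               "Standard Ungapped    0.1347     0.3240",
               "Standard Gapped      0.0410     0.2670",
               "PSI Ungapped         0.1347     0.3240",
               "PSI Gapped           0.0410     0.2670"), con)
  invisible(path)
}

#' Write a synthetic dataset to disk
#'
#' Emits exactly the formats the rest of the toolkit consumes: a FASTA
#' file, an annotation TSV, one PSI-BLAST-dialect PSSM file per protein
#' under `pssm/`, and a JSON-lines ground-truth manifest (first line: the
#' resolved configuration; then one line per designed site).
#'
#' @param syn Result of [generate_synthetic()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(syn, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "pssm"), showWarnings = FALSE)
  write_fasta(syn$records, file.path(dir, "proteins.fasta"))
  write_annotations(syn$records, file.path(dir, "annotations.tsv"))
  for (id in names(syn$profiles))
    make_fixture_pssm(syn$profiles[[id]]$residues, syn$profiles[[id]]$scores,
                      file.path(dir, "pssm", paste0(id, ".pssm")))
  cfg <- syn$config
  cfg$planted_pairs <- NULL
  lines <- c(jsonlite::toJSON(c(record = "config", unclass(cfg),
                                list(planted_pairs = syn$config$planted_pairs)),
                              auto_unbox = TRUE, digits = NA),
             vapply(seq_len(nrow(syn$sites)), function(r)
               as.character(jsonlite::toJSON(
                 c(record = "site", as.list(syn$sites[r, ])),
                 auto_unbox = TRUE)), character(1)))
  writeLines(lines, file.path(dir, "manifest.jsonl"))
  invisible(dir)
}

#' Read the designed-site manifest written by [write_synthetic()]
#'
#' @param path Path to `manifest.jsonl`.
#' @return List with `config` (list) and `sites` (`data.frame`).
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  objs <- lapply(lines, jsonlite::fromJSON)
  types <- vapply(objs, function(o) o$record, character(1))
  sites <- do.call(rbind, lapply(objs[types == "site"], function(o)
    data.frame(protein_id = o$protein_id, position = o$position,
               residue = o$residue, label = o$label, stringsAsFactors = FALSE)))
  list(config = objs[[which(types == "config")[1]]], sites = sites)
}
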