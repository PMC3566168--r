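#' Fit a metal-binding residue classifier
#'
#' The main model constructor. Extracts every candidate residue of the
#' target type (cysteine or histidine), encodes its 13-residue window under
#' the chosen scheme, optionally mines and appends significant amino-acid
#' pair (SAAP) indicator features, and trains the all-centres Gaussian RBF
#' network on the result. The fitted object carries the full feature
#' specification and the training accessions so that prediction and
#' independent-test evaluation can check compatibility and leakage.
#'
#' @param records Named list of annotated [protein_record()] objects.
#' @param residue Target residue type, `"C"` or `"H"`.
#' @param encoding Window encoding; see [encode_window()].
#' @param profiles Named list of `pssm_profile` objects (PSSM encoding).
#' @param saaps Either a ranked `saap_catalog` to use as-is, an integer
#'   (mine on the training data and keep the top so many pairs), or `NULL`
#'   for no SAAP features.
#' @param alpha Significance level used when `saaps` is an integer.
#' @param w Flank width (default 6).
#' @param sigma,ridge RBFN hyper-parameters; see [rbfn()].
#' @param sites Optional explicit site table (defaults to
#'   `extract_sites(records, residue)`).
#' @return Object of class `metalbind` (inherits from `rbfn`) with additional
#'   fields `residue`, `saaps`, `train_proteins` and `feature_spec`.
#' @examples
#' syn <- generate_synthetic(synth_config(seed = 1))
#' fit <- metalbind(syn$records, residue = "C", encoding = "PSSM",
#'                 profiles = syn$profiles, saaps = 5)
#' summary(fit)
#' @export
metalbind <- function(records, residue = c("C", "H"), encoding = "PSSM",
                     profiles = NULL, saaps = NULL, alpha = 0.05, w = 6L,
                     sigma = 5, ridge = 1e-8, sites = NULL) {
  residue <- match.arg(residue)
  encoding <- match.arg(encoding, c("AA", "BLOSUM62", "PAM250", "PSSM"))
  if (is.null(sites)) sites <- extract_sites(records, residue)
  if (!nrow(sites)) .stopf("no candidate %s sites in the training records", residue)
  if (is.numeric(saaps) && length(saaps) == 1L) {
    catalog <- mine_saaps(records, sites, alpha = alpha, w = w)
    saaps <- utils::head(catalog, saaps)
  }
  enc <- encode_dataset(records, sites, encoding, profiles, saaps = saaps, w = w)
  model <- rbfn(enc$x, enc$y, sigma = sigma, ridge = ridge)
  model$residue <- residue
  model$saaps <- saaps
  model$train_proteins <- sort(unique(sites$protein_id))
  model$feature_spec <- list(encoding = encoding, w = as.integer(w),
                             d = ncol(enc$x),
                             n_saaps = if (is.null(saaps)) 0L else nrow(saaps),
                             saap_names = if (is.null(saaps)) character(0)
                                          else saap_names(saaps))
  class(model) <- c("metalbind", "rbfn")
  model
}

#' @export
print.metalbind <- function(x, ...) {
  cat(sprintf("Metal-binding %s classifier (%s%s): %d centres, sigma = %g\n",
              ifelse(x$residue == "C", "cysteine", "histidine"),
              x$feature_spec$encoding,
              if (x$feature_spec$n_saaps) sprintf(" + %d SAAPs", x$feature_spec$n_saaps) else "",
              nrow(x$centers), x$sigma))
  invisible(x)
}

#' @export
summary.metalbind <- function(object, ...) {
  cat(sprintf("Metal-binding %s residue classifier\n",
              ifelse(object$residue == "C", "cysteine", "histidine")))
  cat(sprintf("  encoding     : %s (window %d, %d base features)\n",
              object$feature_spec$encoding, 2L * object$feature_spec$w + 1L,
              (2L * object$feature_spec$w + 1L) * 20L))
  cat(sprintf("  SAAP features: %d\n", object$feature_spec$n_saaps))
  cat(sprintf("  proteins     : %d\n", length(object$train_proteins)))
  NextMethod()
}

#' Predict metal-binding sites in new proteins
#'
#' Scores every candidate residue of the model's target type in `records`
#' and returns per-site decision values and hard labels.
#'
#' @param object A fitted [metalbind()] model.
#' @param records Named list of [protein_record()] objects.
#' @param profiles Named list of `pssm_profile` objects (PSSM models).
#' @param sites Optional explicit site table.
#' @param ... Unused.
#' @return `data.frame` with `protein_id`, `position`, `residue`,
#'   `g_binding`, `g_nonbinding`, `predicted`.
#' @export
predict.metalbind <- function(object, records, profiles = NULL, sites = NULL, ...) {
  fs <- object$feature_spec
  if (is.null(sites)) sites <- extract_sites(records, object$residue)
  if (!nrow(sites)) .stopf("no candidate %s sites to predict", object$residue)
  enc <- encode_dataset(records, sites, fs$encoding, profiles,
                        saaps = object$saaps, w = fs$w)
  if (ncol(enc$x) != ncol(object$centers))
    .stopf("feature spec mismatch: query encodes to %d features, model expects %d",
           ncol(enc$x), ncol(object$centers))
  g <- decision_values(object, enc$x)
  data.frame(protein_id = sites$protein_id, position = sites$position,
             residue = sites$residue,
             g_binding = g[, "binding"], g_nonbinding = g[, "non-binding"],
             predicted = ifelse(g[, "binding"] > g[, "non-binding"],
                                "binding", "non-binding"),
             stringsAsFactors = FALSE)
}

#' Evaluate a fitted model on an independent protein set
#'
#' Predicts every candidate residue of the model's target type in the
#' held-out records and compares against their annotations. Any accession
#' shared between the model's training proteins and the test records is a
#' hard error (leakage guard).
#'
#' @param model A fitted [metalbind()] model.
#' @param records Held-out annotated [protein_record()] list.
#' @param profiles Profiles for the held-out proteins (PSSM models).
#' @return List with `counts` ([confusion_counts()]), `metrics`
#'   ([compute_metrics()]) and `predictions`.
#' @export
run_independent_test <- function(model, records, profiles = NULL) {
  if (inherits(records, "protein_record")) records <- list(records)
  if (!length(records)) .stopf("empty independent test set")
  ids <- vapply(records, function(r) r$id, character(1))
  leak <- intersect(ids, model$train_proteins)
  if (length(leak))
    .stopf("train/test accession leakage: %s", paste(leak, collapse = ", "))
  sites <- extract_sites(records, model$residue)
  if (!nrow(sites)) .stopf("independent test set has no candidate %s sites", model$residue)
  pred <- predict(model, records, profiles = profiles, sites = sites)
  counts <- tabulate_confusion(sites$label, pred$predicted)
  list(counts = counts, metrics = compute_metrics(counts), predictions = pred)
}
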