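#' Confusion counts
#'
#' @param TP,FP,TN,FN Non-negative integer counts.
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  v <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(v < 0) || any(v != round(v))) .stopf("counts must be non-negative integers")
  structure(as.list(v), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Tabulate confusion counts from labels
#'
#' @param truth,predicted Character vectors over
#'   `{"binding", "non-binding"}`.
#' @return A [confusion_counts()] object.
#' @export
tabulate_confusion <- function(truth, predicted) {
  confusion_counts(TP = sum(truth == "binding" & predicted == "binding"),
                   FP = sum(truth == "non-binding" & predicted == "binding"),
                   TN = sum(truth == "non-binding" & predicted == "non-binding"),
                   FN = sum(truth == "binding" & predicted == "non-binding"))
}

#' Classification metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, accuracy `(TP+TN)/total`, and Matthews correlation
#' coefficient `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Metrics with a zero denominator are reported as `NA` and listed in the
#' `undefined` field rather than coerced to 0.
#'
#' @param counts A [confusion_counts()] object.
#' @return Object of class `metrics_report`: proportions in `[0, 1]`, MCC
#'   in `[-1, 1]`, plus `undefined` (character vector of metric names).
#' @export
compute_metrics <- function(counts) {
  TP <- as.numeric(counts$TP); FP <- as.numeric(counts$FP)
  TN <- as.numeric(counts$TN); FN <- as.numeric(counts$FN)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  m <- list(sensitivity = ratio(TP, TP + FN),
            specificity = ratio(TN, TN + FP),
            precision = ratio(TP, TP + FP),
            accuracy = ratio(TP + TN, TP + FP + TN + FN))
  mcc_den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  m$mcc <- if (mcc_den == 0) NA_real_ else (TP * TN - FP * FN) / sqrt(mcc_den)
  m$undefined <- names(m)[vapply(m, function(z) length(z) == 1 && is.na(z), logical(1))]
  m$counts <- counts
  structure(m, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt_pct <- function(v) if (is.na(v)) "undef" else sprintf("%.1f%%", 100 * v)
  with(x$counts, cat(sprintf("TP=%d FP=%d TN=%d FN=%d\n", TP, FP, TN, FN)))
  cat(sprintf("Sensitivity %s  Precision %s  Specificity %s  Accuracy %s  MCC %s\n",
              fmt_pct(x$sensitivity), fmt_pct(x$precision), fmt_pct(x$specificity),
              fmt_pct(x$accuracy), if (is.na(x$mcc)) "undef" else sprintf("%.2f", x$mcc)))
  invisible(x)
}

#' Format an evaluation report row
#'
#' Columns mirror the standard report layout: raw counts, then percentages
#' at one decimal and MCC at two decimals (full precision is retained in
#' the `metrics_report` itself).
#'
#' @param metrics A `metrics_report` from [compute_metrics()].
#' @param method Row label.
#' @return One-row `data.frame` with columns `Method`, `TP`, `FP`, `TN`,
#'   `FN`, `Sensitivity`, `Precision`, `Specificity`, `Accuracy`, `MCC`.
#' @export
metrics_row <- function(metrics, method = "model") {
  pct <- function(v) if (is.na(v)) NA_character_ else sprintf("%.1f%%", 100 * v)
  data.frame(Method = method,
             TP = metrics$counts$TP, FP = metrics$counts$FP,
             TN = metrics$counts$TN, FN = metrics$counts$FN,
             Sensitivity = pct(metrics$sensitivity),
             Precision = pct(metrics$precision),
             Specificity = pct(metrics$specificity),
             Accuracy = pct(metrics$accuracy),
             MCC = if (is.na(metrics$mcc)) NA_character_ else sprintf("%.2f", metrics$mcc),
             stringsAsFactors = FALSE)
}

#' Stratified cross-validation plan
#'
#' Randomly assigns sites to `k` folds, stratified by label so fold sizes
#' differ by at most one within each class. Reproducible for a fixed seed.
#'
#' @param labels Character vector of `"binding"` / `"non-binding"` labels
#'   (or a site table with a `label` column).
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Object of class `cv_plan`: list with `k`, `seed` and
#'   `assignment` (fold index per site).
#' @export
make_cv_plan <- function(labels, k = 10L, seed = 1L) {
  if (is.data.frame(labels)) labels <- labels$label
  k <- as.integer(k)
  tab <- table(labels)
  if (any(tab < k))
    .stopf("class '%s' has %d member(s) but k = %d folds; use a smaller k",
           names(tab)[which.min(tab)], min(tab), k)
  assignment <- integer(length(labels))
  rng <- local({ set.seed(seed); lapply(names(tab), function(cl) {
    idx <- which(labels == cl)
    sample(rep_len(seq_len(k), length(idx)))
  }) })
  for (i in seq_along(rng)) assignment[which(labels == names(tab)[i])] <- rng[[i]]
  structure(list(k = k, seed = as.integer(seed), assignment = assignment),
            class = "cv_plan")
}

#' Cross-validated evaluation
#'
#' Runs the full protocol over a cross-validation plan: in each fold the
#' classifier is trained on the other folds and predicts the held-out
#' fold; predictions are pooled into a single confusion matrix. When SAAP
#' features are requested, the default (`saap_scope = "fold"`) re-mines and
#' re-ranks the catalog inside each fold's *training* split only, so the
#' test fold never influences feature construction. `saap_scope = "global"`
#' instead uses a fixed catalog mined on the whole dataset before
#' splitting — the traditional protocol, which leaks fold information and
#' is kept only as an explicit option for reproducing that behaviour.
#'
#' @param records Named list of annotated [protein_record()] objects.
#' @param sites Site table (single residue type).
#' @param plan A [make_cv_plan()] object aligned with `sites`.
#' @param encoding,profiles,w Encoder configuration; see [encode_dataset()].
#' @param n_saaps Number of top-ranked SAAP indicator features to append
#'   (0 for none).
#' @param alpha Significance level for mining.
#' @param saap_scope `"fold"` (leak-free default) or `"global"`.
#' @param catalog Optional pre-ranked catalog (required for `"global"`).
#' @param sigma,ridge RBFN hyper-parameters.
#' @return List with `counts`, `metrics`, `predictions` (site table plus
#'   fold and predicted label) and `mining_rows` (per fold, the site row
#'   indices whose windows were visible to SAAP mining).
#' @export
run_cv <- function(records, sites, plan, encoding = "PSSM", profiles = NULL,
                   w = 6L, n_saaps = 0L, alpha = 0.05,
                   saap_scope = c("fold", "global"), catalog = NULL,
                   sigma = 5, ridge = 1e-8) {
  saap_scope <- match.arg(saap_scope)
  stopifnot(nrow(sites) == length(plan$assignment))
  enc <- encode_dataset(records, sites, encoding, profiles, w = w)
  wm <- if (n_saaps > 0L) site_window_matrix(records, sites, w = w)
  if (n_saaps > 0L && saap_scope == "global" && is.null(catalog))
    .stopf("saap_scope = 'global' needs a pre-ranked catalog")
  predicted <- character(nrow(sites))
  mining_rows <- vector("list", plan$k)
  for (f in seq_len(plan$k)) {
    tr <- plan$assignment != f
    te <- !tr
    x_tr <- enc$x[tr, , drop = FALSE]
    x_te <- enc$x[te, , drop = FALSE]
    if (n_saaps > 0L) {
      cat_f <- if (saap_scope == "fold") {
        mining_rows[[f]] <- which(tr)
        rank_saaps(enumerate_pairs(wm[tr, , drop = FALSE],
                                   sites$label[tr] == "binding"), alpha = alpha)
      } else catalog
      cat_f <- utils::head(cat_f, n_saaps)
      if (nrow(cat_f)) {
        ind <- encode_saap_indicators(wm, cat_f)
        x_tr <- cbind(x_tr, ind[tr, , drop = FALSE])
        x_te <- cbind(x_te, ind[te, , drop = FALSE])
      }
    }
    model <- rbfn(x_tr, enc$y[tr], sigma = sigma, ridge = ridge)
    predicted[te] <- predict(model, x_te)
  }
  counts <- tabulate_confusion(sites$label, predicted)
  pred <- cbind(sites, fold = plan$assignment, predicted = predicted)
  list(counts = counts, metrics = compute_metrics(counts),
       predictions = pred, mining_rows = mining_rows)
}

#' Greedy forward selection of ranked SAAP features
#'
#' Starting from the base encoding alone, ranked SAAPs are appended one at
#' a time in ascending p-value order; after each addition the pooled
#' cross-validation accuracy is recorded. The selected prefix length `k*`
#' maximises accuracy, with ties broken towards the smallest prefix (so an
#' uninformative catalog selects `k* = 0`).
#'
#' @param records,sites,plan,encoding,profiles,w,sigma,ridge As [run_cv()].
#' @param catalog Ranked `saap_catalog` (e.g. from [mine_saaps()]). The
#'   selection protocol evaluates prefixes of this fixed catalog.
#' @param max_k Longest prefix to evaluate (default: the whole catalog).
#' @return List with `k_star`, `selected` (the chosen catalog prefix),
#'   `base_accuracy`, and `trail` — a `data.frame` of `(k, accuracy)` with
#'   one row per evaluated prefix length `1..K`.
#' @export
forward_select_saaps <- function(records, sites, catalog, plan,
                                 encoding = "PSSM", profiles = NULL, w = 6L,
                                 max_k = NULL, sigma = 5, ridge = 1e-8) {
  K <- nrow(catalog)
  if (!is.null(max_k)) K <- min(K, max_k)
  enc <- encode_dataset(records, sites, encoding, profiles, w = w)
  ind <- if (K > 0L) {
    wm <- site_window_matrix(records, sites, w = w)
    encode_saap_indicators(wm, utils::head(catalog, K))
  }
  cv_accuracy <- function(x) {
    predicted <- character(nrow(sites))
    for (f in seq_len(plan$k)) {
      tr <- plan$assignment != f
      model <- rbfn(x[tr, , drop = FALSE], enc$y[tr], sigma = sigma, ridge = ridge)
      predicted[!tr] <- predict(model, x[!tr, , drop = FALSE])
    }
    mean(predicted == sites$label)
  }
  base_acc <- cv_accuracy(enc$x)
  acc <- numeric(K)
  for (k in seq_len(K)) {
    acc[k] <- cv_accuracy(cbind(enc$x, ind[, seq_len(k), drop = FALSE]))
  }
  all_acc <- c(base_acc, acc)
  k_star <- which.max(all_acc) - 1L   # which.max takes the first maximum: smallest k wins ties
  list(k_star = k_star,
       selected = utils::head(catalog, k_star),
       base_accuracy = base_acc,
       trail = data.frame(k = seq_len(K), accuracy = acc))
}

#' Write an evaluation report TSV
#'
#' One row per `metrics_report`, in the standard column order
#' `TP FP TN FN Sensitivity Precision Specificity Accuracy MCC`.
#'
#' @param reports Named list of `metrics_report` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(reports, path) {
  rows <- do.call(rbind, lapply(names(reports), function(nm)
    metrics_row(reports[[nm]], method = nm)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
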