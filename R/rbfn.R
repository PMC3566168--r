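#' Gaussian radial basis function kernel
#'
#' `exp(-||x - mu||^2 / (2 sigma^2))` with the Euclidean norm.
#'
#' @param x,mu Numeric vectors of equal length.
#' @param sigma Bandwidth, positive.
#' @return Kernel value in `(0, 1]`.
#' @export
rbf_kernel <- function(x, mu, sigma) {
  if (length(x) != length(mu)) .stopf("kernel inputs differ in length (%d vs %d)",
                                      length(x), length(mu))
  if (sigma <= 0) .stopf("sigma must be positive")
  exp(-sum((x - mu)^2) / (2 * sigma^2))
}

# m x k Gram matrix of Gaussian kernels between rows of a and rows of b,
# via the squared-distance expansion; tiny negative distances from
# cancellation are clamped to zero.
gauss_gram <- function(a, b, sigma) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

#' Fit a radial basis function network classifier
#'
#' Fits the all-centres Gaussian RBFN: every training vector becomes a
#' kernel centre with a shared fixed bandwidth, and the two output nodes
#' (binding / non-binding) are linear combinations of the kernels whose
#' weights solve a least-squares system against one-hot class targets.
#' With `ridge = 0` and distinct training points the square kernel system
#' is solved directly and the network interpolates its training labels;
#' with `ridge > 0` the ridge-stabilised normal equations
#' `(Phi' Phi + lambda I) W = Phi' T` are used, which also tolerates
#' duplicated or conflicting rows.
#'
#' @param x Numeric feature matrix, one row per training site.
#' @param y Labels: 0/1, logical, or a character/factor with levels
#'   `"binding"` / `"non-binding"` (1 and `TRUE` mean binding).
#' @param sigma Kernel bandwidth (default 5).
#' @param ridge Ridge stabiliser `lambda >= 0` (default `1e-8`).
#' @return Object of class `rbfn` with fields `centers`, `sigma`, `ridge`,
#'   `weights` (k x 2), `classes` and `feature_spec`.
#' @seealso [predict.rbfn()], [decision_values()], [write_rbfn()]
#' @export
rbfn <- function(x, y, sigma = 5, ridge = 1e-8) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) .stopf("non-finite values in the feature matrix")
  if (nrow(x) < 2L) .stopf("need at least 2 training rows")
  if (sigma <= 0) .stopf("sigma must be positive")
  if (ridge < 0) .stopf("ridge must be non-negative")
  y <- as_binding_label(y)
  if (length(y) != nrow(x)) .stopf("length(y) must equal nrow(x)")
  if (length(unique(y)) < 2L) .stopf("both classes must be present in training data")
  classes <- c("binding", "non-binding")
  targets <- cbind(binding = as.numeric(y == "binding"),
                   `non-binding` = as.numeric(y == "non-binding"))
  phi <- gauss_gram(x, x, sigma)
  weights <- if (ridge == 0) {
    solve(phi, targets)
  } else {
    solve(crossprod(phi) + diag(ridge, nrow(phi)), crossprod(phi, targets))
  }
  dimnames(weights) <- list(NULL, classes)
  structure(list(centers = x, sigma = sigma, ridge = ridge,
                 weights = weights, classes = classes, labels = y,
                 feature_spec = list(d = ncol(x))),
            class = "rbfn")
}

as_binding_label <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.logical(y) || is.numeric(y)) {
    if (is.numeric(y) && !all(y %in% c(0, 1))) .stopf("numeric labels must be 0/1")
    return(ifelse(as.logical(y), "binding", "non-binding"))
  }
  if (!all(y %in% c("binding", "non-binding")))
    .stopf("labels must be 0/1 or 'binding'/'non-binding'")
  y
}

#' Output-node values of an RBFN
#'
#' Evaluates each output node as the weighted sum of Gaussian kernels over
#' all centres: `g_j(x) = sum_i w_ij exp(-||x - mu_i||^2 / (2 sigma^2))`.
#'
#' @param model An [rbfn()] model.
#' @param x Numeric vector or matrix of query points (columns must match
#'   the centre dimension).
#' @return Numeric matrix, one row per query, columns `binding` and
#'   `non-binding`.
#' @export
decision_values <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != ncol(model$centers))
    .stopf("query has %d features but model expects %d", ncol(x), ncol(model$centers))
  gauss_gram(x, model$centers, model$sigma) %*% model$weights
}

#' Predict with an RBFN classifier
#'
#' @param object An [rbfn()] model.
#' @param x Query vector or matrix.
#' @param type `"class"` for hard labels (exact ties resolve to
#'   `"non-binding"`, keeping false positives conservative) or
#'   `"decision"` for the raw output-node values.
#' @param ... Unused.
#' @return Character vector of labels, or the decision-value matrix.
#' @export
predict.rbfn <- function(object, x, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  g <- decision_values(object, x)
  if (type == "decision") return(g)
  unname(ifelse(g[, "binding"] > g[, "non-binding"], "binding", "non-binding"))
}

#' @export
print.rbfn <- function(x, ...) {
  cat(sprintf("Gaussian RBF network: %d centres, %d features, sigma = %g, ridge = %g\n",
              nrow(x$centers), ncol(x$centers), x$sigma, x$ridge))
  invisible(x)
}

#' @export
summary.rbfn <- function(object, ...) {
  tab <- table(object$labels)
  cat(sprintf("Gaussian RBF network classifier\n"))
  cat(sprintf("  centres      : %d (all training points)\n", nrow(object$centers)))
  cat(sprintf("  features     : %d\n", ncol(object$centers)))
  cat(sprintf("  bandwidth    : %g\n", object$sigma))
  cat(sprintf("  ridge        : %g\n", object$ridge))
  cat(sprintf("  class counts : %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(object)
}

#' @export
coef.rbfn <- function(object, ...) object$weights

#' Save / load an RBFN model archive
#'
#' A self-describing JSON archive (format version field, centres, weights,
#' bandwidth, ridge, labels, and the feature specification used at
#' training). Doubles are written at full precision so a round-trip is
#' bit-exact.
#'
#' @param model An [rbfn()] or [metalbind()] model.
#' @param path File path.
#' @return `path` (write) or the restored model (read).
#' @export
write_rbfn <- function(model, path) {
  payload <- list(format = "metalbindr-rbfn", version = 1L,
                  class = class(model)[1],
                  sigma = model$sigma, ridge = model$ridge,
                  classes = model$classes, labels = model$labels,
                  d = ncol(model$centers),
                  residue = model$residue,
                  centers = as.vector(model$centers),
                  weights = as.vector(model$weights),
                  feature_spec = model$feature_spec,
                  train_proteins = model$train_proteins,
                  saaps = if (!is.null(model$saaps)) as.data.frame(model$saaps),
                  saap_meta = if (!is.null(model$saaps))
                    list(N = attr(model$saaps, "N"), M = attr(model$saaps, "M"),
                         w = attr(model$saaps, "w")))
  # digits = I(17): full significant-digit serialisation, bit-exact round-trip
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_rbfn
#' @export
read_rbfn <- function(path) {
  p <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) NULL)
  if (is.null(p) || !identical(p$format, "metalbindr-rbfn"))
    .stopf("%s is not a metalbindr model archive", path)
  k <- length(p$centers) / p$d
  model <- list(centers = matrix(as.numeric(p$centers), nrow = k, ncol = p$d),
                sigma = as.numeric(p$sigma), ridge = as.numeric(p$ridge),
                weights = matrix(as.numeric(p$weights), nrow = k, ncol = 2L,
                                 dimnames = list(NULL, p$classes)),
                classes = p$classes, labels = p$labels,
                feature_spec = p$feature_spec,
                residue = p$residue,
                train_proteins = p$train_proteins)
  if (!is.null(p$saaps) && length(p$saaps)) {
    model$saaps <- structure(as.data.frame(p$saaps),
                             N = p$saap_meta$N, M = p$saap_meta$M,
                             w = p$saap_meta$w,
                             class = c("saap_catalog", "data.frame"))
  }
  class(model) <- p$class
  if (p$class == "metalbind") class(model) <- c("metalbind", "rbfn")
  model
}
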