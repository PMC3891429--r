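# One-vs-all soft-margin classification over precomputed Gram matrices.
#
# The binary dual problems are solved by kernlab's SMO through its
# precomputed-kernel interface; this module owns the one-vs-all assembly,
# the decision function over stored support coefficients, deterministic
# tie-breaking, and BIO-sequence repair of the per-token predictions.

# Deterministic label ordering: the canonical 11 BIO labels first (in
# bio_labels() order), then any remaining labels sorted.
ordered_label_set <- function(labels) {
  present <- unique(labels)
  c(intersect(bio_labels(), present),
    sort(setdiff(present, bio_labels())))
}

train_binary <- function(K, y, C) {
  m <- kernlab::ksvm(kernlab::as.kernelMatrix(K),
                     factor(y, levels = c(-1, 1)),
                     type = "C-svc", C = C)
  coefs <- unlist(kernlab::coef(m), use.names = FALSE)
  idx <- unlist(kernlab::alphaindex(m), use.names = FALSE)
  b <- kernlab::b(m)
  f <- as.numeric(K[, idx, drop = FALSE] %*% coefs - b)
  # kernlab's internal +1 class depends on factor bookkeeping; orient the
  # stored decision function so that positive scores mean the target label
  if (sum(f * y) < 0) {
    coefs <- -coefs
    b <- -b
  }
  list(support = idx, coef = coefs, b = b,
       alpha = unlist(kernlab::alpha(m), use.names = FALSE))
}

#' Train a one-vs-all SVM over a precomputed Gram matrix
#'
#' One binary soft-margin SVM per label present in the data, each trained on
#' the full Gram matrix with that label as the positive class.  Prediction
#' is by maximal decision value with deterministic tie-breaking by label
#' order.
#'
#' @param gram A `gram_matrix` (from [gram_matrix()]) or a plain square
#'   numeric matrix of kernel values.
#' @param labels Character vector of instance labels, one per Gram row; at
#'   least two distinct labels are required.
#' @param C Soft-margin trade-off, positive; default 1.
#' @return An `ova_model`: `label_set`, per-label `binaries` (support
#'   indices, dual coefficients, bias), `C`, `n_train`.
#' @export
train_ova <- function(gram, labels, C = 1) {
  K <- if (inherits(gram, "gram_matrix")) gram$values else as.matrix(gram)
  if (nrow(K) != ncol(K)) stop("gram matrix must be square", call. = FALSE)
  if (length(labels) != nrow(K)) {
    stop("labels length must equal the number of instances", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("training data must contain at least two distinct labels", call. = FALSE)
  }
  if (C <= 0) stop("C must be positive", call. = FALSE)

  # Cheap PSD check by Cholesky with a small ridge; only on failure pay for
  # the eigendecomposition needed to size the jitter.
  psd_ok <- tryCatch({
    chol(K + diag(1e-8 * max(1, max(abs(diag(K)))), nrow(K)))
    TRUE
  }, error = function(e) FALSE)
  if (!psd_ok) {
    eig_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
    warning(sprintf("gram matrix is not PSD (min eigenvalue %.3g); adding jitter",
                    eig_min), call. = FALSE)
    K <- K + diag(abs(eig_min) + 1e-8, nrow(K))
  }

  label_set <- ordered_label_set(labels)
  binaries <- lapply(label_set, function(lab) {
    y <- ifelse(labels == lab, 1, -1)
    train_binary(K, y, C)
  })
  names(binaries) <- label_set
  structure(list(label_set = label_set, binaries = binaries, C = C,
                 n_train = nrow(K)),
            class = "ova_model")
}

#' @export
print.ova_model <- function(x, ...) {
  cat(sprintf("<ova_model %d labels, %d training instances, C=%g>\n",
              length(x$label_set), x$n_train, x$C))
  invisible(x)
}

# Decision scores: one column per label in label_set order.
ova_scores <- function(model, gram_test) {
  if (ncol(gram_test) != model$n_train) {
    stop(sprintf("gram_test has %d columns but the model was trained on %d instances",
                 ncol(gram_test), model$n_train), call. = FALSE)
  }
  scores <- vapply(model$binaries, function(bin) {
    as.numeric(gram_test[, bin$support, drop = FALSE] %*% bin$coef - bin$b)
  }, numeric(nrow(gram_test)))
  matrix(scores, nrow = nrow(gram_test),
         dimnames = list(NULL, model$label_set))
}

#' Predict labels from test-against-training kernel values
#'
#' @param model An `ova_model`.
#' @param gram_test Numeric matrix, one row per test instance and one
#'   column per training instance (aligned with the training Gram).
#' @return Character vector of predicted labels, ties broken by position in
#'   `model$label_set`.
#' @export
predict_labels <- function(model, gram_test) {
  gram_test <- as.matrix(gram_test)
  scores <- ova_scores(model, gram_test)
  model$label_set[max.col(scores, ties.method = "first")]
}

#' Repair an invalid IOB2 sequence
#'
#' Per-token classification can emit `I-X` tags with no open entity; the
#' standard repair turns every `I-X` not preceded by `B-X` or `I-X` into
#' `B-X`.  The result is valid IOB2 and the operation is idempotent.
#'
#' @param labels Character vector of BIO labels.
#' @return Repaired character vector.
#' @examples
#' repair_bio(c("O", "I-DNA"))            # "O", "B-DNA"
#' repair_bio(c("B-DNA", "I-protein"))    # "B-DNA", "B-protein"
#' @export
repair_bio <- function(labels) {
  bad <- setdiff(unique(labels), bio_labels())
  if (length(bad) > 0L) {
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- labels
  for (i in seq_along(out)) {
    tag <- out[[i]]
    if (!startsWith(tag, "I-")) next
    cls <- substring(tag, 3L)
    prev_ok <- i > 1L && out[[i - 1L]] %in% paste0(c("B-", "I-"), cls)
    if (!prev_ok) out[[i]] <- paste0("B-", cls)
  }
  out
}

#' Serialize an OVA model to JSON
#'
#' Stores the label set, C, and per-label support indices, dual
#' coefficients and biases in a single text archive readable by
#' [read_ova()].
#'
#' @param model An `ova_model`.
#' @param path Output file path.
#' @export
write_ova <- function(model, path) {
  payload <- list(label_set = model$label_set, C = model$C,
                  n_train = model$n_train,
                  binaries = lapply(model$binaries, function(b) {
                    list(support = b$support, coef = b$coef, b = b$b)
                  }))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read an OVA model written by [write_ova()]
#' @param path File path.
#' @return An `ova_model`.
#' @export
read_ova <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  binaries <- lapply(p$binaries, function(b) {
    list(support = as.integer(b$support), coef = as.numeric(b$coef),
         b = as.numeric(b$b))
  })
  structure(list(label_set = p$label_set, binaries = binaries, C = p$C,
                 n_train = as.integer(p$n_train)),
            class = "ova_model")
}
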