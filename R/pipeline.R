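# End-to-end tagger: corpus -> instances -> Gram -> one-vs-all SVM ->
# per-token prediction -> BIO repair.  Three kernels are available: the
# sliding tree kernel in SST or ST mode, and the linear word-window
# baseline.

#' Train a BIO tagger on an annotated corpus
#'
#' Builds one instance per token (a sliding tree fragment for the tree
#' kernels, a word-window feature vector for the linear baseline), assembles
#' the Gram matrix and trains a one-vs-all SVM over it.
#'
#' @param corpus List of `tagged_sentence` objects (with POS for the tree
#'   kernels; sentences without POS fall back to a single generic
#'   preterminal).
#' @param kernel `"sliding-sst"`, `"sliding-st"` or `"linear"`.
#' @param s Sliding-window width (tree kernels), odd; default 7.
#' @param lambda Tree-kernel decay in (0, 1]; default 0.4.
#' @param C Soft-margin trade-off; default 1.
#' @param window_k Word-window width for the linear baseline; default 5.
#' @param marker_label Current-word marker label; `NULL` disables the
#'   marker (ablation).  Default `"CW"`.
#' @param normalize Cosine-normalize tree-kernel values; default `TRUE`.
#' @param verbose Log instance counts and timing via `message()`.
#' @return An `sl_tagger` model carrying the OVA model and the training
#'   instances needed to kernel new data against.
#' @export
train_tagger <- function(corpus,
                         kernel = c("sliding-sst", "sliding-st", "linear"),
                         s = 7, lambda = 0.4, C = 1, window_k = 5,
                         marker_label = "CW", normalize = TRUE,
                         verbose = FALSE) {
  kernel <- match.arg(kernel)
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  t0 <- proc.time()[["elapsed"]]

  if (kernel == "linear") {
    fvecs <- corpus_feature_vectors(corpus, window_k)
    labels <- unlist(lapply(corpus, `[[`, "tags"), use.names = FALSE)
    say("training instances: %d (linear window k=%d)", length(fvecs), window_k)
    lg <- linear_gram(fvecs)
    say("gram matrix: %d x %d (%d kernel evaluations)",
        nrow(lg$K), ncol(lg$K), nrow(lg$K)^2)
    ova <- train_ova(lg$K, labels, C = C)
    model <- list(kernel = kernel, window_k = as.integer(window_k), C = C,
                  ova = ova, train_features = fvecs)
  } else {
    params <- kernel_params(mode = if (kernel == "sliding-st") "ST" else "SST",
                            lambda = lambda, normalize = normalize, s = s,
                            marker_label = marker_label)
    inst <- corpus_instances(corpus, s = s, marker_label = marker_label)
    say("training instances: %d (sliding fragments, s=%d)",
        length(inst$fragments), s)
    gram <- gram_matrix(inst$fragments, params)
    say("gram matrix: %d x %d (%d kernel evaluations)",
        nrow(gram$values), ncol(gram$values),
        length(inst$fragments) * (length(inst$fragments) + 1) / 2)
    ova <- train_ova(gram, inst$labels, C = C)
    model <- list(kernel = kernel, params = params, C = C, ova = ova,
                  train_fragments = inst$fragments)
  }
  say("training time: %.1f s", proc.time()[["elapsed"]] - t0)
  structure(model, class = "sl_tagger")
}

#' @export
print.sl_tagger <- function(x, ...) {
  n <- if (x$kernel == "linear") length(x$train_features) else length(x$train_fragments)
  cat(sprintf("<sl_tagger kernel=%s, %d training instances, %d labels>\n",
              x$kernel, n, length(x$ova$label_set)))
  invisible(x)
}

#' Tag a corpus with a trained model
#'
#' Kernels every test token against the stored training instances, predicts
#' per-token labels by maximal one-vs-all decision value, and repairs the
#' resulting sequences into valid IOB2.
#'
#' @param model An `sl_tagger` from [train_tagger()].
#' @param corpus List of `tagged_sentence` objects (gold tags, if any, are
#'   ignored).
#' @param verbose Log progress via `message()`.
#' @return The corpus with predicted tags.
#' @export
predict_tagger <- function(model, corpus, verbose = FALSE) {
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  t0 <- proc.time()[["elapsed"]]

  if (model$kernel == "linear") {
    fvecs <- corpus_feature_vectors(corpus, model$window_k)
    vocab <- unique(unlist(model$train_features, use.names = FALSE))
    Xtr <- feature_matrix(model$train_features, vocab)
    Xte <- feature_matrix(fvecs, vocab)
    Ktest <- as.matrix(Matrix::tcrossprod(Xte, Xtr))
    say("test instances: %d", length(fvecs))
  } else {
    inst <- corpus_instances(corpus, s = model$params$s,
                             marker_label = model$params$marker_label)
    say("test instances: %d", length(inst$fragments))
    Ktest <- cross_gram_matrix(inst$fragments, model$train_fragments,
                               model$params)
  }
  pred <- predict_labels(model$ova, Ktest)
  say("prediction time: %.1f s", proc.time()[["elapsed"]] - t0)

  out <- vector("list", length(corpus))
  pos0 <- 0L
  for (k in seq_along(corpus)) {
    sent <- corpus[[k]]
    n <- length(sent$tokens)
    tags <- repair_bio(pred[pos0 + seq_len(n)])
    out[[k]] <- tagged_sentence(sent$tokens, tags, pos = sent$pos)
    pos0 <- pos0 + n
  }
  out
}

#' Sliding-value sweep: token-level scores for one tag across window widths
#'
#' Trains and evaluates the sliding tree kernel tagger once per value of
#' `s` and reports token-level precision / recall / F for a single tag,
#' yielding one row per `s`.
#'
#' @param train_corpus,test_corpus Annotated corpora.
#' @param s_values Odd window widths to sweep; default `c(5, 7, 9)`.
#' @param tag Label scored, default `"B-DNA"`.
#' @param ... Passed on to [train_tagger()] (e.g. `lambda`, `C`).
#' @return Data frame with columns `class`, `s`, `precision`, `recall`, `f`.
#' @export
sweep_s <- function(train_corpus, test_corpus, s_values = c(5, 7, 9),
                    tag = "B-DNA", ...) {
  rows <- lapply(s_values, function(s) {
    model <- train_tagger(train_corpus, kernel = "sliding-sst", s = s, ...)
    pred <- predict_tagger(model, test_corpus)
    prf <- tag_prf(test_corpus, pred, tag)
    data.frame(class = tag, s = s, precision = prf[["precision"]],
               recall = prf[["recall"]], f = prf[["f"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Serialize a trained tagger to JSON
#'
#' A single text archive: kernel type and parameters, the OVA duals, and
#' the training instances (fragment trees in bracketed form, or feature
#' vectors for the linear baseline).
#'
#' @param model An `sl_tagger`.
#' @param path Output file path.
#' @export
write_tagger <- function(model, path) {
  payload <- list(kernel = model$kernel, C = model$C,
                  ova = list(label_set = model$ova$label_set,
                             n_train = model$ova$n_train,
                             binaries = lapply(model$ova$binaries, function(b) {
                               list(support = b$support, coef = b$coef, b = b$b)
                             })))
  if (model$kernel == "linear") {
    payload$window_k <- model$window_k
    payload$train_features <- model$train_features
  } else {
    payload$params <- unclass(model$params)
    payload$train_fragments <- lapply(model$train_fragments, function(f) {
      list(tree = write_bracketed(f$tree), sentence_id = f$sentence_id,
           center_index = f$center_index, s = f$s)
    })
  }
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a tagger written by [write_tagger()]
#' @param path File path.
#' @return An `sl_tagger`.
#' @export
read_tagger <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  ova <- structure(list(
    label_set = unlist(p$ova$label_set),
    binaries = lapply(p$ova$binaries, function(b) {
      list(support = as.integer(unlist(b$support)),
           coef = as.numeric(unlist(b$coef)), b = as.numeric(b$b))
    }),
    C = p$C, n_train = as.integer(p$ova$n_train)), class = "ova_model")
  names(ova$binaries) <- ova$label_set

  if (p$kernel == "linear") {
    model <- list(kernel = "linear", window_k = as.integer(p$window_k),
                  C = p$C, ova = ova,
                  train_features = lapply(p$train_features, unlist))
  } else {
    prm <- p$params
    params <- kernel_params(mode = prm$mode, lambda = prm$lambda,
                            normalize = isTRUE(prm$normalize), s = prm$s,
                            marker_label = if (is.null(prm$marker_label)) NULL else prm$marker_label)
    frags <- lapply(p$train_fragments, function(f) {
      structure(list(tree = parse_bracketed(f$tree),
                     sentence_id = f$sentence_id,
                     center_index = as.integer(f$center_index),
                     s = as.integer(f$s),
                     marker_label = params$marker_label),
                class = "sl_fragment")
    })
    model <- list(kernel = p$kernel, params = params, C = p$C, ova = ova,
                  train_fragments = frags)
  }
  structure(model, class = "sl_tagger")
}
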