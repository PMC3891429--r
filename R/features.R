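# Linear-SVM baseline: binary word-window features and their dot-product
# kernel.  Each token instance activates one (offset, word) indicator per
# in-bounds offset in a window of k tokens; the kernel between two
# instances is the number of shared indicators.

#' Word-window features for one token
#'
#' One binary feature `(offset, word)` per in-bounds offset in the window of
#' odd width `k` centred on token `i`; offsets outside the sentence
#' contribute nothing (truncation, no padding).
#'
#' @param tokens Character vector: the sentence's words.
#' @param i Focus token position, 1-based.
#' @param k Odd window width.
#' @return Character vector of active feature identifiers `"offset:word"`.
#' @examples
#' word_window_features(c("a", "b", "c"), 2, 3)
#' @export
word_window_features <- function(tokens, i, k) {
  if (k < 1 || k %% 2 != 1) {
    stop("window width k must be an odd positive integer", call. = FALSE)
  }
  n <- length(tokens)
  if (i < 1 || i > n) {
    stop(sprintf("focus index %d out of range 1..%d", i, n), call. = FALSE)
  }
  h <- (k - 1) / 2
  offs <- (-h):h
  pos <- i + offs
  keep <- pos >= 1 & pos <= n
  sprintf("%+d:%s", offs[keep], tokens[pos[keep]])
}

#' Linear kernel between two feature vectors
#'
#' Dot product of the binary indicator vectors: the size of the intersection
#' of the active feature sets.
#'
#' @param u,v Character vectors of active feature identifiers.
#' @return Non-negative integer.
#' @export
linear_kernel <- function(u, v) {
  length(intersect(u, v))
}

# Feature vectors for every token of a corpus, in corpus token order.
corpus_feature_vectors <- function(sentences, k) {
  out <- list()
  for (sent in sentences) {
    n <- length(sent$tokens)
    for (i in seq_len(n)) {
      out[[length(out) + 1L]] <- word_window_features(sent$tokens, i, k)
    }
  }
  out
}

# Sparse indicator matrix (instances x features) over a shared vocabulary;
# Gram and cross-Gram matrices follow by sparse cross products.
feature_matrix <- function(fvecs, vocab = NULL) {
  if (is.null(vocab)) {
    vocab <- unique(unlist(fvecs, use.names = FALSE))
  }
  ii <- rep.int(seq_along(fvecs), lengths(fvecs))
  jj <- match(unlist(fvecs, use.names = FALSE), vocab)
  keep <- !is.na(jj)
  Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = 1,
                       dims = c(length(fvecs), length(vocab)))
}

# Dense Gram matrix of the linear window-feature kernel.
linear_gram <- function(fvecs) {
  X <- feature_matrix(fvecs)
  K <- as.matrix(Matrix::tcrossprod(X))
  list(K = K, vocab = colnames(X))
}
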