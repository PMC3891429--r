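# Per-token windowed tree fragments: the instances the sliding tree kernel
# compares.  Each fragment is the sentence tree pruned to a window of s
# tokens around the focus token, with a marker node ("CW", current word)
# inserted between the focus token's preterminal and its leaf so that
# fragments centred on different tokens of one sentence are structurally
# distinct.

#' Token window around a focus position
#'
#' The window of odd width `s` centred on token `i` covers
#' `max(1, i - h) .. min(n, i + h)` with `h = (s - 1) / 2`; it is truncated,
#' not padded, at sentence boundaries.  Indices are 1-based.
#'
#' @param n Sentence length in tokens.
#' @param i Focus token position, `1 <= i <= n`.
#' @param s Odd window width, `s >= 1`.
#' @return Integer vector `c(lo, hi)` of the first and last covered indices.
#' @examples
#' window_indices(8, 2, 5)   # c(1, 4)
#' @export
window_indices <- function(n, i, s) {
  stopifnot(is.numeric(n), is.numeric(i), is.numeric(s))
  if (s < 1 || s %% 2 != 1) {
    stop("window width s must be an odd positive integer", call. = FALSE)
  }
  if (i < 1 || i > n) {
    stop(sprintf("focus index %d out of range 1..%d", as.integer(i), as.integer(n)),
         call. = FALSE)
  }
  h <- (s - 1) / 2
  c(as.integer(max(1, i - h)), as.integer(min(n, i + h)))
}

#' Extract the sliding fragment for one focus token
#'
#' The sentence tree is pruned to the leaves inside the window: leaves
#' outside the window are removed, internal nodes that no longer dominate a
#' surviving leaf are removed, and all ancestors of surviving leaves are kept
#' up to the root (unary chains are left uncollapsed so that no production
#' absent from the source tree is invented).  A marker node labelled
#' `marker_label` is then inserted between the focus token's preterminal and
#' its leaf, giving the focus word the path POS -> marker -> word.  Passing
#' `marker_label = NULL` skips marker insertion (used for ablation).
#'
#' @param tree Sentence tree (`tk_node`) whose leaves are the tokens.
#' @param i Focus token position, 1-based.
#' @param s Odd window width in tokens.
#' @param marker_label Marker node label, default `"CW"`; `NULL` disables.
#' @param sentence_id Identifier stored on the fragment.
#' @return A `sl_fragment`: list with fields `tree`, `sentence_id`,
#'   `center_index`, `s`, `marker_label`.
#' @examples
#' tr <- build_flat_tree(c("Presence", "of", "beta", "2-M"),
#'                       c("NN", "IN", "NN", "NN"))
#' extract_sliding_fragment(tr, 2, 3)
#' @export
extract_sliding_fragment <- function(tree, i, s, marker_label = "CW",
                                     sentence_id = NA_character_) {
  leaves <- tree_leaves(tree)
  rng <- window_indices(length(leaves), i, s)

  counter <- new.env(parent = emptyenv())
  counter$k <- 0L
  prune <- function(node) {
    if (is_leaf(node)) {
      counter$k <- counter$k + 1L
      idx <- counter$k
      if (idx < rng[1L] || idx > rng[2L]) return(NULL)
      leaf <- node
      if (!is.null(marker_label) && idx == i) {
        return(tk_node(marker_label, list(leaf)))
      }
      return(leaf)
    }
    kept <- Filter(Negate(is.null), lapply(node$children, prune))
    if (length(kept) == 0L) return(NULL)
    tk_node(node$label, kept)
  }
  pruned <- prune(tree)

  structure(list(tree = pruned,
                 sentence_id = sentence_id,
                 center_index = as.integer(i),
                 s = as.integer(s),
                 marker_label = marker_label),
            class = "sl_fragment")
}

#' @export
print.sl_fragment <- function(x, ...) {
  cat(sprintf("<sl_fragment center=%d s=%d> %s\n",
              x$center_index, x$s, write_bracketed(x$tree)))
  invisible(x)
}

#' All sliding fragments of a sentence
#'
#' One fragment per word token, in token order.
#'
#' @inheritParams extract_sliding_fragment
#' @return List of `sl_fragment`, length equal to the token count.
#' @export
sliding_fragments <- function(tree, s, marker_label = "CW",
                              sentence_id = NA_character_) {
  n <- length(tree_leaves(tree))
  lapply(seq_len(n), function(i) {
    extract_sliding_fragment(tree, i, s, marker_label = marker_label,
                             sentence_id = sentence_id)
  })
}

#' Fragment instance identifier
#' @param fragment A `sl_fragment`.
#' @return Character scalar `"<sentence_id>:<center>"`.
#' @export
fragment_id <- function(fragment) {
  paste0(fragment$sentence_id, ":", fragment$center_index)
}
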