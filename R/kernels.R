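# Convolution tree kernels (ST and SST), the sliding tree kernel over
# windowed fragments, cosine normalization and Gram-matrix assembly.
#
# The kernel between two trees is the decayed count of their common
# fragments, computed by the classic node-pair dynamic programme rather than
# by enumerating the fragment space.  The heavy lifting is in src/kernels.cpp;
# delta() below is the plain recursive reference used on single node pairs.

#' Kernel parameters
#'
#' @param mode Fragment space: `"SST"` (subset trees: descendants may be cut
#'   but every retained node keeps its full production) or `"ST"` (subtrees:
#'   a node with all of its descendants).
#' @param lambda Decay in (0, 1] applied per fragment node; `lambda = 1`
#'   makes the unnormalized kernel an exact common-fragment count, while
#'   values below 1 damp the dominance of large fragments.  Default 0.4.
#' @param normalize Cosine-normalize kernel values so self-similarity is
#'   exactly 1.  Default `TRUE`.
#' @param s Sliding-window width in tokens (odd), default 7.
#' @param marker_label Label of the current-word marker node, default
#'   `"CW"`; `NULL` disables the marker.
#' @return A `kernel_params` object.
#' @export
kernel_params <- function(mode = c("SST", "ST"), lambda = 0.4,
                          normalize = TRUE, s = 7, marker_label = "CW") {
  mode <- match.arg(mode)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0 || lambda > 1) {
    stop("lambda must be a single number in (0, 1]", call. = FALSE)
  }
  if (s < 1 || s %% 2 != 1) {
    stop("window width s must be an odd positive integer", call. = FALSE)
  }
  structure(list(mode = mode, lambda = lambda, normalize = isTRUE(normalize),
                 s = as.integer(s), marker_label = marker_label),
            class = "kernel_params")
}

# Flatten a tree for the C++ kernel: a character production key per internal
# node (parent label + ordered child labels, with leaf children marked so
# that a frontier nonterminal never aliases a preterminal) and each node's
# internal children as indices.
flatten_tree <- function(tree) {
  prods <- character(0)
  kids <- list()
  walk <- function(node) {
    if (is_leaf(node)) return(NA_integer_)
    child_ids <- vapply(node$children, walk, integer(1))
    tags <- vapply(seq_along(node$children), function(k) {
      ch <- node$children[[k]]
      paste0(if (is_leaf(ch)) "w:" else "n:", ch$label)
    }, character(1))
    id <- length(prods) + 1L
    prods[[id]] <<- paste0(node$label, " -> ", paste(tags, collapse = " "))
    kids[[id]] <<- child_ids[!is.na(child_ids)]
    id
  }
  walk(tree)
  list(prod = prods, kids = kids)
}

# Map flattened trees to the integer-coded form the C++ routines expect;
# production ids are shared across all trees in the call.
encode_flat <- function(flats) {
  all_keys <- unique(unlist(lapply(flats, `[[`, "prod"), use.names = FALSE))
  lapply(flats, function(f) {
    list(prod = match(f$prod, all_keys),
         kids = lapply(f$kids, function(k) as.integer(k - 1L)))
  })
}

#' Node-pair similarity (delta recursion)
#'
#' The number of common fragments rooted at a pair of internal nodes, each
#' fragment decayed by `lambda` per node.  Zero when the productions differ;
#' `lambda` for matching preterminals; otherwise `lambda` times the product
#' over aligned children of `1 + delta` (SST mode) or of `delta` (ST mode,
#' which therefore requires entire descendant subtrees to match).
#'
#' This is the plain recursive reference; [tree_kernel()] computes the same
#' quantity summed over all node pairs with memoization in compiled code.
#'
#' @param n1,n2 Internal `tk_node`s.
#' @param params A [kernel_params()] object (only `mode` and `lambda` used).
#' @return Non-negative real.
#' @export
delta <- function(n1, n2, params = kernel_params()) {
  stopifnot(!is_leaf(n1), !is_leaf(n2))
  key <- function(n) {
    paste0(n$label, " -> ", paste(vapply(n$children, function(ch) {
      paste0(if (is_leaf(ch)) "w:" else "n:", ch$label)
    }, character(1)), collapse = " "))
  }
  if (!identical(key(n1), key(n2))) return(0)
  v <- params$lambda
  for (k in seq_along(n1$children)) {
    c1 <- n1$children[[k]]
    c2 <- n2$children[[k]]
    if (is_leaf(c1)) next
    d <- delta(c1, c2, params)
    v <- v * if (params$mode == "ST") d else (1 + d)
    if (v == 0) break
  }
  v
}

#' Tree kernel between two trees
#'
#' Sum of [delta()] over all internal-node pairs: the decayed count of
#' common ST or SST fragments.  With `lambda = 1` and identical trees the
#' value equals the number of fragments of the corresponding mode (counted
#' per node pair).  Unnormalized; normalization belongs to
#' [sliding_tree_kernel()] and [gram_matrix()].
#'
#' @param t1,t2 `tk_node` trees.
#' @param params A [kernel_params()] object.
#' @return Non-negative real.
#' @examples
#' t <- parse_bracketed("(S (NN dog) (VB runs))")
#' tree_kernel(t, t, kernel_params(mode = "SST", lambda = 1))  # 6
#' @export
tree_kernel <- function(t1, t2, params = kernel_params()) {
  enc <- encode_flat(list(flatten_tree(t1), flatten_tree(t2)))
  cpp_tree_kernel(enc[[1L]], enc[[2L]], params$lambda, params$mode == "ST")
}

#' Sliding tree kernel between two fragments
#'
#' The tree kernel on the fragments' windowed, marker-augmented trees; when
#' `params$normalize` is set, the value is cosine-normalized to
#' `K(f1, f2) / sqrt(K(f1, f1) * K(f2, f2))`, lying in `[0, 1]` with
#' self-similarity exactly 1.
#'
#' @param f1,f2 `sl_fragment` objects built with the same `s` and marker.
#' @param params A [kernel_params()] object.
#' @return Real kernel value.
#' @export
sliding_tree_kernel <- function(f1, f2, params = kernel_params()) {
  k12 <- tree_kernel(f1$tree, f2$tree, params)
  if (!params$normalize) return(k12)
  k11 <- tree_kernel(f1$tree, f1$tree, params)
  k22 <- tree_kernel(f2$tree, f2$tree, params)
  if (k11 <= 0 || k22 <= 0) {
    stop("degenerate fragment with zero self-kernel", call. = FALSE)
  }
  k12 / sqrt(k11 * k22)
}

#' Gram matrix over a set of sliding fragments
#'
#' Pairwise sliding-tree-kernel values; only the upper triangle is computed
#' and mirrored.  The result is symmetric and, when normalized, has unit
#' diagonal and entries in `[0, 1]`; it is positive semidefinite up to
#' floating-point error.
#'
#' @param fragments List of `sl_fragment` objects.
#' @param params A [kernel_params()] object.
#' @return A `gram_matrix`: list with `values` (numeric matrix) and `ids`
#'   (instance identifiers from [fragment_id()]).
#' @export
gram_matrix <- function(fragments, params = kernel_params()) {
  if (length(fragments) == 0L) stop("no fragments supplied", call. = FALSE)
  enc <- encode_flat(lapply(fragments, function(f) flatten_tree(f$tree)))
  K <- cpp_gram_matrix(enc, params$lambda, params$mode == "ST",
                       params$normalize)
  ids <- vapply(fragments, fragment_id, character(1))
  dimnames(K) <- list(ids, ids)
  structure(list(values = K, ids = ids, params = params),
            class = "gram_matrix")
}

#' Cross Gram matrix between two fragment sets
#'
#' Kernel values of every fragment in `fragments` (rows, e.g. test
#' instances) against every fragment in `ref_fragments` (columns, e.g.
#' training instances), normalized with each instance's own self-kernel when
#' `params$normalize` is set.
#'
#' @param fragments,ref_fragments Lists of `sl_fragment` objects.
#' @param params A [kernel_params()] object.
#' @return Numeric matrix of dimension `length(fragments)` by
#'   `length(ref_fragments)`.
#' @export
cross_gram_matrix <- function(fragments, ref_fragments,
                              params = kernel_params()) {
  enc_a <- lapply(fragments, function(f) flatten_tree(f$tree))
  enc_b <- lapply(ref_fragments, function(f) flatten_tree(f$tree))
  enc <- encode_flat(c(enc_a, enc_b))
  K <- cpp_cross_matrix(enc[seq_along(enc_a)],
                        enc[length(enc_a) + seq_along(enc_b)],
                        params$lambda, params$mode == "ST", params$normalize)
  rownames(K) <- vapply(fragments, fragment_id, character(1))
  colnames(K) <- vapply(ref_fragments, fragment_id, character(1))
  K
}

#' @export
print.gram_matrix <- function(x, ...) {
  cat(sprintf("<gram_matrix %d x %d, mode=%s lambda=%g normalize=%s>\n",
              nrow(x$values), ncol(x$values), x$params$mode,
              x$params$lambda, x$params$normalize))
  invisible(x)
}

#' Write a Gram matrix to a tab-separated file
#'
#' Layout: header row of instance identifiers, then one row per instance
#' with its identifier in the first column.  [read_gram()] inverts it.
#'
#' @param gram A `gram_matrix`.
#' @param path Output file path.
#' @export
write_gram <- function(gram, path) {
  df <- data.frame(id = gram$ids, gram$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Gram matrix written by [write_gram()]
#' @param path File path.
#' @return A `gram_matrix` (with `params = NULL`: the file does not carry
#'   kernel parameters).
#' @export
read_gram <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  K <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(K) <- list(ids, ids)
  structure(list(values = K, ids = ids, params = NULL), class = "gram_matrix")
}
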