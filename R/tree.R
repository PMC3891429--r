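# Labeled ordered rooted trees for syntactic structure.
#
# A tree node is a list with fields `label` (non-empty character scalar) and
# `children` (possibly empty list of nodes).  Leaves carry word tokens;
# preterminals are part-of-speech tags with a single leaf child.

#' Construct a tree node
#'
#' Trees are labeled, ordered, rooted: leaves are word tokens, preterminals
#' are part-of-speech tags dominating a single leaf, and internal nodes carry
#' phrase labels.
#'
#' @param label Non-empty character scalar.
#' @param children List of `tk_node` objects (empty for a leaf).
#' @return A `tk_node` object.
#' @examples
#' tk_node("NN", list(tk_node("dog")))
#' @export
tk_node <- function(label, children = list()) {
  if (!is.character(label) || length(label) != 1L || is.na(label) || !nzchar(label)) {
    stop("node label must be a non-empty character scalar", call. = FALSE)
  }
  stopifnot(is.list(children))
  structure(list(label = label, children = children), class = "tk_node")
}

#' @export
print.tk_node <- function(x, ...) {
  cat(write_bracketed(x), "\n")
  invisible(x)
}

#' Is a node a leaf?
#' @param node A `tk_node`.
#' @return Logical scalar.
#' @export
is_leaf <- function(node) length(node$children) == 0L

#' Is a node a preterminal?
#'
#' A preterminal has exactly one child and that child is a leaf (a
#' part-of-speech tag directly over a word).
#' @param node A `tk_node`.
#' @return Logical scalar.
#' @export
is_preterminal <- function(node) {
  length(node$children) == 1L && is_leaf(node$children[[1L]])
}

#' Leaves of a tree, left to right
#' @param tree A `tk_node`.
#' @return Character vector of leaf labels in token order.
#' @export
tree_leaves <- function(tree) {
  if (is_leaf(tree)) return(tree$label)
  unlist(lapply(tree$children, tree_leaves), use.names = FALSE)
}

#' Number of internal (non-leaf) nodes
#' @param tree A `tk_node`.
#' @return Integer count.
#' @export
n_internal <- function(tree) {
  if (is_leaf(tree)) return(0L)
  1L + sum(vapply(tree$children, n_internal, integer(1)))
}

#' Serialize a tree to canonical bracketed form
#'
#' Canonical form puts a single space between constituents:
#' `(S (NN dog) (VB runs))`.  A bare leaf serializes to its label.  The
#' output round-trips through [parse_bracketed()].
#'
#' @param tree A `tk_node`.
#' @return Character scalar.
#' @export
write_bracketed <- function(tree) {
  if (is_leaf(tree)) return(tree$label)
  paste0("(", tree$label, " ",
         paste(vapply(tree$children, write_bracketed, character(1)),
               collapse = " "),
         ")")
}

#' Structural equality of trees
#'
#' Trees are equal when labels and ordered child structure agree recursively;
#' implemented by comparing canonical serializations.
#' @param a,b `tk_node` objects.
#' @return Logical scalar.
#' @export
tree_equal <- function(a, b) identical(write_bracketed(a), write_bracketed(b))

#' Parse a Penn-style bracketed tree string
#'
#' Accepts strings like `"(S (NP (NN Presence)) (PP (IN of)))"`.  Whitespace
#' between tokens is insignificant.  Malformed input (unbalanced parentheses,
#' empty labels, trailing text) raises an error naming the 1-based character
#' offset of the problem.
#'
#' @param text Character scalar holding one bracketed tree.
#' @return A `tk_node`.
#' @examples
#' parse_bracketed("(S (NN dog) (VB runs))")
#' @export
parse_bracketed <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  pos <- 1L

  perr <- function(msg, at) {
    stop(sprintf("parse error at offset %d: %s", at, msg), call. = FALSE)
  }
  skip_ws <- function() {
    while (pos <= n && grepl("^[[:space:]]$", chars[pos])) pos <<- pos + 1L
  }
  read_atom <- function() {
    start <- pos
    while (pos <= n && !grepl("^[[:space:]()]$", chars[pos])) pos <<- pos + 1L
    if (pos == start) perr("expected a label", start)
    paste(chars[start:(pos - 1L)], collapse = "")
  }
  read_node <- function() {
    skip_ws()
    if (pos > n) perr("unexpected end of input", n + 1L)
    if (chars[pos] != "(") {
      # bare leaf
      return(tk_node(read_atom()))
    }
    open_at <- pos
    pos <<- pos + 1L
    skip_ws()
    if (pos > n || chars[pos] %in% c("(", ")")) {
      perr("internal node is missing a label", if (pos > n) n + 1L else pos)
    }
    label <- read_atom()
    children <- list()
    repeat {
      skip_ws()
      if (pos > n) perr("unbalanced '(': missing ')'", open_at)
      if (chars[pos] == ")") {
        pos <<- pos + 1L
        break
      }
      children[[length(children) + 1L]] <- read_node()
    }
    if (length(children) == 0L) perr("internal node has no children", open_at)
    tk_node(label, children)
  }

  node <- read_node()
  skip_ws()
  if (pos <= n) perr("trailing text after tree", pos)
  node
}

#' Build a flat (depth-2) sentence tree from tokens and POS tags
#'
#' When no full constituency parse is available, a sentence becomes a root
#' `S` whose i-th child is the preterminal `pos_tags[i]` over the leaf
#' `tokens[i]`.  This is the default linguistic input for the sliding tree
#' kernel when only part-of-speech information is supplied.
#'
#' @param tokens Character vector of words.
#' @param pos_tags Character vector of POS tags, same length as `tokens`.
#' @param root Root label, default `"S"`.
#' @return A `tk_node`.
#' @examples
#' build_flat_tree(c("Presence", "of"), c("NN", "IN"))
#' @export
build_flat_tree <- function(tokens, pos_tags, root = "S") {
  if (length(tokens) == 0L) stop("tokens must be nonempty", call. = FALSE)
  if (length(tokens) != length(pos_tags)) {
    stop("tokens and pos_tags must have equal length", call. = FALSE)
  }
  kids <- mapply(function(w, p) tk_node(p, list(tk_node(w))),
                 tokens, pos_tags, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  tk_node(root, kids)
}

#' Productions of a tree
#'
#' One production per internal node: the parent label together with the full
#' ordered child label sequence.  Returned as the multiset of canonical
#' production strings `"parent -> c1 c2 ..."`.
#'
#' @param tree A `tk_node`.
#' @return Character vector, one entry per internal node.
#' @export
tree_productions <- function(tree) {
  if (is_leaf(tree)) return(character(0))
  own <- paste0(tree$label, " -> ",
                paste(vapply(tree$children, function(ch) ch$label, character(1)),
                      collapse = " "))
  c(own, unlist(lapply(tree$children, tree_productions), use.names = FALSE))
}

# All internal nodes of a tree as a flat list (preorder).
internal_nodes <- function(tree) {
  if (is_leaf(tree)) return(list())
  c(list(tree), unlist(lapply(tree$children, internal_nodes), recursive = FALSE))
}
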