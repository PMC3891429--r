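# Brute-force fragment enumeration.  Exponential in tree size; used as the
# independent oracle against which the dynamic-programming kernel is checked.

# Fragments rooted at one internal node.  A subset-tree (SST) fragment keeps
# the node's full production; each internal child is either cut (it becomes a
# frontier node carrying only its label) or replaced by one of its own rooted
# fragments.  Terminal children are always kept.
rooted_sst_fragments <- function(node) {
  stopifnot(!is_leaf(node))
  per_child <- lapply(node$children, function(ch) {
    if (is_leaf(ch)) return(list(ch))
    c(list(tk_node(ch$label)), rooted_sst_fragments(ch))
  })
  combos <- list(list())
  for (opts in per_child) {
    combos <- unlist(lapply(combos, function(pref) {
      lapply(opts, function(o) c(pref, list(o)))
    }), recursive = FALSE)
  }
  lapply(combos, function(kids) tk_node(node$label, kids))
}

# A subtree (ST) fragment is the node with all of its descendants; exactly
# one per internal node.
rooted_st_fragments <- function(node) {
  stopifnot(!is_leaf(node))
  list(node)
}

#' Enumerate all subset-tree (SST) fragments of a tree
#'
#' An SST fragment is rooted at some internal node and may cut descendants,
#' but every internal node it retains keeps that node's entire production
#' (all children); a cut child survives as a bare frontier node.  The
#' enumeration is exponential and intended for small trees only (roughly up
#' to a dozen internal nodes); it serves as the counting oracle for the
#' kernel.
#'
#' @param tree A `tk_node`.
#' @return List of `tk_node` fragments, deduplicated by canonical
#'   serialization.
#' @examples
#' length(enumerate_sst_fragments(parse_bracketed("(S (NN dog) (VB runs))")))
#' @export
enumerate_sst_fragments <- function(tree) {
  frags <- unlist(lapply(internal_nodes(tree), rooted_sst_fragments),
                  recursive = FALSE)
  keys <- vapply(frags, write_bracketed, character(1))
  frags[!duplicated(keys)]
}

#' Enumerate all subtree (ST) fragments of a tree
#'
#' A subtree fragment consists of a node together with all of its
#' descendants, so there is exactly one fragment per internal node (before
#' deduplication of repeated structure).
#'
#' @param tree A `tk_node`.
#' @return List of `tk_node` fragments, deduplicated by canonical
#'   serialization.
#' @export
enumerate_st_fragments <- function(tree) {
  frags <- internal_nodes(tree)
  keys <- vapply(frags, write_bracketed, character(1))
  frags[!duplicated(keys)]
}

# Oracle for the unnormalized convolution kernel at decay 1: the number of
# common fragments counted per matched node pair, i.e. the sum over all
# pairs (n1 in t1, n2 in t2) of |rooted fragments of n1  ∩  rooted fragments
# of n2| under structural equality.
oracle_common_fragments <- function(t1, t2, mode = c("SST", "ST")) {
  mode <- match.arg(mode)
  rooted <- switch(mode,
                   SST = rooted_sst_fragments,
                   ST  = rooted_st_fragments)
  keysets1 <- lapply(internal_nodes(t1), function(n) {
    unique(vapply(rooted(n), write_bracketed, character(1)))
  })
  keysets2 <- lapply(internal_nodes(t2), function(n) {
    unique(vapply(rooted(n), write_bracketed, character(1)))
  })
  total <- 0L
  for (a in keysets1) {
    for (b in keysets2) {
      total <- total + length(intersect(a, b))
    }
  }
  total
}
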