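# Shared fixtures: the worked example sentence and small random trees.

example_tokens <- function() {
  c("Presence", "of", "beta", "2-M", "was", "analyzed", "by",
    "immunohistochemistry")
}

example_pos <- function() {
  c("NN", "IN", "NN", "NN", "VBD", "VBN", "IN", "NN")
}

example_flat_tree <- function() {
  build_flat_tree(example_tokens(), example_pos())
}

# A plausible constituency parse of the example sentence, used where the
# windowed-fragment structure of a real (non-flat) tree matters.
example_parse <- function() {
  parse_bracketed(paste0(
    "(S (NP (NP (NN Presence)) (PP (IN of) (NP (NN beta) (NN 2-M)))) ",
    "(VP (VBD was) (VP (VBN analyzed) ",
    "(PP (IN by) (NP (NN immunohistochemistry))))))"))
}

# Random labeled tree with a bounded number of internal nodes; the small
# label/word alphabets make cross-tree matches common.
random_tree <- function(max_depth = 3, labels = c("A", "B", "C"),
                        words = c("x", "y", "z")) {
  gen <- function(d) {
    if (d == 0 || stats::runif(1) < 0.35) {
      return(tk_node(sample(labels, 1), list(tk_node(sample(words, 1)))))
    }
    n_children <- sample(1:3, 1)
    tk_node(sample(labels, 1), lapply(seq_len(n_children), function(i) gen(d - 1)))
  }
  gen(max_depth)
}

# Tiny annotated corpus written by hand, exercising all five classes.
tiny_corpus <- function() {
  list(
    tagged_sentence(c("the", "IL2-pa", "receptor", "induced1", "activation2"),
                    c("O", "B-protein", "I-protein", "O", "O"),
                    pos = c("DT", "NNP", "NN", "VBD", "NN")),
    tagged_sentence(c("a", "Dg1-na", "gene", "showed2", "the", "mR2-tb"),
                    c("O", "B-DNA", "I-DNA", "O", "O", "B-RNA"),
                    pos = c("DT", "NNP", "NN", "VBD", "DT", "NNP")),
    tagged_sentence(c("the", "CL4-jd", "line", "of", "Tc1-ca", "cells"),
                    c("O", "B-cell_line", "I-cell_line", "O",
                      "B-cell_type", "I-cell_type"),
                    pos = c("DT", "NNP", "NN", "IN", "NNP", "NN"))
  )
}
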