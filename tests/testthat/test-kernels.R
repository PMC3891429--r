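params_count_sst <- kernel_params(mode = "SST", lambda = 1, normalize = FALSE)
params_count_st <- kernel_params(mode = "ST", lambda = 1, normalize = FALSE)

test_that("delta follows the counting recursion on hand-checked node pairs", {
  dog <- parse_bracketed("(NN dog)")
  cat <- parse_bracketed("(NN cat)")
  s <- parse_bracketed("(S (NN dog) (VB runs))")

  expect_equal(delta(dog, cat, params_count_sst), 0)
  expect_equal(delta(dog, dog, params_count_sst), 1)
  # root pair of identical two-child tree: 1 * (1+1) * (1+1)
  expect_equal(delta(s, s, params_count_sst), 4)
  # ST mode at the same roots: full subtrees must match: 1 * 1 * 1
  expect_equal(delta(s, s, params_count_st), 1)
  # decay scales per fragment node
  expect_equal(delta(dog, dog, kernel_params(lambda = 0.4)), 0.4)
})

test_that("tree kernel counts common fragments and agrees with the R delta sum", {
  s <- parse_bracketed("(S (NN dog) (VB runs))")
  expect_equal(tree_kernel(s, s, params_count_sst), 6)
  expect_equal(tree_kernel(s, s, params_count_st), 3)
  expect_equal(tree_kernel(parse_bracketed("(NN dog)"),
                           parse_bracketed("(VB runs)"), params_count_sst), 0)

  # compiled path equals the plain recursive reference summed over node pairs
  set.seed(21)
  for (i in 1:20) {
    t1 <- random_tree(); t2 <- random_tree()
    for (p in list(params_count_sst, kernel_params(lambda = 0.5, normalize = FALSE))) {
      by_delta <- 0
      for (n1 in sltk:::internal_nodes(t1)) {
        for (n2 in sltk:::internal_nodes(t2)) {
          by_delta <- by_delta + delta(n1, n2, p)
        }
      }
      expect_equal(tree_kernel(t1, t2, p), by_delta, tolerance = 1e-9)
    }
  }
})

test_that("kernel at unit decay equals brute-force common-fragment counts", {
  set.seed(31)
  for (i in 1:60) {
    t1 <- random_tree()
    t2 <- if (i %% 3 == 0) t1 else random_tree()
    expect_equal(tree_kernel(t1, t2, params_count_sst),
                 sltk:::oracle_common_fragments(t1, t2, "SST"))
    expect_equal(tree_kernel(t1, t2, params_count_st),
                 sltk:::oracle_common_fragments(t1, t2, "ST"))
  }
  # identity case ties the kernel to the enumerated fragment set size
  s <- parse_bracketed("(S (NN dog) (VB runs))")
  expect_equal(tree_kernel(s, s, params_count_sst),
               length(enumerate_sst_fragments(s)))
})

test_that("kernel value is nondecreasing in the decay", {
  set.seed(41)
  for (i in 1:10) {
    t1 <- random_tree(); t2 <- random_tree()
    vals <- vapply(c(0.2, 0.5, 0.8, 1), function(l) {
      tree_kernel(t1, t2, kernel_params(lambda = l, normalize = FALSE))
    }, numeric(1))
    expect_true(all(diff(vals) >= -1e-12))
  }
})

test_that("sliding kernel normalizes self-similarity to one and separates centres", {
  frags <- sliding_fragments(example_flat_tree(), 5)
  p <- kernel_params(lambda = 0.4)
  expect_equal(sliding_tree_kernel(frags[[2]], frags[[2]], p), 1)
  k12 <- sliding_tree_kernel(frags[[1]], frags[[2]], p)
  expect_lt(k12, 1)
  expect_gte(k12, 0)

  # disjoint vocabulary and POS: no common production at all
  other <- sliding_fragments(build_flat_tree(c("qq", "zz"), c("XX", "YY")), 5)
  expect_equal(sliding_tree_kernel(frags[[1]], other[[1]], p), 0)
})

test_that("the marker trades word-identity matches for centre-role matches", {
  tr <- example_flat_tree()
  pos <- example_pos()
  p <- kernel_params(lambda = 0.4, normalize = FALSE)
  kern_at <- function(i, j, marker) {
    tree_kernel(extract_sliding_fragment(tr, i, 5, marker_label = marker)$tree,
                extract_sliding_fragment(tr, j, 5, marker_label = marker)$tree,
                p)
  }
  for (i in c(1, 3, 5)) {
    for (j in c(2, 4, 8)) {
      with_m <- kern_at(i, j, "CW")
      no_m <- kern_at(i, j, NULL)
      if (pos[i] != pos[j]) {
        # centres of different POS: the marked productions cannot match, so
        # removing the marker can only add matches back
        expect_gte(no_m + 1e-12, with_m)
      } else {
        # centres of equal POS: the marked preterminals match each other
        # even for different words -- the centre-role match the marker is
        # there to create -- so the gap is at most that one decayed match
        expect_gte(no_m + p$lambda * (1 + p$lambda), with_m)
      }
    }
  }
})

test_that("with no marker and a full-sentence window the kernel is centre-invariant", {
  tr <- example_flat_tree()
  n <- length(tree_leaves(tr))
  s_full <- 2L * n - 1L
  p <- kernel_params(lambda = 0.4, normalize = FALSE)
  frags <- sliding_fragments(tr, s_full, marker_label = NULL)
  ref <- tree_kernel(tr, tr, p)
  for (i in c(1, 4, 8)) {
    for (j in c(2, 5)) {
      expect_equal(tree_kernel(frags[[i]]$tree, frags[[j]]$tree, p), ref)
    }
  }
})

test_that("gram matrices are symmetric, unit-diagonal and PSD", {
  corpus <- generate_corpus(synth_config(n_sentences = 12, seed = 5))
  inst <- sltk:::corpus_instances(corpus, s = 5)
  g <- gram_matrix(inst$fragments, kernel_params(lambda = 0.4))
  K <- g$values
  expect_identical(dim(K), c(length(inst$fragments), length(inst$fragments)))
  expect_lt(max(abs(K - t(K))), 1e-9)
  expect_equal(unname(diag(K)), rep(1, nrow(K)))
  expect_true(all(K >= -1e-12 & K <= 1 + 1e-12))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)

  # single instance
  g1 <- gram_matrix(inst$fragments[1], kernel_params())
  expect_equal(unname(g1$values), matrix(1, 1, 1))
})

test_that("cross gram rows reproduce pairwise sliding kernels", {
  corpus <- generate_corpus(synth_config(n_sentences = 4, seed = 9))
  inst <- sltk:::corpus_instances(corpus, s = 5)
  p <- kernel_params(lambda = 0.4)
  a <- inst$fragments[1:3]
  b <- inst$fragments[4:8]
  K <- cross_gram_matrix(a, b, p)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      expect_equal(K[i, j], sliding_tree_kernel(a[[i]], b[[j]], p),
                   tolerance = 1e-9)
    }
  }
})

test_that("gram matrices round-trip through the tab-separated format", {
  corpus <- generate_corpus(synth_config(n_sentences = 5, seed = 3))
  inst <- sltk:::corpus_instances(corpus, s = 5)
  g <- gram_matrix(inst$fragments, kernel_params())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gram(g, path)
  g2 <- read_gram(path)
  expect_identical(g2$ids, g$ids)
  expect_equal(g2$values, g$values, tolerance = 1e-12)
})
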