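# Block-diagonal Gram matrix: high similarity within a class block, low
# across blocks; separable by construction.
block_gram <- function(sizes, within = 0.8, between = 0.1) {
  n <- sum(sizes)
  K <- matrix(between, n, n)
  at <- 0L
  for (s in sizes) {
    K[at + seq_len(s), at + seq_len(s)] <- within
    at <- at + s
  }
  diag(K) <- 1
  K
}

test_that("one-vs-all training reproduces labels on separable Gram matrices", {
  # 2-instance identity Gram
  m2 <- train_ova(diag(2), c("O", "B-protein"), C = 100)
  expect_identical(predict_labels(m2, diag(2)), c("O", "B-protein"))

  # 20-instance two-block Gram
  K <- block_gram(c(10, 10))
  labels <- rep(c("O", "B-DNA"), each = 10)
  m <- train_ova(K, labels, C = 1)
  expect_identical(predict_labels(m, K), labels)

  # multi-class blocks
  K3 <- block_gram(c(8, 8, 8))
  labels3 <- rep(c("O", "B-DNA", "I-DNA"), each = 8)
  m3 <- train_ova(K3, labels3, C = 1)
  expect_identical(predict_labels(m3, K3), labels3)

  expect_error(train_ova(diag(3), rep("O", 3)), "two distinct labels")
  expect_error(train_ova(diag(3), c("O", "B-DNA"), C = 1), "labels length")
})

test_that("dual solutions are feasible and complementary within tolerance", {
  K <- block_gram(c(12, 12))
  labels <- rep(c("O", "B-RNA"), each = 12)
  C <- 1
  m <- train_ova(K, labels, C = C)
  for (lab in m$label_set) {
    bin <- m$binaries[[lab]]
    y <- ifelse(labels == lab, 1, -1)
    alpha <- abs(bin$coef)
    expect_true(all(alpha >= -1e-8 & alpha <= C + 1e-8))
    # coefficients are alpha_i * y_i
    expect_true(all(sign(bin$coef) == y[bin$support]))
    # KKT: margin support vectors (0 < alpha < C) sit on the margin
    f <- as.numeric(K[, bin$support, drop = FALSE] %*% bin$coef - bin$b)
    on_margin <- bin$support[alpha > 1e-6 & alpha < C - 1e-6]
    if (length(on_margin) > 0) {
      expect_lt(max(abs(y[on_margin] * f[on_margin] - 1)), 1e-3)
    }
  }
})

test_that("prediction is invariant to permuting the training instances", {
  set.seed(17)
  K <- block_gram(c(9, 9, 9), within = 0.7, between = 0.05)
  labels <- rep(c("O", "B-protein", "B-DNA"), each = 9)
  perm <- sample(nrow(K))
  m1 <- train_ova(K, labels, C = 1)
  m2 <- train_ova(K[perm, perm], labels[perm], C = 1)
  test_rows <- block_gram(c(9, 9, 9), within = 0.65, between = 0.08)
  expect_identical(predict_labels(m1, test_rows),
                   predict_labels(m2, test_rows[, perm, drop = FALSE]))
})

test_that("ties break deterministically by label-set order", {
  m <- train_ova(diag(2), c("O", "B-DNA"), C = 1)
  # a zero kernel row scores every label at its negative bias; the winner
  # must be reproducible and first-in-order among exact ties
  z <- matrix(0, 1, 2)
  expect_identical(predict_labels(m, z), predict_labels(m, z))
  scores <- sltk:::ova_scores(m, z)
  best <- max(scores)
  expect_identical(predict_labels(m, z),
                   m$label_set[which(abs(scores - best) < 1e-12)[1L]])
})

test_that("BIO repair rewrites orphan continuations and is idempotent", {
  expect_identical(repair_bio(c("O", "I-DNA")), c("O", "B-DNA"))
  expect_identical(repair_bio(c("B-DNA", "I-protein")),
                   c("B-DNA", "B-protein"))
  valid <- c("B-DNA", "I-DNA", "O", "B-protein")
  expect_identical(repair_bio(valid), valid)
  expect_identical(repair_bio("I-RNA"), "B-RNA")

  set.seed(12)
  labels <- bio_labels()
  for (i in 1:50) {
    seq <- sample(labels, 12, replace = TRUE)
    fixed <- repair_bio(seq)
    expect_identical(repair_bio(fixed), fixed)
    expect_silent(decode_entities(fixed))
  }
  expect_error(repair_bio("I-GENE"), "unknown label")
})

test_that("OVA models survive JSON serialization", {
  K <- block_gram(c(6, 6))
  labels <- rep(c("O", "B-cell_type"), each = 6)
  m <- train_ova(K, labels, C = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_ova(m, path)
  m2 <- read_ova(path)
  expect_identical(m2$label_set, m$label_set)
  expect_equal(m2$C, m$C)
  rows <- block_gram(c(6, 6), within = 0.75)
  expect_identical(predict_labels(m2, rows), predict_labels(m, rows))
})
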