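test_that("BIO files round-trip through read and write", {
  corpus <- tiny_corpus()
  path <- withr::local_tempfile(fileext = ".bio")
  write_bio(corpus, path)
  back <- read_bio(path)
  expect_length(back, length(corpus))
  for (k in seq_along(corpus)) {
    expect_identical(back[[k]]$tokens, corpus[[k]]$tokens)
    expect_identical(back[[k]]$pos, corpus[[k]]$pos)
    expect_identical(back[[k]]$tags, corpus[[k]]$tags)
  }
  # canonical form is byte-stable under a second round trip
  path2 <- withr::local_tempfile(fileext = ".bio")
  write_bio(back, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("two-column files yield no POS and blank lines delimit sentences", {
  path <- withr::local_tempfile(fileext = ".bio")
  writeLines(c("IL-2\tB-protein", "gene\tI-protein", "rose\tO", "",
               "it\tO", "fell\tO"), path)
  corpus <- read_bio(path)
  expect_length(corpus, 2L)
  expect_identical(lengths(lapply(corpus, `[[`, "tokens")), c(3L, 2L))
  expect_identical(corpus[[1]]$tokens[1], "IL-2")
  expect_identical(corpus[[1]]$tags[1], "B-protein")
  expect_null(corpus[[1]]$pos)

  # space-separated variant is tolerated
  path_sp <- withr::local_tempfile(fileext = ".bio")
  writeLines(c("IL-2  B-protein", "rose O"), path_sp)
  expect_identical(read_bio(path_sp)[[1]]$tags, c("B-protein", "O"))
})

test_that("malformed lines and bad tags are reported with their line number", {
  path <- withr::local_tempfile(fileext = ".bio")
  writeLines(c("good\tO", "orphan"), path)
  expect_error(read_bio(path), "line 2")

  writeLines(c("good\tO", "bad\tB-GENE"), path)
  expect_error(read_bio(path), "line 2.*B-GENE")

  writeLines(c("a\tb\tc\td\tO"), path)
  expect_error(read_bio(path), "line 1")

  expect_error(read_bio(file.path(tempdir(), "no-such-file.bio")), "no such file")
})

test_that("empty corpora write empty files and sentences validate their fields", {
  path <- withr::local_tempfile(fileext = ".bio")
  write_bio(list(), path)
  expect_identical(file.size(path), 0)

  expect_error(tagged_sentence(c("a", "b"), "O"), "equal length")
  expect_error(tagged_sentence("a", "B-GENE"), "invalid BIO tag")
  expect_error(tagged_sentence("a", "O", pos = c("NN", "NN")), "match tokens")
  expect_error(tagged_sentence("a", "O", parse = build_flat_tree("b", "NN")),
               "parse leaves")
})

test_that("the command-line driver covers synth, train, predict and evaluate", {
  dir <- withr::local_tempdir()
  corpus_path <- file.path(dir, "train.bio")
  model_path <- file.path(dir, "model.json")
  pred_path <- file.path(dir, "pred.bio")

  suppressMessages(sltk_cli(c("synth", "--out", corpus_path, "--n-sentences", "25",
                              "--seed", "5")))
  expect_true(file.exists(corpus_path))
  corpus <- read_bio(corpus_path)
  expect_length(corpus, 25L)

  suppressMessages(sltk_cli(c("train", "--corpus", corpus_path,
                              "--model", model_path, "--s", "5")))
  expect_true(file.exists(model_path))

  suppressMessages(sltk_cli(c("predict", "--model", model_path,
                              "--corpus", corpus_path, "--out", pred_path)))
  pred <- read_bio(pred_path)
  expect_length(pred, 25L)
  expect_identical(pred[[1]]$tokens, corpus[[1]]$tokens)

  report_path <- file.path(dir, "report.tsv")
  out <- utils::capture.output(suppressMessages(
    sltk_cli(c("evaluate", "--gold", corpus_path, "--pred", pred_path,
               "--out", report_path))))
  expect_true(any(grepl("overall", out)))
  expect_true(file.exists(report_path))

  # a YAML config mirrors the flags; explicit flags take precedence
  config_path <- file.path(dir, "synth.yaml")
  writeLines(c("out: ignored.bio", "n-sentences: 4", "seed: 5"), config_path)
  corpus_small <- suppressMessages(
    sltk_cli(c("synth", "--config", config_path,
               "--out", file.path(dir, "from-config.bio"))))
  expect_length(corpus_small, 4L)
  expect_true(file.exists(file.path(dir, "from-config.bio")))
  expect_false(file.exists(file.path(dir, "ignored.bio")))

  expect_error(sltk_cli(c("nonsense")), "unknown command")
  expect_error(sltk_cli(c("train", "--corpus")), "missing value")
})
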