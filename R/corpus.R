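# JNLPBA-dialect BIO corpus I/O.
#
# Token-per-line files, tab-separated (space-separated accepted on read),
# blank line between sentences.  Two columns are token / tag; three columns
# are token / POS / tag.  Tags follow IOB2 over the five JNLPBA classes.

#' The five JNLPBA entity classes
#' @return Character vector.
#' @export
jnlpba_classes <- function() {
  c("DNA", "RNA", "protein", "cell_line", "cell_type")
}

#' The 11 BIO labels (O plus B-/I- per class)
#' @return Character vector; `"O"` first, then B- labels, then I- labels.
#' @export
bio_labels <- function() {
  cls <- jnlpba_classes()
  c("O", paste0("B-", cls), paste0("I-", cls))
}

#' Construct a tagged sentence
#'
#' @param tokens Character vector of words.
#' @param tags IOB2 tags, same length as `tokens`.
#' @param pos Optional POS tags, same length (or `NULL`).
#' @param parse Optional constituency parse of the sentence (a `tk_node`
#'   whose leaves equal `tokens`); used by the tree kernels instead of the
#'   flat POS tree when present.  Not written by [write_bio()].
#' @return A `tagged_sentence`: list with `tokens`, `pos`, `tags`, `parse`.
#' @export
tagged_sentence <- function(tokens, tags, pos = NULL, parse = NULL) {
  if (length(tokens) != length(tags)) {
    stop("tokens and tags must have equal length", call. = FALSE)
  }
  if (!is.null(pos) && length(pos) != length(tokens)) {
    stop("pos must be NULL or match tokens in length", call. = FALSE)
  }
  bad <- setdiff(unique(tags), bio_labels())
  if (length(bad) > 0L) {
    stop("invalid BIO tag(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(parse)) {
    stopifnot(inherits(parse, "tk_node"))
    if (!identical(tree_leaves(parse), as.character(tokens))) {
      stop("parse leaves do not match tokens", call. = FALSE)
    }
  }
  structure(list(tokens = as.character(tokens),
                 pos = if (is.null(pos)) NULL else as.character(pos),
                 tags = as.character(tags),
                 parse = parse),
            class = "tagged_sentence")
}

#' @export
print.tagged_sentence <- function(x, ...) {
  cat(paste(x$tokens, x$tags, sep = "/", collapse = " "), "\n")
  invisible(x)
}

#' Read a BIO-annotated corpus
#'
#' Lines are `token<TAB>tag` or `token<TAB>pos<TAB>tag` (runs of spaces also
#' accepted as separators); a blank line ends a sentence.  Malformed lines
#' and unknown tag strings raise errors naming the offending line number.
#'
#' @param path File path.
#' @return List of `tagged_sentence` objects.
#' @export
read_bio <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  sentences <- list()
  toks <- character(0); poss <- character(0); tags <- character(0)
  has_pos <- FALSE

  flush_sentence <- function() {
    if (length(toks) == 0L) return()
    sentences[[length(sentences) + 1L]] <<- tagged_sentence(
      toks, tags, pos = if (has_pos) poss else NULL)
    toks <<- character(0); poss <<- character(0); tags <<- character(0)
    has_pos <<- FALSE
  }

  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(trimws(line))) {
      flush_sentence()
      next
    }
    fields <- strsplit(line, "\t| +")[[1L]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 2L || length(fields) > 3L) {
      stop(sprintf("line %d: expected 2 or 3 columns, found %d",
                   ln, length(fields)), call. = FALSE)
    }
    tag <- fields[[length(fields)]]
    if (!tag %in% bio_labels()) {
      stop(sprintf("line %d: invalid BIO tag '%s'", ln, tag), call. = FALSE)
    }
    toks <- c(toks, fields[[1L]])
    tags <- c(tags, tag)
    if (length(fields) == 3L) {
      has_pos <- TRUE
      poss <- c(poss, fields[[2L]])
    } else {
      poss <- c(poss, NA_character_)
    }
  }
  flush_sentence()
  sentences
}

#' Write a BIO-annotated corpus
#'
#' Canonical dialect: tab-separated, UTF-8, Unix newlines, one blank line
#' between sentences.  Reading the output back reproduces the input.
#'
#' @param sentences List of `tagged_sentence` objects.
#' @param path Output file path.
#' @export
write_bio <- function(sentences, path) {
  blocks <- vapply(sentences, function(s) {
    if (is.null(s$pos)) {
      paste(s$tokens, s$tags, sep = "\t", collapse = "\n")
    } else {
      paste(s$tokens, s$pos, s$tags, sep = "\t", collapse = "\n")
    }
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(blocks) > 0L) {
    writeLines(paste(blocks, collapse = "\n\n"), con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

# Sentence tree for kernel instances: the constituency parse when the
# sentence carries one, otherwise a flat POS tree; sentences without POS
# fall back to a single generic preterminal label.
sentence_tree <- function(sentence) {
  if (!is.null(sentence$parse)) return(sentence$parse)
  pos <- sentence$pos
  if (is.null(pos) || anyNA(pos)) pos <- rep("TOK", length(sentence$tokens))
  build_flat_tree(sentence$tokens, pos)
}

# All sliding fragments and token labels of a corpus, flattened in token
# order across sentences.
corpus_instances <- function(sentences, s, marker_label = "CW") {
  frags <- list()
  labels <- character(0)
  for (k in seq_along(sentences)) {
    sent <- sentences[[k]]
    tr <- sentence_tree(sent)
    fs <- sliding_fragments(tr, s, marker_label = marker_label,
                            sentence_id = sprintf("s%d", k))
    frags <- c(frags, fs)
    labels <- c(labels, sent$tags)
  }
  list(fragments = frags, labels = labels)
}
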