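# Entity-level and per-tag precision / recall / F, following the JNLPBA
# 2004 convention: an entity is correct only when class, start and end all
# match exactly.

#' Harmonic-mean F-score from precision and recall (percent)
#'
#' `F = 2 * P * R / (P + R)`, reported to two decimals; 0 when both inputs
#' are zero.
#'
#' @param P,R Precision and recall in percent, `>= 0`.
#' @return F-score in percent, rounded to 2 decimals.
#' @examples
#' fscore(72.63, 51.99)  # 60.60
#' @export
fscore <- function(P, R) {
  if (any(P < 0) || any(R < 0)) stop("P and R must be >= 0", call. = FALSE)
  ifelse(P + R == 0, 0, round(2 * P * R / (P + R), 2))
}

#' Decode entity spans from an IOB2 tag sequence
#'
#' Maximal B-initiated runs of one class become spans.  The sequence must be
#' valid IOB2 (run [repair_bio()] first if it may not be): an `I-X` not
#' preceded by `B-X` or `I-X` is an error.
#'
#' @param tags Character vector of IOB2 tags.
#' @return Data frame with columns `class`, `start`, `end` (1-based,
#'   inclusive), one row per entity.
#' @examples
#' decode_entities(c("B-DNA", "I-DNA", "O"))
#' @export
decode_entities <- function(tags) {
  bad <- setdiff(unique(tags), bio_labels())
  if (length(bad) > 0L) {
    stop("invalid BIO tag(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cls <- character(0); start <- integer(0); end <- integer(0)
  open_class <- NULL; open_start <- NA_integer_
  close_open <- function(i) {
    if (!is.null(open_class)) {
      cls <<- c(cls, open_class)
      start <<- c(start, open_start)
      end <<- c(end, i)
    }
    open_class <<- NULL
  }
  for (i in seq_along(tags)) {
    tag <- tags[[i]]
    if (tag == "O") {
      close_open(i - 1L)
    } else if (startsWith(tag, "B-")) {
      close_open(i - 1L)
      open_class <- substring(tag, 3L)
      open_start <- i
    } else {  # I-
      icls <- substring(tag, 3L)
      if (is.null(open_class) || !identical(open_class, icls)) {
        stop(sprintf("invalid IOB2 at position %d: %s continues no open %s entity",
                     i, tag, icls), call. = FALSE)
      }
    }
  }
  close_open(length(tags))
  data.frame(class = cls, start = start, end = end,
             stringsAsFactors = FALSE)
}

# Spans of a whole corpus, keyed "<sentence>:<class>:<start>:<end>".
corpus_span_keys <- function(sentences) {
  unlist(lapply(seq_along(sentences), function(k) {
    sp <- decode_entities(sentences[[k]]$tags)
    if (nrow(sp) == 0L) return(character(0))
    sprintf("%d:%s:%d:%d", k, sp$class, sp$start, sp$end)
  }), use.names = FALSE)
}

# 0/0 ratios report 0 rather than NaN; callers warn once per report.
prf_from_counts <- function(correct, predicted, gold) {
  P <- if (predicted == 0) 0 else 100 * correct / predicted
  R <- if (gold == 0) 0 else 100 * correct / gold
  c(precision = round(P, 2), recall = round(R, 2), f = fscore(P, R))
}

#' Entity-level precision / recall / F report
#'
#' Exact-match evaluation: a predicted entity counts as correct only when
#' its class, start and end all equal a gold entity's.  Reported per class
#' and micro-averaged overall, in percent.
#'
#' @param gold,pred Aligned lists of `tagged_sentence` (same tokenization;
#'   only the tags may differ).
#' @return An `eval_report`: data frame with columns `class`, `correct`,
#'   `predicted`, `gold`, `precision`, `recall`, `f`; the `overall` row is
#'   the micro-average.
#' @export
entity_prf <- function(gold, pred) {
  if (length(gold) != length(pred)) {
    stop("gold and pred have different sentence counts", call. = FALSE)
  }
  for (k in seq_along(gold)) {
    if (!identical(gold[[k]]$tokens, pred[[k]]$tokens)) {
      stop(sprintf("token mismatch in sentence %d", k), call. = FALSE)
    }
  }
  gk <- corpus_span_keys(gold)
  pk <- corpus_span_keys(pred)
  if (length(pk) == 0L && length(gk) > 0L) {
    warning("no predicted spans; precision reported as 0", call. = FALSE)
  }
  span_class <- function(keys) sub("^[0-9]+:([^:]+):.*$", "\\1", keys)

  rows <- lapply(c(jnlpba_classes(), "overall"), function(cl) {
    g <- if (cl == "overall") gk else gk[span_class(gk) == cl]
    p <- if (cl == "overall") pk else pk[span_class(pk) == cl]
    correct <- length(intersect(g, p))
    stats <- prf_from_counts(correct, length(p), length(g))
    data.frame(class = cl, correct = correct, predicted = length(p),
               gold = length(g), precision = stats[["precision"]],
               recall = stats[["recall"]], f = stats[["f"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("eval_report", class(out))
  out
}

#' Token-level precision / recall / F for a single tag
#'
#' Treats one BIO label (e.g. `"B-DNA"`) as the positive class and scores
#' per-token predictions against gold.
#'
#' @param gold,pred Aligned lists of `tagged_sentence`.
#' @param tag The label scored as positive; must be one of [bio_labels()].
#' @return Named numeric vector `c(precision, recall, f)` in percent.
#' @export
tag_prf <- function(gold, pred, tag) {
  if (!tag %in% bio_labels()) stop("unknown tag: ", tag, call. = FALSE)
  if (length(gold) != length(pred)) {
    stop("gold and pred have different sentence counts", call. = FALSE)
  }
  g <- unlist(lapply(gold, `[[`, "tags"), use.names = FALSE)
  p <- unlist(lapply(pred, `[[`, "tags"), use.names = FALSE)
  if (length(g) != length(p)) stop("token mismatch between corpora", call. = FALSE)
  correct <- sum(g == tag & p == tag)
  if (sum(p == tag) == 0L && sum(g == tag) > 0L) {
    warning("tag never predicted; precision reported as 0", call. = FALSE)
  }
  prf_from_counts(correct, sum(p == tag), sum(g == tag))
}

#' Format an evaluation report as an aligned text table
#' @param report An `eval_report` from [entity_prf()].
#' @return Character vector of report lines.
#' @export
format_eval_report <- function(report) {
  hdr <- sprintf("%-10s %8s %9s %6s %10s %8s %8s",
                 "class", "correct", "predicted", "gold",
                 "precision", "recall", "F")
  rows <- vapply(seq_len(nrow(report)), function(i) {
    sprintf("%-10s %8d %9d %6d %10.2f %8.2f %8.2f",
            report$class[i], report$correct[i], report$predicted[i],
            report$gold[i], report$precision[i], report$recall[i],
            report$f[i])
  }, character(1))
  c(hdr, rows)
}

#' Write an evaluation report as key-value pairs
#'
#' Machine-readable companion to [format_eval_report()]: lines of
#' `class.metric<TAB>value`.
#'
#' @param report An `eval_report`.
#' @param path Output file path.
#' @export
write_eval_report <- function(report, path) {
  lines <- unlist(lapply(seq_len(nrow(report)), function(i) {
    sprintf("%s.%s\t%s", report$class[i],
            c("correct", "predicted", "gold", "precision", "recall", "f"),
            c(report$correct[i], report$predicted[i], report$gold[i],
              report$precision[i], report$recall[i], report$f[i]))
  }))
  writeLines(lines, path)
  invisible(path)
}
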