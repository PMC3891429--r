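# Seeded generator of JNLPBA-like annotated corpora.
#
# Sentences come from a small closed grammar (NP VP with optional PPs) over
# a fixed POS tagset.  Noun slots are filled either by entity mentions of
# one of the five JNLPBA classes or by ordinary nouns.  An entity mention
# mirrors the characteristic shape of biomedical names: a proper-name token
# (alphanumeric-with-hyphen forms such as "IL2-pa"), optionally closed by a
# class head noun ("gene", "mRNA", "cells", ...).  Each entity token is drawn from its intended class lexicon with
# probability cue_strength and otherwise from a shared noise lexicon, so
# classifiers can recover the labeling when the cue is strong and must cope
# with ambiguity when it is not.

#' Class-specific, noise and ordinary-word lexicons of the generator
#'
#' Fixed (seed-independent) lexicons per entity class: 12 proper-name
#' surface forms with class-distinct alphanumeric-hyphen shapes plus three
#' class head nouns that close multi-token mentions (the way JNLPBA
#' mentions characteristically end in "gene", "mRNA", "cells", ...).  A
#' shared 24-form noise lexicon supplies tokens that may appear inside
#' entities of any class and occasionally as plain nouns.  Small
#' ordinary-word lists drive the surrounding grammar.
#'
#' @return Named list with, per entity class, `<class>` (name forms) and
#'   `<class>_head` (head nouns), plus `noise`, `common`, `adjectives`,
#'   `verbs`, `determiners`, `prepositions`.
#' @export
sl_lexicons <- function() {
  idx <- seq_len(12L)
  nidx <- seq_len(24L)
  tail_letter <- letters[(idx - 1L) %% 26L + 1L]
  list(
    DNA       = sprintf("Dg%d-n%s", idx, tail_letter),
    RNA       = sprintf("mR%d-t%s", idx, tail_letter),
    protein   = sprintf("IL%d-p%s", idx, tail_letter),
    cell_line = sprintf("CL%d-j%s", idx, tail_letter),
    cell_type = sprintf("Tc%d-c%s", idx, tail_letter),
    DNA_head       = c("gene", "promoter", "enhancer"),
    RNA_head       = c("mRNA", "transcript", "rRNA"),
    protein_head   = c("protein", "receptor", "kinase"),
    cell_line_head = c("line", "clone", "hybridoma"),
    cell_type_head = c("cells", "lymphocytes", "monocytes"),
    noise     = sprintf("x%d-q%s", nidx, letters[(nidx - 1L) %% 26L + 1L]),
    # Open-class vocabulary is kept deliberately large (as in real text) so
    # that chance lexical overlap between token windows stays low and the
    # closed-class entity lexicons dominate repeated word matches.
    common    = paste0(rep(c("presence", "expression", "analysis",
                             "activation", "level", "response", "binding",
                             "induction", "pathway", "sample", "culture",
                             "assay", "method", "result", "sequence",
                             "effect", "role", "study", "increase",
                             "factor"), each = 8L), rep(1:8, times = 20L)),
    adjectives = paste0(rep(c("human", "nuclear", "specific", "normal",
                              "acute", "cellular", "early", "functional",
                              "distinct", "novel"), each = 6L),
                        rep(1:6, times = 10L)),
    verbs = paste0(rep(c("analyzed", "induced", "expressed", "activated",
                         "inhibited", "showed", "regulated", "suppressed",
                         "mediated", "detected"), each = 6L),
                   rep(1:6, times = 10L)),
    determiners = c("the", "a", "this"),
    prepositions = c("of", "in", "by", "with", "from")
  )
}

#' Synthetic-corpus configuration
#'
#' @param n_sentences Number of sentences, `>= 1`.
#' @param mean_length Approximate mean sentence length in tokens (the
#'   grammar appends prepositional phrases until a Poisson-drawn target is
#'   reached).  Default 6: short declarative sentences, so that a
#'   sliding window of the default width spans most of a sentence.
#' @param entity_rate Probability that a noun slot is an entity mention.
#'   Default 0.4, echoing the high mention density of biomedical abstracts.
#' @param cue_strength Probability that an entity token comes from its
#'   class-specific lexicon rather than the shared noise lexicon.  Default
#'   0.9.
#' @param multi_token_rate Probability that an entity spans two tokens
#'   (modifier + head) rather than one.  Default 0.5: multi-token mentions
#'   are about as common as single-token ones in biomedical corpora.
#' @param seed RNG seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_sentences = 100, mean_length = 6,
                         entity_rate = 0.4, cue_strength = 0.9,
                         multi_token_rate = 0.5, seed = 1) {
  probs <- c(entity_rate, cue_strength, multi_token_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("entity_rate, cue_strength and multi_token_rate must lie in [0, 1]",
         call. = FALSE)
  }
  if (n_sentences < 1) stop("n_sentences must be >= 1", call. = FALSE)
  structure(list(n_sentences = as.integer(n_sentences),
                 mean_length = mean_length, entity_rate = entity_rate,
                 cue_strength = cue_strength,
                 multi_token_rate = multi_token_rate,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# One noun slot: an entity mention or an ordinary noun.  Each mention
# token independently keeps its intended lexicon with probability
# cue_strength and is otherwise replaced by a shared-noise form.
gen_noun_slot <- function(config, lex) {
  if (stats::runif(1) < config$entity_rate) {
    cls <- sample(jnlpba_classes(), 1L)
    len <- if (stats::runif(1) < config$multi_token_rate) 2L else 1L
    # a mention is a proper-name token ("IL2-pa"), optionally closed by a
    # class head noun ("IL2-pa receptor"); bare head nouns are not mentions
    pools <- c(list(lex[[cls]]),
               if (len == 2L) list(lex[[paste0(cls, "_head")]]))
    toks <- vapply(pools, function(pool) {
      if (stats::runif(1) < config$cue_strength) sample(pool, 1L) else sample(lex$noise, 1L)
    }, character(1))
    list(tokens = toks, pos = c("NNP", rep("NN", len - 1L)),
         tags = c(paste0("B-", cls), rep(paste0("I-", cls), len - 1L)))
  } else {
    tok <- if (stats::runif(1) < 0.2) sample(lex$noise, 1L) else sample(lex$common, 1L)
    list(tokens = tok, pos = "NN", tags = "O")
  }
}

# Chunks carry their constituency subtree so the corpus can ship parses:
# each chunk is list(tokens, pos, tags, tree).
chunk_preterminals <- function(tokens, pos) {
  mapply(function(w, p) tk_node(p, list(tk_node(w))), tokens, pos,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

gen_np <- function(config, lex) {
  toks <- sample(lex$determiners, 1L); pos <- "DT"; tags <- "O"
  slot <- gen_noun_slot(config, lex)
  toks <- c(toks, slot$tokens); pos <- c(pos, slot$pos); tags <- c(tags, slot$tags)
  list(tokens = toks, pos = pos, tags = tags,
       tree = tk_node("NP", chunk_preterminals(toks, pos)))
}

# Prepositional adjunct as two sibling chunks (IN preterminal + NP), the
# way a shallow chunker would segment it.
gen_pp <- function(config, lex) {
  prep <- sample(lex$prepositions, 1L)
  np <- gen_np(config, lex)
  list(tokens = c(prep, np$tokens), pos = c("IN", np$pos),
       tags = c("O", np$tags),
       trees = c(list(tk_node("IN", list(tk_node(prep)))), list(np$tree)))
}

gen_sentence <- function(config, lex) {
  target <- max(4L, stats::rpois(1L, config$mean_length))
  subj <- gen_np(config, lex)
  verb <- sample(lex$verbs, 1L)
  obj <- gen_np(config, lex)
  pps <- list()
  repeat {
    n <- length(subj$tokens) + 1L + length(obj$tokens) +
      sum(vapply(pps, function(p) length(p$tokens), integer(1)))
    if (n >= target) break
    pps[[length(pps) + 1L]] <- gen_pp(config, lex)
  }
  # shallow chunk parse: sentence node directly over NP chunks and the
  # verb/preposition preterminals, as a chunker would produce
  parse <- tk_node("S", c(list(subj$tree,
                               tk_node("VBD", list(tk_node(verb))),
                               obj$tree),
                          unlist(lapply(pps, `[[`, "trees"),
                                 recursive = FALSE)))
  parts <- c(list(subj, list(tokens = verb, pos = "VBD", tags = "O"), obj), pps)
  tagged_sentence(
    tokens = unlist(lapply(parts, `[[`, "tokens"), use.names = FALSE),
    tags = unlist(lapply(parts, `[[`, "tags"), use.names = FALSE),
    pos = unlist(lapply(parts, `[[`, "pos"), use.names = FALSE),
    parse = parse)
}

#' Generate a synthetic JNLPBA-like corpus
#'
#' Deterministic for a fixed seed; the caller's RNG state is left
#' untouched.
#'
#' @param config A [synth_config()].
#' @return List of `tagged_sentence` objects with POS tags.
#' @examples
#' corpus <- generate_corpus(synth_config(n_sentences = 3, seed = 7))
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  lex <- sl_lexicons()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(config$seed)
  lapply(seq_len(config$n_sentences), function(k) gen_sentence(config, lex))
}

#' Empirical entity rate over the noun slots of a corpus
#'
#' Noun slots are the positions the generator fills with either an entity
#' mention or an ordinary noun: entity mentions (counted once per entity)
#' plus O-tagged tokens with POS `NN`.
#'
#' @param sentences List of `tagged_sentence` with POS.
#' @return List with `entities`, `slots`, `rate`.
#' @export
entity_slot_rate <- function(sentences) {
  n_entities <- sum(vapply(sentences, function(s) {
    sum(startsWith(s$tags, "B-"))
  }, numeric(1)))
  n_plain <- sum(vapply(sentences, function(s) {
    sum(s$tags == "O" & s$pos == "NN")
  }, numeric(1)))
  slots <- n_entities + n_plain
  list(entities = n_entities, slots = slots,
       rate = if (slots == 0) NA_real_ else n_entities / slots)
}
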