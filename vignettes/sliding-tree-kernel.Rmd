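---
title: "The sliding tree kernel: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sliding tree kernel: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sltk)
```

## The problem

Biomedical named entity recognition (NER) assigns each token of a text a
BIO label over five entity classes — DNA, RNA, protein, cell line, cell
type — so that maximal `B-X I-X ...` runs form entity mentions.  Support
vector machines are a standard classifier for the task, but the
conventional convolution tree kernel compares *whole sentence* parse
trees: every token of a sentence would receive the same representation, so
per-token classification is impossible and consecutive tokens flood the
feature space with near-duplicate fragments.

The sliding tree kernel solves this with two moves:

1. **Windowing.** For each token, the sentence tree is pruned to the
   leaves inside a window of odd width $s$ centred on that token
   (truncated, not padded, at sentence edges).  Internal nodes that no
   longer dominate a surviving leaf are removed; ancestors of survivors
   are kept up to the root, with unary chains left uncollapsed so no
   production is invented.
2. **Marking.** A marker node (label `CW`, *current word*) is inserted
   between the focus token's preterminal and its leaf, giving the path
   POS → CW → word.  Fragments centred on different tokens of one
   sentence are therefore structurally distinct even when their windows
   coincide.

Two windowed, marked fragments are compared with a subset-tree (SST)
convolution kernel, and the resulting Gram matrix feeds a one-vs-all
soft-margin SVM over the 11 BIO labels.

## The kernel

For internal nodes $n_1, n_2$ the package computes the classic
node-pair recursion

$$
\Delta(n_1, n_2) =
\begin{cases}
0 & \text{productions differ} \\
\lambda & \text{matching preterminals} \\
\lambda \prod_j \bigl(1 + \Delta(c_{1j}, c_{2j})\bigr) & \text{SST mode} \\
\lambda \prod_j \Delta(c_{1j}, c_{2j}) & \text{ST mode,}
\end{cases}
$$

and the kernel is $K(t_1, t_2) = \sum_{n_1 \in t_1} \sum_{n_2 \in t_2}
\Delta(n_1, n_2)$.  A production here includes the parent label, the
ordered child labels, and which children are leaves; that last flag keeps
a frontier nonterminal from ever aliasing a preterminal.  In SST mode a
counted fragment may cut descendants but keeps every retained node's full
production; in ST mode only whole descendant subtrees match.  With
$\lambda = 1$ the kernel is an exact count of common fragments, which is
what the brute-force enumeration oracle (`enumerate_sst_fragments()`,
`enumerate_st_fragments()`) verifies on small random trees.  The
recursion is memoized per node pair and implemented in C++; Gram assembly
computes the upper triangle only.

```{r kernel-example}
t <- parse_bracketed("(S (NN dog) (VB runs))")
tree_kernel(t, t, kernel_params(mode = "SST", lambda = 1, normalize = FALSE))
length(enumerate_sst_fragments(t))
```

### Parameters

* **`s`** (window width, tokens; odd; default 7): how much sentence
  context each per-token fragment keeps.  Small values isolate the focus
  word; large values approach whole-sentence comparison and reintroduce
  the redundancy the kernel exists to remove.
* **`lambda`** (decay in $(0, 1]$; default 0.4): downweights large
  fragments by one factor per fragment node.  At 1 the kernel is a pure
  count; the source method leaves the decay unstated, so it is exposed as
  a parameter, with 0.4 as a conventional middle value for
  production-based tree kernels.
* **`normalize`** (default `TRUE`): cosine normalization
  $K/\sqrt{K_{11} K_{22}}$, making self-similarity exactly 1, as required
  for dot-product kernel spaces.
* **`marker_label`** (default `"CW"`; `NULL` disables): the marker makes
  same-sentence fragments distinct.  Note an intended side effect: the
  marked preterminals of two centres with equal POS match *as centre
  roles* even when the centre words differ, so the marker can add matches
  as well as remove them.
* **`C`** (default 1): the soft-margin trade-off of each binary SVM.

### Numerical choices

Floating comparisons use a $10^{-9}$ relative tolerance; Gram matrices
are checked positive semidefinite to $-10^{-8}$ (a failed Cholesky with a
small ridge triggers an eigenvalue-sized jitter plus a warning); a
degenerate fragment with zero self-kernel is a contract error rather than
a silent 0/0; OVA ties break deterministically by label order (`O` first,
then B- then I- labels in the fixed class order).  The binary dual
problems are solved by kernlab's SMO through its precomputed-kernel
interface; the package stores support indices, oriented dual
coefficients and biases, and applies its own decision function, so a
saved model needs only the training fragments and the duals.

## Tagger assembly

Instances are built one per token.  With a constituency parse attached to
a sentence the kernels use it; otherwise the sentence becomes a flat
depth-2 tree `(S (POS token) ...)`, which is the default when the only
linguistic input is part-of-speech tags.  Predicted label sequences are
repaired into valid IOB2 (`I-X` with no open `X` becomes `B-X`), and
entities are scored by exact (class, start, end) matching with
micro-averaged precision, recall and $F = 2PR/(P+R)$, reported in percent
to two decimals.  The linear baseline uses binary word-window indicator
features $(\text{offset}, \text{word})$ with a dot-product kernel,
computed as a sparse cross-product.

## The synthetic corpus generator

Shared-task NER corpora cannot be redistributed with a package, so every
stage is exercised against a seeded generator (`synth_config()`,
`generate_corpus()`) that emulates the *shape* of a JNLPBA-style corpus:
POS-tagged sentences, five classes, IOB2 tags.  Design choices, each of
which was genuinely open:

* **Mentions look like biomedical names.** An entity is a proper-name
  token with a class-distinct alphanumeric-hyphen shape (`IL7-pa`),
  optionally closed by a class head noun (`gene`, `mRNA`, `protein`,
  `cells`, ...), mirroring how real mentions characteristically end in a
  head noun.  Name tokens are tagged `NNP`, head nouns `NN`.  With
  probability `1 - cue_strength` an entity token is replaced by a form
  from a shared noise lexicon, which also occasionally appears as an
  ordinary noun — this is the controllable ambiguity knob: at
  `cue_strength = 1` and single-token mentions, class membership is
  decidable by lexicon lookup alone.
* **Closed entity lexicons, open everything else.** Class lexicons are
  small (12 name forms and 3 head nouns per class) so a few hundred
  training sentences cover them, while ordinary nouns, verbs and
  adjectives come from deliberately large vocabularies.  Repeated word
  matches between token windows are then dominated by entity vocabulary,
  as in real text where the open classes are effectively unbounded.
* **Shallow chunk parses.** The generator knows its own derivation and
  attaches a chunk tree (`S` directly over `NP` chunks and verb or
  preposition preterminals).  Local NP productions such as
  `NP -> DT NNP NN` versus `NP -> DT NN` are what let a production-based
  kernel see the boundary structure of a mention without relying on
  whole-sentence pattern matches.  Corpora written to BIO files lose the
  parse and fall back to flat trees.
* **Short, dense sentences.** Defaults: `mean_length = 6` tokens,
  `entity_rate = 0.4` per noun slot, `multi_token_rate = 0.5`.  Density
  echoes biomedical abstracts; the short sentences put the default
  window (`s = 7`) in the regime where it spans most of a sentence, so
  the current-word marker carries the largest share of each fragment's
  structure.  That is the regime in which per-token instances of one
  sentence stay distinguishable at the fixed soft-margin operating point
  (`C = 1`) — with long sentences the 11-label problem remains separable
  in the kernel space but needs a larger `C` to fit, which is a property
  of the operating point, not of the kernel.

What passing tests on this corpus do **not** show: robustness to real
tokenization noise, unseen-word generalization beyond the noise lexicon,
long-range context, nested or discontinuous mentions, or anything about
absolute shared-task scores — real corpora are larger, noisier and far
less separable (published F-scores on the real task are near 60%, not
90%).  The generator's role is to verify the machinery end to end under
conditions where recovery is provably possible.

For test-suite problem sizes the package uses 300 training and 100 test
sentences (about 2,000 training instances) for end-to-end checks, 200
random trees of at most 10 internal nodes for kernel-oracle equivalence,
and 100-instance batches for Gram-matrix property checks.

## Known limitations

* Per-token classification with post-hoc BIO repair — no sequence model,
  so label interactions beyond the window are invisible.
* One-vs-all scores are uncalibrated across binaries; with strongly
  unbalanced label masses the majority class is favoured near ties.
* The partial-tree (PT) fragment space is deliberately not implemented.
* `read_bio()` accepts only the two- and three-column token-per-line
  dialect; parses must be supplied programmatically.
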