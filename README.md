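# sltk — a sliding tree kernel for biomedical named entity recognition

`sltk` implements a complete SVM-based BIO tagger for biomedical named
entity recognition (NER) built around the **sliding tree kernel**: a
subset-tree convolution kernel computed not between whole sentence parse
trees but between per-token *windowed* tree fragments, each augmented
with a current-word marker node.  It is aimed at researchers studying
kernel methods for sequence labeling who need oracle-verified kernel
math, JNLPBA-dialect corpus I/O, entity-level evaluation and a seeded
synthetic corpus generator in one package.

## The method

Conventional tree kernels measure the similarity of two trees by the
(decayed) number of common fragments, via the node-pair recursion

    Δ(n1, n2) = 0                                if productions differ
              = λ                                if matching preterminals
              = λ · Π_j (1 + Δ(c1j, c2j))        (SST mode)
              = λ · Π_j Δ(c1j, c2j)              (ST mode)

    K(t1, t2) = Σ_{n1 ∈ t1} Σ_{n2 ∈ t2} Δ(n1, n2)

Because the kernel compares sentences, it cannot label individual
tokens.  The sliding tree kernel turns it into a per-token kernel: for
token *i* the sentence tree is pruned to a window of `s` tokens centred
on *i* (truncated at sentence edges), and a marker node `CW` is inserted
between the focus token's preterminal and its leaf (POS → CW → word).
Fragments of different centres are structurally distinct, so `K` compares
*words in context* and a one-vs-all soft-margin SVM over the precomputed
Gram matrix performs the full 11-label BIO task — entity identification
and boundary detection at once.  Kernel values are cosine-normalized
(`K/√(K11·K22)`), the recursion is memoized in compiled code, and with
`λ = 1` the kernel equals a brute-force count of common fragments, which
the package's enumeration oracles verify.

## Worked example

```r
library(sltk)

# kernel arithmetic: at lambda = 1 the kernel counts common fragments
t <- parse_bracketed("(S (NN dog) (VB runs))")
tree_kernel(t, t, kernel_params(mode = "SST", lambda = 1, normalize = FALSE))
#> [1] 6            # = length(enumerate_sst_fragments(t))

# the per-token instance: window of 5 around "of", marker on the focus word
tr <- build_flat_tree(
  c("Presence", "of", "beta", "2-M", "was", "analyzed", "by",
    "immunohistochemistry"),
  c("NN", "IN", "NN", "NN", "VBD", "VBN", "IN", "NN"))
extract_sliding_fragment(tr, 2, 5)
#> <sl_fragment center=2 s=5> (S (NN Presence) (IN (CW of)) (NN beta) (NN 2-M))

# end-to-end on a synthetic JNLPBA-like corpus
train <- generate_corpus(synth_config(n_sentences = 300, cue_strength = 0.95,
                                      seed = 1))
test  <- generate_corpus(synth_config(n_sentences = 100, cue_strength = 0.95,
                                      seed = 2))
model <- train_tagger(train, kernel = "sliding-sst", s = 7, lambda = 0.4, C = 1)
pred  <- predict_tagger(model, test)
writeLines(format_eval_report(entity_prf(test, pred)))
#> class       correct predicted   gold  precision   recall        F
#> DNA              22        23     24      95.65    91.67    93.62
#> RNA              20        23     22      86.96    90.91    88.89
#> protein          22        23     24      95.65    91.67    93.62
#> cell_line        13        15     14      86.67    92.86    89.66
#> cell_type        36        39     38      92.31    94.74    93.51
#> overall         113       123    122      91.87    92.62    92.24
```

The report counts exactly matched (class, start, end) spans: precision
is correct/predicted, recall is correct/gold, and F is their harmonic
mean in percent.  On this strongly-cued synthetic corpus the sliding
kernel recovers over 90% of mentions; replacing the windowed, marked
fragments with whole-sentence trees and no marker collapses performance
to zero, because every token of a sentence then has an identical
representation.

A command-line driver wraps the same functions:

```sh
Rscript inst/cli/sltk.R synth --out train.bio --n 300 --seed 1
Rscript inst/cli/sltk.R train --corpus train.bio --model model.json --s 7
Rscript inst/cli/sltk.R predict --model model.json --corpus test.bio --out pred.bio
Rscript inst/cli/sltk.R evaluate --gold test.bio --pred pred.bio
Rscript inst/cli/sltk.R sweep --train train.bio --test test.bio --out sweep.tsv
```

(after installation, the script lives at `system.file("cli", "sltk.R",
package = "sltk")`).

## Package layout

| Where | What |
|---|---|
| `R/tree.R`, `R/oracle.R` | tree structures, bracketed parsing, fragment enumeration oracles |
| `R/sliding.R` | windowed, marker-augmented fragment extraction |
| `R/kernels.R`, `src/kernels.cpp` | ST/SST delta recursion, sliding kernel, Gram assembly |
| `R/features.R` | binary word-window features and their linear kernel |
| `R/classifier.R` | one-vs-all SVM over precomputed kernels, BIO repair |
| `R/corpus.R`, `R/evaluation.R` | JNLPBA-dialect I/O, entity-level scoring |
| `R/synthetic.R` | seeded JNLPBA-like corpus generator |
| `vignettes/sliding-tree-kernel.Rmd` | methods, parameter and design notes |
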