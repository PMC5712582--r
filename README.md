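# ccrel — cell–cytokine relation extraction and knowledge graphs

`ccrel` builds an evidence-backed knowledge graph of cell–cytokine
relations from biomedical abstracts. It is aimed at immunology text-mining:
given a corpus of abstracts, a cell lexicon (from an OBO ontology), a
cytokine synonym registry and a reference relation database, it

1. recognizes cell and cytokine mentions by exact, token-boundary-aligned
   dictionary matching (with plural expansion and common-English-word
   filtering of ambiguous synonyms),
2. pairs mentions within sentences and groups all sentence-level
   co-occurrences of a pair into a *bag*,
3. labels bags by **distant supervision** (positive iff the pair exists in
   the reference database) and trains a **sparse multi-instance (sMIL)**
   linear max-margin classifier over tf-idf context features,
4. emits an undirected bipartite graph whose edges carry a calibrated
   confidence, a pair frequency, and the supporting (pmid, sentence)
   evidence, plus cross-validation, graph-comparison and manual-curation
   tooling.

The core statistic is the sMIL program: negative bags contribute one margin
constraint per instance (`w·x + b ≤ −1 + ξ`), while each positive bag `B`
is represented by its mean instance vector with the relaxed margin

```
w·φ̄(B) + b ≥ (2 − |B|)/|B| − ξ_B,   φ̄(B) = (Σ_{x∈B} x)/|B|
```

so a singleton positive bag must clear the full margin (the program is then
exactly a soft-margin SVM) and larger, more diluted bags clear progressively
weaker ones. The dual is solved by a deterministic SMO loop verified against
a generic interior-point QP solver; bag scores are mapped to `[0, 1]` by a
monotone logistic calibration. The competing baseline ranking is the **pair
frequency**: supporting abstracts over corpus size.

A seedable synthetic-corpus generator with planted relations, synonym
variants, sparse relational sentences and Zipf-weighted co-occurrence noise
makes the whole pipeline testable offline.

## Worked example

```r
library(ccrel)

bundle   <- synth_generate(synth_config(seed = 42))   # corpus + lexicons + noisy db + truth
cells    <- expand_plurals(bundle$cells)
mentions <- annotate_corpus(bundle$corpus, cells, bundle$cytokines)

cv <- cross_validate(bundle$corpus, mentions, bundle$db, k = 5, seed = 42)
cv
#> 5-fold document-level cross-validation (500 documents, 597 scored bags)
#>   pooled AUC-PR: confidence 0.650, pair frequency 0.225
#>   best F1 (confidence): 0.705 at threshold 0.062 (P 0.802, R 0.630)

fit    <- train_pair_classifier(bundle$corpus, mentions, bundle$db)
scores <- score_bags(fit, bundle$corpus, mentions)
g      <- build_graph(scores, bundle$corpus,
                      best_f_threshold(cv$curves$confidence)$threshold)
g
#> <knowledge graph> 20 cells + 20 cytokines, 277 edges

score_recovery(g, bundle$truth, scores)
#> $precision ... 0.181
#> $recall    ... 1
#> $auc_confidence ... 0.920
#> $auc_frequency  ... 0.378
```

Reading the numbers: the distant-supervision classifier ranks pairs far
better than raw co-occurrence frequency (pooled cross-validated AUC-PR 0.650
vs 0.225; 0.920 vs 0.378 against the planted ground truth), and at the
cross-validated best-F threshold the graph recovers every planted relation
(recall 1.0), including the 20% of relations deliberately withheld from the
reference database. The low edge precision at that recall-heavy threshold
reflects the threshold chosen by pooled cross-validation, which transfers
conservatively to the final model; raising the threshold trades recall for
precision along the reported curve. `head(g$edges)` shows per-edge
confidence, frequency and sentence counts; `export_graph(g, "out/")` writes
`edges.tsv`, `evidence.tsv` and GraphML.

One-call variant: `run_pipeline(pipeline_config(corpus, cells, cytokines,
db, out_dir))` runs annotate → pairs → cross-validate → train → graph →
export with a reproducibility manifest; `inst/scripts/ccrel.R` wraps the
same stages as a small command line (`simulate`, `annotate`, `eval`, `run`,
`fetch`).

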