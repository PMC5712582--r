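---
title: "Mining cell-cytokine relations from abstracts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining cell-cytokine relations from abstracts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccrel)
```

## The problem

Immunology abstracts describe, in free text, which cell types produce,
respond to, or are regulated by which cytokines. `ccrel` turns a corpus of
abstracts into an undirected bipartite knowledge graph whose edges are
cell-cytokine relations, each backed by the sentences it was extracted from,
a classifier confidence and a corpus frequency. No sentence-level manual
annotation is required: supervision comes "distantly" from a reference
relation database, under the assumption that a sentence mentioning both
members of a known pair tends to express their relation.

The pipeline has four stages:

1. **Dictionary NER.** Cell and cytokine lexicons (ontology labels plus
   synonyms, each mapped to one canonical name) are matched exactly,
   case-insensitively, at token boundaries. Plural variants of cell names are
   added so "dendritic cells" normalizes to the *dendritic cell* concept, and
   ambiguous single-token synonyms that are ordinary English words ("light",
   "killer") are removed from the cytokine lexicon.
2. **Pairing.** Within each sentence, every cell mention is paired with every
   cytokine mention (an *instance*). All instances of one (cell, cytokine)
   pair across the corpus form a *bag*, labeled positive exactly when the
   pair exists in the reference database.
3. **Classification.** Each instance is represented by tf-idf-weighted
   lemmas from a +/-3-token window around each entity; the sparse
   multi-instance (sMIL) linear classifier scores bags, and a logistic
   calibration maps the hyperplane distance to a confidence in [0, 1]. The
   *pair frequency* (supporting abstracts / corpus size) is the non-learning
   baseline ranking.
4. **Graph.** Bags above a confidence threshold become edges; tooling covers
   graph statistics, novelty comparison against a reference graph,
   evidence-backed exports, and curation sampling with Fleiss' kappa.

## The sMIL objective

Distant supervision yields skewed, weak labels: a negative bag contains only
negative instances, while a positive bag guarantees just one positive
instance among many. sMIL encodes this asymmetry in a max-margin program.
With negative instances $x$ and positive bags $B$ with mean vector
$\bar\phi(B)$:

$$
\min_{w, b, \xi \ge 0} \tfrac{1}{2}\lVert w \rVert^2 + C \sum \xi
\quad \text{s.t.} \quad
\begin{cases}
w \cdot x + b \le -1 + \xi_x & \text{negative instances} \\
w \cdot \bar\phi(B) + b \ge \frac{2 - |B|}{|B|} - \xi_B & \text{positive bags.}
\end{cases}
$$

The relaxed margin $(2-|B|)/|B|$ reflects that at least one of $|B|$
instances is positive: a singleton bag must clear the full margin 1 (the
program is then exactly a soft-margin SVM, which the tests exploit as a
reduction check against `e1071::svm`), while a large bag whose mean is
diluted by negative instances needs only to clear a margin approaching $-1$.

**Solver.** The dual is a box-constrained QP with one equality constraint and
per-constraint linear coefficients. It is solved by a deterministic
sequential-minimal-optimization loop (maximal-violating-pair selection,
exact two-variable updates, KKT gap tolerance `1e-8`, no random
initialization). Identical constraint rows are collapsed with summed slack
costs, which is exact at the optimum and shrinks template-heavy corpora
considerably. The test suite verifies the primal objective against
`kernlab::ipop`, a generic interior-point QP solver, on randomized problems
to `1e-6`.

**Confidence.** Raw bag scores $s = w\cdot\bar\phi(B)+b$ are mapped to
$[0,1]$ by a Platt-style logistic calibration fitted on training-bag scores
with regularized targets; the map is constrained monotone increasing, so
rankings are preserved, and symmetric score distributions map $s=0$ to 0.5.
Thresholds are inclusive (`score >= t` is positive).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `window` | 3 | tokens kept before/after each entity of a pair |
| `min_df` | 0.01 | minimum document frequency (fraction) for a feature |
| `C` | 1 | soft-margin cost of the sMIL program |
| `k` | 5 | cross-validation folds (split by document) |
| `threshold` | best-F from CV | confidence cutoff for graph edges |

The window size, minimum document frequency and fold count are the method's
published settings; `C` is a free parameter of the program. idf uses
$\ln(n/\mathrm{df}) + 1$ with L2-normalized vectors, a standard tf-idf
variant; document frequency counts documents, not instances. Context tokens
inside any entity mention are replaced by the `CELL` / `CYTOKINE`
placeholder, which prevents the classifier from memorizing entity identities
and forces it onto relational context words.

## What the synthetic generator emulates

`synth_config()` / `synth_generate()` create the package's reference study
conditions: 20 cells x 20 cytokines (2 synonyms each), 50 planted relations,
500 abstracts of 8 sentences, and a reference database with a 20% false
negative rate and no false positives — the error profile reported for the
silver-standard database this design emulates. Sentences come in three
kinds:

- **relational** (5% of sentences): a planted relation expressed through a
  template with distinctive relational vocabulary ("secreted", "induces the
  differentiation of", ...). Relations are used uniformly, and every planted
  relation is guaranteed at least one relational sentence. The 5% rate
  encodes the sparsity of genuine relational statements in abstracts — most
  co-mentions of a pair are not direct relations.
- **noise co-occurrence** (25%): a pair placed in a non-relational template
  ("... were cultured overnight while ... was quantified ..."). Pair usage
  is Zipf-weighted over a random permutation of *all* pairs, so a handful of
  spurious pairs co-occur more often than many genuine relations. This is
  what makes the pair-frequency baseline fallible while context features
  remain informative.
- **filler** (the rest): no entities.

Because relational and noise vocabularies are disjoint by construction
(unless the `template_overlap` dial injects shared phrasing), a linear
classifier can in principle separate them; the interesting failure pressure
comes from the database false negatives, whose relational sentences enter
training as negative instances. A generator with heavily skewed *relation*
usage would hand a single withheld relation enough contradictory negative
mass to make the degenerate solution $w = 0$ optimal at any cost $C$ —
uniform relation usage with sparse positives keeps the program
well-conditioned, which is why those are the defaults.

What passing tests on this generator do **not** show: robustness to
orthographic variation, abbreviations, anaphora, negated or hypothetical
statements, or realistic vocabulary overlap between relational and
incidental contexts. The generator exercises the pipeline's plumbing,
normalization, learning dynamics and determinism, not language understanding.

## Evaluation choices

- **Cross-validation** splits *documents* (not pairs) into folds, preventing
  evidence leakage between train and test; the vocabulary and calibration
  are refitted per fold and scores are pooled. Per-fold AUC averages are
  also reported (`fold_auc`), but the pooled curve is the default because
  single folds can lack positive bags at desk scale.
- **PR curves** place one point per distinct score threshold (inclusive
  comparison) without truncation, so the lowest-threshold point always has
  recall 1 and precision equal to prevalence — which is why the confidence
  and frequency rankings coincide there. The area is computed by step-wise
  interpolation over recall (the average-precision convention).
- **Best-F threshold** breaks ties toward the higher threshold.
- Bag-level evaluation treats membership of the reference database as truth
  (the distant-supervision regime); `score_recovery()` instead scores
  against the *planted* relations of the generator, quantifying whether the
  classifier overcomes database false negatives.

At the package's reference conditions (500 documents, seed 42), a full
5-fold cross-validation plus final training runs in well under a minute on
one core; the numbers it produces are computed by `scripts/acceptance.R` and
the test suite, not recorded here.

## Numerical and design notes

- **Sentence segmentation** is rule-based: terminal punctuation followed by
  whitespace and an upper-case letter/digit, with a biomedical abbreviation
  list ("i.v.", "Fig.", "et al."). Offsets are 0-based half-open on the raw
  abstract (NFC, no further normalization), which makes them stable across
  runs and makes `substr(abstract, start+1, end)` reproduce each span.
- **Token boundaries in NER**: a match may not be flanked by letters or
  digits; hyphens are boundaries. This is the strictest reproducible
  reading of exact dictionary matching ("IL6R" never matches "IL6"; "IL6"
  never matches inside "IL-6").
- **Overlap resolution** keeps the longest span (ties: earlier start, then
  cell before cytokine); it is idempotent and makes nested matches such as a
  "killer" cytokine synonym inside "natural killer cell" resolve to the
  cell.
- **Duplicate lexicon synonyms** mapping to different canonicals keep the
  lexicographically first canonical and log the conflict.
- **Pluralization** uses English inflection rules plus an irregulars table
  ("-is" to "-es", "-us" to "-i"); synonyms whose final word already looks
  plural are not re-pluralized, making expansion idempotent.
- **Lemmatization** is a rule-based suffix stripper (plurals, -ed/-ing with
  consonant undoubling, small irregular table); unknown tokens pass through
  lower-cased. It aims at consistent feature identity, not linguistic
  correctness.
- **Common-word list**: a bundled, curated list of about 900 high-frequency
  English words; any one-word-per-line file can be substituted. Only
  single-token synonyms are ever filtered, and canonical names are never
  removed.
- **Degenerate inputs**: empty corpora load to empty collections; records
  without abstracts are skipped with a warning; training demands at least
  one positive and one negative bag; a fold without positive training bags
  triggers a reseeded re-split with a warning; Fleiss' kappa on a
  single-category matrix and Pearson correlation on constant inputs are
  reported as undefined rather than silently coerced.
- **Graph statistics** (diameter, center) are computed on the largest
  connected component, since literature-derived graphs are routinely
  disconnected; cross-graph novelty matching is exact on canonical names,
  and unreconciled synonyms across graphs are a known, surfaced limitation.
- **Curation**: shared edges enter accuracy once, by majority verdict (a tie
  counts as reject); kappa is computed on the accept/reject binary.

## Known limitations

Exact dictionary matching misses orthographic variants and unlisted
synonyms and cannot disambiguate by context. Relation direction and
sentiment are not modeled. The sMIL classifier scores bags, not instances,
so the specific supporting sentence of a relation is not identified — only
that at least one exists. The `fetch_pubmed()` helper is a thin cached
convenience; all tests and examples run on local files.
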