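# Seedable synthetic corpora with planted cell-cytokine relations.
#
# The generator emulates the study conditions of a distant-supervision
# experiment: a reference database that misses a fraction of true relations
# (false negatives) but contains no false positives; relational sentences
# drawn from templates with a distinctive relational vocabulary; and
# non-relational "noise" co-occurrences whose pair usage is Zipf-weighted, so
# that some spurious pairs co-occur more often than some genuine relations —
# the regime in which a context classifier can outrank the raw pair
# frequency.

REL_TEMPLATES <- c(
  "{CELL} secreted elevated {CYT} after activation.",
  "{CYT} induces the differentiation of {CELL}.",
  "{CELL} produce {CYT} in response to antigen challenge.",
  "{CYT} signaling activates {CELL} directly.",
  "Stimulation of {CELL} triggered robust {CYT} release."
)

NOISE_TEMPLATES <- c(
  "{CELL} were cultured overnight while {CYT} was quantified by immunoassay.",
  "Baseline concentrations of {CYT} and counts of {CELL} were recorded separately.",
  "Aliquots containing {CELL} were frozen prior to {CYT} quantification.",
  "The assay panel included {CYT} alongside unrelated markers, with {CELL} as controls."
)

FILLER_SENTENCES <- c(
  "The experimental protocol followed institutional guidelines.",
  "Statistical analyses used standard software with default settings.",
  "Cohort characteristics are summarized in the supplementary material."
)

OVERLAP_PHRASE <- " Levels were quantified by immunoassay."

#' Configuration of the synthetic corpus generator
#'
#' Defaults define the package's reference study conditions: 20 cells and 20
#' cytokines with 2 synonyms each, 50 planted relations, 500 abstracts of 8
#' sentences, sparse positives (5% of sentences relational — most pair
#' co-occurrences describe no direct relation) against a quarter of sentences
#' with non-relational co-occurrence noise, and a reference database
#' withholding 20% of the true relations (false negatives, no false
#' positives).
#'
#' @param n_cells,n_cytokines Entity counts.
#' @param synonyms_per_entity Synonyms per entity in addition to the
#'   canonical name.
#' @param n_true_relations Planted relations (at most `n_cells *
#'   n_cytokines`).
#' @param n_docs,sentences_per_doc Corpus dimensions.
#' @param p_relation_sentence Probability a sentence expresses a planted
#'   relation through a relational template.
#' @param p_cooccur_noise Probability of a non-relational co-occurrence
#'   sentence (Zipf-weighted pair usage).
#' @param db_fn_rate Fraction of true relations withheld from the reference
#'   database.
#' @param template_overlap Probability of appending noise-vocabulary phrasing
#'   to a relational sentence, making the vocabularies less separable.
#' @param seed Integer seed; identical configurations generate byte-identical
#'   corpora.
#' @return A validated `ccr_synth_config` list.
#' @export
synth_config <- function(n_cells = 20L, n_cytokines = 20L,
                         synonyms_per_entity = 2L, n_true_relations = 50L,
                         n_docs = 500L, sentences_per_doc = 8L,
                         p_relation_sentence = 0.05, p_cooccur_noise = 0.25,
                         db_fn_rate = 0.2, template_overlap = 0,
                         seed = 42L) {
  cfg <- list(n_cells = as.integer(n_cells),
              n_cytokines = as.integer(n_cytokines),
              synonyms_per_entity = as.integer(synonyms_per_entity),
              n_true_relations = as.integer(n_true_relations),
              n_docs = as.integer(n_docs),
              sentences_per_doc = as.integer(sentences_per_doc),
              p_relation_sentence = p_relation_sentence,
              p_cooccur_noise = p_cooccur_noise,
              db_fn_rate = db_fn_rate, template_overlap = template_overlap,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_cells > 0, n_cytokines > 0, synonyms_per_entity >= 0,
              n_docs > 0, sentences_per_doc > 0)
    if (n_true_relations > n_cells * n_cytokines) {
      stop("n_true_relations exceeds the number of possible pairs")
    }
    for (p in c(p_relation_sentence, p_cooccur_noise, db_fn_rate,
                template_overlap)) {
      if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
    }
    if (p_relation_sentence + p_cooccur_noise > 1) {
      stop("p_relation_sentence + p_cooccur_noise must not exceed 1")
    }
  })
  structure(cfg, class = "ccr_synth_config")
}

zipf_weights <- function(n) {
  w <- 1 / seq_len(n)
  w / sum(w)
}

#' Generate a synthetic corpus bundle with planted relations
#'
#' Produces lexicons, a segmented corpus, a noisy reference database and the
#' ground truth, all reproducible from the seed. Every planted relation
#' appears in at least one relational sentence (unless
#' `p_relation_sentence = 0`); relation usage and noise-pair usage are
#' Zipf-weighted over a seeded permutation, so pair frequency is informative
#' but fallible. Entity mentions use a uniformly drawn synonym (cells also in
#' plural form), exercising normalization and plural expansion.
#'
#' @param cfg A [synth_config()].
#' @return List with components `cells`, `cytokines` (lexicons; apply
#'   [expand_plurals()] before matching), `corpus` (segmented `ccr_corpus`),
#'   `db` (reference database), `truth` (list: `true_relations` data frame,
#'   `db_relations`, `sentence_tags` data frame with per-sentence tag
#'   `relational` / `noise` / `filler`).
#' @export
synth_generate <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "ccr_synth_config"))
  with_seed(cfg$seed, synth_generate_impl(cfg))
}

synth_generate_impl <- function(cfg) {
  cell_can <- sprintf("CL%02d cell", seq_len(cfg$n_cells))
  cyt_can <- sprintf("CYK%02d", seq_len(cfg$n_cytokines))
  cell_syn <- lapply(seq_len(cfg$n_cells), function(i) {
    c(cell_can[i], sprintf("CL%02d-%s cell", i,
                           letters[seq_len(cfg$synonyms_per_entity)]))
  })
  cyt_syn <- lapply(seq_len(cfg$n_cytokines), function(i) {
    c(cyt_can[i], sprintf("CYK%02d-%s", i,
                          letters[seq_len(cfg$synonyms_per_entity)]))
  })
  cells <- lexicon(unlist(cell_syn),
                   rep(cell_can, lengths(cell_syn)), "cell", "synthetic")
  cytokines <- lexicon(unlist(cyt_syn),
                       rep(cyt_can, lengths(cyt_syn)), "cytokine", "synthetic")

  # planted relations and the noisy reference database
  all_pairs <- expand.grid(cell = cell_can, cytokine = cyt_can,
                           stringsAsFactors = FALSE)
  rel_ix <- sample(nrow(all_pairs), cfg$n_true_relations)
  true_rel <- all_pairs[rel_ix, , drop = FALSE]
  rownames(true_rel) <- NULL
  n_keep <- round((1 - cfg$db_fn_rate) * nrow(true_rel))
  keep_ix <- sort(sample(nrow(true_rel), n_keep))
  db <- reference_db(true_rel$cell[keep_ix], true_rel$cytokine[keep_ix],
                     provenance = "synthetic reference db")

  # relational sentences use planted relations uniformly (positives are
  # sparse: each relation is expressed in a handful of sentences); noise
  # co-occurrence usage is Zipf-weighted over a random permutation of all
  # pairs, so a few spurious pairs co-occur more often than genuine ones
  rel_w <- rep(1 / nrow(true_rel), nrow(true_rel))
  pair_order <- sample(nrow(all_pairs))
  pair_w <- zipf_weights(nrow(all_pairs))[order(pair_order)]

  surface_cell <- function(can) {
    i <- match(can, cell_can)
    s <- sample(cell_syn[[i]], 1L)
    if (stats::runif(1) < 0.5) pluralize_term(s) else s
  }
  surface_cyt <- function(can) {
    i <- match(can, cyt_can)
    sample(cyt_syn[[i]], 1L)
  }
  fill_template <- function(tpl, cell, cyt) {
    out <- sub("{CELL}", surface_cell(cell), tpl, fixed = TRUE)
    sub("{CYT}", surface_cyt(cyt), out, fixed = TRUE)
  }

  n_sent <- cfg$n_docs * cfg$sentences_per_doc
  kind <- sample(c("relational", "noise", "filler"), n_sent, replace = TRUE,
                 prob = c(cfg$p_relation_sentence, cfg$p_cooccur_noise,
                          1 - cfg$p_relation_sentence - cfg$p_cooccur_noise))
  # coverage guarantee: each planted relation gets >= 1 relational sentence
  if (cfg$p_relation_sentence > 0) {
    need <- cfg$n_true_relations
    if (n_sent < need) {
      stop("corpus too small to express every planted relation: ",
           n_sent, " sentences < ", need, " relations")
    }
    have <- which(kind == "relational")
    if (length(have) < need) {
      extra <- sample(which(kind != "relational"), need - length(have))
      kind[extra] <- "relational"
      have <- which(kind == "relational")
    }
    forced <- sample(have, need)
  } else {
    forced <- integer()
  }

  sent_text <- character(n_sent)
  sent_cell <- rep(NA_character_, n_sent)
  sent_cyt <- rep(NA_character_, n_sent)
  for (s in seq_len(n_sent)) {
    k <- kind[s]
    if (k == "relational") {
      r <- if (s %in% forced) {
        match(s, forced)
      } else {
        sample(nrow(true_rel), 1L, prob = rel_w)
      }
      txt <- fill_template(sample(REL_TEMPLATES, 1L),
                           true_rel$cell[r], true_rel$cytokine[r])
      if (cfg$template_overlap > 0 &&
          stats::runif(1) < cfg$template_overlap) {
        txt <- paste0(txt, OVERLAP_PHRASE)
      }
      sent_cell[s] <- true_rel$cell[r]
      sent_cyt[s] <- true_rel$cytokine[r]
    } else if (k == "noise") {
      p <- sample(nrow(all_pairs), 1L, prob = pair_w)
      txt <- fill_template(sample(NOISE_TEMPLATES, 1L),
                           all_pairs$cell[p], all_pairs$cytokine[p])
      sent_cell[s] <- all_pairs$cell[p]
      sent_cyt[s] <- all_pairs$cytokine[p]
    } else {
      txt <- sample(FILLER_SENTENCES, 1L)
    }
    sent_text[s] <- txt
  }

  doc_of <- rep(seq_len(cfg$n_docs), each = cfg$sentences_per_doc)
  pmids <- sprintf("S%05d", seq_len(cfg$n_docs))
  docs <- lapply(seq_len(cfg$n_docs), function(d) {
    document(pmids[d], sprintf("Synthetic abstract %s", pmids[d]),
             paste(sent_text[doc_of == d], collapse = " "))
  })
  corpus <- segment_corpus(new_corpus(docs))

  sentence_tags <- df0(
    pmid = pmids[doc_of],
    sentence_index = stats::ave(seq_len(n_sent), doc_of,
                                FUN = seq_along),
    tag = kind, cell = sent_cell, cytokine = sent_cyt
  )

  list(cells = cells, cytokines = cytokines, corpus = corpus, db = db,
       truth = list(true_relations = true_rel,
                    db_relations = as.data.frame(db),
                    sentence_tags = sentence_tags),
       config = cfg)
}

#' Write the synthetic bundle to files
#'
#' Emits the same formats the pipeline consumes: `corpus.jsonl`,
#' `cells.tsv` / `cytokines.tsv` lexicons, `reference_db.tsv`, plus
#' `ground_truth.json`.
#'
#' @param bundle A [synth_generate()] result.
#' @param dir Output directory.
#' @return Named vector of paths, invisibly.
#' @export
write_synth_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    corpus = file.path(dir, "corpus.jsonl"),
    cells = file.path(dir, "cells.tsv"),
    cytokines = file.path(dir, "cytokines.tsv"),
    db = file.path(dir, "reference_db.tsv"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_corpus(bundle$corpus, paths["corpus"])
  write_lexicon(bundle$cells, paths["cells"])
  write_lexicon(bundle$cytokines, paths["cytokines"])
  write_reference_db(bundle$db, paths["db"])
  jsonlite::write_json(bundle$truth, paths["truth"], dataframe = "rows",
                       auto_unbox = TRUE)
  invisible(paths)
}

#' Score a predicted graph against the planted ground truth
#'
#' Precision and recall of the predicted edge set against the planted
#' relations (not the noisy reference database), quantifying whether the
#' classifier overcomes the database's false negatives. When the full scored
#' bag table is supplied, the AUC-PR of the confidence and frequency rankings
#' against the ground truth is also reported.
#'
#' @param g Predicted `ccr_graph` (or data frame with `cell`, `cytokine`).
#' @param truth The `truth` component of [synth_generate()].
#' @param scores Optional [score_bags()] data frame for ranking AUCs.
#' @return List with `precision`, `recall`, and (if `scores` given)
#'   `auc_confidence`, `auc_frequency`.
#' @export
score_recovery <- function(g, truth, scores = NULL) {
  if (nrow(truth$true_relations) == 0L) stop("empty ground truth")
  edges <- if (inherits(g, "ccr_graph")) g$edges else g
  pred <- unique(pair_key(edges$cell, edges$cytokine))
  tru <- unique(pair_key(truth$true_relations$cell,
                         truth$true_relations$cytokine))
  tp <- sum(pred %in% tru)
  out <- list(
    precision = if (length(pred)) tp / length(pred) else 0,
    recall = tp / length(tru)
  )
  if (!is.null(scores) && nrow(scores)) {
    lab <- pair_key(scores$cell, scores$cytokine) %in% tru
    out$auc_confidence <- auc_pr(pr_curve(scores$confidence, lab))
    out$auc_frequency <- auc_pr(pr_curve(scores$frequency, lab))
  }
  out
}
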