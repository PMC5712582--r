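# Cross-validation and precision-recall evaluation of the two pair-ranking
# scores: the classifier confidence and the pair frequency.

#' Train a pair classifier on an annotated corpus
#'
#' Convenience wrapper tying the feature and classifier stages together:
#' extracts lemma context windows for every instance, fits the tf-idf
#' vocabulary on these documents, labels bags against the reference database,
#' and fits the sMIL model. The vocabulary is frozen inside the returned
#' object so new data is transformed with training-time idf weights.
#'
#' @param corpus Segmented corpus (training documents only).
#' @param mentions Overlap-resolved mentions of those documents.
#' @param db Reference relation database for distant supervision.
#' @param window Context window size (default 3).
#' @param min_df Minimum document frequency fraction (default 0.01).
#' @param C Soft-margin cost (default 1).
#' @return List with elements `model` (class `smil`), `vocab`, `bags`.
#' @export
train_pair_classifier <- function(corpus, mentions, db, window = 3L,
                                  min_df = 0.01, C = 1) {
  instances <- generate_instances(mentions)
  if (nrow(instances) == 0L) stop("no cell-cytokine instances in the corpus")
  contexts <- extract_contexts(instances, corpus, mentions, window)
  vocab <- fit_vocabulary(contexts, instances$pmid, min_df)
  x <- vectorize(contexts, vocab)
  bags <- label_bags(build_bags(instances), db)
  bag_ids <- pair_key(instances$cell, instances$cytokine)
  bag_lab <- vapply(bags, `[[`, "", "label")[bag_ids] == "positive"
  model <- smil(x, bag_ids, bag_lab, C = C)
  list(model = model, vocab = vocab, bags = bags)
}

#' Score every bag of a corpus with a trained classifier
#'
#' @param fit Result of [train_pair_classifier()] (or a list with `model` and
#'   `vocab`).
#' @param corpus Segmented corpus to score.
#' @param mentions Overlap-resolved mentions of that corpus.
#' @param window Context window size used at training.
#' @return Data frame with one row per bag: `cell`, `cytokine`, `confidence`,
#'   `frequency`, `n_docs`, `n_instances`, plus the bags themselves as the
#'   `"bags"` attribute (for evidence extraction).
#' @export
score_bags <- function(fit, corpus, mentions, window = 3L) {
  instances <- generate_instances(mentions)
  if (nrow(instances) == 0L) {
    out <- df0(cell = character(), cytokine = character(),
               confidence = numeric(), frequency = numeric(),
               n_docs = integer(), n_instances = integer())
    attr(out, "bags") <- structure(list(), class = "ccr_bags")
    return(out)
  }
  contexts <- extract_contexts(instances, corpus, mentions, window)
  x <- vectorize(contexts, fit$vocab)
  bag_ids <- pair_key(instances$cell, instances$cytokine)
  conf <- predict(fit$model, x, bag_ids, type = "confidence")
  bags <- build_bags(instances)
  stopifnot(identical(names(bags), names(conf)[order(names(conf))]))
  conf <- conf[names(bags)]
  out <- df0(
    cell = vapply(bags, `[[`, "", "cell"),
    cytokine = vapply(bags, `[[`, "", "cytokine"),
    confidence = as.numeric(conf),
    frequency = vapply(bags, pair_frequency, 0, corpus_size = length(corpus)),
    n_docs = vapply(bags, function(b) length(b$docs), 1L),
    n_instances = vapply(bags, function(b) nrow(b$instances), 1L)
  )
  rownames(out) <- NULL
  attr(out, "bags") <- bags
  out
}

#' Precision-recall curve over score thresholds
#'
#' One point per distinct score value used as the threshold, predicting
#' positive iff `score >= t`; recall is non-increasing in the threshold.
#'
#' @param score Numeric scores.
#' @param label Logical (or 0/1) true labels; at least one must be positive.
#' @return Data frame of class `ccr_pr_curve` with columns `threshold`,
#'   `precision`, `recall`, `f1`, ordered by decreasing threshold.
#' @export
pr_curve <- function(score, label) {
  label <- as.logical(label)
  stopifnot(length(score) == length(label))
  if (!any(label)) stop("no positive labels: recall is undefined")
  thresholds <- sort(unique(score), decreasing = TRUE)
  npos <- sum(label)
  ord <- order(-score)
  s <- score[ord]
  l <- label[ord]
  ctp <- cumsum(l)
  cnt <- seq_along(l)
  # index of the last item with score >= t, per distinct threshold
  last <- findInterval(-thresholds, -s)
  precision <- ctp[last] / cnt[last]
  recall <- ctp[last] / npos
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  out <- df0(threshold = thresholds, precision = precision, recall = recall,
             f1 = f1)
  class(out) <- c("ccr_pr_curve", "data.frame")
  out
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise interpolation over recall (the average-precision convention):
#' `AP = sum_i (R_i - R_{i-1}) * P_i` over the curve ordered by increasing
#' recall, with `R_0 = 0`.
#'
#' @param curve A [pr_curve()] result.
#' @return Scalar in `[0, 1]`.
#' @export
auc_pr <- function(curve) {
  if (nrow(curve) < 1L) stop("empty precision-recall curve")
  cv <- curve[order(curve$recall, -curve$threshold), , drop = FALSE]
  dr <- diff(c(0, cv$recall))
  sum(dr * cv$precision)
}

#' Threshold with the highest F-measure
#'
#' @param curve A [pr_curve()] result.
#' @return The one-row curve point maximizing F1; ties are broken in favor of
#'   the higher threshold.
#' @export
best_f_threshold <- function(curve) {
  if (nrow(curve) < 1L) stop("empty precision-recall curve")
  best <- which(curve$f1 == max(curve$f1))
  best <- best[which.max(curve$threshold[best])]
  curve[best, , drop = FALSE]
}

#' Document-level k-fold cross-validation of pair ranking
#'
#' Documents are split into `k` folds by a seeded shuffle. For each fold the
#' vocabulary and sMIL model are fitted on the training documents only; bags
#' built from the held-out documents are scored with the classifier
#' confidence and the pair frequency, labeled against the reference database,
#' and pooled across folds into one PR curve per ranking. A fold whose
#' training documents yield no positive bag triggers a warning and a re-split
#' with an incremented seed.
#'
#' @param corpus Segmented corpus.
#' @param mentions Overlap-resolved mentions of the corpus.
#' @param db Reference relation database.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold shuffle.
#' @param window,min_df,C Pipeline parameters (see
#'   [train_pair_classifier()]).
#' @return An object of class `ccr_cv`: list with `folds` (named fold index
#'   per pmid), `scores` (pooled data frame: cell, cytokine, fold,
#'   confidence, frequency, label), `curves` (list of two [pr_curve()]s),
#'   `auc` (named vector), and per-fold metric averages `fold_auc`.
#' @export
cross_validate <- function(corpus, mentions, db, k = 5L, seed = 42L,
                           window = 3L, min_df = 0.01, C = 1) {
  stopifnot(k >= 2L, length(corpus) >= k)
  pmids <- names(corpus)
  attempt <- 0L
  repeat {
    folds <- with_seed(seed + attempt, {
      stats::setNames(sample(rep_len(seq_len(k), length(pmids))), pmids)
    })
    ok <- TRUE
    score_rows <- list()
    for (fold in seq_len(k)) {
      train_ids <- pmids[folds != fold]
      test_ids <- pmids[folds == fold]
      m_train <- mentions[mentions$pmid %in% train_ids, , drop = FALSE]
      m_test <- mentions[mentions$pmid %in% test_ids, , drop = FALSE]
      fit <- tryCatch(
        train_pair_classifier(corpus[train_ids], m_train, db,
                              window = window, min_df = min_df, C = C),
        error = function(e) e
      )
      if (inherits(fit, "error")) {
        ok <- FALSE
        break
      }
      sc <- score_bags(fit, corpus[test_ids], m_test, window = window)
      if (nrow(sc) == 0L) next
      db_keys <- pair_key(db$cell, db$cytokine)
      score_rows[[fold]] <- df0(
        cell = sc$cell, cytokine = sc$cytokine, fold = fold,
        confidence = sc$confidence, frequency = sc$frequency,
        label = pair_key(sc$cell, sc$cytokine) %in% db_keys
      )
    }
    if (ok) break
    attempt <- attempt + 1L
    warning("a fold had no positive training bags; re-splitting with seed ",
            seed + attempt)
    if (attempt > 25L) stop("could not build folds with positive bags in each")
  }
  scores <- do.call(rbind, score_rows)
  rownames(scores) <- NULL
  curves <- list(
    confidence = pr_curve(scores$confidence, scores$label),
    frequency = pr_curve(scores$frequency, scores$label)
  )
  per_fold <- vapply(sort(unique(scores$fold)), function(fd) {
    s <- scores[scores$fold == fd, ]
    if (!any(s$label) || !any(!s$label)) return(c(NA_real_, NA_real_))
    c(auc_pr(pr_curve(s$confidence, s$label)),
      auc_pr(pr_curve(s$frequency, s$label)))
  }, numeric(2))
  structure(
    list(folds = folds, scores = scores, curves = curves,
         auc = c(confidence = auc_pr(curves$confidence),
                 frequency = auc_pr(curves$frequency)),
         fold_auc = c(confidence = mean(per_fold[1, ], na.rm = TRUE),
                      frequency = mean(per_fold[2, ], na.rm = TRUE)),
         k = k, seed = seed),
    class = "ccr_cv"
  )
}

#' @export
print.ccr_cv <- function(x, ...) {
  cat(sprintf("%d-fold document-level cross-validation (%d documents, %d scored bags)\n",
              x$k, length(x$folds), nrow(x$scores)))
  cat(sprintf("  pooled AUC-PR: confidence %.3f, pair frequency %.3f\n",
              x$auc["confidence"], x$auc["frequency"]))
  bf <- best_f_threshold(x$curves$confidence)
  cat(sprintf("  best F1 (confidence): %.3f at threshold %.3f (P %.3f, R %.3f)\n",
              bf$f1, bf$threshold, bf$precision, bf$recall))
  invisible(x)
}

#' Export cross-validation results as TSV files
#'
#' Writes `folds.tsv`, `scores.tsv` and `curve_confidence.tsv` /
#' `curve_frequency.tsv` under `dir`.
#'
#' @param cv A [cross_validate()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
export_cv <- function(cv, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(df0(pmid = names(cv$folds), fold = as.integer(cv$folds)),
                     file.path(dir, "folds.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cv$scores, file.path(dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(cv$curves)) {
    utils::write.table(as.data.frame(cv$curves[[nm]]),
                       file.path(dir, paste0("curve_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
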