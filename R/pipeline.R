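# Single entry point wiring all stages: annotate -> pairs -> train/predict ->
# graph -> exports, with a manifest recording parameters, seed and input
# checksums for reproducibility.

PIPELINE_DEFAULTS <- list(
  corpus = NULL, cells = NULL, cytokines = NULL, db = NULL, out_dir = NULL,
  corpus_format = "jsonl", window = 3L, min_df = 0.01, C = 1,
  threshold = NULL, k = 5L, seed = 42L,
  expand_cell_plurals = TRUE, filter_cytokine_common_words = TRUE,
  common_words_path = NULL, run_cv = TRUE,
  export_formats = c("edge-tsv", "evidence-tsv", "graphml")
)

#' Build a validated pipeline configuration
#'
#' Defaults follow the method's published settings where stated: context
#' window 3, minimum document frequency 0.01, 5-fold cross-validation.
#' Unknown keys are rejected. When `threshold` is `NULL` the confidence
#' threshold maximizing F1 in cross-validation is used; `run_cv = FALSE` with
#' a `NULL` threshold falls back to 0.5.
#'
#' @param corpus,cells,cytokines,db Input paths (JSONL corpus, lexicon TSVs,
#'   reference-db TSV).
#' @param out_dir Output directory.
#' @param ... Overrides of the remaining defaults (see
#'   `ccrel:::PIPELINE_DEFAULTS`).
#' @return A `ccr_pipeline_config` list.
#' @export
pipeline_config <- function(corpus, cells, cytokines, db, out_dir, ...) {
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(PIPELINE_DEFAULTS))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, overrides, keep.null = TRUE)
  cfg$corpus <- corpus; cfg$cells <- cells; cfg$cytokines <- cytokines
  cfg$db <- db; cfg$out_dir <- out_dir
  for (p in c("corpus", "cells", "cytokines", "db")) {
    if (!file.exists(cfg[[p]])) stop("input path does not exist: ", cfg[[p]])
  }
  structure(cfg, class = "ccr_pipeline_config")
}

#' Run the full extraction pipeline
#'
#' Loads and segments the corpus, prepares the lexicons (plural expansion for
#' cells, common-word filtering for cytokines), annotates mentions, builds
#' and labels bags, optionally cross-validates to select the confidence
#' threshold, trains the final sMIL model on all documents, scores every
#' bag, builds the knowledge graph and exports it together with a manifest
#' (`manifest.json`: package version, seed, parameters, input checksums,
#' output checksums). A stage failure aborts with the stage name; partial
#' outputs are kept under a `failed/` marker directory.
#'
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with `graph`, `scores`, `cv` (or `NULL`),
#'   `model_fit`, `threshold`, `out_dir`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "ccr_pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[ccrel] ", sprintf(...))
  stage <- "load"
  result <- tryCatch({
    say("loading corpus %s", cfg$corpus)
    corpus <- load_corpus(cfg$corpus, cfg$corpus_format)
    cells <- read_lexicon(cfg$cells, "cell")
    if (cfg$expand_cell_plurals) cells <- expand_plurals(cells)
    cytokines <- read_lexicon(cfg$cytokines, "cytokine")
    if (cfg$filter_cytokine_common_words) {
      words <- if (is.null(cfg$common_words_path)) common_words() else
        common_words(cfg$common_words_path)
      cytokines <- filter_common_words(cytokines, words)
    }
    db <- read_reference_db(cfg$db)

    stage <- "annotate"
    say("annotating %d documents", length(corpus))
    mentions <- annotate_corpus(corpus, cells, cytokines)

    stage <- "cross-validate"
    cv <- NULL
    threshold <- cfg$threshold
    if (cfg$run_cv) {
      say("%d-fold cross-validation", cfg$k)
      cv <- cross_validate(corpus, mentions, db, k = cfg$k, seed = cfg$seed,
                           window = cfg$window, min_df = cfg$min_df,
                           C = cfg$C)
      export_cv(cv, file.path(cfg$out_dir, "cv"))
      if (is.null(threshold)) {
        threshold <- best_f_threshold(cv$curves$confidence)$threshold
      }
    }
    if (is.null(threshold)) threshold <- 0.5

    stage <- "train"
    say("training final model on all documents")
    fit <- train_pair_classifier(corpus, mentions, db, window = cfg$window,
                                 min_df = cfg$min_df, C = cfg$C)
    stage <- "score"
    scores <- score_bags(fit, corpus, mentions, window = cfg$window)

    stage <- "graph"
    say("building graph at confidence threshold %.3f", threshold)
    graph <- build_graph(scores, corpus, threshold)
    paths <- export_graph(graph, cfg$out_dir, cfg$export_formats)
    utils::write.table(scores, file.path(cfg$out_dir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_vocabulary(fit$vocab, file.path(cfg$out_dir, "vocabulary.tsv"))

    stage <- "manifest"
    manifest <- list(
      package = "ccrel",
      version = as.character(utils::packageVersion("ccrel")),
      seed = cfg$seed, threshold = threshold,
      parameters = cfg[c("window", "min_df", "C", "k",
                         "expand_cell_plurals",
                         "filter_cytokine_common_words")],
      inputs = as.list(stats::setNames(
        tools::md5sum(c(cfg$corpus, cfg$cells, cfg$cytokines, cfg$db)),
        c("corpus", "cells", "cytokines", "db"))),
      outputs = as.list(stats::setNames(tools::md5sum(unname(paths)),
                                        basename(unname(paths))))
    )
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    list(graph = graph, scores = scores, cv = cv, model_fit = fit,
         threshold = threshold, out_dir = cfg$out_dir)
  }, error = function(e) {
    dir.create(file.path(cfg$out_dir, "failed"), showWarnings = FALSE)
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               file.path(cfg$out_dir, "failed", "error.txt"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
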