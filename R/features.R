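# Tokenization, lemmatization and tf-idf context features.

#' Tokenize text with character offsets
#'
#' Splits on whitespace and punctuation while keeping hyphenated biomedical
#' tokens whole ("IL-6", "CD40-ligand" are single tokens). Offsets are
#' 0-based half-open relative to the input string.
#'
#' @param text Character scalar.
#' @return Data frame with columns `token`, `start`, `end`.
#' @export
tokenize <- function(text) {
  m <- gregexpr("[A-Za-z0-9]+(?:[-'/][A-Za-z0-9]+)*", text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(df0(token = character(), start = integer(), end = integer()))
  }
  starts <- as.integer(m) - 1L
  ends <- starts + attr(m, "match.length")
  df0(token = substring(text, starts + 1L, ends), start = starts, end = ends)
}

# Small irregular-form table for the rule-based lemmatizer.
LEMMA_IRREGULAR <- c(
  "was" = "be", "were" = "be", "is" = "be", "are" = "be", "been" = "be",
  "has" = "have", "had" = "have", "did" = "do", "does" = "do",
  "cells" = "cell", "mice" = "mouse", "media" = "medium",
  "bacteria" = "bacterium", "criteria" = "criterion",
  "analyses" = "analysis", "stimuli" = "stimulus", "nuclei" = "nucleus",
  "found" = "find", "shown" = "show", "seen" = "see", "given" = "give"
)

#' Rule-based English lemmatizer
#'
#' Lower-cases the token, applies an irregular-form table, then
#' suffix-stripping rules for plural nouns and regular verb inflections
#' (-ies, -es, -s, -ied, -ed, -ing) with simple stem-restoration. Unknown or
#' non-alphabetic tokens pass through lower-cased. The goal is that
#' inflectional variants of the same root map to one feature, not
#' linguistically perfect lemmas.
#'
#' @param token Character vector of tokens.
#' @return Character vector of lemmas.
#' @export
lemmatize <- function(token) {
  low <- tolower(token)
  out <- low
  irr <- match(low, names(LEMMA_IRREGULAR))
  out[!is.na(irr)] <- LEMMA_IRREGULAR[irr[!is.na(irr)]]
  todo <- is.na(irr) & grepl("^[a-z]+$", low) & nchar(low) > 3L
  w <- low[todo]
  # plural nouns / 3rd-person verbs
  w <- ifelse(grepl("ies$", w) & nchar(w) > 4L, sub("ies$", "y", w),
       ifelse(grepl("(ss|us|is)$", w), w,
       ifelse(grepl("(ches|shes|xes|zes)$", w), sub("es$", "", w),
       ifelse(grepl("s$", w), sub("s$", "", w), w))))
  # regular past tense / participle / gerund, undoubling final consonants
  # ("stimulated" -> "stimulate" is out of reach; "secreted" -> "secret" is
  # acceptable as long as the mapping is consistent across variants)
  stripped <- grepl("(ied|ed|ing)$", w) & nchar(w) > 4L
  w2 <- w
  w2 <- ifelse(grepl("ied$", w2) & nchar(w2) > 4L, sub("ied$", "y", w2),
        ifelse(grepl("ed$", w2) & nchar(w2) > 4L, sub("ed$", "", w2),
        ifelse(grepl("ing$", w2) & nchar(w2) > 5L, sub("ing$", "", w2), w2)))
  w2 <- ifelse(stripped, sub("([b-df-hj-np-tv-z])\\1$", "\\1", w2), w2)
  out[todo] <- w2
  out
}

#' Extract the lemma context window of one instance
#'
#' Collects up to `window` tokens before and after the cell mention and up to
#' `window` before and after the cytokine mention of the instance, truncated
#' at the sentence boundaries. The two windows are merged positionally: a
#' token position selected by both windows contributes once. Tokens that lie
#' inside any entity mention (including a third entity that happens to fall
#' in the window) are represented by the placeholder `CELL` or `CYTOKINE`
#' instead of their lemma, to avoid bias toward specific entity names.
#'
#' @param inst One-row instance data frame (see [generate_instances()]).
#' @param sentence One row of a document's `sentences` table.
#' @param sentence_mentions All overlap-resolved mentions of that sentence.
#' @param window Context window size in tokens (default 3).
#' @return Character vector of feature tokens (possibly empty).
#' @export
extract_context <- function(inst, sentence, sentence_mentions, window = 3L) {
  toks <- tokenize(sentence$text)
  if (nrow(toks) == 0L) return(character())
  # absolute offsets
  toks$start <- toks$start + sentence$start
  toks$end <- toks$end + sentence$start
  tok_entity <- rep(NA_character_, nrow(toks))
  if (nrow(sentence_mentions)) {
    for (j in seq_len(nrow(sentence_mentions))) {
      inside <- toks$start < sentence_mentions$end[j] &
        toks$end > sentence_mentions$start[j]
      tok_entity[inside] <- toupper(sentence_mentions$entity_type[j])
    }
  }
  span_tokens <- function(s, e) which(toks$start < e & toks$end > s)
  ctx_positions <- function(s, e) {
    ent <- span_tokens(s, e)
    if (length(ent) == 0L) return(integer())
    lo <- min(ent)
    hi <- max(ent)
    c(if (lo > 1L) seq.int(max(1L, lo - window), lo - 1L),
      if (hi < nrow(toks)) seq.int(hi + 1L, min(nrow(toks), hi + window)))
  }
  # union of both entities positional windows; a position selected by both
  # windows contributes once; the partner entity tokens falling inside a
  # window surface as placeholders via tok_entity
  pos <- sort(unique(c(
    ctx_positions(inst$cell_start, inst$cell_end),
    ctx_positions(inst$cytokine_start, inst$cytokine_end)
  )))
  if (length(pos) == 0L) return(character())
  ifelse(is.na(tok_entity[pos]), lemmatize(toks$token[pos]), tok_entity[pos])
}

#' Extract context token lists for all instances
#'
#' @param instances Instance data frame.
#' @param corpus Segmented corpus the instances came from.
#' @param mentions Overlap-resolved mentions of the corpus.
#' @param window Context window size (default 3).
#' @return List of character vectors, one per instance row.
#' @export
extract_contexts <- function(instances, corpus, mentions, window = 3L) {
  if (nrow(instances) == 0L) return(list())
  mkey <- paste(mentions$pmid, mentions$sentence_index, sep = "\r")
  lapply(seq_len(nrow(instances)), function(i) {
    inst <- instances[i, , drop = FALSE]
    doc <- corpus[[inst$pmid]]
    sentence <- doc$sentences[inst$sentence_index, , drop = FALSE]
    sm <- mentions[mkey == paste(inst$pmid, inst$sentence_index, sep = "\r"), ,
                   drop = FALSE]
    extract_context(inst, sentence, sm, window)
  })
}

#' Fit a tf-idf vocabulary on training instances
#'
#' Document frequency is counted over documents (a term counts once per
#' abstract however many instances mention it); terms seen in fewer than
#' `min_df` of the documents are pruned. The idf weight is
#' `ln(n_docs / df) + 1`, so a term present in every document gets weight 1.
#' The vocabulary is frozen after fitting: transforming new data never
#' changes terms or idf.
#'
#' @param token_lists List of context token vectors (one per instance).
#' @param doc_ids Character vector of the pmid of each instance.
#' @param min_df Minimum document frequency as a fraction (default 0.01).
#' @return A `ccr_vocabulary`: list with `terms` (lexicographically sorted),
#'   `df`, `idf`, `min_df`, `n_docs`.
#' @export
fit_vocabulary <- function(token_lists, doc_ids, min_df = 0.01) {
  stopifnot(length(token_lists) == length(doc_ids))
  if (length(token_lists) == 0L) stop("no instances to fit a vocabulary on")
  n_docs <- length(unique(doc_ids))
  per_doc <- lapply(split(token_lists, doc_ids),
                    function(tl) unique(unlist(tl)))
  df_counts <- table(unlist(per_doc))
  if (length(df_counts) == 0L) stop("no tokens observed")
  keep <- as.integer(df_counts) >= min_df * n_docs
  terms <- sort(names(df_counts)[keep], method = "radix")
  dfv <- as.integer(df_counts[terms])
  structure(
    list(terms = terms, df = dfv, idf = log(n_docs / dfv) + 1,
         min_df = min_df, n_docs = n_docs),
    class = "ccr_vocabulary"
  )
}

#' @export
print.ccr_vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary> %d terms, fitted on %d documents (min_df = %g)\n",
              length(x$terms), x$n_docs, x$min_df))
  invisible(x)
}

#' Vectorize token lists with frozen tf-idf weights
#'
#' Each instance becomes a sparse row: raw term counts multiplied by the
#' vocabulary's idf weights, then L2-normalized (rows with no in-vocabulary
#' token stay zero). Out-of-vocabulary tokens are ignored.
#'
#' @param token_lists List of context token vectors.
#' @param vocab A fitted [fit_vocabulary()] object.
#' @return A `dgCMatrix` of dimension n_instances x n_terms.
#' @export
vectorize <- function(token_lists, vocab) {
  n <- length(token_lists)
  p <- length(vocab$terms)
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (i in seq_len(n)) {
    idx <- match(token_lists[[i]], vocab$terms)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) next
    tf <- table(idx)
    j <- as.integer(names(tf))
    w <- as.numeric(tf) * vocab$idf[j]
    nrm <- sqrt(sum(w^2))
    ii <- c(ii, rep(i, length(j))); jj <- c(jj, j); xx <- c(xx, w / nrm)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, p),
                       dimnames = list(NULL, vocab$terms))
}

#' Write a vocabulary as TSV (term, df, idf)
#' @param vocab A `ccr_vocabulary`.
#' @param path Output path.
#' @export
write_vocabulary <- function(vocab, path) {
  utils::write.table(df0(term = vocab$terms, df = vocab$df, idf = vocab$idf),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
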