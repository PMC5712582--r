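#' Dictionary-based named entity recognition
#'
#' Matches every lexicon synonym in the abstract of a segmented document,
#' case-insensitively and aligned to token boundaries: a match may not be
#' flanked by a letter or digit, so "IL6R" does not match the synonym "IL6",
#' while a hyphen counts as a boundary ("IL-6" matches the synonym "IL-6").
#' Offsets are 0-based half-open on the abstract string: annotating
#' "The dendritic cells were safely tolerated." with a plural-expanded
#' lexicon containing "dendritic cell" yields one mention spanning
#' characters 4 to 19.
#'
#' Mentions of overlapping synonyms are all returned; apply
#' [resolve_overlaps()] to keep the longest spans only.
#'
#' @param doc A segmented [document()].
#' @param lex A [lexicon()].
#' @return Data frame of mentions: `pmid`, `sentence_index` (1-based),
#'   `start`, `end` (0-based half-open), `surface`, `entity_type`,
#'   `canonical`, sorted by (start, end).
#' @export
annotate <- function(doc, lex) {
  if (is.null(doc$sentences)) stop("document must be segmented first")
  if (nrow(lex) == 0L) stop("lexicon is empty")
  corpus <- structure(list(doc), names = doc$pmid, class = "ccr_corpus")
  annotate_many(corpus, lex)
}

# Vectorized matcher: one regex pass per synonym over all abstracts.
annotate_many <- function(corpus, lex) {
  texts <- vapply(corpus, `[[`, "", "abstract")
  pmids <- names(corpus)
  etype <- attr(lex, "entity_type")
  out <- list()
  for (i in seq_len(nrow(lex))) {
    syn <- lex$synonym[i]
    pat <- paste0("(?<![A-Za-z0-9])", escape_regex(syn), "(?![A-Za-z0-9])")
    ms <- gregexpr(pat, texts, perl = TRUE, ignore.case = TRUE)
    for (d in seq_along(ms)) {
      m <- ms[[d]]
      if (m[1] == -1L) next
      starts <- as.integer(m) - 1L              # to 0-based
      ends <- starts + attr(m, "match.length")  # half-open
      out[[length(out) + 1L]] <- df0(
        pmid = pmids[d], start = starts, end = ends,
        surface = substring(texts[d], starts + 1L, ends),
        canonical = lex$canonical[i]
      )
    }
  }
  if (length(out) == 0L) return(empty_mentions())
  hits <- do.call(rbind, out)
  # attach sentence index; drop matches crossing sentence boundaries
  res <- list()
  for (pm in unique(hits$pmid)) {
    h <- hits[hits$pmid == pm, , drop = FALSE]
    sent <- corpus[[pm]]$sentences
    idx <- vapply(seq_len(nrow(h)), function(j) {
      k <- which(sent$start <= h$start[j] & h$end[j] <= sent$end)
      if (length(k)) k[1] else NA_integer_
    }, 1L)
    keep <- !is.na(idx)
    h <- h[keep, , drop = FALSE]
    res[[pm]] <- df0(
      pmid = h$pmid, sentence_index = idx[keep],
      start = h$start, end = h$end, surface = h$surface,
      entity_type = rep(etype, nrow(h)), canonical = h$canonical
    )
  }
  res <- do.call(rbind, res)
  res <- res[order(res$pmid, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

escape_regex <- function(x) gsub("([\\^$.|?*+()\\[\\]{}\\\\])", "\\\\\\1", x, perl = TRUE)

#' Annotate a whole corpus with cell and cytokine lexicons
#'
#' Runs [annotate()] with both lexicons on every document and resolves
#' overlaps, so downstream pairing sees disjoint, longest-match mentions.
#'
#' @param corpus A segmented `ccr_corpus`.
#' @param cell_lex,cytokine_lex Lexicons of the respective entity types.
#' @return Data frame of overlap-resolved mentions for the whole corpus.
#' @export
annotate_corpus <- function(corpus, cell_lex, cytokine_lex) {
  m <- rbind(
    if (nrow(cell_lex)) annotate_many(corpus, cell_lex) else empty_mentions(),
    if (nrow(cytokine_lex)) annotate_many(corpus, cytokine_lex) else empty_mentions()
  )
  if (nrow(m) == 0L) return(m)
  resolve_overlaps(m)
}

#' Resolve overlapping mentions by longest match
#'
#' Among overlapping candidate mentions the longest span wins (so "natural
#' killer cell" suppresses a nested "killer" cytokine match); ties are broken
#' by earlier start, then by entity type with cell before cytokine. The
#' result has no two overlapping spans and the operation is idempotent.
#'
#' @param mentions Mention data frame as returned by [annotate()].
#' @return Filtered mention data frame sorted by (pmid, start, end).
#' @export
resolve_overlaps <- function(mentions) {
  if (nrow(mentions) <= 1L) return(mentions)
  out <- list()
  for (pm in unique(mentions$pmid)) {
    m <- mentions[mentions$pmid == pm, , drop = FALSE]
    len <- m$end - m$start
    type_rank <- ifelse(m$entity_type == "cell", 0L, 1L)
    ord <- order(-len, m$start, type_rank)
    m <- m[ord, , drop = FALSE]
    kept_start <- integer()
    kept_end <- integer()
    keep <- logical(nrow(m))
    for (j in seq_len(nrow(m))) {
      if (all(m$end[j] <= kept_start | m$start[j] >= kept_end)) {
        keep[j] <- TRUE
        kept_start <- c(kept_start, m$start[j])
        kept_end <- c(kept_end, m$end[j])
      }
    }
    out[[pm]] <- m[keep, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  res <- res[order(res$pmid, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Document-level NER evaluation against an entity reference
#'
#' The reference lists, per document, which canonical entities occur (no
#' offsets — the silver-standard regime), so predicted mentions are collapsed
#' to unique (pmid, entity_type, canonical) triples before counting. A
#' predicted triple is a true positive iff present in the reference.
#'
#' @param predicted Mention data frame (see [annotate()]).
#' @param reference Data frame with columns `pmid`, `entity_type`,
#'   `canonical`.
#' @return List with elements `precision` and `recall`. Both are 1 by
#'   convention when reference and predictions are empty; precision is 0 when
#'   predictions are empty but the reference is not.
#' @export
evaluate_ner <- function(predicted, reference) {
  pred <- unique(df0(pmid = predicted$pmid, entity_type = predicted$entity_type,
                     canonical = predicted$canonical))
  ref <- unique(df0(pmid = reference$pmid, entity_type = reference$entity_type,
                    canonical = reference$canonical))
  key <- function(d) paste(d$pmid, d$entity_type, tolower(d$canonical), sep = "\r")
  tp <- sum(key(pred) %in% key(ref))
  if (nrow(pred) == 0L && nrow(ref) == 0L) return(list(precision = 1, recall = 1))
  precision <- if (nrow(pred) == 0L) 0 else tp / nrow(pred)
  recall <- if (nrow(ref) == 0L) 1 else tp / nrow(ref)
  list(precision = precision, recall = recall)
}

#' Write corpus annotations as TSV
#'
#' One row per mention: pmid, sentence_index, start, end, surface,
#' entity_type, canonical.
#'
#' @param mentions Mention data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(mentions, path) {
  utils::write.table(mentions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
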