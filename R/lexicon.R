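#' Construct a lexicon
#'
#' A lexicon maps every synonym to one canonical reference string (the
#' ontology concept label for cells, the gene/Entrez-style name for
#' cytokines). Lookup is case-insensitive; surface case of the text is
#' irrelevant to normalization.
#'
#' @param synonym Character vector of synonyms (non-empty strings).
#' @param canonical Character vector of canonical names, same length.
#' @param entity_type `"cell"` or `"cytokine"`.
#' @param provenance Free-text source + version string.
#' @return A `ccr_lexicon` (a data frame with columns `synonym`, `canonical`
#'   and attributes `entity_type`, `provenance`).
#' @export
lexicon <- function(synonym, canonical, entity_type = c("cell", "cytokine"),
                    provenance = "unspecified") {
  entity_type <- match.arg(entity_type)
  stopifnot(length(synonym) == length(canonical))
  synonym <- as.character(synonym)
  canonical <- as.character(canonical)
  if (any(!nzchar(trimws(synonym)))) stop("empty synonym in lexicon")
  lex <- df0(synonym = synonym, canonical = canonical)
  # duplicate synonyms (case-insensitive) mapping to different canonicals:
  # keep the lexicographically first canonical, log the conflict
  key <- tolower(lex$synonym)
  ord <- order(key, lex$canonical)
  lex <- lex[ord, , drop = FALSE]
  key <- key[ord]
  dup <- duplicated(key)
  conflict <- dup & !duplicated(df0(k = key, c = lex$canonical))
  if (any(conflict)) {
    message(sprintf(
      "lexicon: %d synonym(s) mapped to multiple canonicals; keeping the lexicographically first (e.g. '%s')",
      sum(conflict), lex$synonym[conflict][1]))
  }
  lex <- lex[!dup, , drop = FALSE]
  rownames(lex) <- NULL
  structure(lex, entity_type = entity_type, provenance = provenance,
            class = c("ccr_lexicon", "data.frame"))
}

#' @export
print.ccr_lexicon <- function(x, ...) {
  cat(sprintf("<%s lexicon> %d synonyms -> %d canonical names (%s)\n",
              attr(x, "entity_type"), nrow(x),
              length(unique(x$canonical)), attr(x, "provenance")))
  invisible(x)
}

#' Case-insensitive canonical lookup
#'
#' @param lex A [lexicon()].
#' @param term Character vector of surface strings.
#' @return Canonical names (`NA` where the term is not in the lexicon).
#' @export
lookup_canonical <- function(lex, term) {
  lex$canonical[match(tolower(term), tolower(lex$synonym))]
}

#' Build a cell lexicon from an OBO ontology file
#'
#' Reads an OBO 1.2/1.4 flat file (e.g. a cell ontology release) and compiles
#' one lexicon entry per primary label and per synonym of every non-obsolete
#' term; the canonical string is always the primary label.
#'
#' @param obo_path Path to the OBO file.
#' @param provenance Source string recorded on the lexicon.
#' @return A `ccr_lexicon` of entity type `"cell"`.
#' @export
build_cell_lexicon <- function(obo_path, provenance = basename(obo_path)) {
  terms <- parse_obo(obo_path)
  terms <- Filter(function(t) !isTRUE(t$obsolete) && nzchar(t$name %||% ""), terms)
  if (length(terms) == 0L) {
    return(lexicon(character(), character(), "cell", provenance))
  }
  syn <- unlist(lapply(terms, function(t) c(t$name, t$synonyms)))
  can <- unlist(lapply(terms, function(t) rep(t$name, 1L + length(t$synonyms))))
  lexicon(syn, can, "cell", provenance)
}

# Minimal OBO flat-file reader: [Term] stanzas with id, name,
# synonym: "text" TYPE [...], is_obsolete.
parse_obo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  terms <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function() if (in_term && !is.null(cur)) terms[[length(terms) + 1L]] <<- cur
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush()
      cur <- list(id = NA_character_, name = "", synonyms = character(),
                  obsolete = FALSE)
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) { # other stanza type
      flush()
      in_term <- FALSE
      cur <- NULL
      next
    }
    if (!in_term || !nzchar(ln)) next
    if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
    else if (grepl("^name:", ln)) cur$name <- trimws(sub("^name:", "", ln))
    else if (grepl("^synonym:", ln)) {
      m <- regmatches(ln, regexec('^synonym:\\s*"((?:[^"\\\\]|\\\\.)*)"', ln))[[1]]
      if (length(m) == 2L) {
        cur$synonyms <- c(cur$synonyms, gsub('\\\\(.)', "\\1", m[2]))
      } else {
        stop("malformed synonym line in OBO file: ", ln)
      }
    } else if (grepl("^is_obsolete:\\s*true", ln)) cur$obsolete <- TRUE
  }
  flush()
  terms
}

#' Build a cytokine lexicon from a synonym registry TSV
#'
#' The registry is a two-column tab-separated file with a header naming the
#' columns `canonical` and `synonym` (any order). The canonical name itself
#' is always added as its own synonym.
#'
#' @param registry_path Path to the TSV registry.
#' @param provenance Source string recorded on the lexicon.
#' @return A `ccr_lexicon` of entity type `"cytokine"`.
#' @export
build_cytokine_lexicon <- function(registry_path,
                                   provenance = basename(registry_path)) {
  tab <- utils::read.delim(registry_path, sep = "\t", header = TRUE,
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) {
    return(lexicon(character(), character(), "cytokine", provenance))
  }
  if (!all(c("canonical", "synonym") %in% names(tab))) {
    stop("registry must have columns 'canonical' and 'synonym'")
  }
  syn <- c(tab$synonym, unique(tab$canonical))
  can <- c(tab$canonical, unique(tab$canonical))
  lexicon(syn, can, "cytokine", provenance)
}

# Irregular plurals common in cell/cytokine nomenclature.
PLURAL_IRREGULAR <- c(
  "analysis" = "analyses", "axis" = "axes", "basis" = "bases",
  "hypothesis" = "hypotheses", "synthesis" = "syntheses",
  "nucleus" = "nuclei", "locus" = "loci", "fungus" = "fungi",
  "stimulus" = "stimuli", "bacterium" = "bacteria", "medium" = "media",
  "ganglion" = "ganglia", "criterion" = "criteria",
  "erythrocyte" = "erythrocytes",
  "leukocyte" = "leukocytes", "lymphocyte" = "lymphocytes",
  "macrophage" = "macrophages", "monocyte" = "monocytes"
)

# Pluralize the final word of a (possibly multi-word) term with English
# inflection rules; used to let "dendritic cells" normalize to the
# "dendritic cell" concept.
pluralize_term <- function(term) {
  vapply(term, function(x) {
    words <- strsplit(x, " ", fixed = TRUE)[[1]]
    last <- words[length(words)]
    low <- tolower(last)
    pl <- if (low %in% names(PLURAL_IRREGULAR)) {
      PLURAL_IRREGULAR[[low]]
    } else if (grepl("[a-z]is$", low)) {
      paste0(substr(last, 1L, nchar(last) - 2L), "es")
    } else if (grepl("(s|x|z|ch|sh)$", low)) {
      paste0(last, "es")
    } else if (grepl("[b-df-hj-np-tv-z]y$", low)) {
      paste0(substr(last, 1L, nchar(last) - 1L), "ies")
    } else {
      paste0(last, "s")
    }
    words[length(words)] <- pl
    paste(words, collapse = " ")
  }, "", USE.NAMES = FALSE)
}

#' Add plural variants of every synonym
#'
#' For each entry a pluralized synonym mapping to the same canonical name is
#' added, so that a plural surface form ("dendritic cells") normalizes to the
#' singular concept ("dendritic cell"). Idempotent: expanding twice adds
#' nothing new.
#'
#' @param lex A [lexicon()].
#' @return The expanded lexicon.
#' @export
expand_plurals <- function(lex) {
  if (nrow(lex) == 0L) return(lex)
  # skip synonyms that already look plural (final word ending in plain "s",
  # not "-is"/"-us"/"-ss") so a second expansion adds nothing
  last_word <- vapply(strsplit(tolower(lex$synonym), " ", fixed = TRUE),
                      function(w) w[length(w)], "")
  already_plural <- grepl("s$", last_word) & !grepl("(is|us|ss)$", last_word)
  plural <- pluralize_term(lex$synonym)
  keep <- !already_plural & !(tolower(plural) %in% tolower(lex$synonym))
  lexicon(c(lex$synonym, plural[keep]), c(lex$canonical, lex$canonical[keep]),
          attr(lex, "entity_type"), attr(lex, "provenance"))
}

#' Bundled list of common English words
#'
#' A curated list of high-frequency English words (including "light" and
#' "killer") used to prune ambiguous single-token synonyms from the cytokine
#' lexicon. Any plain one-word-per-line file can be supplied instead.
#'
#' @param path Path to a word list file; defaults to the bundled list.
#' @return Character vector of lower-case words.
#' @export
common_words <- function(path = system.file("extdata", "common_words.txt",
                                            package = "ccrel")) {
  tolower(trimws(readLines(path, warn = FALSE, encoding = "UTF-8")))
}

#' Remove common-English-word synonyms from a lexicon
#'
#' Single-token synonyms that are ordinary English words ("light", "killer")
#' cause spurious matches in unrelated contexts, so they are dropped.
#' Multi-word synonyms are never filtered (only single tokens can be
#' ambiguous English words), and a synonym that is itself a canonical name of
#' the lexicon is always retained.
#'
#' @param lex A [lexicon()].
#' @param words Character vector of common words (see [common_words()]).
#' @return The filtered lexicon.
#' @export
filter_common_words <- function(lex, words = common_words()) {
  if (nrow(lex) == 0L) return(lex)
  words <- tolower(words)
  single <- !grepl("\\s", lex$synonym)
  is_common <- single & (tolower(lex$synonym) %in% words)
  protected <- tolower(lex$synonym) %in% tolower(lex$canonical)
  drop <- is_common & !protected
  lexicon(lex$synonym[!drop], lex$canonical[!drop],
          attr(lex, "entity_type"), attr(lex, "provenance"))
}

#' Read / write a lexicon as a two-column TSV (synonym, canonical)
#'
#' @param lex A [lexicon()].
#' @param path File path.
#' @param entity_type Entity type when reading.
#' @return `write_lexicon` returns `path` invisibly; `read_lexicon` a lexicon.
#' @export
write_lexicon <- function(lex, path) {
  utils::write.table(as.data.frame(lex)[, c("synonym", "canonical")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path, entity_type = c("cell", "cytokine")) {
  entity_type <- match.arg(entity_type)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  lexicon(tab$synonym, tab$canonical, entity_type, basename(path))
}
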