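#' Construct a document
#'
#' A document is the unit of retrieval and annotation: a PubMed identifier,
#' a title and an abstract, plus (after [segment_sentences()]) a table of
#' sentence spans given as 0-based half-open character offsets into the
#' abstract.
#'
#' @param pmid Character scalar, unique document identifier.
#' @param title Character scalar (may be empty).
#' @param abstract Character scalar, the abstract text.
#' @return An object of class `ccr_document`.
#' @export
document <- function(pmid, title = "", abstract = "") {
  stopifnot(length(pmid) == 1, nchar(pmid) > 0)
  structure(
    list(pmid = as.character(pmid), title = as.character(title),
         abstract = as.character(abstract), sentences = NULL),
    class = "ccr_document"
  )
}

#' @export
print.ccr_document <- function(x, ...) {
  cat(sprintf("<document %s> %d chars, %s sentences\n", x$pmid,
              nchar(x$abstract),
              if (is.null(x$sentences)) "unsegmented" else nrow(x$sentences)))
  invisible(x)
}

new_corpus <- function(docs) {
  pmids <- vapply(docs, `[[`, "", "pmid")
  if (anyDuplicated(pmids)) stop("duplicate pmid in corpus: ",
                                 pmids[duplicated(pmids)][1])
  names(docs) <- pmids
  structure(docs, class = "ccr_corpus")
}

#' @export
print.ccr_corpus <- function(x, ...) {
  cat(sprintf("<corpus> %d documents\n", length(x)))
  invisible(x)
}

#' @export
`[.ccr_corpus` <- function(x, i) {
  new_corpus(unclass(x)[i])
}

#' Load a corpus of abstracts
#'
#' Reads either a JSON-lines file (one object per line with keys `pmid`,
#' `title`, `abstract`) or a Medline/PubMed XML file (`PubmedArticleSet`).
#' Records without an abstract are skipped with a warning; malformed JSONL
#' lines are likewise skipped per record rather than aborting the load.
#'
#' @param path Path to the corpus file.
#' @param format `"jsonl"` or `"medline-xml"`.
#' @return A `ccr_corpus`: a named list of [document()]s keyed by pmid.
#' @seealso [write_corpus()], [segment_sentences()]
#' @export
load_corpus <- function(path, format = c("jsonl", "medline-xml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file not found: ", path)
  docs <- switch(format,
    "jsonl" = load_corpus_jsonl(path),
    "medline-xml" = load_corpus_medline(path)
  )
  corpus <- new_corpus(docs)
  segment_corpus(corpus)
}

load_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  docs <- list()
  skipped <- 0L
  for (ln in lines) {
    rec <- tryCatch(jsonlite::fromJSON(ln), error = function(e) NULL)
    if (is.null(rec) || is.null(rec$pmid) || is.null(rec$abstract) ||
        !nzchar(rec$abstract %||% "")) {
      skipped <- skipped + 1L
      next
    }
    docs[[length(docs) + 1L]] <-
      document(rec$pmid, rec$title %||% "", rec$abstract)
  }
  if (skipped > 0L) {
    warning(sprintf("skipped %d record(s) without a parseable abstract", skipped))
  }
  docs
}

load_corpus_medline <- function(path) {
  xml <- xml2::read_xml(path)
  arts <- xml2::xml_find_all(xml, ".//PubmedArticle")
  docs <- list()
  skipped <- 0L
  for (a in arts) {
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//MedlineCitation/PMID"))
    title <- xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle"))
    abst_nodes <- xml2::xml_find_all(a, ".//Abstract/AbstractText")
    abstract <- paste(xml2::xml_text(abst_nodes), collapse = " ")
    if (!nzchar(pmid) || !nzchar(abstract)) {
      skipped <- skipped + 1L
      next
    }
    docs[[length(docs) + 1L]] <- document(pmid, title, abstract)
  }
  if (skipped > 0L) {
    warning(sprintf("skipped %d record(s) without a parseable abstract", skipped))
  }
  docs
}

#' Write a corpus as JSON-lines
#'
#' @param corpus A `ccr_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (doc in corpus) {
    writeLines(jsonlite::toJSON(
      list(pmid = doc$pmid, title = doc$title, abstract = doc$abstract),
      auto_unbox = TRUE
    ), con)
  }
  invisible(path)
}

# Abbreviations that must not terminate a sentence when followed by a period.
# Tuned to biomedical abstracts.
SENT_ABBREV <- c(
  "fig", "figs", "ref", "refs", "eq", "eqs", "al", "et", "vs", "etc",
  "i.e", "e.g", "i.v", "i.p", "s.c", "p.o", "approx", "ca", "cf",
  "dr", "st", "no", "nr", "vol", "pp", "min", "max", "sp", "spp",
  "subsp", "var", "mol", "wt"
)

#' Segment an abstract into sentences
#'
#' Rule-based splitter: a sentence boundary is a `.`, `!` or `?` followed by
#' whitespace and an upper-case letter, digit or opening bracket, unless the
#' token before the period is a known abbreviation (handles "i.v.", "Fig.",
#' "et al."). Offsets are 0-based half-open on
#' the raw abstract string; spans are trimmed to non-whitespace so that
#' `substr(abstract, start + 1, end)` reproduces the sentence text exactly.
#' When no boundary is found the whole abstract is a single sentence.
#'
#' @param doc A [document()].
#' @return The document with its `sentences` data frame populated
#'   (columns `start`, `end`, `text`).
#' @export
segment_sentences <- function(doc) {
  text <- doc$abstract
  if (!nzchar(trimws(text))) {
    doc$sentences <- df0(start = integer(), end = integer(), text = character())
    return(doc)
  }
  n <- nchar(text)
  # candidate boundaries: terminal punctuation + whitespace + sentence opener
  m <- gregexpr("[.!?]+(?=\\s+[\"'(\\[]?[A-Z0-9])", text, perl = TRUE)[[1]]
  breaks <- integer()
  if (m[1] != -1L) {
    ends <- as.integer(m) + attr(m, "match.length") - 1L # last punct char (1-based)
    for (e in ends) {
      punct <- substr(text, as.integer(e), as.integer(e))
      if (punct == ".") {
        # word immediately before the period
        prefix <- substr(text, max(1L, e - 15L), e - 1L)
        word <- sub(".*?([A-Za-z][A-Za-z.]*)$", "\\1", prefix)
        w <- tolower(sub("\\.$", "", word))
        if (w %in% SENT_ABBREV) next
      }
      breaks <- c(breaks, e)
    }
  }
  bounds <- c(0L, breaks, n) # 0-based cut points (end of sentence inclusive)
  starts0 <- bounds[-length(bounds)]
  ends0 <- bounds[-1L]
  out <- list()
  for (i in seq_along(starts0)) {
    s <- starts0[i] # 0-based start candidate
    e <- ends0[i]   # 0-based exclusive end candidate
    seg <- substr(text, s + 1L, e)
    # trim to non-whitespace, keeping offsets on the raw string
    lead <- nchar(seg) - nchar(sub("^\\s+", "", seg))
    trail <- nchar(seg) - nchar(sub("\\s+$", "", seg))
    s2 <- s + lead
    e2 <- e - trail
    if (e2 > s2) {
      out[[length(out) + 1L]] <-
        df0(start = s2, end = e2, text = substr(text, s2 + 1L, e2))
    }
  }
  sents <- if (length(out)) do.call(rbind, out) else
    df0(start = 0L, end = n, text = text)
  doc$sentences <- sents
  doc
}

#' Segment every document of a corpus
#'
#' @param corpus A `ccr_corpus`.
#' @return The corpus with sentences populated in each document.
#' @export
segment_corpus <- function(corpus) {
  new_corpus(lapply(corpus, segment_sentences))
}

#' Fetch abstracts from PubMed into a local JSONL corpus (thin, cached)
#'
#' Convenience wrapper over the NCBI E-utilities. Results are cached under
#' `cache_dir`, keyed by query and date range; a repeated call with the same
#' arguments reads the cache and performs no network access. All package
#' tests run on local files only.
#'
#' @param query PubMed query string (e.g. a MeSH term).
#' @param date_range Character vector of length 2, `c("YYYY/MM", "YYYY/MM")`,
#'   or `NULL` for no date restriction.
#' @param cache_dir Writable directory for cached downloads.
#' @param retmax Maximum number of records to retrieve.
#' @return Path to a JSONL corpus file loadable by [load_corpus()].
#' @export
fetch_pubmed <- function(query, date_range = NULL, cache_dir = tempdir(),
                         retmax = 10000L) {
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  key <- paste(gsub("[^A-Za-z0-9]+", "_", query),
               paste(gsub("[^0-9]", "", date_range %||% "any"), collapse = "-"),
               sep = "_")
  out <- file.path(cache_dir, paste0(key, ".jsonl"))
  if (file.exists(out)) return(out)
  base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils"
  dr <- if (!is.null(date_range)) {
    sprintf("&mindate=%s&maxdate=%s&datetype=pdat",
            utils::URLencode(date_range[1]), utils::URLencode(date_range[2]))
  } else ""
  esearch <- sprintf("%s/esearch.fcgi?db=pubmed&term=%s&retmax=%d%s",
                     base, utils::URLencode(query, reserved = TRUE), retmax, dr)
  sx <- tempfile(fileext = ".xml")
  utils::download.file(esearch, sx, quiet = TRUE)
  ids <- xml2::xml_text(xml2::xml_find_all(xml2::read_xml(sx), ".//IdList/Id"))
  if (length(ids) == 0L) {
    file.create(out)
    return(out)
  }
  efetch <- sprintf("%s/efetch.fcgi?db=pubmed&id=%s&rettype=abstract&retmode=xml",
                    base, paste(ids, collapse = ","))
  fx <- tempfile(fileext = ".xml")
  utils::download.file(efetch, fx, quiet = TRUE)
  corpus <- new_corpus(load_corpus_medline(fx))
  write_corpus(corpus, out)
  out
}
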