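#' Generate sentence-level cell-cytokine co-occurrence instances
#'
#' For every sentence, the full Cartesian product of its cell mentions and
#' cytokine mentions yields one instance each; pairs never cross sentence
#' boundaries. Mentions must already be overlap-resolved.
#'
#' @param mentions Overlap-resolved mention data frame (whole corpus or one
#'   document; see [annotate_corpus()]).
#' @return Instance data frame with columns `cell`, `cytokine`, `pmid`,
#'   `sentence_index`, and the character offsets of both mentions.
#' @export
generate_instances <- function(mentions) {
  if (nrow(mentions) == 0L) return(empty_instances())
  out <- list()
  grp <- split(mentions, paste(mentions$pmid, mentions$sentence_index, sep = "\r"))
  for (m in grp) {
    cells <- m[m$entity_type == "cell", , drop = FALSE]
    cyts <- m[m$entity_type == "cytokine", , drop = FALSE]
    if (nrow(cells) == 0L || nrow(cyts) == 0L) next
    idx <- expand.grid(i = seq_len(nrow(cells)), j = seq_len(nrow(cyts)))
    # overlap between the two mentions is impossible after resolution
    stopifnot(all(cells$end[idx$i] <= cyts$start[idx$j] |
                  cyts$end[idx$j] <= cells$start[idx$i]))
    out[[length(out) + 1L]] <- df0(
      cell = cells$canonical[idx$i], cytokine = cyts$canonical[idx$j],
      pmid = cells$pmid[idx$i], sentence_index = cells$sentence_index[idx$i],
      cell_start = cells$start[idx$i], cell_end = cells$end[idx$i],
      cytokine_start = cyts$start[idx$j], cytokine_end = cyts$end[idx$j]
    )
  }
  if (length(out) == 0L) return(empty_instances())
  res <- do.call(rbind, out)
  res <- res[order(res$pmid, res$sentence_index, res$cell_start,
                   res$cytokine_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

pair_key <- function(cell, cytokine) paste(cell, cytokine, sep = " | ")

#' Group instances into corpus-level bags
#'
#' One bag per distinct (cell, cytokine) pair across the whole corpus;
#' instances are partitioned among bags and labels start as `"unlabeled"`.
#'
#' @param instances Instance data frame from [generate_instances()].
#' @return A `ccr_bags` object: a list of bags, each with fields `cell`,
#'   `cytokine`, `instances` (data frame), `label`, `docs` (supporting
#'   pmids).
#' @export
build_bags <- function(instances) {
  if (nrow(instances) == 0L) {
    return(structure(list(), class = "ccr_bags"))
  }
  keys <- pair_key(instances$cell, instances$cytokine)
  groups <- split(seq_len(nrow(instances)), keys)
  bags <- lapply(groups, function(ix) {
    inst <- instances[ix, , drop = FALSE]
    rownames(inst) <- NULL
    list(cell = inst$cell[1], cytokine = inst$cytokine[1],
         instances = inst, label = "unlabeled",
         docs = sort(unique(inst$pmid)))
  })
  bags <- bags[order(names(bags))]
  structure(bags, class = "ccr_bags")
}

#' @export
print.ccr_bags <- function(x, ...) {
  labs <- vapply(x, `[[`, "", "label")
  cat(sprintf("<bags> %d pairs (%d positive, %d negative, %d unlabeled), %d instances\n",
              length(x), sum(labs == "positive"), sum(labs == "negative"),
              sum(labs == "unlabeled"),
              sum(vapply(x, function(b) nrow(b$instances), 1L))))
  invisible(x)
}

#' Read a reference relation database (TSV: cell<TAB>cytokine)
#'
#' @param path TSV path with a header row `cell`, `cytokine`.
#' @param provenance Source string.
#' @return A `ccr_refdb`: data frame of unique pairs with a provenance
#'   attribute.
#' @export
read_reference_db <- function(path, provenance = basename(path)) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  reference_db(tab$cell, tab$cytokine, provenance)
}

#' Construct a reference relation database in memory
#'
#' @param cell,cytokine Character vectors of canonical names.
#' @param provenance Source string.
#' @rdname read_reference_db
#' @export
reference_db <- function(cell, cytokine, provenance = "unspecified") {
  db <- unique(df0(cell = as.character(cell), cytokine = as.character(cytokine)))
  rownames(db) <- NULL
  structure(db, provenance = provenance, class = c("ccr_refdb", "data.frame"))
}

#' @export
print.ccr_refdb <- function(x, ...) {
  cat(sprintf("<reference db> %d cell-cytokine relations (%s)\n", nrow(x),
              attr(x, "provenance")))
  invisible(x)
}

#' Write a reference database TSV
#' @param db A `ccr_refdb`.
#' @param path Output path.
#' @export
write_reference_db <- function(db, path) {
  utils::write.table(as.data.frame(db), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Label bags by distant supervision
#'
#' A bag is labeled positive iff its (cell, cytokine) pair has an entry in
#' the reference database, negative otherwise — no sentence-level annotation
#' is used. A warning is issued for bag entities found in neither the
#' database nor the supplied lexicons (a canonical-namespace mismatch).
#'
#' @param bags A `ccr_bags` object.
#' @param db A reference database ([reference_db()]).
#' @param lexicons Optional list of lexicons used to detect namespace
#'   mismatches.
#' @return The bags with labels set to `"positive"` / `"negative"`.
#' @export
label_bags <- function(bags, db, lexicons = NULL) {
  db_keys <- pair_key(db$cell, db$cytokine)
  known <- unique(c(db$cell, db$cytokine,
                    unlist(lapply(lexicons, function(l) l$canonical))))
  unknown <- character()
  out <- lapply(bags, function(b) {
    b$label <- if (pair_key(b$cell, b$cytokine) %in% db_keys) "positive" else "negative"
    if (!is.null(lexicons)) {
      for (ent in c(b$cell, b$cytokine)) {
        if (!(ent %in% known)) unknown <<- c(unknown, ent)
      }
    }
    b
  })
  if (length(unknown)) {
    warning("bag entities absent from reference db and lexicons: ",
            paste(unique(unknown), collapse = ", "))
  }
  structure(out, class = "ccr_bags")
}

#' Pair frequency score
#'
#' The number of abstracts in which the pair co-occurs within a sentence,
#' divided by the total number of abstracts in the corpus — the non-learning
#' baseline ranking for pairs.
#'
#' @param bag A single bag from [build_bags()].
#' @param corpus_size Total number of abstracts in the corpus.
#' @return Scalar in `[0, 1]`.
#' @export
pair_frequency <- function(bag, corpus_size) {
  if (corpus_size <= 0) stop("corpus_size must be positive")
  n <- length(bag$docs)
  if (corpus_size < n) stop("corpus_size smaller than number of supporting documents")
  n / corpus_size
}

#' Serialize / load bags as JSON-lines
#'
#' One JSON object per bag: `cell`, `cytokine`, `label`, and the list of
#' instances as (pmid, sentence_index, offsets).
#'
#' @param bags A `ccr_bags` object.
#' @param path File path.
#' @return `write_bags` returns `path` invisibly; `read_bags` a `ccr_bags`.
#' @export
write_bags <- function(bags, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (b in bags) {
    writeLines(jsonlite::toJSON(
      list(cell = b$cell, cytokine = b$cytokine, label = b$label,
           instances = b$instances),
      auto_unbox = TRUE, dataframe = "rows"
    ), con)
  }
  invisible(path)
}

#' @rdname write_bags
#' @export
read_bags <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  bags <- lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln)
    inst <- as.data.frame(rec$instances, stringsAsFactors = FALSE)
    list(cell = rec$cell, cytokine = rec$cytokine, instances = inst,
         label = rec$label, docs = sort(unique(inst$pmid)))
  })
  names(bags) <- vapply(bags, function(b) pair_key(b$cell, b$cytokine), "")
  structure(bags[order(names(bags))], class = "ccr_bags")
}
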