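# The knowledge graph: an undirected bipartite simple graph whose edges are
# cell-cytokine relations with a classifier confidence, a pair frequency and
# sentence-level evidence.

#' Build the cell-cytokine knowledge graph from scored bags
#'
#' One edge per bag with confidence at or above the threshold; the node set
#' consists of the endpoints of included edges, and each edge carries all
#' supporting (pmid, sentence) evidence. The graph is bipartite (cell vs
#' cytokine), undirected and simple by construction.
#'
#' @param scores A [score_bags()] result (with its `"bags"` attribute).
#' @param corpus The segmented corpus, used to recover sentence text.
#' @param threshold Minimum confidence for inclusion.
#' @return An object of class `ccr_graph`: list with `edges` (data frame:
#'   cell, cytokine, confidence, frequency, n_sentences) and `evidence`
#'   (data frame: cell, cytokine, pmid, sentence).
#' @export
build_graph <- function(scores, corpus, threshold) {
  bags <- attr(scores, "bags")
  keep <- scores$confidence >= threshold
  edges <- scores[keep, c("cell", "cytokine", "confidence", "frequency"),
                  drop = FALSE]
  rownames(edges) <- NULL
  ev <- list()
  for (i in which(keep)) {
    b <- bags[[pair_key(scores$cell[i], scores$cytokine[i])]]
    inst <- unique(b$instances[, c("pmid", "sentence_index")])
    ev[[length(ev) + 1L]] <- df0(
      cell = b$cell, cytokine = b$cytokine, pmid = inst$pmid,
      sentence = vapply(seq_len(nrow(inst)), function(j) {
        corpus[[inst$pmid[j]]]$sentences$text[inst$sentence_index[j]]
      }, "")
    )
  }
  evidence <- if (length(ev)) do.call(rbind, ev) else
    df0(cell = character(), cytokine = character(), pmid = character(),
        sentence = character())
  rownames(evidence) <- NULL
  if (nrow(edges)) {
    ek <- pair_key(edges$cell, edges$cytokine)
    ns <- table(pair_key(evidence$cell, evidence$cytokine))
    edges$n_sentences <- as.integer(ns[ek])
    stopifnot(all(edges$n_sentences >= 1L))
  } else {
    edges$n_sentences <- integer()
  }
  knowledge_graph(edges, evidence)
}

#' Construct a knowledge graph from edge and evidence tables
#'
#' @param edges Data frame with at least `cell` and `cytokine` columns
#'   (optionally `confidence`, `frequency`, `n_sentences`).
#' @param evidence Optional data frame of (cell, cytokine, pmid, sentence)
#'   rows.
#' @return A `ccr_graph`.
#' @export
knowledge_graph <- function(edges, evidence = NULL) {
  stopifnot(all(c("cell", "cytokine") %in% names(edges)))
  if (anyDuplicated(pair_key(edges$cell, edges$cytokine))) {
    stop("duplicate edge: the knowledge graph is simple")
  }
  both <- intersect(unique(edges$cell), unique(edges$cytokine))
  if (length(both)) {
    stop("graph is not bipartite: node(s) typed both cell and cytokine: ",
         paste(both, collapse = ", "))
  }
  structure(list(edges = edges, evidence = evidence), class = "ccr_graph")
}

#' @export
print.ccr_graph <- function(x, ...) {
  cat(sprintf("<knowledge graph> %d cells + %d cytokines, %d edges\n",
              length(unique(x$edges$cell)), length(unique(x$edges$cytokine)),
              nrow(x$edges)))
  invisible(x)
}

#' Convert the knowledge graph to an igraph object
#'
#' Nodes carry a `type` attribute (`"cell"` / `"cytokine"`); edges carry
#' `confidence` and `frequency` when available.
#'
#' @param g A `ccr_graph`.
#' @return An undirected [igraph::graph].
#' @export
as_igraph <- function(g) {
  e <- g$edges
  nodes <- df0(
    name = c(unique(e$cell), unique(e$cytokine)),
    type = c(rep("cell", length(unique(e$cell))),
             rep("cytokine", length(unique(e$cytokine))))
  )
  edge_attrs <- e[, intersect(c("confidence", "frequency", "n_sentences"),
                              names(e)), drop = FALSE]
  igraph::graph_from_data_frame(
    cbind(df0(from = e$cell, to = e$cytokine), edge_attrs),
    directed = FALSE, vertices = nodes
  )
}

#' Structural statistics of the knowledge graph
#'
#' Node/edge counts by type, the diameter and center of the largest connected
#' component (the center is the set of nodes whose eccentricity equals the
#' radius), and the mean number of supporting sentences per edge.
#'
#' @param g A `ccr_graph` with at least one edge.
#' @return List with `n_nodes`, `n_cells`, `n_cytokines`, `n_edges`,
#'   `diameter`, `center_nodes`, `mean_sentences_per_edge`.
#' @export
graph_stats <- function(g) {
  if (nrow(g$edges) == 0L) stop("empty graph")
  ig <- as_igraph(g)
  comp <- igraph::components(ig)
  main <- igraph::induced_subgraph(ig, which(comp$membership ==
                                             which.max(comp$csize)))
  ecc <- igraph::eccentricity(main)
  list(
    n_nodes = as.integer(igraph::vcount(ig)),
    n_cells = as.integer(sum(igraph::V(ig)$type == "cell")),
    n_cytokines = as.integer(sum(igraph::V(ig)$type == "cytokine")),
    n_edges = as.integer(igraph::ecount(ig)),
    diameter = max(ecc),
    center_nodes = sort(names(ecc)[ecc == min(ecc)]),
    mean_sentences_per_edge = if ("n_sentences" %in% names(g$edges)) {
      mean(g$edges$n_sentences)
    } else if (!is.null(g$evidence)) {
      nrow(g$evidence) / nrow(g$edges)
    } else {
      NA_real_
    }
  )
}

#' Pearson correlation between edge confidence and evidence count
#'
#' @param g A `ccr_graph` whose edges carry `confidence` and `n_sentences`.
#' @return Pearson product-moment correlation, or `NA` with a warning when
#'   either variable is constant (undefined correlation).
#' @export
confidence_evidence_correlation <- function(g) {
  e <- g$edges
  if (nrow(e) < 2L) stop("need at least 2 edges")
  if (stats::sd(e$confidence) == 0 || stats::sd(e$n_sentences) == 0) {
    warning("constant input: correlation undefined")
    return(NA_real_)
  }
  stats::cor(e$confidence, e$n_sentences, method = "pearson")
}

#' Categorize edges by novelty relative to a reference graph
#'
#' Each edge of `g` is assigned to exactly one of four categories by exact
#' canonical node-name matching: (i) present in the reference graph, (ii)
#' both nodes present but not connected there, (iii) exactly one node
#' present, (iv) neither node present. Counts always sum to the number of
#' edges of `g`. Node-name mismatches that look like unreconciled synonyms
#' are a known failure mode of exact matching and are left to the caller's
#' inspection.
#'
#' @param g,ref `ccr_graph` objects (or data frames with `cell`/`cytokine`).
#' @return List with `table` (data frame of category counts) and `category`
#'   (factor per edge of `g`).
#' @export
compare_graphs <- function(g, ref) {
  edges <- if (inherits(g, "ccr_graph")) g$edges else g
  redges <- if (inherits(ref, "ccr_graph")) ref$edges else ref
  ref_keys <- pair_key(redges$cell, redges$cytokine)
  ref_nodes <- unique(c(redges$cell, redges$cytokine))
  in_ref_edge <- pair_key(edges$cell, edges$cytokine) %in% ref_keys
  cell_known <- edges$cell %in% ref_nodes
  cyt_known <- edges$cytokine %in% ref_nodes
  lev <- c("shared_edge", "new_edge_known_nodes", "one_new_node",
           "two_new_nodes")
  category <- factor(ifelse(in_ref_edge, lev[1],
                     ifelse(cell_known & cyt_known, lev[2],
                     ifelse(cell_known | cyt_known, lev[3], lev[4]))),
                     levels = lev)
  tab <- df0(category = lev, n = as.integer(table(category)))
  stopifnot(sum(tab$n) == nrow(edges))
  list(table = tab, category = category)
}

#' Export the knowledge graph to files
#'
#' `edges.tsv`: one row per edge with cell, cytokine, confidence, frequency
#' and the semicolon-joined supporting pmids. `evidence.tsv`: one row per
#' (edge, pmid, sentence). `graph.graphml`: loadable by standard graph tools,
#' with the node `type` attribute.
#'
#' @param g A `ccr_graph`.
#' @param dir Output directory (created if absent).
#' @param formats Subset of `c("edge-tsv", "evidence-tsv", "graphml")`.
#' @return Named character vector of written paths, invisibly.
#' @export
export_graph <- function(g, dir,
                         formats = c("edge-tsv", "evidence-tsv", "graphml")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  if ("edge-tsv" %in% formats) {
    e <- g$edges
    pmids <- rep("", nrow(e))
    if (!is.null(g$evidence) && nrow(e)) {
      ek <- pair_key(e$cell, e$cytokine)
      evk <- pair_key(g$evidence$cell, g$evidence$cytokine)
      pmids <- vapply(ek, function(k) {
        paste(sort(unique(g$evidence$pmid[evk == k])), collapse = ";")
      }, "")
    }
    path <- file.path(dir, "edges.tsv")
    utils::write.table(cbind(e, df0(pmids = pmids)), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written["edge-tsv"] <- path
  }
  if ("evidence-tsv" %in% formats) {
    path <- file.path(dir, "evidence.tsv")
    ev <- g$evidence %||% df0(cell = character(), cytokine = character(),
                              pmid = character(), sentence = character())
    utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written["evidence-tsv"] <- path
  }
  if ("graphml" %in% formats) {
    path <- file.path(dir, "graph.graphml")
    if (nrow(g$edges)) {
      igraph::write_graph(as_igraph(g), path, format = "graphml")
    } else {
      igraph::write_graph(igraph::make_empty_graph(directed = FALSE), path,
                          format = "graphml")
    }
    written["graphml"] <- path
  }
  invisible(written)
}

#' Read a reference graph from an edge TSV (cell<TAB>cytokine, header row)
#'
#' Multi-edges are collapsed: the reference graph is simplified to an
#' undirected simple graph regardless of direction/sentiment attributes in
#' the source.
#'
#' @param path TSV path.
#' @return A `ccr_graph` with edges only.
#' @export
read_reference_graph <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  edges <- unique(df0(cell = tab$cell, cytokine = tab$cytokine))
  rownames(edges) <- NULL
  knowledge_graph(edges)
}
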