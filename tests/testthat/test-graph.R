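edges_df <- function(cell, cytokine, confidence = 0.9, frequency = 0.1,
                     n_sentences = 1L) {
  n <- max(length(cell), length(cytokine))
  data.frame(cell = rep_len(cell, n), cytokine = rep_len(cytokine, n),
             confidence = rep_len(confidence, n),
             frequency = rep_len(frequency, n),
             n_sentences = rep_len(n_sentences, n),
             stringsAsFactors = FALSE)
}

scored_fixture <- function(seed = 30, n_docs = 40) {
  bundle <- small_bundle(seed = seed, n_docs = n_docs)
  mentions <- annotate_corpus(bundle$corpus, expand_plurals(bundle$cells),
                              bundle$cytokines)
  fit <- train_pair_classifier(bundle$corpus, mentions, bundle$db)
  scores <- score_bags(fit, bundle$corpus, mentions)
  list(bundle = bundle, scores = scores)
}

test_that("graph construction filters by threshold and carries evidence", {
  fx <- scored_fixture()
  g <- build_graph(fx$scores, fx$bundle$corpus, threshold = 1.01)
  expect_identical(nrow(g$edges), 0L)

  thr <- stats::median(fx$scores$confidence)
  g2 <- build_graph(fx$scores, fx$bundle$corpus, thr)
  # edge set equals a brute-force filter of the score table
  expect_setequal(paste(g2$edges$cell, g2$edges$cytokine),
                  with(fx$scores[fx$scores$confidence >= thr, ],
                       paste(cell, cytokine)))
  expect_true(all(g2$edges$n_sentences >= 1L))
  # raising the threshold never adds an edge
  g3 <- build_graph(fx$scores, fx$bundle$corpus, thr + 0.05)
  expect_true(all(paste(g3$edges$cell, g3$edges$cytokine) %in%
                  paste(g2$edges$cell, g2$edges$cytokine)))
  # evidence sentences contain both canonical mentions somewhere in the corpus
  expect_true(all(nchar(g2$evidence$sentence) > 0))
})

test_that("the graph container enforces bipartite simple structure", {
  expect_error(knowledge_graph(edges_df(c("a", "a"), c("x", "x"))), "simple")
  expect_error(knowledge_graph(edges_df(c("a", "x"), c("x", "b"))),
               "bipartite")
})

test_that("graph statistics match closed-form values on path and star graphs", {
  # path c1 - k1 - c2 - k2: diameter 3, center = the middle two nodes
  path <- knowledge_graph(edges_df(c("c1", "c2", "c2"), c("k1", "k1", "k2")))
  st <- graph_stats(path)
  expect_identical(st$n_nodes, 4L)
  expect_identical(st$n_edges, 3L)
  expect_equal(st$diameter, 3)
  expect_setequal(st$center_nodes, c("k1", "c2"))

  # star: hub cytokine with 3 cells -> diameter 2, center = hub
  star <- knowledge_graph(edges_df(c("c1", "c2", "c3"), "hub"))
  st2 <- graph_stats(star)
  expect_equal(st2$diameter, 2)
  expect_identical(st2$center_nodes, "hub")
  expect_equal(st2$mean_sentences_per_edge, 1)
  expect_error(graph_stats(knowledge_graph(edges_df(character(), character()))),
               "empty")
})

test_that("diameter and center match a Floyd-Warshall oracle on random bipartite graphs", {
  set.seed(77)
  for (trial in 1:10) {
    nc <- sample(3:8, 1); nk <- sample(3:8, 1)
    ne <- sample(5:(nc * nk), 1)
    pairs <- expand.grid(cell = sprintf("c%d", 1:nc),
                         cytokine = sprintf("k%d", 1:nk),
                         stringsAsFactors = FALSE)
    e <- pairs[sample(nrow(pairs), ne), ]
    g <- knowledge_graph(edges_df(e$cell, e$cytokine))
    st <- graph_stats(g)
    d <- fw_oracle(e)
    # restrict the oracle to the largest connected component
    finite <- is.finite(d)
    comp_sizes <- rowSums(finite)
    main <- comp_sizes == max(comp_sizes)
    dmain <- d[main, main, drop = FALSE]
    expect_equal(st$diameter, max(dmain))
    ecc <- apply(dmain, 1, max)
    expect_setequal(st$center_nodes, names(ecc)[ecc == min(ecc)])
  }
})

test_that("confidence-evidence correlation is the Pearson formula", {
  g <- knowledge_graph(edges_df(sprintf("c%d", 1:5), "k",
                                confidence = c(1, 2, 3, 4, 5) / 10,
                                n_sentences = 1:5))
  expect_equal(confidence_evidence_correlation(g), 1.0)
  g2 <- knowledge_graph(edges_df(sprintf("c%d", 1:5), "k",
                                 confidence = c(5, 4, 3, 2, 1) / 10,
                                 n_sentences = 1:5))
  expect_equal(confidence_evidence_correlation(g2), -1.0)
  # 10 synthetic edges vs the textbook formula
  set.seed(3)
  conf <- stats::runif(10); ns <- sample(1:6, 10, replace = TRUE)
  g3 <- knowledge_graph(edges_df(sprintf("c%d", 1:10), "k",
                                 confidence = conf, n_sentences = ns))
  hand <- sum((conf - mean(conf)) * (ns - mean(ns))) /
    sqrt(sum((conf - mean(conf))^2) * sum((ns - mean(ns))^2))
  expect_equal(confidence_evidence_correlation(g3), hand, tolerance = 1e-12)
  gc <- knowledge_graph(edges_df(c("c1", "c2"), "k", confidence = 0.5,
                                 n_sentences = 2L))
  expect_warning(expect_true(is.na(confidence_evidence_correlation(gc))),
                 "constant")
})

test_that("novelty categories partition the edges", {
  ref <- knowledge_graph(edges_df(c("c1", "c2"), c("k1", "k2")))
  # identical graphs: everything shared
  cmp <- compare_graphs(ref, ref)
  expect_identical(cmp$table$n, c(2L, 0L, 0L, 0L))
  # empty reference: both nodes new everywhere
  empty_ref <- knowledge_graph(edges_df(character(), character()))
  cmp2 <- compare_graphs(ref, empty_ref)
  expect_identical(cmp2$table$n, c(0L, 0L, 0L, 2L))
  # constructed example with exactly two edges per category
  g <- knowledge_graph(edges_df(
    cell = c("c1", "c2", "c1", "c2", "c1", "c3", "c4", "c5"),
    cytokine = c("k1", "k2", "k2", "k1", "k9", "k1", "k8", "k7")
  ))
  cmp3 <- compare_graphs(g, ref)
  expect_identical(cmp3$table$n, c(2L, 2L, 2L, 2L))
  expect_identical(sum(cmp3$table$n), nrow(g$edges))
  expect_identical(length(cmp3$category), nrow(g$edges))
})

test_that("graph export writes the documented tables and loadable graphml", {
  fx <- scored_fixture(seed = 33, n_docs = 30)
  g <- build_graph(fx$scores, fx$bundle$corpus,
                   stats::median(fx$scores$confidence))
  d <- withr::local_tempdir()
  paths <- export_graph(g, d)
  expect_true(all(file.exists(paths)))
  # edge table row count and evidence row arithmetic
  etab <- utils::read.delim(paths["edge-tsv"])
  expect_identical(nrow(etab), nrow(g$edges))
  evtab <- utils::read.delim(paths["evidence-tsv"])
  expect_identical(nrow(evtab), nrow(g$evidence))
  # graphml round-trip: isomorphic with preserved types
  ig <- igraph::read_graph(paths["graphml"], format = "graphml")
  expect_true(igraph::isomorphic(ig, as_igraph(g)))
  expect_setequal(igraph::V(ig)$type, c("cell", "cytokine"))
  # empty graph: header-only files
  g0 <- knowledge_graph(edges_df(character(), character()))
  d0 <- withr::local_tempdir()
  p0 <- export_graph(g0, d0)
  expect_identical(nrow(utils::read.delim(p0["edge-tsv"])), 0L)
})

test_that("evidence rows: a 3-edge graph with 2-document evidence on one edge has 4 rows", {
  edges <- edges_df(c("c1", "c2", "c3"), "k", n_sentences = c(2L, 1L, 1L))
  ev <- data.frame(
    cell = c("c1", "c1", "c2", "c3"), cytokine = "k",
    pmid = c("p1", "p2", "p3", "p4"),
    sentence = "supporting sentence", stringsAsFactors = FALSE
  )
  g <- knowledge_graph(edges, ev)
  d <- withr::local_tempdir()
  paths <- export_graph(g, d, formats = c("evidence-tsv"))
  expect_identical(nrow(utils::read.delim(paths["evidence-tsv"])), 4L)
})
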