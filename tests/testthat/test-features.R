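make_instance <- function(doc, cell_canonical, cytokine_canonical, mentions) {
  inst <- generate_instances(mentions)
  inst[inst$cell == cell_canonical & inst$cytokine == cytokine_canonical, ,
       drop = FALSE]
}

test_that("tokenizer keeps hyphenated tokens whole and reports 0-based offsets", {
  t <- tokenize("IL-6 level, CD40-ligand!")
  expect_identical(t$token, c("IL-6", "level", "CD40-ligand"))
  expect_identical(t$start, c(0L, 5L, 12L))
  expect_identical(substring("IL-6 level, CD40-ligand!", t$start + 1, t$end),
                   t$token)
  expect_identical(nrow(tokenize("...")), 0L)
})

test_that("lemmatizer normalizes inflectional variants and passes unknowns through", {
  expect_identical(lemmatize(c("cells", "Was", "secretes", "induces")),
                   c("cell", "be", "secrete", "induce"))
  expect_identical(lemmatize("stimulated"), "stimulat")
  expect_identical(lemmatize(c("IL-6", "p70")), c("il-6", "p70"))
  # inflected variants of one root map to one feature
  expect_identical(lemmatize("triggered"), lemmatize("triggering"))
})

ctx_fixture <- function(text, lexes) {
  doc <- make_doc("d", text)
  mentions <- annotate_corpus(ccrel:::new_corpus(list(doc)),
                              lexes$cell, lexes$cyt)
  list(doc = doc, mentions = mentions,
       instances = generate_instances(mentions))
}

toy_lexes <- function() {
  list(cell = lexicon(c("T cell", "B cell"), c("T cell", "B cell"), "cell"),
       cyt = lexicon(c("IL2", "IL9"), c("IL2", "IL9"), "cytokine"))
}

test_that("context window truncates at sentence boundaries", {
  fx <- ctx_fixture("T cell responses require IL2 signaling always.", toy_lexes())
  inst <- fx$instances[1, ]
  sent <- fx$doc$sentences[1, ]
  ctx <- extract_context(inst, sent, fx$mentions, window = 3)
  # entity at sentence start: no left context for the cell; the pair's own
  # entity tokens inside the partner's window surface as placeholders
  expect_setequal(ctx, c("CELL", "response", "require", "CYTOKINE",
                         "signal", "alway"))
})

test_that("a third entity inside the window becomes its type placeholder", {
  fx <- ctx_fixture("Activated T cell and B cell populations released IL2 today.",
                    toy_lexes())
  inst <- fx$instances[fx$instances$cell == "T cell", ]
  ctx <- extract_context(inst, fx$doc$sentences[1, ], fx$mentions, window = 3)
  expect_true("CELL" %in% ctx)              # the B cell mention, masked
  expect_false(any(c("b") %in% ctx))        # not its surface lemma
})

test_that("overlapping windows of the two entities count positions once", {
  fx <- ctx_fixture("Resting T cell secreted IL2 rapidly today.", toy_lexes())
  inst <- fx$instances[1, ]
  ctx <- extract_context(inst, fx$doc$sentences[1, ], fx$mentions, window = 3)
  # positional enumeration: tokens are [Resting, T, cell, secreted, IL2,
  # rapidly, today]; cell window = positions {1,4,5,6}, cytokine window =
  # positions {2,3,4,6,7}; the union counts 'secreted' and 'rapidly' once,
  # and entity tokens surface as one placeholder per token position
  expect_identical(sort(ctx), sort(c("rest", "CELL", "CELL", "secret",
                                     "CYTOKINE", "rapidly", "today")))
})

test_that("vocabulary fitting applies the idf formula and min_df pruning", {
  # token in every document: retained with idf exactly 1
  tl <- list(c("alpha", "beta"), c("alpha"), c("alpha", "gamma"))
  v <- fit_vocabulary(tl, c("d1", "d2", "d3"), min_df = 0)
  expect_identical(v$terms, c("alpha", "beta", "gamma"))
  expect_equal(v$idf[v$terms == "alpha"], 1.0)
  expect_equal(v$idf[v$terms == "beta"], log(3 / 1) + 1)

  # a token in 1 of 200 documents is pruned at min_df = 0.01
  tl2 <- c(list(c("common", "rare")), replicate(199, "common", simplify = FALSE))
  v2 <- fit_vocabulary(tl2, sprintf("d%03d", 1:200), min_df = 0.01)
  expect_identical(v2$terms, "common")
  # threshold 0 keeps everything observed
  v3 <- fit_vocabulary(tl2, sprintf("d%03d", 1:200), min_df = 0)
  expect_setequal(v3$terms, c("common", "rare"))
  expect_error(fit_vocabulary(list(), character()), "no instances")
})

test_that("document frequency counts documents, not instances", {
  tl <- list(c("dup"), c("dup"), c("other"))
  v <- fit_vocabulary(tl, c("d1", "d1", "d2"), min_df = 0)
  expect_identical(v$df[v$terms == "dup"], 1L)
  expect_identical(v$n_docs, 2L)
})

test_that("vectorization is tf x idf with L2 normalization", {
  v <- fit_vocabulary(list("a", "b", c("a", "c")), c("1", "2", "3"), min_df = 0)
  # all tokens out-of-vocabulary: zero vector
  x <- vectorize(list(c("zzz")), v)
  expect_equal(Matrix::rowSums(x^2)[1], 0)
  # single in-vocabulary token: unit vector on that coordinate
  x1 <- vectorize(list("b"), v)
  expect_equal(as.numeric(x1[1, "b"]), 1)
  expect_equal(sum(x1[1, ]^2), 1)
  # three-token example against hand arithmetic
  x2 <- vectorize(list(c("a", "a", "c")), v)
  idf_a <- v$idf[v$terms == "a"]; idf_c <- v$idf[v$terms == "c"]
  raw <- c(2 * idf_a, idf_c)
  expected <- raw / sqrt(sum(raw^2))
  expect_equal(as.numeric(x2[1, c("a", "c")]), expected, tolerance = 1e-12)
  expect_equal(as.numeric(x2[1, "b"]), 0)
})

test_that("vectors are non-negative with L2 norm 0 or 1; vocabulary is frozen", {
  bundle <- small_bundle(seed = 17, n_docs = 20)
  mentions <- annotate_corpus(bundle$corpus, expand_plurals(bundle$cells),
                              bundle$cytokines)
  inst <- generate_instances(mentions)
  ctx <- extract_contexts(inst, bundle$corpus, mentions)
  vocab <- fit_vocabulary(ctx, inst$pmid)
  x <- vectorize(ctx, vocab)
  norms <- sqrt(Matrix::rowSums(x^2))
  expect_true(all(x@x >= 0))
  expect_true(all(abs(norms) < 1e-9 | abs(norms - 1) < 1e-9))
  # transforming new tokens does not mutate the vocabulary
  before <- unserialize(serialize(vocab, NULL))
  invisible(vectorize(list(c("brand", "new", "tokens")), vocab))
  expect_identical(vocab, before)
})

test_that("permuting instances leaves the fitted vocabulary unchanged", {
  bundle <- small_bundle(seed = 21, n_docs = 15)
  mentions <- annotate_corpus(bundle$corpus, expand_plurals(bundle$cells),
                              bundle$cytokines)
  inst <- generate_instances(mentions)
  ctx <- extract_contexts(inst, bundle$corpus, mentions)
  v1 <- fit_vocabulary(ctx, inst$pmid)
  set.seed(1)
  perm <- sample(length(ctx))
  v2 <- fit_vocabulary(ctx[perm], inst$pmid[perm])
  expect_identical(v1$terms, v2$terms)
  expect_identical(v1$idf, v2$idf)
})
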