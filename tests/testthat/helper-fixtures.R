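# Shared fixtures and independent oracles, built in code.

make_doc <- function(pmid, abstract, title = "") {
  segment_sentences(document(pmid, title, abstract))
}

make_corpus <- function(abstracts) {
  docs <- lapply(names(abstracts), function(p) make_doc(p, abstracts[[p]]))
  segment_corpus(ccrel:::new_corpus(docs))
}

toy_cell_lexicon <- function() {
  expand_plurals(lexicon(
    c("dendritic cell", "DC", "natural killer cell", "T cell", "macrophage"),
    c("dendritic cell", "dendritic cell", "natural killer cell", "T cell",
      "macrophage"),
    "cell", "toy"
  ))
}

toy_cytokine_lexicon <- function() {
  lexicon(
    c("IL-6", "interleukin-6", "IL6", "killer", "TNF", "tumor necrosis factor"),
    c("IL6", "IL6", "IL6", "KILLER_CYT", "TNF", "TNF"),
    "cytokine", "toy"
  )
}

# naive O(n * |lexicon|) substring-scan NER oracle (token-boundary aware)
naive_annotate <- function(doc, lex) {
  text <- doc$abstract
  low <- tolower(text)
  n <- nchar(text)
  is_alnum <- function(ch) grepl("^[A-Za-z0-9]$", ch)
  rows <- list()
  for (i in seq_len(nrow(lex))) {
    syn <- tolower(lex$synonym[i])
    L <- nchar(syn)
    if (L == 0 || L > n) next
    for (s in 1:(n - L + 1)) {
      if (substr(low, s, s + L - 1) != syn) next
      before <- if (s > 1) substr(text, s - 1, s - 1) else ""
      after <- if (s + L <= n) substr(text, s + L, s + L) else ""
      if (nzchar(before) && is_alnum(before)) next
      if (nzchar(after) && is_alnum(after)) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = s - 1L, end = s - 1L + L,
        surface = substr(text, s, s + L - 1),
        canonical = lex$canonical[i], stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      surface = character(), canonical = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), ]
}

# Floyd-Warshall all-pairs shortest paths oracle for small graphs
fw_oracle <- function(edges_df) {
  nodes <- sort(unique(c(edges_df$cell, edges_df$cytokine)))
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (i in seq_len(nrow(edges_df))) {
    a <- edges_df$cell[i]; b <- edges_df$cytokine[i]
    d[a, b] <- 1; d[b, a] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# step-by-step Fleiss kappa, written independently of the package version
fleiss_oracle <- function(m) {
  m <- as.matrix(m)
  N <- nrow(m)
  n <- sum(m[1, ])
  P_i <- numeric(N)
  for (i in 1:N) {
    acc <- 0
    for (j in seq_len(ncol(m))) acc <- acc + m[i, j] * (m[i, j] - 1)
    P_i[i] <- acc / (n * (n - 1))
  }
  p_j <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) p_j[j] <- sum(m[, j]) / (N * n)
  Pbar <- mean(P_i)
  Pe <- sum(p_j^2)
  (Pbar - Pe) / (1 - Pe)
}

# small, quick synthetic bundle for unit tests
small_bundle <- function(seed = 7, n_docs = 80) {
  synth_generate(synth_config(n_docs = n_docs, n_cells = 8, n_cytokines = 8,
                              n_true_relations = 12, seed = seed))
}
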