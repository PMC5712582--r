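# Manual curation support: sampling edges for validation, accuracy, and
# Fleiss' kappa interannotator agreement.

#' Sample knowledge-graph edges for manual curation
#'
#' Draws `n_total` edges uniformly without replacement (seeded), assigns
#' `n_shared` of them to every curator, and splits the remainder evenly among
#' the curators; with the default design of 60 edges, 3 curators and 15
#' shared, every curator rates 30 edges (15 shared + 15 unique).
#'
#' @param g A `ccr_graph`.
#' @param n_total Total edges to sample (default 60).
#' @param n_curators Number of curators (default 3).
#' @param n_shared Edges rated by every curator (default 15).
#' @param seed Integer seed.
#' @return A `ccr_curation` object: list with `sampled_edges` (edge keys),
#'   `shared` (keys), `per_curator` (named list of keys incl. the shared
#'   set), `seed`.
#' @export
sample_edges <- function(g, n_total = 60L, n_curators = 3L, n_shared = 15L,
                         seed = 42L) {
  keys <- pair_key(g$edges$cell, g$edges$cytokine)
  if (length(keys) < n_total) {
    stop("graph has ", length(keys), " edges; cannot sample ", n_total)
  }
  n_rest <- n_total - n_shared
  if (n_rest %% n_curators != 0L) {
    stop("non-shared edges (", n_rest, ") must split evenly among ",
         n_curators, " curators")
  }
  quota <- n_shared + n_rest %/% n_curators
  if (n_shared > quota) stop("n_shared exceeds the per-curator quota")
  with_seed(seed, {
    sampled <- sample(keys, n_total)
    shared <- sampled[seq_len(n_shared)]
    rest <- sampled[-seq_len(n_shared)]
    assign_ix <- rep_len(seq_len(n_curators), length(rest))
    per_curator <- lapply(seq_len(n_curators), function(cu) {
      c(shared, rest[assign_ix == cu])
    })
    names(per_curator) <- paste0("curator", seq_len(n_curators))
    structure(list(sampled_edges = sampled, shared = shared,
                   per_curator = per_curator, seed = seed),
              class = "ccr_curation")
  })
}

#' @export
print.ccr_curation <- function(x, ...) {
  cat(sprintf("<curation assignment> %d edges, %d curators, %d shared (%d each)\n",
              length(x$sampled_edges), length(x$per_curator),
              length(x$shared), length(x$per_curator[[1]])))
  invisible(x)
}

#' Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement for `n` raters over categorical items:
#' `kappa = (Pbar - Pe) / (1 - Pe)` with per-item agreement
#' `P_i = (sum_j n_ij^2 - n) / (n (n - 1))` and expected agreement
#' `Pe = sum_j p_j^2` where `p_j` is the overall fraction of ratings in
#' category `j`.
#'
#' @param m Integer matrix, items x categories; each row sums to the common
#'   rater count `n >= 2`.
#' @return Scalar kappa in `[-1, 1]`, or `NA` with a warning when all ratings
#'   fall into one category (expected agreement 1, kappa undefined).
#' @export
fleiss_kappa <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) >= 2L, all(m >= 0), all(m == round(m)))
  n <- sum(m[1L, ])
  if (n < 2L || !all(rowSums(m) == n)) {
    stop("every item must be rated by the same number (>= 2) of raters")
  }
  p_j <- colSums(m) / sum(m)
  pe <- sum(p_j^2)
  if (isTRUE(all.equal(pe, 1))) {
    warning("all ratings in one category: kappa undefined")
    return(NA_real_)
  }
  p_i <- (rowSums(m^2) - n) / (n * (n - 1))
  (mean(p_i) - pe) / (1 - pe)
}

#' Accuracy of curated edges
#'
#' The fraction of accepted edges. Each edge counts once: an edge rated by
#' several curators (the shared subset) enters with its majority verdict
#' (ties count as reject).
#'
#' @param verdicts Data frame with columns `edge`, `curator`, `verdict`
#'   (`"accept"` / `"reject"`; rejection causes may be recorded in an extra
#'   column, ignored here).
#' @return Scalar in `[0, 1]`.
#' @export
curation_accuracy <- function(verdicts) {
  stopifnot(all(c("edge", "verdict") %in% names(verdicts)))
  if (nrow(verdicts) == 0L) stop("no verdicts")
  stopifnot(all(verdicts$verdict %in% c("accept", "reject")))
  per_edge <- tapply(verdicts$verdict == "accept", verdicts$edge,
                     function(v) mean(v) > 0.5)
  mean(per_edge)
}

#' Write / read curation assignments and verdicts as TSV
#'
#' @param assignment A [sample_edges()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_curation_assignment <- function(assignment, path) {
  rows <- do.call(rbind, lapply(names(assignment$per_curator), function(cu) {
    df0(edge = assignment$per_curator[[cu]], curator = cu,
        shared = assignment$per_curator[[cu]] %in% assignment$shared)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
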