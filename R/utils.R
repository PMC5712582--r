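# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stringsAsFactors-proof data.frame constructor
df0 <- function(...) data.frame(..., stringsAsFactors = FALSE)

empty_mentions <- function() {
  df0(
    pmid = character(), sentence_index = integer(),
    start = integer(), end = integer(), surface = character(),
    entity_type = character(), canonical = character()
  )
}

empty_instances <- function() {
  df0(
    cell = character(), cytokine = character(),
    pmid = character(), sentence_index = integer(),
    cell_start = integer(), cell_end = integer(),
    cytokine_start = integer(), cytokine_end = integer()
  )
}
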