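# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so simulations are reproducible without
# clobbering the session.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# All exact occurrences (1-based starts) of `pattern` in `subject`.
str_find_all <- function(pattern, subject) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

# 0-based half-open substring: seq0(x, a, b) == x[a, b)
seq0 <- function(x, a, b) {
  if (b <= a) return("")
  substr(x, a + 1L, b)
}

# Overlap length of two 0-based half-open intervals.
interval_overlap <- function(a1, a2, b1, b2) {
  max(0L, min(a2, b2) - max(a1, b1))
}

intervals_intersect <- function(a1, a2, b1, b2) {
  interval_overlap(a1, a2, b1, b2) > 0L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
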