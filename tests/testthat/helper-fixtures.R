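# Shared fixtures, built once per test run.

test_locus <- build_locus(locus_config(), seed = 1L)

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else with_seed_test(seed, draw())
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

delete_interval <- function(x, a, b) {
  # 0-based half-open deletion
  paste0(substr(x, 1, a), substr(x, b + 1, nchar(x)))
}

# Reference carrying a planted annealing tract: deleting [nchar(A)+k, ...]
# leaves exactly the k-mer M as junction microhomology. Verified against the
# brute-force oracle during construction.
planted_mh_reference <- function(k = 8L, seed = 42L) {
  with_seed_test(seed, {
    for (i in 1:50) {
      a <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
      m <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
      mid <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
      b <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
      ref <- paste0(a, m, mid, m, b)
      dl <- 80L + k
      dr <- 80L + k + 60L + k
      if (microhomology_oracle(ref, dl, dr) == k) {
        return(list(reference = ref, allele = delete_interval(ref, dl, dr),
                    del_left = dl, del_right = dr, mh = m))
      }
    }
    stop("could not construct planted-microhomology reference")
  })
}
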