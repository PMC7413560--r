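test_that("align_junction handles identity, insertions and planted microhomology", {
  ref <- random_dna(400, seed = 31)

  # identical allele: empty call
  jc0 <- align_junction(ref, ref)
  expect_equal(jc0$del_right - jc0$del_left, 0L)
  expect_identical(jc0$insertion, "")
  expect_identical(jc0$mh_tract, "")

  # planted clean insertion is recovered verbatim
  al_ins <- paste0(substr(ref, 1, 200), "CTGTG", substr(ref, 201, 400))
  jc1 <- align_junction(ref, al_ins)
  expect_identical(jc1$insertion, "CTGTG")
  expect_equal(jc1$del_right - jc1$del_left, 0L)
  # clean junction in random sequence: no (or chance-length) homology shift
  expect_identical(recompose_allele(ref, jc1), al_ins)

  # planted 8 nt annealing tract
  px <- planted_mh_reference(k = 8L)
  jc2 <- align_junction(px$reference, px$allele)
  expect_equal(nchar(jc2$mh_tract), 8L)
  expect_identical(jc2$mh_tract, px$mh)
  expect_identical(recompose_allele(px$reference, jc2), px$allele)

  # no shared flank anchor: unalignable (candidate translocation)
  expect_error(align_junction(ref, random_dna(400, seed = 32)), "unalignable")
})

test_that("align_junction agrees with the brute-force oracle on exhaustive deletions", {
  # exhaustive: every deletion placement on a 300 bp reference
  ref <- random_dna(300, seed = 33)
  for (i in seq(30, 265, by = 1)) {
    for (j in seq(i + 1, 270, by = 1)) {
      al <- delete_interval(ref, i, j)
      jc <- align_junction(ref, al)
      expect_identical(recompose_allele(ref, jc), al)
      mh <- microhomology_oracle(ref, jc$del_left, jc$del_right)
      if (nchar(jc$mh_tract) != mh) {
        fail(sprintf("mismatch at del [%d, %d): caller %d, oracle %d",
                     i, j, nchar(jc$mh_tract), mh))
      }
    }
  }
  succeed()
})

test_that("align_junction matches the oracle on repeat-rich 2 kb references", {
  # repeat-bearing reference: tandem CTG tract plus a duplicated block
  with_seed_test(34, {
    base <- random_dna(2000)
    ref <- paste0(substr(base, 1, 800), strrep("CTG", 40),
                  substr(base, 801, 1400), substr(base, 801, 900),
                  substr(base, 1401, 2000))
    n <- nchar(ref)
    for (t in 1:2000) {
      i <- sample(30:(n - 40), 1)
      j <- sample((i + 1):(n - 30), 1)
      al <- delete_interval(ref, i, j)
      jc <- align_junction(ref, al)
      expect_identical(recompose_allele(ref, jc), al)
      expect_equal(nchar(jc$mh_tract),
                   microhomology_oracle(ref, jc$del_left, jc$del_right))
    }
  })
})

test_that("junction calls are canonical under placement shifts", {
  # deletion between two identical LTRs: any junction placement inside the
  # homology tract yields the same left-aligned call
  loc1 <- build_locus(locus_config(ltr_identity = 1), seed = 4L)
  d19 <- locus_feature(loc1, "delta19")
  d20 <- locus_feature(loc1, "delta20")
  calls <- lapply(c(0, 50, 150, 329), function(off) {
    al <- delete_interval(loc1$sequence, d19[1] + off, d20[1] + off)
    align_junction(loc1$sequence, al)
  })
  for (k in 2:4) {
    expect_identical(calls[[k]]$del_left, calls[[1]]$del_left)
    expect_identical(calls[[k]]$del_right, calls[[1]]$del_right)
    expect_identical(calls[[k]]$mh_tract, calls[[1]]$mh_tract)
  }
  # microhomology bounded by the LTR length
  expect_gte(nchar(calls[[1]]$mh_tract), 330L)
})

test_that("measure_repeat counts units and flags the repeat-absent state", {
  loc <- test_locus
  expect_equal(measure_repeat(loc$sequence, loc), 80L)

  ev <- repair_event("II", "contraction", loc$repeat_interval[1],
                     loc$repeat_interval[2], repeat_length_after = 30L)
  expect_equal(measure_repeat(apply_event(loc, ev), loc), 30L)

  ev6 <- with_seed_test(35, ssa_deletion(loc, c("delta19", "delta20")))
  expect_true(is.na(measure_repeat(apply_event(loc, ev6), loc)))
})

test_that("the decision tree assigns the published types from assay evidence", {
  loc <- test_locus

  check_type <- function(allele, type) {
    jc <- align_junction(loc$sequence, allele)
    as <- assay_clone(loc, allele, junction = jc)
    tc <- classify_clone(as, jc, loc, allele)
    expect_equal(tc$type, type)
    tc
  }

  # unchanged clone
  tc1 <- check_type(loc$sequence, "I")
  expect_true(tc1$evidence$southern_band)
  expect_false(is.na(tc1$evidence$su4748_product))

  # 3 nt guide-templated insertion at the cut, band present
  al3 <- paste0(substr(loc$sequence, 1, loc$cut_site), "TGG",
                substr(loc$sequence, loc$cut_site + 1, nchar(loc$sequence)))
  check_type(al3, "III")

  # natural drift: two triplets lost with unchanged flanks is still type I
  ev_d <- repair_event("II", "contraction", loc$repeat_interval[1],
                       loc$repeat_interval[2], repeat_length_after = 78L)
  check_type(apply_event(loc, ev_d), "I")

  # large deletion removing su23 + probe: no band, no product, type XI
  ev_xi <- with_seed_test(36, {
    repeat {
      ev <- large_deletion(loc)
      if (ev$viable) break
    }
    ev
  })
  tc_xi <- check_type(apply_event(loc, ev_xi), "XI")
  expect_false(tc_xi$evidence$southern_band)
  expect_true(is.na(tc_xi$evidence$su2342_product))

  # LTR fusions on the delta18/delta19 side keep su23: types VI / VII
  for (pair in list(c("delta19", "delta20"), c("delta18", "delta20"))) {
    ev <- with_seed_test(37, ssa_deletion(loc, pair))
    expected <- default_pair_type_map()[paste(pair, collapse = ".")]
    check_type(apply_event(loc, ev), unname(expected))
  }

  # a delta17/delta20 fusion deletes su23 and is assay-indistinguishable
  # from a very large deletion: reported XI
  ev8 <- with_seed_test(38, ssa_deletion(loc, c("delta17", "delta20")))
  check_type(apply_event(loc, ev8), "XI")

  # complex inverted-duplication event
  ev12 <- with_seed_test(39, complex_event(loc))
  check_type(apply_event(loc, ev12), "XII")
})

test_that("truth labels are recovered on a noise-free simulated cohort", {
  loc <- test_locus
  mix <- c(I = 0.06, I_expansion = 0.04, II = 0.10, III = 0.12, IV = 0.15,
           V = 0.08, VI = 0.15, VII = 0.12, XI = 0.10, XII = 0.08)
  coh <- generate_cohort(loc, mix = mix, n = 150, seed = 11)
  calls <- classify_cohort(loc, coh$alleles)
  expect_identical(calls$type, expected_call(coh$truth$type))
})

test_that("type summaries keep empty categories and normalized proportions", {
  types <- c(rep("IV", 8), rep("VI", 20), rep("VII", 12), rep("II", 5),
             rep("III", 3), rep("XI", 2), rep("I", 1))
  expect_equal(length(types), 51)
  s <- summarize_types(types)
  expect_equal(s$proportion[s$type == "IV"], 8 / 51)
  expect_equal(round(100 * s$proportion[s$type == "IV"], 1), 15.7)
  expect_equal(sum(s$proportion), 1, tolerance = 1e-12)
  expect_true(all(TYPE_LEVELS %in% s$type))
  expect_equal(s$count[s$type == "XII"], 0L)

  s1 <- summarize_types("I")
  expect_equal(s1$proportion[s1$type == "I"], 1)
})
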