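test_that("SSA deletions fuse the LTR pair at a shared identical block", {
  loc <- test_locus
  ev <- with_seed_test(3, ssa_deletion(loc, c("delta19", "delta20")))
  d19 <- locus_feature(loc, "delta19")
  d20 <- locus_feature(loc, "delta20")
  expect_true(ev$del_left >= d19[1] && ev$del_left < d19[2])
  expect_true(ev$del_right >= d20[1] && ev$del_right < d20[2])
  expect_equal(ev$event_type, "VI")
  # one full-length chimeric LTR remains
  al <- apply_event(loc, ev)
  expect_equal(nchar(loc$sequence) - nchar(al), ev$del_right - ev$del_left)
  expect_true(nchar(ev$microhomology_used) >= 1)

  # identical LTRs: homology interval is the whole LTR
  loc1 <- build_locus(locus_config(ltr_identity = 1), seed = 4L)
  ev1 <- with_seed_test(5, ssa_deletion(loc1, c("delta19", "delta20")))
  expect_equal(nchar(ev1$microhomology_used), 330L)

  # pairs on the same side of the cut are invalid
  expect_error(ssa_deletion(loc, c("delta18", "delta19")), "same side")

  # default weighting favours the repeat-proximal pairs
  types <- with_seed_test(6, vapply(1:1000, function(i) ssa_deletion(loc)$event_type,
                                    character(1)))
  near <- sum(types %in% c("VI", "VII"))    # delta19/delta20 + delta18/delta20
  far <- sum(types %in% c("VIII", "IX"))    # delta17/delta16-involving
  expect_gt(near, far)
})

test_that("local end-joining events match the published insertion spectrum", {
  loc <- test_locus
  with_seed_test(7, {
    for (i in 1:200) {
      ev <- nhej_local(loc, "insertion")
      expect_equal(ev$event_type, "III")
      expect_true(nchar(ev$insertion) >= 1 && nchar(ev$insertion) <= 8)
      # insertions are templated from the guide: C, T or G, never adenosine
      expect_false(grepl("A", ev$insertion, fixed = TRUE))
    }
    for (i in 1:50) {
      ev <- nhej_local(loc, "small_del")
      expect_equal(ev$event_type, "IV")
      expect_gt(ev$del_right - ev$del_left, 0)
      expect_lte(loc$cut_site - ev$del_left, 300)
      expect_lte(ev$del_right - loc$cut_site, 300)
    }
  })
  # captured-donor insertion: the inserted tract matches the donor exactly
  donor <- random_dna(211, seed = 8)
  ev <- with_seed_test(9, nhej_local(loc, "del_ins", donor = donor))
  expect_equal(ev$event_type, "V")
  expect_identical(ev$insertion, donor)
  expect_true(grepl(donor, apply_event(loc, ev), fixed = TRUE))
})

test_that("repeat resizing never reproduces the starting length", {
  loc <- test_locus
  with_seed_test(10, {
    for (i in 1:100) {
      ev <- repeat_resize(loc, "contract")
      expect_true(ev$repeat_length_after >= 3 && ev$repeat_length_after <= 79)
      expect_true(ev$repeat_length_after != 80)
      al <- apply_event(loc, ev)
      expect_equal(measure_repeat(al, loc), ev$repeat_length_after)
    }
    for (i in 1:50) {
      ev <- repeat_resize(loc, "expand")
      expect_gt(ev$repeat_length_after, 80)
    }
  })
})

test_that("very large deletions respect the essential-gene bound", {
  loc <- test_locus
  cdc8 <- locus_feature(loc, "CDC8")
  su42 <- locus_feature(loc, "su42")
  with_seed_test(12, {
    n_inviable <- 0L
    for (i in 1:200) {
      ev <- large_deletion(loc)
      if (!ev$viable) {
        n_inviable <- n_inviable + 1L
        next
      }
      # viable draws never extend past the downstream edge of su42
      expect_lte(ev$del_right, su42[2])
      al <- apply_event(loc, ev)
      # CDC8 interval is intact in the output allele
      cdc8_seq <- substr(loc$sequence, cdc8[1] + 1, cdc8[2])
      expect_true(grepl(cdc8_seq, al, fixed = TRUE))
      # no su23/su42 product (a primer site is gone)
      expect_null(pcr(al, locus_primer_oligo(loc, "su23"),
                      locus_primer_oligo(loc, "su42"), 5000))
    }
    expect_gt(n_inviable, 0L)
  })
})

test_that("complex events carry an inverted duplication of a distal segment", {
  loc <- test_locus
  ev <- with_seed_test(13, complex_event(loc))
  expect_equal(ev$event_type, "XII")
  al <- apply_event(loc, ev)
  # the insertion is the reverse complement of a reference segment
  expect_true(grepl(revcomp(ev$insertion), loc$sequence, fixed = TRUE))
  expect_true(grepl(ev$insertion, al, fixed = TRUE))
})

test_that("microhomology-mediated deletions anneal at short exact matches", {
  loc <- test_locus
  ev <- with_seed_test(14, mmej_deletion(loc, mh_len = 8L))
  expect_equal(nchar(ev$microhomology_used), 8L)
  expect_equal(ev$pathway, "MMEJ")
  # the annealed 8-mer flanks both deletion endpoints
  expect_identical(substr(loc$sequence, ev$del_left - 7, ev$del_left),
                   ev$microhomology_used)
  expect_identical(substr(loc$sequence, ev$del_right - 7, ev$del_right),
                   ev$microhomology_used)
})

test_that("cohort generation is seeded, truthful and viability-filtered", {
  loc <- test_locus

  # degenerate mix: all clones identical to the reference
  coh1 <- generate_cohort(loc, mix = c(I = 1), n = 5, seed = 3)
  expect_true(all(coh1$alleles == loc$sequence))
  expect_error(generate_cohort(loc, mix = c(I = 0, XI = 0), n = 5, seed = 3),
               "all-zero")

  # an XI-only mix must hit CDC8 in some draws (simulated mortality)
  coh_xi <- generate_cohort(loc, mix = c(XI = 1), n = 40, seed = 4)
  expect_gt(coh_xi$mortality, 0L)
  expect_equal(nrow(coh_xi$truth), 40L)
  expect_true(all(coh_xi$truth$viable))

  # binomial composition: per-type counts within 3 sigma of n/2
  coh2 <- generate_cohort(loc, mix = c(III = 0.5, VI = 0.5), n = 1000, seed = 5)
  n3 <- sum(coh2$truth$type == "III")
  expect_lt(abs(n3 - 500), 3 * sqrt(1000 * 0.25))

  # truth records re-derive the allele exactly
  coh3 <- generate_cohort(loc, n = 40, seed = 6)
  for (i in seq_len(40)) {
    tr <- coh3$truth[i, ]
    al <- coh3$alleles[[i]]
    if (tr$type %in% c("II", "I_expansion")) {
      expect_equal(measure_repeat(al, loc), tr$repeat_after)
      expect_identical(substr(al, 1, loc$repeat_interval[1]),
                       substr(loc$sequence, 1, loc$repeat_interval[1]))
    } else {
      rebuilt <- paste0(substr(loc$sequence, 1, tr$del_left), tr$insertion,
                        substr(loc$sequence, tr$del_right + 1, nchar(loc$sequence)))
      expect_identical(al, rebuilt)
    }
  }

  # no viable clone ever lacks an intact CDC8 interval
  cdc8 <- locus_feature(loc, "CDC8")
  cdc8_seq <- substr(loc$sequence, cdc8[1] + 1, cdc8[2])
  expect_true(all(vapply(coh3$alleles, grepl, logical(1),
                         pattern = cdc8_seq, fixed = TRUE)))
})

test_that("identical seeds give byte-identical cohort files", {
  loc <- test_locus
  f1 <- tempfile(fileext = ".fa"); t1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".fa"); t2 <- tempfile(fileext = ".tsv")
  write_cohort(generate_cohort(loc, n = 25, seed = 9), f1, t1)
  write_cohort(generate_cohort(loc, n = 25, seed = 9), f2, t2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
  expect_identical(readBin(t1, "raw", file.size(t1)), readBin(t2, "raw", file.size(t2)))
})

test_that("simulated qPCR inverts the resection estimator", {
  # deterministic delta-Ct encoding
  tb <- simulate_qpcr(c(a = 1, b = 2/3), dsb = 0.5)
  dct <- with(tb, tapply(ct_digested - ct_mock, site_id, mean))
  expect_equal(unname(dct["a"]), 0)
  expect_equal(unname(dct["b"]), 1)

  # an unresected site gives no amplification
  tb0 <- simulate_qpcr(0, dsb = 0.5)
  expect_true(all(tb0$no_amplification))
  expect_true(all(is.na(tb0$ct_digested)))

  expect_error(simulate_qpcr(1.2, dsb = 0.5), "domain")
  expect_error(simulate_qpcr(0.5, dsb = 0), "domain")

  # exact inverse of raw_resection at zero noise
  for (r in seq(0.1, 1, by = 0.1)) {
    tb <- simulate_qpcr(r, dsb = 0.3)
    expect_equal(raw_resection(tb$ct_digested, tb$ct_mock), r, tolerance = 1e-9)
  }
})

test_that("plating survival draws recover the true rate", {
  s0 <- simulate_survival(0, 1e4, replicates = 3, seed = 15)
  expect_true(all(s0$cfu_galactose == 0))

  s1 <- simulate_survival(1, 1e5, replicates = 5, seed = 16)
  expect_equal(mean(s1$cfu_galactose / s1$cfu_glucose), 1, tolerance = 0.01)

  # wild-type-like survival, 100 plating replicates of 1e5 cells
  s <- simulate_survival(0.179, 1e5, replicates = 100, seed = 17)
  expect_equal(mean(s$cfu_galactose / s$cfu_glucose), 0.179, tolerance = 0.01)
})
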