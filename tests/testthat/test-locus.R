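test_that("distance calibration solves the printed fragment sizes", {
  cal <- calibrate_distances(1145, 821, 80, 2)
  expect_equal(cal$d5_proximal, 911L)
  expect_equal(cal$d3_proximal, 815L)
  expect_equal(cal$parental, 1966L)

  # boundary: cut at the repeat 3' end, minimal flanks
  cal2 <- calibrate_distances(240 + 1, 1, 80, 0)
  expect_equal(cal2$d3_proximal, 1L)
  expect_equal(cal2$d5_proximal, 1L)

  expect_error(calibrate_distances(200, 821, 80, 2), "frag5")
  expect_error(calibrate_distances(1145, 6, 80, 2), "frag3")
})

test_that("built locus reproduces the calibrated digest exactly", {
  loc <- test_locus
  expect_equal(diff(loc$repeat_interval), 240L)  # 80 x CTG
  # gRNA1 cuts 2 triplets from the repeat 3' end
  expect_equal(loc$repeat_interval[2] - loc$cut_site, 6L)

  sz <- expected_dsb_sizes(loc, "EcoRV")
  expect_equal(unname(sz), c(1966, 1145, 821))
  expect_equal(unname(sz["parental"]), unname(sz["fragment5"] + sz["fragment3"]))

  # digest of the built locus hits the calibration targets exactly
  frags <- digest(loc$sequence, loc$enzyme_sites$EcoRV)
  expect_true(1966 %in% frags$size)
})

test_that("locus construction is deterministic and guide-2 shifts the cut by 2 nt", {
  loc2 <- build_locus(locus_config(), seed = 1L)
  expect_identical(loc2$sequence, test_locus$sequence)
  expect_identical(loc2$features, test_locus$features)

  loc3 <- build_locus(locus_config(), seed = 2L)
  expect_false(identical(loc3$sequence, test_locus$sequence))

  locg2 <- build_locus(locus_config(guide_id = "gRNA2"), seed = 1L)
  expect_equal(locg2$cut_site - test_locus$cut_site, 2L)
})

test_that("background sequence carries no spurious assay targets", {
  loc <- test_locus
  # exactly the planted restriction sites
  expect_length(enzyme_cut_positions(loc$sequence, "EcoRV"), 4L)
  expect_length(enzyme_cut_positions(loc$sequence, "SspI"), 2L)
  ec <- loc$enzyme_sites$EcoRV
  r <- loc$repeat_interval
  expect_equal(sum(ec < r[1]), 2L)
  expect_equal(sum(ec >= r[2]), 2L)

  # primer sites are unique on both strands
  for (nm in c("su23", "su47", "su48", "su42")) {
    iv <- locus_feature(loc, nm)
    plus <- substr(loc$sequence, iv[1] + 1, iv[2])
    expect_length(gregexpr(plus, loc$sequence, fixed = TRUE)[[1]], 1L)
    expect_equal(gregexpr(revcomp(plus), loc$sequence, fixed = TRUE)[[1]][1], -1L)
  }

  # the repeat tract is the only repeat-unit run of >= 3 units
  hits <- gregexpr("CTGCTGCTG", loc$sequence, fixed = TRUE)[[1]]
  expect_true(all(hits >= r[1] - 2 & hits + 9 <= r[2] + 3))
  expect_equal(gregexpr("CAGCAGCAG", loc$sequence, fixed = TRUE)[[1]][1], -1L)

  # virtual PCR on the unmodified locus: su47/su48 one product, su23/su42 none
  p1 <- pcr(loc$sequence, locus_primer_oligo(loc, "su47"),
            locus_primer_oligo(loc, "su48"), 3000)
  expect_false(is.null(p1))
  expect_true(p1$start < r[1] && p1$end > r[2])  # spans the repeat
  expect_null(pcr(loc$sequence, locus_primer_oligo(loc, "su23"),
                  locus_primer_oligo(loc, "su42"), 5000))
})

test_that("LTR family has the configured pairwise identity", {
  loc <- test_locus
  ltrs <- paste0("delta", 16:20)
  seqs <- lapply(ltrs, function(nm) {
    iv <- locus_feature(loc, nm)
    charToRaw(substr(loc$sequence, iv[1] + 1, iv[2]))
  })
  for (i in 1:4) for (j in (i + 1):5) {
    ident <- mean(seqs[[i]] == seqs[[j]])
    expect_true(abs(ident - 0.85) <= 0.02,
                label = sprintf("%s vs %s identity %.3f", ltrs[i], ltrs[j], ident))
  }
})

test_that("FASTA + BED round-trip preserves the locus", {
  loc <- test_locus
  fa <- tempfile(fileext = ".fa")
  bed <- tempfile(fileext = ".bed")
  write_locus(loc, fa, bed)
  back <- read_locus(fa, bed)
  expect_identical(back$sequence, loc$sequence)
  expect_identical(back$features, loc$features)
  expect_identical(back$cut_site, loc$cut_site)
  expect_identical(back$repeat_interval, loc$repeat_interval)
  expect_identical(back$enzyme_sites, loc$enzyme_sites)

  # BED feature for the repeat of an 80-triplet locus spans 240 bp
  rep_row <- back$features[back$features$name == "repeat", ]
  expect_equal(rep_row$end - rep_row$start, 240L)

  # empty feature list still round-trips
  loc0 <- loc
  loc0$features <- loc$features[0, ]
  loc0$repeat_interval <- c(NA_integer_, NA_integer_)
  fa0 <- tempfile(fileext = ".fa"); bed0 <- tempfile(fileext = ".bed")
  write_locus(loc0, fa0, bed0)
  back0 <- read_locus(fa0, bed0)
  expect_identical(back0$sequence, loc$sequence)
  expect_equal(nrow(back0$features), 0L)
})

test_that("malformed BED lines are rejected with their line number", {
  fa <- tempfile(fileext = ".fa")
  bed <- tempfile(fileext = ".bed")
  write_locus(test_locus, fa, bed)
  lines <- readLines(bed)
  lines[3] <- "locusX\tnot_a_number\t500\tX\t0\t+"
  writeLines(lines, bed)
  expect_error(read_locus(fa, bed), "line 3")
})

test_that("invalid configurations are refused with the violated constraint", {
  expect_error(locus_config(n_triplets = 0), "n_triplets")
  expect_error(locus_config(d5_ecorv_proximal = 2000), "d5_ecorv_proximal < d5_ecorv_distal")
  off <- default_feature_offsets()
  off$CDC8 <- c(1000L, 1300L)  # would overlap/precede su42
  expect_error(locus_config(feature_offsets = off), "CDC8")
  off2 <- default_feature_offsets()
  off2$probe <- c(900L, 1100L)  # beyond the 3' proximal EcoRV site
  expect_error(locus_config(feature_offsets = off2), "probe")
})
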