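#' Construct a repair event record
#'
#' One simulated (or inferred) repair outcome. Deletion coordinates are
#' 0-based half-open on the reference; an empty deletion has
#' `del_left == del_right`. For the repeat-resizing types (II and
#' I_expansion) the allele is regenerated from `repeat_length_after` and the
#' deletion fields span the original tract.
#'
#' @param event_type One of I, I_expansion, II, ..., XII.
#' @param pathway One of NHEJ, SSA_LTR, MMEJ, contraction, expansion,
#'   complex, none.
#' @param del_left,del_right Deleted reference interval.
#' @param insertion Inserted sequence ("" if none).
#' @param microhomology_used Annealed tract ("" if none).
#' @param repeat_length_after Triplet count in the repaired allele (`NA` when
#'   the tract is deleted).
#' @param viable Logical; FALSE iff the deletion hits CDC8 or its promoter
#'   margin.
#' @return A `repair_event` list.
#' @export
repair_event <- function(event_type, pathway, del_left, del_right,
                         insertion = "", microhomology_used = "",
                         repeat_length_after = NA_integer_, viable = TRUE) {
  stopifnot(del_left <= del_right)
  structure(list(
    event_type = event_type,
    pathway = pathway,
    del_left = as.integer(del_left),
    del_right = as.integer(del_right),
    insertion = insertion,
    microhomology_used = microhomology_used,
    repeat_length_after = as.integer(repeat_length_after),
    viable = viable
  ), class = "repair_event")
}

#' Default LTR-pair to type mapping for single-strand annealing deletions
#'
#' Ordered by deletion span: VI is the smallest fusion (delta19/delta20), IX
#' the largest (delta16/delta20); the Ty-fragment-capture variant of the
#' largest pair is type X.
#'
#' @return Named character vector, names "leftLTR.rightLTR".
#' @export
default_pair_type_map <- function() {
  c(delta19.delta20 = "VI", delta18.delta20 = "VII",
    delta17.delta20 = "VIII", delta16.delta20 = "IX")
}

viability_window <- function(locus) {
  cdc8 <- locus_feature(locus, "CDC8")
  margin <- locus$config$cdc8_margin %||% 180L
  c(cdc8[1] - margin, cdc8[2])
}

event_is_viable <- function(locus, event) {
  win <- viability_window(locus)
  !intervals_intersect(event$del_left, event$del_right, win[1], win[2])
}

#' Apply a repair event to the reference, producing the repaired allele
#'
#' @param locus A `locus_map`.
#' @param event A `repair_event`.
#' @return Allele sequence (character).
#' @export
apply_event <- function(locus, event) {
  ref <- locus$sequence
  if (event$event_type %in% c("II", "I_expansion")) {
    r <- locus$repeat_interval
    unit <- locus$config$repeat_unit %||% "CTG"
    return(paste0(seq0(ref, 0L, r[1]),
                  strrep(unit, event$repeat_length_after),
                  seq0(ref, r[2], nchar(ref))))
  }
  paste0(seq0(ref, 0L, event$del_left), event$insertion,
         seq0(ref, event$del_right, nchar(ref)))
}

# Maximal identical blocks between two equal-length LTR copies, as a
# data.frame of 0-based half-open offsets within the LTR.
ltr_identical_blocks <- function(seq_a, seq_b) {
  eq <- charToRaw(seq_a) == charToRaw(seq_b)
  r <- rle(eq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep], len = r$lengths[keep])
}

#' Single-strand annealing deletion between two flanking LTRs
#'
#' Resection exposes the two LTR copies, which anneal at a shared identical
#' block; everything between the annealed positions is lost and a single
#' chimeric LTR remains. The junction is sampled from the identical blocks of
#' the pair, weighted by block length.
#'
#' @param locus A `locus_map`.
#' @param ltr_pair `c(left, right)` LTR feature names, one on each side of
#'   the cut; if NULL a pair is drawn from `weights`.
#' @param weights Named sampling weights over "left.right" pairs; the default
#'   favours the pairs closest to the repeat (resection reveals the nearest
#'   homologies first).
#' @param ty_insert If TRUE, a random fragment of the synthetic Ty1 internal
#'   sequence is captured at the junction (type X variant).
#' @param pair_type_map See [default_pair_type_map()].
#' @return A `repair_event` (uses the current RNG state).
#' @export
ssa_deletion <- function(locus, ltr_pair = NULL,
                         weights = c(delta19.delta20 = 0.4, delta18.delta20 = 0.3,
                                     delta17.delta20 = 0.2, delta16.delta20 = 0.1),
                         ty_insert = FALSE,
                         pair_type_map = default_pair_type_map()) {
  if (is.null(ltr_pair)) {
    key <- sample(names(weights), 1L, prob = weights)
    ltr_pair <- strsplit(key, ".", fixed = TRUE)[[1]]
  }
  a <- locus_feature(locus, ltr_pair[1])
  b <- locus_feature(locus, ltr_pair[2])
  cut <- locus$cut_site
  if ((a[2] <= cut) == (b[2] <= cut)) {
    stop("invalid LTR pair: ", ltr_pair[1], " and ", ltr_pair[2],
         " lie on the same side of the cut")
  }
  if (a[1] > b[1]) { tmp <- a; a <- b; b <- tmp; ltr_pair <- rev(ltr_pair) }
  seq_a <- seq0(locus$sequence, a[1], a[2])
  seq_b <- seq0(locus$sequence, b[1], b[2])
  blocks <- ltr_identical_blocks(seq_a, seq_b)
  if (!nrow(blocks)) stop("LTR pair shares no identical block")
  bi <- sample.int(nrow(blocks), 1L, prob = blocks$len)
  pos <- blocks$start[bi] + sample.int(blocks$len[bi], 1L) - 1L
  ins <- ""
  if (ty_insert) {
    ty <- locus$aux$ty_internal
    len <- sample(50:300, 1L)
    start <- sample.int(nchar(ty) - len + 1L, 1L)
    ins <- substr(ty, start, start + len - 1L)
  }
  key <- paste(ltr_pair, collapse = ".")
  repair_event(
    event_type = unname(pair_type_map[key]) %||% "UNCLASSIFIED",
    pathway = "SSA_LTR",
    del_left = a[1] + pos, del_right = b[1] + pos,
    insertion = ins,
    microhomology_used = seq0(seq_a, blocks$start[bi], blocks$end[bi]),
    repeat_length_after = NA_integer_
  )
}

#' Microhomology-mediated deletion at a short exact match
#'
#' RAD52-independent variant of the LTR fusion: the junction anneals at a
#' short (default 8 nt) exact sequence match located near, but not inside a
#' shared identical block of, the two LTR neighbourhoods.
#'
#' @param locus A `locus_map`.
#' @param pair LTR neighbourhood pair (default delta19/delta20).
#' @param mh_len Annealing-tract length (default 8).
#' @param window Search half-width around each LTR (default 200 bp).
#' @return A `repair_event`.
#' @export
mmej_deletion <- function(locus, pair = c("delta19", "delta20"), mh_len = 8L,
                          window = 200L) {
  a <- locus_feature(locus, pair[1])
  b <- locus_feature(locus, pair[2])
  ref <- locus$sequence
  for (w in c(window, 2L * window, 4L * window)) {
    wa <- c(max(0L, a[1] - w), min(a[2] + w, locus$cut_site))
    wb <- c(max(b[1] - w, locus$cut_site), min(b[2] + w, nchar(ref)))
    sa <- seq0(ref, wa[1], wa[2])
    kmers <- vapply(seq_len(nchar(sa) - mh_len + 1L),
                    function(i) substr(sa, i, i + mh_len - 1L), character(1))
    sb <- seq0(ref, wb[1], wb[2])
    hits <- list()
    for (i in seq_along(kmers)) {
      at <- str_find_all(kmers[i], sb)
      for (p in at) hits[[length(hits) + 1L]] <- c(wa[1] + i - 1L, wb[1] + p - 1L)
    }
    if (length(hits)) {
      h <- hits[[sample.int(length(hits), 1L)]]
      return(repair_event(
        event_type = unname(default_pair_type_map()[paste(pair, collapse = ".")]) %||% "VI",
        pathway = "MMEJ",
        del_left = h[1] + mh_len, del_right = h[2] + mh_len,
        microhomology_used = seq0(ref, h[1], h[1] + mh_len),
        repeat_length_after = NA_integer_
      ))
    }
  }
  stop("no exact ", mh_len, " nt match found between the ", pair[1], "/",
       pair[2], " neighbourhoods")
}

#' Local end-joining events at the cut site (types III-V)
#'
#' `insertion`: 1-8 nt drawn from C/T/G (the guide-encoded bases; adenosines
#' are never inserted) at the junction. `small_del`: a local deletion within
#' `window` bp of the cut on each side, always removing flank beyond the
#' PAM-repeat boundary window. `del_ins`: the same deletion plus an inserted
#' tract, either random or templated from a configured donor cassette
#' (capture of ectopic DNA).
#'
#' Insertion draws whose product is sequence-identical to a pure
#' repeat-length change (e.g. an in-frame repeat-unit insertion) are
#' resampled: they are definitionally indistinguishable from repeat
#' instability.
#'
#' @param locus A `locus_map`.
#' @param mode One of "insertion", "small_del", "del_ins".
#' @param window Maximum distance (bp) of deletion bounds from the cut
#'   (default 300).
#' @param donor Optional donor sequence for `del_ins` capture; if NULL a
#'   random 10-30 nt filler is used.
#' @param boundary_margin Deletions must start at least this far upstream of
#'   the repeat start (default 13 bp, one beyond the classifier's boundary
#'   window).
#' @return A `repair_event`.
#' @export
nhej_local <- function(locus, mode = c("insertion", "small_del", "del_ins"),
                       window = 300L, donor = NULL, boundary_margin = 13L) {
  mode <- match.arg(mode)
  cut <- locus$cut_site
  r <- locus$repeat_interval
  unit <- locus$config$repeat_unit %||% "CTG"
  if (mode == "insertion") {
    for (i in 1:100) {
      k <- sample.int(8L, 1L)
      ins <- paste(sample(c("C", "T", "G"), k, replace = TRUE), collapse = "")
      ev <- repair_event("III", "NHEJ", cut, cut, insertion = ins,
                         repeat_length_after = NA_integer_)
      allele <- apply_event(locus, ev)
      if (!is_perfect_repeat(repeat_region(allele, locus), unit)) {
        ev$repeat_length_after <- measure_repeat(allele, locus)
        return(ev)
      }
    }
    stop("could not draw a distinguishable insertion")
  }
  # deletion bounds: left beyond the boundary window, right at/after the cut
  dl <- sample(seq.int(max(cut - window, 0L), r[1] - boundary_margin), 1L)
  dr <- sample(seq.int(cut, min(cut + window, nchar(locus$sequence))), 1L)
  if (mode == "small_del") {
    ev <- repair_event("IV", "NHEJ", dl, dr, repeat_length_after = NA_integer_)
  } else {
    ins <- if (!is.null(donor)) donor else {
      paste(sample(c("A", "C", "G", "T"), sample(10:30, 1L), replace = TRUE),
            collapse = "")
    }
    ev <- repair_event("V", "NHEJ", dl, dr, insertion = ins,
                       repeat_length_after = NA_integer_)
  }
  ev$repeat_length_after <- measure_repeat(apply_event(locus, ev), locus)
  ev
}

#' Repeat contraction or expansion
#'
#' Resizes the tract without touching the flanks. Contractions never land
#' within the natural-drift band (losses of 1-2 triplets score as type I by
#' the classification convention), and never at the starting length.
#'
#' @param locus A `locus_map`.
#' @param direction "contract" or "expand".
#' @param floor Minimum triplet count after contraction (default 3).
#' @param max_gain Maximum triplets added by an expansion (default 10;
#'   observed expansions were small).
#' @param drift Triplet losses up to this are natural drift, excluded from
#'   contraction draws (default 2).
#' @return A `repair_event`.
#' @export
repeat_resize <- function(locus, direction = c("contract", "expand"),
                          floor = 3L, max_gain = 10L, drift = 2L) {
  direction <- match.arg(direction)
  n0 <- locus$config$n_triplets %||%
    ((locus$repeat_interval[2] - locus$repeat_interval[1]) %/% 3L)
  r <- locus$repeat_interval
  if (direction == "contract") {
    hi <- n0 - drift - 1L
    if (hi < floor) stop("repeat too short to contract below the drift band")
    m <- sample(seq.int(floor, hi), 1L)
    repair_event("II", "contraction", r[1], r[2], repeat_length_after = m)
  } else {
    m <- n0 + sample.int(max_gain, 1L)
    repair_event("I_expansion", "expansion", r[1], r[2], repeat_length_after = m)
  }
}

#' Very large deletion sparing the essential downstream gene (type XI)
#'
#' Removes the su23 primer site, the probe target and (possibly) more; the
#' right bound is drawn beyond the viable window so that draws hitting CDC8
#' (or its promoter margin) occur and are reported inviable - the cohort
#' generator logs them as simulated mortality and resamples.
#'
#' @param locus A `locus_map`.
#' @param left_min Minimum left bound (default 150, preserving an alignment
#'   anchor at the window edge).
#' @param right_overshoot How far beyond the CDC8 promoter margin the right
#'   bound may be drawn (default 440 bp).
#' @return A `repair_event`; check `$viable`.
#' @export
large_deletion <- function(locus, left_min = 150L, right_overshoot = 440L) {
  su23 <- locus_feature(locus, "su23")
  probe <- locus_feature(locus, "probe")
  win <- viability_window(locus)
  dl <- sample(seq.int(left_min, su23[1]), 1L)
  dr <- sample(seq.int(probe[2], win[1] + right_overshoot), 1L)
  ev <- repair_event("XI", "complex", dl, dr, repeat_length_after = NA_integer_)
  ev$viable <- event_is_viable(locus, ev)
  ev
}

#' Complex rearrangement: deletion to delta20 with an inverted duplication
#'
#' Models the type XII outcome: the junction deletes from within delta18 into
#' delta20 and carries an inverted (reverse-complemented) copy of a distal
#' segment anchored at the delta16 LTR.
#'
#' @param locus A `locus_map`.
#' @param dup_len Length of the inverted duplicated segment (default 250).
#' @return A `repair_event`.
#' @export
complex_event <- function(locus, dup_len = 250L) {
  d18 <- locus_feature(locus, "delta18")
  d20 <- locus_feature(locus, "delta20")
  d16 <- locus_feature(locus, "delta16")
  dl <- sample(seq.int(d18[1], d18[2] - 1L), 1L)
  dr <- d20[1] + sample.int(d20[2] - d20[1], 1L) - 1L
  seg_start <- max(0L, d16[1] - dup_len %/% 2L)
  seg <- seq0(locus$sequence, seg_start, seg_start + dup_len)
  repair_event("XII", "complex", dl, dr, insertion = revcomp(seg),
               repeat_length_after = NA_integer_)
}

#' Default survivor-type mix (wild-type-like spectrum)
#'
#' Descriptive per-type generative probabilities approximating the wild-type
#' survivor spectrum (local deletions ~16%, LTR fusions ~63%, very large
#' deletions ~4%); they describe observed survivor proportions, not
#' mechanistic pathway rates.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_type_mix <- function() {
  c(I = 0.020, I_expansion = 0.000, II = 0.039, III = 0.059, IV = 0.157,
    V = 0.039, VI = 0.250, VII = 0.200, VIII = 0.098, IX = 0.059, X = 0.020,
    XI = 0.039, XII = 0.020)
}

draw_event <- function(locus, type, donor = NULL) {
  switch(type,
    I = repair_event("I", "none", locus$cut_site, locus$cut_site,
                     repeat_length_after = locus$config$n_triplets),
    I_expansion = repeat_resize(locus, "expand"),
    II = repeat_resize(locus, "contract"),
    III = nhej_local(locus, "insertion"),
    IV = nhej_local(locus, "small_del"),
    V = nhej_local(locus, "del_ins", donor = donor),
    VI = ssa_deletion(locus, c("delta19", "delta20")),
    VII = ssa_deletion(locus, c("delta18", "delta20")),
    VIII = ssa_deletion(locus, c("delta17", "delta20")),
    IX = ssa_deletion(locus, c("delta16", "delta20")),
    X = ssa_deletion(locus, c("delta16", "delta20"), ty_insert = TRUE),
    XI = large_deletion(locus),
    XII = complex_event(locus),
    MMEJ = mmej_deletion(locus),
    stop("unknown event type: ", type)
  )
}

#' Generate a cohort of surviving clones with known truth labels
#'
#' Draws event types from `mix`, simulates each repair event, applies it to
#' the reference, and keeps exactly `n` viable survivors (only survivors grow
#' on plates); draws whose deletion hits the essential CDC8 interval are
#' logged as simulated mortality and resampled.
#'
#' @param locus A `locus_map`.
#' @param mix Named per-type probabilities (normalized internally; all-zero
#'   is an error). See [default_type_mix()].
#' @param n Number of surviving clones to emit.
#' @param seed Integer seed; identical (locus, mix, n, seed) give
#'   byte-identical output.
#' @param donor Optional donor sequence for type V capture events.
#' @return List: `alleles` (named character), `truth` (data.frame: clone_id,
#'   type, pathway, del_left, del_right, insertion, mh_len, repeat_after,
#'   viable), `log` (per-draw simulation log), `mortality` (count of
#'   inviable draws).
#' @export
generate_cohort <- function(locus, mix = default_type_mix(), n, seed = 1L,
                            donor = NULL) {
  stopifnot(n >= 1L)
  if (any(mix < 0)) stop("mix probabilities must be >= 0")
  if (sum(mix) <= 0) stop("all-zero type mix")
  mix <- mix / sum(mix)
  with_seed(seed, {
    alleles <- character(n)
    truth <- vector("list", n)
    log <- list()
    mortality <- 0L
    i <- 0L
    draw <- 0L
    while (i < n) {
      draw <- draw + 1L
      type <- sample(names(mix), 1L, prob = mix)
      ev <- draw_event(locus, type, donor = donor)
      log[[draw]] <- data.frame(draw = draw, type = type, viable = ev$viable)
      if (!ev$viable) {
        mortality <- mortality + 1L
        next
      }
      i <- i + 1L
      id <- sprintf("clone_%04d", i)
      alleles[i] <- apply_event(locus, ev)
      truth[[i]] <- data.frame(
        clone_id = id, type = ev$event_type, pathway = ev$pathway,
        del_left = ev$del_left, del_right = ev$del_right,
        insertion = ev$insertion, mh_len = nchar(ev$microhomology_used),
        repeat_after = ev$repeat_length_after, viable = ev$viable,
        stringsAsFactors = FALSE
      )
      names(alleles)[i] <- id
    }
    list(alleles = alleles, truth = do.call(rbind, truth),
         log = do.call(rbind, log), mortality = mortality)
  })
}

#' Write a cohort to multi-FASTA + truth/log TSV
#'
#' @param cohort Result of [generate_cohort()].
#' @param fasta,truth_tsv Output paths.
#' @param log_tsv Optional simulation-log path.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, fasta, truth_tsv, log_tsv = NULL) {
  dna <- Biostrings::DNAStringSet(cohort$alleles)
  Biostrings::writeXStringSet(dna, fasta, width = 70L)
  utils::write.table(cohort$truth, truth_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(log_tsv)) {
    utils::write.table(cohort$log, log_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(fasta = fasta, truth = truth_tsv))
}

#' Simulate a resection qPCR experiment
#'
#' Produces mock- and EcoRV-digested Ct values such that the published
#' estimator recovers the planted resected fraction in expectation:
#' `deltaCt = log2((2 - r) / r)` for `r > 0`; a fully unresected site
#' (`r = 0`) yields no amplification in the digested wells.
#'
#' @param r Planted resected fraction(s) in `[0, 1]`, optionally named by
#'   site.
#' @param dsb DSB fraction at the time point (carried into the output for
#'   relative-resection computation), in `(0, 1]`.
#' @param noise_sd Gaussian Ct noise per replicate well (cycles, default 0).
#' @param replicates Wells per condition (default 3).
#' @param baseline_ct Mean mock Ct (default 22).
#' @param seed Optional seed.
#' @return data.frame: `site_id`, `replicate`, `ct_mock`, `ct_digested`,
#'   `no_amplification`, `dsb_fraction`.
#' @export
simulate_qpcr <- function(r, dsb, noise_sd = 0, replicates = 3L,
                          baseline_ct = 22, seed = NULL) {
  if (any(r < 0 | r > 1)) stop("domain error: resected fraction must be in [0, 1]")
  if (dsb <= 0 || dsb > 1) stop("domain error: dsb fraction must be in (0, 1]")
  stopifnot(replicates >= 1L)
  ids <- names(r) %||% sprintf("site_%d", seq_along(r))
  with_seed(seed, {
    rows <- lapply(seq_along(r), function(i) {
      mock <- baseline_ct + stats::rnorm(replicates, 0, noise_sd)
      if (r[i] == 0) {
        data.frame(site_id = ids[i], replicate = seq_len(replicates),
                   ct_mock = mock, ct_digested = NA_real_,
                   no_amplification = TRUE, dsb_fraction = dsb)
      } else {
        dct <- log2((2 - r[i]) / r[i])
        data.frame(site_id = ids[i], replicate = seq_len(replicates),
                   ct_mock = mock,
                   ct_digested = baseline_ct + dct + stats::rnorm(replicates, 0, noise_sd),
                   no_amplification = FALSE, dsb_fraction = dsb)
      }
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a plating survival assay
#'
#' The same number of cells is plated on inducing (galactose) and repressing
#' (glucose) plates; colony counts are binomial draws at the plating
#' efficiency, with survival additionally thinning the galactose plate.
#'
#' @param true_rate True survival probability in `[0, 1]`.
#' @param cells_plated Cells plated per replicate.
#' @param replicates Number of plating replicates (default 1).
#' @param plating_efficiency Colony-forming efficiency (default 0.85).
#' @param seed Optional seed.
#' @return data.frame with `cfu_galactose`, `cfu_glucose` per replicate.
#' @export
simulate_survival <- function(true_rate, cells_plated, replicates = 1L,
                              plating_efficiency = 0.85, seed = NULL) {
  stopifnot(true_rate >= 0, true_rate <= 1)
  with_seed(seed, data.frame(
    replicate = seq_len(replicates),
    cfu_galactose = stats::rbinom(replicates, cells_plated,
                                  plating_efficiency * true_rate),
    cfu_glucose = stats::rbinom(replicates, cells_plated, plating_efficiency)
  ))
}
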