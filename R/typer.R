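#' Infer the rearrangement junction of an allele against the reference
#'
#' Computes the longest exact prefix (`P`) and suffix (`S`) matches between
#' allele and reference. When `P + S` covers the allele, the event is a pure
#' deletion whose junction overhang is microhomology (sequence present in
#' both deletion endpoints but only once in the allele); otherwise the
#' unexplained middle is reported as an insertion. Deletions and insertions
#' are left-aligned: the junction is placed maximally to the left of any
#' homology tract, so all placements of the same event yield one canonical
#' call.
#'
#' @param reference Reference sequence.
#' @param allele Rearranged allele sequence.
#' @param anchor Minimum exact flank match (bp) required at each end
#'   (default 30); failure raises an "unalignable" error (candidate
#'   translocation).
#' @return A `junction_call` list: `del_left`, `del_right` (0-based half-open
#'   deleted reference interval), `insertion`, `mh_tract`,
#'   `mh_interval_left`, `mh_interval_right` (reference intervals of the two
#'   annealed copies), `placement = "left_aligned"`. Reconstruction identity:
#'   `reference[..del_left] + insertion + reference[del_right..]` equals the
#'   allele byte-exactly.
#' @export
align_junction <- function(reference, allele, anchor = 30L) {
  rr <- charToRaw(reference)
  ar <- charToRaw(allele)
  nr <- length(rr)
  na <- length(ar)
  m <- min(nr, na)

  if (nr == na && identical(rr, ar)) {
    return(junction_call(0L, 0L, "", reference, nr, na))
  }
  pre_mis <- which(rr[seq_len(m)] != ar[seq_len(m)])
  P <- if (length(pre_mis)) pre_mis[1] - 1L else m
  suf_mis <- which(rr[nr - seq_len(m) + 1L] != ar[na - seq_len(m) + 1L])
  S <- if (length(suf_mis)) suf_mis[1] - 1L else m
  if (P < anchor || S < anchor) {
    stop("unalignable allele: flank anchor < ", anchor,
         " bp (prefix ", P, ", suffix ", S, "); candidate translocation")
  }

  if (na <= nr && P + S >= na) {
    # pure deletion; overhang P + S - na is annealed microhomology
    dl <- na - S
    dr <- nr - S
    junction_call(dl, dr, "", reference, nr, na, mh = P + S - na)
  } else if (na > nr && P + S >= nr) {
    # pure insertion, left-aligned
    dl <- nr - S
    junction_call(dl, dl, seq0(allele, dl, dl + na - nr), reference, nr, na)
  } else {
    junction_call(P, nr - S, seq0(allele, P, na - S), reference, nr, na)
  }
}

junction_call <- function(del_left, del_right, insertion, reference, nr, na, mh = 0L) {
  mh <- max(0L, as.integer(mh))
  structure(list(
    del_left = as.integer(del_left),
    del_right = as.integer(del_right),
    insertion = insertion,
    mh_tract = if (mh > 0L) seq0(reference, del_left, del_left + mh) else "",
    mh_interval_left = c(del_left, del_left + mh),
    mh_interval_right = c(del_right, del_right + mh),
    placement = "left_aligned",
    ref_length = as.integer(nr),
    allele_length = as.integer(na)
  ), class = "junction_call")
}

#' @export
print.junction_call <- function(x, ...) {
  cat(sprintf("junction: del [%d, %d) (%d bp), ins %d nt, mh %d nt\n",
              x$del_left, x$del_right, x$del_right - x$del_left,
              nchar(x$insertion), nchar(x$mh_tract)))
  invisible(x)
}

#' Rebuild an allele from a junction call
#'
#' @param reference Reference sequence.
#' @param junction A `junction_call`.
#' @return The recomposed allele sequence.
#' @export
recompose_allele <- function(reference, junction) {
  paste0(seq0(reference, 0L, junction$del_left),
         junction$insertion,
         seq0(reference, junction$del_right, nchar(reference)))
}

#' Brute-force microhomology length at a deletion junction
#'
#' Exhaustive symmetric scan: counts identical nucleotides extending leftward
#' from (`del_left`, `del_right`) plus identical nucleotides extending
#' rightward, i.e. the annealed tract present in only one copy after the
#' deletion. Independent oracle for [align_junction()].
#'
#' @param reference Reference sequence.
#' @param del_left,del_right Deleted interval (0-based half-open).
#' @return Microhomology length (integer >= 0).
#' @export
microhomology_oracle <- function(reference, del_left, del_right) {
  rr <- charToRaw(reference)
  nr <- length(rr)
  stopifnot(del_left >= 0L, del_left <= del_right, del_right <= nr)
  left <- 0L
  while (del_left - left >= 1L &&
         rr[del_left - left] == rr[del_right - left]) {
    left <- left + 1L
  }
  right <- 0L
  while (del_right + right + 1L <= nr &&
         rr[del_left + right + 1L] == rr[del_right + right + 1L]) {
    right <- right + 1L
  }
  left + right
}

#' Measure the repeat-tract length of an allele
#'
#' Anchors on the reference sequence immediately upstream of the repeat and
#' counts contiguous repeat units from there; any interruption (including the
#' 1-8 nt insertions seen between the PAM and the tract) terminates the
#' count.
#'
#' @param allele Allele sequence.
#' @param locus A `locus_map`.
#' @param flank Anchor length in bp (default 20).
#' @return Triplet count, or `NA` (repeat-absent) when the upstream flank
#'   anchor was deleted.
#' @export
measure_repeat <- function(allele, locus, flank = 20L) {
  r <- locus$repeat_interval
  anchor <- seq0(locus$sequence, r[1] - flank, r[1])
  hit <- str_find_all(anchor, allele)
  if (!length(hit)) return(NA_integer_)
  pos <- hit[1] - 1L + flank  # 0-based start of the tract in the allele
  unit <- locus$config$repeat_unit %||% "CTG"
  n <- 0L
  while (seq0(allele, pos, pos + 3L) == unit) {
    n <- n + 1L
    pos <- pos + 3L
  }
  n
}

# Allele subsequence between the reference flanks of the repeat tract, or NA
# if either anchor is gone.
repeat_region <- function(allele, locus, flank = 20L) {
  r <- locus$repeat_interval
  left <- seq0(locus$sequence, r[1] - flank, r[1])
  right <- seq0(locus$sequence, r[2], r[2] + flank)
  lh <- str_find_all(left, allele)
  rh <- str_find_all(right, allele)
  if (!length(lh) || !length(rh)) return(NA_character_)
  a <- lh[1] - 1L + flank
  rh <- rh[rh - 1L >= a]
  if (!length(rh)) return(NA_character_)
  seq0(allele, a, rh[1] - 1L)
}

is_perfect_repeat <- function(region, unit) {
  !is.na(region) && nchar(region) %% nchar(unit) == 0L &&
    region == strrep(unit, nchar(region) %/% nchar(unit))
}

#' Classification thresholds for the twelve rearrangement types
#'
#' @param type1_max_loss Repeat-length losses up to this many triplets (with
#'   unchanged flanks) are scored as natural drift, type I (default 2).
#' @param local_indel_max Maximum indel size (bp, each of deletion and
#'   insertion) for a type III call at the PAM-repeat boundary (default 8).
#' @param repeat_margin Half-width (bp) of the PAM-repeat boundary window
#'   around the repeat interval (default 12).
#' @param complex_min_ins Minimum insertion length whose reverse complement
#'   must match the reference to call an inverted-duplication (type XII)
#'   event (default 30).
#' @param min_ltr_pair_ins Minimum junction insertion (bp) that promotes an
#'   LTR-fusion call to the Ty-fragment-capture type (default 10).
#' @param pair_type_map Named character vector mapping "leftLTR.rightLTR"
#'   pairs to types VI-IX; the Ty-capture variant of any mapped pair is
#'   `x_type`.
#' @param x_type Type label for LTR fusions carrying a captured insertion.
#' @return A `classify_config` list.
#' @export
classify_config <- function(type1_max_loss = 2L,
                            local_indel_max = 8L,
                            repeat_margin = 12L,
                            complex_min_ins = 30L,
                            min_ltr_pair_ins = 10L,
                            pair_type_map = c(delta19.delta20 = "VI",
                                              delta18.delta20 = "VII",
                                              delta17.delta20 = "VIII",
                                              delta16.delta20 = "IX"),
                            x_type = "X") {
  structure(list(type1_max_loss = as.integer(type1_max_loss),
                 local_indel_max = as.integer(local_indel_max),
                 repeat_margin = as.integer(repeat_margin),
                 complex_min_ins = as.integer(complex_min_ins),
                 min_ltr_pair_ins = as.integer(min_ltr_pair_ins),
                 pair_type_map = pair_type_map,
                 x_type = x_type),
            class = "classify_config")
}

#' Rearrangement type labels
#' @export
TYPE_LEVELS <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX",
                 "X", "XI", "XII", "UNCLASSIFIED")

# Which LTR feature hosts each junction end (with a small slop to absorb
# chance flank matches during left-alignment).
ltr_pair_of <- function(junction, locus, slop = 5L) {
  feats <- locus$features
  ltrs <- feats[startsWith(feats$name, "delta"), , drop = FALSE]
  mh <- nchar(junction$mh_tract)
  find_ltr <- function(p) {
    ov <- vapply(seq_len(nrow(ltrs)), function(i) {
      interval_overlap(p - slop, p + max(mh, 1L) + slop, ltrs$start[i], ltrs$end[i])
    }, numeric(1))
    if (max(ov) == 0) NA_character_ else ltrs$name[which.max(ov)]
  }
  c(left = find_ltr(junction$del_left), right = find_ltr(junction$del_right))
}

#' Run the virtual typing assays on one clone
#'
#' Reproduces the bench workflow: digest the clone's genomic DNA, probe the
#' blot for a band near the repeat locus, then attempt the su47/su48 (local)
#' and su23/su42 (LTR-spanning) PCRs.
#'
#' @param locus A `locus_map`.
#' @param allele Clone allele sequence.
#' @param junction Optional precomputed `junction_call` (computed if NULL).
#' @param enzyme Survivor-blot enzyme (default "SspI"; EcoRV also supported).
#' @param min_overlap Band-detection threshold, see [southern()].
#' @param max_su4748,max_su2342 PCR product-size caps (bp).
#' @return List with `bands` (data.frame), `band` (logical), `p4748`,
#'   `p2342` (each a `pcr_product` or NULL), and `junction`.
#' @export
assay_clone <- function(locus, allele, junction = NULL, enzyme = "SspI",
                        min_overlap = 50L, max_su4748 = 3000L, max_su2342 = 5000L) {
  if (is.null(junction)) junction <- align_junction(locus$sequence, allele)
  probe <- locus_feature(locus, "probe")
  pieces <- map_interval_to_allele(junction, probe)
  frags <- digest(allele, enzyme_cut_positions(allele, enzyme))
  bands <- if (is.null(pieces)) {
    data.frame(size = numeric(0), probe_overlap = numeric(0),
               relative_signal = numeric(0))
  } else {
    southern(list(list(fragments = frags, fraction = 1)), pieces,
             min_overlap = min_overlap, probe_length = probe[2] - probe[1])
  }
  list(
    bands = bands,
    band = nrow(bands) > 0L,
    p4748 = pcr(allele, locus_primer_oligo(locus, "su47"),
                locus_primer_oligo(locus, "su48"), max_su4748),
    p2342 = pcr(allele, locus_primer_oligo(locus, "su23"),
                locus_primer_oligo(locus, "su42"), max_su2342),
    junction = junction
  )
}

# Map a reference interval through a junction into allele coordinates,
# returning the retained piece(s) as a 2-column matrix (or NULL).
map_interval_to_allele <- function(junction, iv) {
  dl <- junction$del_left
  dr <- junction$del_right
  shift <- nchar(junction$insertion) - (dr - dl)
  pieces <- list()
  if (iv[1] < dl) {
    pieces[[1]] <- c(iv[1], min(iv[2], dl))
  }
  if (iv[2] > dr) {
    a <- max(iv[1], dr)
    pieces[[length(pieces) + 1L]] <- c(a + shift, iv[2] + shift)
  }
  if (!length(pieces)) return(NULL)
  do.call(rbind, pieces)
}

#' Assign a rearrangement type from assay evidence
#'
#' Implements the published decision procedure: a Southern band routes the
#' clone to the local su47/su48 PCR (types I-V, falling back to su23/su42 for
#' IV-V when the su48 site is deleted); no band routes it directly to
#' su23/su42 (LTR fusions VI-X and inverted-duplication complex events XII);
#' no product at all is a very large deletion, type XI. Sequence-level
#' sub-calls use the junction call and the measured repeat length.
#'
#' @param assays Result of [assay_clone()].
#' @param junction A `junction_call` (defaults to `assays$junction`).
#' @param locus A `locus_map`.
#' @param allele Allele sequence (for repeat measurement).
#' @param config A [classify_config()].
#' @return A `type_call` list: `type`, plus an `evidence` list recording the
#'   ordered decision trail (band, PCR products, junction summary, repeat
#'   length after).
#' @export
classify_clone <- function(assays, junction = NULL, locus, allele,
                           config = classify_config()) {
  junction <- junction %||% assays$junction
  n0 <- locus$config$n_triplets %||%
    ((locus$repeat_interval[2] - locus$repeat_interval[1]) %/% 3L)
  unit <- locus$config$repeat_unit %||% "CTG"
  r <- locus$repeat_interval
  rep_after <- measure_repeat(allele, locus)

  del_len <- junction$del_right - junction$del_left
  ins_len <- nchar(junction$insertion)
  evidence <- list(
    southern_band = assays$band,
    su4748_product = if (is.null(assays$p4748)) NA_integer_ else assays$p4748$size,
    su2342_product = if (is.null(assays$p2342)) NA_integer_ else assays$p2342$size,
    junction = sprintf("del[%d,%d) ins=%dnt mh=%dnt", junction$del_left,
                       junction$del_right, ins_len, nchar(junction$mh_tract)),
    repeat_after = rep_after
  )
  finish <- function(type) {
    structure(list(type = type, evidence = evidence), class = "type_call")
  }

  rc_core_in_ref <- function(ins) {
    trim <- min(10L, nchar(ins) %/% 4L)
    core <- substr(ins, trim + 1L, nchar(ins) - trim)
    nchar(core) > 0L && length(str_find_all(revcomp(core), locus$sequence)) > 0L
  }

  if (!assays$band) {
    if (is.null(assays$p2342)) return(finish("XI"))
    if (ins_len >= config$complex_min_ins && rc_core_in_ref(junction$insertion)) {
      return(finish("XII"))
    }
    pair <- ltr_pair_of(junction, locus)
    key <- paste(pair["left"], pair["right"], sep = ".")
    if (!anyNA(pair) && pair["left"] != pair["right"] &&
        key %in% names(config$pair_type_map)) {
      if (ins_len >= config$min_ltr_pair_ins) return(finish(config$x_type))
      return(finish(unname(config$pair_type_map[key])))
    }
    return(finish("UNCLASSIFIED"))
  }

  # Southern band present: local analysis (types I-V)
  if (is.null(assays$p4748) && is.null(assays$p2342)) {
    return(finish("UNCLASSIFIED"))  # band but intact-primer amplification failed
  }
  if (del_len == 0L && ins_len == 0L) return(finish("I"))

  zone <- c(r[1] - config$repeat_margin, r[2] + config$repeat_margin)
  confined <- junction$del_left >= zone[1] && junction$del_right <= zone[2]
  if (confined) {
    region <- repeat_region(allele, locus)
    if (is_perfect_repeat(region, unit)) {
      m <- nchar(region) %/% nchar(unit)
      if (m >= n0 - config$type1_max_loss) return(finish("I"))
      return(finish("II"))
    }
    if (del_len <= config$local_indel_max && ins_len <= config$local_indel_max) {
      return(finish("III"))
    }
  }
  if (ins_len == 0L) finish("IV") else finish("V")
}

#' Classify a cohort of alleles
#'
#' Runs [align_junction()], [assay_clone()] and [classify_clone()] per clone.
#' Unalignable alleles are reported as UNCLASSIFIED with the error recorded.
#'
#' @param locus A `locus_map`.
#' @param alleles Named character vector (or `DNAStringSet`) of allele
#'   sequences; names are clone ids.
#' @param enzyme Survivor-blot enzyme (default "SspI").
#' @param config A [classify_config()].
#' @return data.frame of type calls with the evidence columns
#'   `southern_band`, `su4748_product`, `su2342_product`, `del_left`,
#'   `del_right`, `ins_len`, `mh_len`, `repeat_after`.
#' @export
classify_cohort <- function(locus, alleles, enzyme = "SspI",
                            config = classify_config()) {
  if (methods::is(alleles, "XStringSet")) {
    alleles <- stats::setNames(as.character(alleles), names(alleles))
  }
  ids <- names(alleles) %||% sprintf("clone_%04d", seq_along(alleles))
  rows <- lapply(seq_along(alleles), function(i) {
    al <- alleles[[i]]
    jc <- tryCatch(align_junction(locus$sequence, al), error = function(e) NULL)
    if (is.null(jc)) {
      return(data.frame(clone_id = ids[i], type = "UNCLASSIFIED",
                        southern_band = NA, su4748_product = NA_integer_,
                        su2342_product = NA_integer_, del_left = NA_integer_,
                        del_right = NA_integer_, ins_len = NA_integer_,
                        mh_len = NA_integer_, repeat_after = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    as <- assay_clone(locus, al, junction = jc, enzyme = enzyme)
    tc <- classify_clone(as, jc, locus, al, config)
    data.frame(clone_id = ids[i], type = tc$type,
               southern_band = tc$evidence$southern_band,
               su4748_product = tc$evidence$su4748_product,
               su2342_product = tc$evidence$su2342_product,
               del_left = jc$del_left, del_right = jc$del_right,
               ins_len = nchar(jc$insertion), mh_len = nchar(jc$mh_tract),
               repeat_after = tc$evidence$repeat_after,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-type counts and proportions
#'
#' @param calls Character vector of types, or a data.frame with a `type`
#'   column and optionally a `strain` column for per-strain grouping.
#' @param levels Category levels to retain (zero counts kept; default
#'   [TYPE_LEVELS]).
#' @return data.frame `strain`, `type`, `count`, `proportion`; proportions
#'   sum to 1 within each strain.
#' @export
summarize_types <- function(calls, levels = TYPE_LEVELS) {
  if (is.character(calls)) {
    calls <- data.frame(type = calls, stringsAsFactors = FALSE)
  }
  if (!nrow(calls)) stop("at least one type call is required")
  if (is.null(calls$strain)) calls$strain <- "all"
  out <- list()
  for (s in unique(calls$strain)) {
    tt <- table(factor(calls$type[calls$strain == s], levels = levels))
    out[[s]] <- data.frame(strain = s, type = names(tt),
                           count = as.integer(tt),
                           proportion = as.integer(tt) / sum(tt),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
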