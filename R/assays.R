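#' Virtual restriction digest
#'
#' Cuts a linear analysis window at the given positions. The window ends act
#' as flanking virtual sites, so the fragments always partition the window.
#'
#' @param sequence Allele sequence (character) or its length.
#' @param cut_positions Sorted 0-based cut positions within the window.
#' @return data.frame with `start`, `end` (0-based half-open) and `size`.
#' @export
digest <- function(sequence, cut_positions = integer(0)) {
  n <- if (is.character(sequence)) nchar(sequence) else as.integer(sequence)
  cuts <- sort(unique(as.integer(cut_positions)))
  if (length(cuts) && (min(cuts) < 0L || max(cuts) > n)) {
    stop("cut positions must lie within [0, ", n, "]")
  }
  bounds <- unique(c(0L, cuts, n))
  data.frame(
    start = bounds[-length(bounds)],
    end = bounds[-1],
    size = diff(bounds)
  )
}

#' Enzyme cut positions on an arbitrary allele sequence
#'
#' Rescans the allele for the enzyme's recognition motif (rearrangements move
#' or delete sites), returning blunt cut positions at the motif centre.
#'
#' @param sequence Allele sequence.
#' @param enzyme "EcoRV" or "SspI".
#' @return Integer vector of 0-based cut positions.
#' @export
enzyme_cut_positions <- function(sequence, enzyme = c("EcoRV", "SspI")) {
  enzyme <- match.arg(enzyme)
  motif <- if (enzyme == "EcoRV") ECORV_SITE else SSPI_SITE
  str_find_all(motif, sequence) - 1L + 3L
}

#' Virtual Southern blot of one lane
#'
#' A lane is a mixture of molecule species; each species contributes its
#' digest fragments at its molecule fraction. One band is reported per
#' distinct probe-overlapping fragment size; the band signal is
#' molecule fraction x (probe overlap / probe length), renormalized so the
#' lane sums to 1. Fragments whose probe overlap falls below `min_overlap`
#' are dropped, modelling the signal loss of partially deleted probe targets.
#'
#' @param lane List of species, each `list(fragments = <digest data.frame>,
#'   fraction = <molecule fraction>)`. Fractions must sum to 1.
#' @param probe Probe target interval `c(start, end)` in the species'
#'   fragment coordinates, or a 2-column matrix of intervals when a
#'   rearrangement has split the probe target.
#' @param min_overlap Minimum probe overlap (bp) for a detectable band.
#' @param probe_length Full probe length used for signal weighting; defaults
#'   to the total width of `probe`.
#' @param noise_sd Gaussian noise s.d. applied to each band signal before
#'   renormalization (default 0, deterministic).
#' @return data.frame of bands: `size`, `probe_overlap`, `relative_signal`,
#'   sorted by decreasing size. Zero rows if no fragment retains the probe.
#' @export
southern <- function(lane, probe, min_overlap = 50L, probe_length = NULL,
                     noise_sd = 0) {
  if (is.null(dim(probe))) probe <- matrix(probe, ncol = 2, byrow = TRUE)
  fractions <- vapply(lane, function(sp) sp$fraction, numeric(1))
  if (abs(sum(fractions) - 1) > 1e-6) {
    stop("molecule fractions in a lane must sum to 1")
  }
  plen <- probe_length %||% sum(probe[, 2] - probe[, 1])
  if (plen <= 0) stop("probe interval is empty")

  rows <- list()
  for (sp in lane) {
    fr <- sp$fragments
    win <- c(min(fr$start), max(fr$end))
    if (max(probe[, 2]) > win[2] || min(probe[, 1]) < win[1]) {
      stop("probe interval lies outside the analysis window")
    }
    for (i in seq_len(nrow(fr))) {
      ov <- sum(vapply(seq_len(nrow(probe)), function(j) {
        interval_overlap(fr$start[i], fr$end[i], probe[j, 1], probe[j, 2])
      }, numeric(1)))
      if (ov >= min_overlap) {
        rows[[length(rows) + 1L]] <- data.frame(
          size = fr$size[i], probe_overlap = ov,
          signal = sp$fraction * ov / plen
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(size = numeric(0), probe_overlap = numeric(0),
                      relative_signal = numeric(0)))
  }
  bands <- do.call(rbind, rows)
  bands <- stats::aggregate(cbind(signal, probe_overlap) ~ size, bands, sum)
  if (noise_sd > 0) {
    bands$signal <- pmax(0, bands$signal + stats::rnorm(nrow(bands), 0, noise_sd))
  }
  total <- sum(bands$signal)
  if (total <= 0) {
    return(data.frame(size = numeric(0), probe_overlap = numeric(0),
                      relative_signal = numeric(0)))
  }
  out <- data.frame(size = bands$size, probe_overlap = bands$probe_overlap,
                    relative_signal = bands$signal / total)
  out[order(-out$size), , drop = FALSE]
}

#' DSB fraction from Southern band signals
#'
#' The total 5' + 3' break-fragment signal as a fraction of the total lane
#' signal. Bands are assigned to the expected parental / 5' / 3' sizes within
#' a gel-resolution tolerance; an assignment ambiguity is an error.
#'
#' @param bands Band table from [southern()].
#' @param parental,fragment5,fragment3 Expected fragment sizes (bp).
#' @param tolerance Size-resolution tolerance (bp, default 30).
#' @return DSB fraction in `[0, 1]`.
#' @export
dsb_fraction <- function(bands, parental, fragment5, fragment3, tolerance = 30) {
  expected <- c(parental = parental, fragment5 = fragment5, fragment3 = fragment3)
  if (min(dist(expected)) <= tolerance) {
    stop("ambiguous band assignment: expected sizes ",
         paste(expected, collapse = ", "), " are within tolerance ", tolerance)
  }
  if (!nrow(bands)) return(0)
  sig <- c(parental = 0, fragment5 = 0, fragment3 = 0)
  for (i in seq_len(nrow(bands))) {
    hit <- which(abs(bands$size[i] - expected) <= tolerance)
    if (length(hit) > 1L) {
      stop("ambiguous band assignment: band of ", bands$size[i], " bp matches ",
           paste(names(expected)[hit], collapse = " and "))
    }
    if (length(hit) == 1L) sig[hit] <- sig[hit] + bands$relative_signal[i]
  }
  total <- sum(bands$relative_signal)
  unname((sig["fragment5"] + sig["fragment3"]) / total)
}

#' Virtual PCR
#'
#' Exact-match primer model (the underlying assays report binary
#' product/no-product outcomes): the forward primer must match the plus
#' strand, the reverse primer the minus strand, in convergent orientation,
#' and the shortest product not exceeding `max_product` is returned. A
#' deleted primer site yields no product.
#'
#' @param sequence Template (plus strand).
#' @param fwd,rev Primer oligos (>= 18 nt).
#' @param max_product Product-size cap in bp.
#' @return A `pcr_product` list (`size`, `start`, `end`, `sequence`) or
#'   `NULL`. Multiple non-nested candidate products raise a warning and the
#'   shortest is returned.
#' @export
pcr <- function(sequence, fwd, rev, max_product = 3000L) {
  if (nchar(fwd) < 18L || nchar(rev) < 18L) {
    stop("primers must be at least 18 nt")
  }
  f_starts <- str_find_all(fwd, sequence) - 1L
  r_starts <- str_find_all(revcomp(rev), sequence) - 1L
  if (!length(f_starts) || !length(r_starts)) return(NULL)
  cand <- list()
  for (f in f_starts) {
    ends <- r_starts[r_starts >= f] + nchar(rev)
    for (e in ends) {
      if (e - f <= max_product) cand[[length(cand) + 1L]] <- c(f, e)
    }
  }
  if (!length(cand)) return(NULL)
  sizes <- vapply(cand, function(x) x[2] - x[1], numeric(1))
  if (length(cand) > 1L) {
    # non-nested candidates (distinct primer-site pairs) are reported
    starts <- vapply(cand, `[`, numeric(1), 1L)
    if (length(unique(starts)) > 1L || length(unique(sizes)) > 1L) {
      warning("multiple PCR product candidates; returning the shortest")
    }
  }
  best <- cand[[which.min(sizes)]]
  structure(
    list(size = best[2] - best[1], start = best[1], end = best[2],
         sequence = seq0(sequence, best[1], best[2])),
    class = "pcr_product"
  )
}

#' Simulate a DSB time-point Southern lane and estimate the cut fraction
#'
#' Mixes uncut and cut molecules at the given fraction, digests both with the
#' chosen enzyme, detects bands with the repeat-spanning quantification
#' probe, and (optionally) perturbs band signals with Gaussian noise.
#'
#' @param locus A `locus_map`.
#' @param cut_fraction True fraction of broken molecules.
#' @param enzyme "EcoRV" (default) or "SspI".
#' @param noise_sd Band-signal noise s.d. (default 0).
#' @return Band table from [southern()].
#' @export
simulate_dsb_lane <- function(locus, cut_fraction, enzyme = "EcoRV", noise_sd = 0) {
  stopifnot(cut_fraction >= 0, cut_fraction <= 1)
  cuts <- locus$enzyme_sites[[enzyme]]
  lane <- list(
    list(fragments = digest(locus$sequence, cuts), fraction = 1 - cut_fraction),
    list(fragments = digest(locus$sequence, c(cuts, locus$cut_site)),
         fraction = cut_fraction)
  )
  lane <- lane[vapply(lane, function(sp) sp$fraction > 0, logical(1))]
  southern(lane, locus_feature(locus, "probe_dsb"), noise_sd = noise_sd)
}

#' Expected parental and DSB fragment sizes for a locus
#'
#' @param locus A `locus_map`.
#' @param enzyme "EcoRV" (default) or "SspI".
#' @return Named vector `parental`, `fragment5`, `fragment3` (bp).
#' @export
expected_dsb_sizes <- function(locus, enzyme = "EcoRV") {
  cuts <- locus$enzyme_sites[[enzyme]]
  left <- max(cuts[cuts <= locus$repeat_interval[1]])
  right <- min(cuts[cuts >= locus$repeat_interval[2]])
  c(parental = right - left,
    fragment5 = locus$cut_site - left,
    fragment3 = right - locus$cut_site)
}
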