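#' Configuration for the synthetic SUP4-like locus
#'
#' Describes a ~10 kb chromosome-X-like segment carrying a (CTG)n tract inside
#' a suppressor-tRNA gene, flanked by five Ty1 LTRs (delta16-delta20), two
#' primer pairs (su47/su48 close to the repeat, su23/su42 spanning the LTR
#' neighbourhood), a Southern probe ~300 bp downstream of the repeat, four
#' EcoRV sites (two on each side of the repeat), two SspI sites, and an
#' essential downstream gene (CDC8). All coordinates are 0-based half-open.
#'
#' Feature offsets are expressed relative to the repeat tract: negative values
#' are bp upstream of the repeat start, non-negative values are bp downstream
#' of the repeat end. The default geometry places delta19/delta20 nearest the
#' repeat, delta16/delta17 distal, KCH1 ~5 kb upstream, su23 between delta17
#' and delta18, and su42 between the probe region and CDC8.
#'
#' @param repeat_unit Repeat unit on the top strand (default "CTG").
#' @param n_triplets Number of repeat units (default 80).
#' @param guide_id Guide RNA: "gRNA1" cuts `cut_offset_triplets_3p` triplets
#'   from the repeat 3' end; "gRNA2" cuts 2 nt closer to the repeat 3' end.
#' @param cut_offset_triplets_3p Triplets left on the 3' DSB fragment
#'   (default 2).
#' @param d5_ecorv_proximal,d5_ecorv_distal EcoRV cut distances (bp) upstream
#'   of the repeat start.
#' @param d3_ecorv_proximal,d3_ecorv_distal EcoRV cut distances (bp)
#'   downstream of the repeat end.
#' @param d5_sspi,d3_sspi SspI cut distances flanking the repeat.
#' @param ltr_length LTR length in bp (default 330).
#' @param ltr_identity Pairwise fraction identity between non-identical LTR
#'   copies (default 0.85); implemented with disjoint per-copy mutation sets
#'   so every pairwise identity is deterministic.
#' @param feature_offsets Named list of `c(start, end)` offsets (see Details).
#' @param gc Background GC content (default 0.38, yeast-like).
#' @param cdc8_margin Promoter margin (bp) upstream of CDC8 that must stay
#'   intact for viability (default 180, which makes the viability bound
#'   coincide with the downstream edge of the su42 primer site).
#' @return A `locus_config` list.
#' @export
locus_config <- function(repeat_unit = "CTG",
                         n_triplets = 80L,
                         guide_id = c("gRNA1", "gRNA2"),
                         cut_offset_triplets_3p = 2L,
                         d5_ecorv_proximal = 911L,
                         d5_ecorv_distal = 1880L,
                         d3_ecorv_proximal = 815L,
                         d3_ecorv_distal = 2940L,
                         d5_sspi = 250L,
                         d3_sspi = 550L,
                         ltr_length = 330L,
                         ltr_identity = 0.85,
                         feature_offsets = default_feature_offsets(),
                         gc = 0.38,
                         cdc8_margin = 180L) {
  guide_id <- match.arg(guide_id)
  cfg <- list(
    repeat_unit = toupper(repeat_unit),
    n_triplets = as.integer(n_triplets),
    guide_id = guide_id,
    cut_offset_triplets_3p = as.integer(cut_offset_triplets_3p),
    d5_ecorv_proximal = as.integer(d5_ecorv_proximal),
    d5_ecorv_distal = as.integer(d5_ecorv_distal),
    d3_ecorv_proximal = as.integer(d3_ecorv_proximal),
    d3_ecorv_distal = as.integer(d3_ecorv_distal),
    d5_sspi = as.integer(d5_sspi),
    d3_sspi = as.integer(d3_sspi),
    ltr_length = as.integer(ltr_length),
    ltr_identity = ltr_identity,
    feature_offsets = feature_offsets,
    gc = gc,
    cdc8_margin = as.integer(cdc8_margin)
  )
  class(cfg) <- "locus_config"
  validate_locus_config(cfg)
  cfg
}

#' Default feature offsets of the synthetic locus
#'
#' Offsets in bp relative to the repeat: negative = upstream of repeat start,
#' non-negative = downstream of repeat end. `probe_dsb` spans the repeat and
#' is the hybridisation target used for DSB-level quantification; `probe` is
#' the downstream survivor-typing probe.
#'
#' @return Named list of `c(start, end)` integer offsets.
#' @export
default_feature_offsets <- function() {
  list(
    KCH1      = c(-5600L, -5000L),
    delta16   = c(-4500L, -4170L),
    delta17   = c(-3900L, -3570L),
    su23      = c(-3400L, -3380L),
    delta18   = c(-3100L, -2770L),
    delta19   = c(-1600L, -1270L),
    su47      = c(-180L,  -160L),
    probe_dsb = c(-150L,   150L),
    probe     = c(280L,    480L),
    su48      = c(500L,    520L),
    delta20   = c(900L,   1230L),
    su42      = c(1400L,  1420L),
    CDC8      = c(1600L,  2200L),
    ARS       = c(3100L,  3300L)
  )
}

validate_locus_config <- function(cfg) {
  stopifnot(nchar(cfg$repeat_unit) == 3L)
  if (cfg$n_triplets < 1L) stop("invalid config: n_triplets >= 1 required")
  dists <- c(cfg$d5_ecorv_proximal, cfg$d5_ecorv_distal,
             cfg$d3_ecorv_proximal, cfg$d3_ecorv_distal,
             cfg$d5_sspi, cfg$d3_sspi)
  if (any(dists <= 0L)) stop("invalid config: all enzyme distances must be > 0")
  if (cfg$d5_ecorv_proximal >= cfg$d5_ecorv_distal) {
    stop("invalid config: d5_ecorv_proximal < d5_ecorv_distal required")
  }
  if (cfg$d3_ecorv_proximal >= cfg$d3_ecorv_distal) {
    stop("invalid config: d3_ecorv_proximal < d3_ecorv_distal required")
  }
  if (cfg$cut_offset_triplets_3p < 0L) {
    stop("invalid config: cut_offset_triplets_3p >= 0 required")
  }
  if (cfg$cut_offset_triplets_3p > cfg$n_triplets) {
    stop("invalid config: cut offset exceeds repeat length")
  }
  off <- cfg$feature_offsets
  need <- c("delta16", "delta17", "delta18", "delta19", "delta20",
            "su23", "su47", "su48", "su42", "probe", "probe_dsb", "CDC8")
  missing <- setdiff(need, names(off))
  if (length(missing)) {
    stop("invalid config: missing feature offsets: ", paste(missing, collapse = ", "))
  }
  for (nm in names(off)) {
    if (off[[nm]][1] >= off[[nm]][2]) {
      stop("invalid config: feature ", nm, " has start >= end")
    }
  }
  # CDC8 must lie downstream of the su42 primer site (essential-gene bound).
  if (off$CDC8[1] <= off$su42[2]) {
    stop("invalid config: CDC8 interval must lie downstream of su42")
  }
  # The survivor probe must sit downstream of the repeat, inside the 3'
  # proximal EcoRV fragment so the 3' DSB fragment carries it.
  if (off$probe[1] < 0L || off$probe[2] > cfg$d3_ecorv_proximal) {
    stop("invalid config: probe must lie between the repeat end and the 3' proximal EcoRV site")
  }
  ltrs <- c("delta16", "delta17", "delta18", "delta19", "delta20")
  for (nm in ltrs) {
    if (diff(off[[nm]]) != cfg$ltr_length) {
      stop("invalid config: LTR ", nm, " offsets do not match ltr_length")
    }
  }
  if (cfg$ltr_identity < 0 || cfg$ltr_identity > 1) {
    stop("invalid config: ltr_identity must be in [0, 1]")
  }
  k <- ltr_mut_count(cfg$ltr_length, cfg$ltr_identity)
  if (5L * k > cfg$ltr_length) {
    stop("invalid config: ltr_identity too low for disjoint mutation sets")
  }
  invisible(cfg)
}

ltr_mut_count <- function(len, identity) as.integer(round(len * (1 - identity) / 2))

#' Calibrate EcoRV flanking distances from printed DSB fragment sizes
#'
#' Solves the proximal EcoRV distances so that the virtual digest of the
#' built locus reproduces the observed 5'-end and 3'-end DSB fragment sizes,
#' and predicts the parental (uncut) fragment.
#'
#' @param frag5 Observed 5' DSB fragment size (bp); the fragment carrying
#'   most of the repeat tract.
#' @param frag3 Observed 3' DSB fragment size (bp); the fragment carrying
#'   `cut_offset_triplets_3p` triplets.
#' @param n_triplets Repeat length in triplets.
#' @param cut_offset_triplets_3p Triplets left on the 3' fragment.
#' @return List with `d5_proximal`, `d3_proximal` (bp) and the predicted
#'   `parental` fragment size `d5 + 3 n + d3`.
#' @examples
#' calibrate_distances(1145, 821, 80, 2)  # d5 = 911, d3 = 815, parental 1966
#' @export
calibrate_distances <- function(frag5, frag3, n_triplets, cut_offset_triplets_3p) {
  n <- as.integer(n_triplets)
  off <- as.integer(cut_offset_triplets_3p)
  d5 <- as.integer(frag5) - 3L * (n - off)
  d3 <- as.integer(frag3) - 3L * off
  if (d5 <= 0L) {
    stop("calibration error: frag5 > 3*(n_triplets - cut_offset) violated (d5 = ", d5, ")")
  }
  if (d3 <= 0L) {
    stop("calibration error: frag3 > 3*cut_offset violated (d3 = ", d3, ")")
  }
  list(d5_proximal = d5, d3_proximal = d3, parental = d5 + 3L * n + d3)
}

ECORV_SITE <- "GATATC"  # blunt cutter, GAT|ATC
SSPI_SITE  <- "AATATT"  # blunt cutter, AAT|ATT

#' Build the synthetic locus
#'
#' Generates a reproducible annotated sequence: seeded random background at
#' the configured GC content, the repeat tract with its PAM, an LTR family
#' with controlled pairwise identity, planted primer sites and restriction
#' motifs. Background is rejection-sampled so that no spurious EcoRV/SspI
#' site, primer match (either strand) or repeat-unit run (>= 3 units, either
#' strand; this also removes PAM-adjacent guide matches) survives outside its
#' sanctioned location.
#'
#' @param config A [locus_config()].
#' @param seed Integer seed; identical (config, seed) give byte-identical
#'   sequences.
#' @return A `locus_map` list with elements `sequence`, `features`
#'   (data.frame: name, start, end, strand; 0-based half-open), `cut_site`,
#'   `repeat_interval`, `enzyme_sites` (cut positions per enzyme), `config`,
#'   and `aux` (auxiliary sequences: `ty_internal`, a synthetic Ty1 internal
#'   fragment used as capture donor).
#' @export
build_locus <- function(config = locus_config(), seed = 1L) {
  validate_locus_config(config)
  with_seed(seed, build_locus_impl(config))
}

build_locus_impl <- function(cfg) {
  off <- cfg$feature_offsets
  rep_len <- 3L * cfg$n_triplets
  starts <- vapply(off, `[`, numeric(1), 1L)
  ends <- vapply(off, `[`, numeric(1), 2L)
  pad <- 200L
  r0 <- as.integer(pad - min(c(starts, -cfg$d5_ecorv_distal - 3L)))
  re <- r0 + rep_len
  total <- as.integer(re + max(c(ends, cfg$d3_ecorv_distal + 3L)) + pad)

  abs_int <- function(o) {
    a <- if (o[1] < 0L) r0 + o[1] else re + o[1]
    b <- if (o[2] <= 0L) r0 + o[2] else re + o[2]
    c(as.integer(a), as.integer(b))
  }
  feats <- lapply(off, abs_int)

  ecorv_cuts <- sort(c(r0 - cfg$d5_ecorv_distal, r0 - cfg$d5_ecorv_proximal,
                       re + cfg$d3_ecorv_proximal, re + cfg$d3_ecorv_distal))
  sspi_cuts <- sort(c(r0 - cfg$d5_sspi, re + cfg$d3_sspi))
  motif_ivs <- rbind(cbind(ecorv_cuts - 3L, ecorv_cuts + 3L),
                     cbind(sspi_cuts - 3L, sspi_cuts + 3L))

  forbidden <- c(ECORV_SITE, SSPI_SITE,
                 strrep(cfg$repeat_unit, 3L), strrep(revcomp(cfg$repeat_unit), 3L))

  base_probs <- c(A = (1 - cfg$gc) / 2, C = cfg$gc / 2, G = cfg$gc / 2, T = (1 - cfg$gc) / 2)
  rand_dna <- function(n) {
    paste(sample(names(base_probs), n, replace = TRUE, prob = base_probs), collapse = "")
  }
  rand_clean <- function(n, extra = character(0)) {
    pats <- c(forbidden, extra)
    for (i in 1:100) {
      s <- rand_dna(n)
      if (!any(vapply(pats, function(p) length(str_find_all(p, s)) > 0, logical(1)))) return(s)
    }
    stop("placement conflict: could not generate clean sequence of length ", n)
  }

  # LTR family: one sanitized consensus, disjoint mutated position sets per
  # copy so that every pairwise identity is 1 - 2k/len.
  ltr_names <- c("delta16", "delta17", "delta18", "delta19", "delta20")
  base_ltr <- rand_clean(cfg$ltr_length)
  k <- ltr_mut_count(cfg$ltr_length, cfg$ltr_identity)
  pool <- sample.int(cfg$ltr_length)
  cycle <- c(A = "C", C = "G", G = "T", T = "A")
  ltr_seqs <- list()
  for (i in seq_along(ltr_names)) {
    s <- strsplit(base_ltr, "")[[1]]
    if (k > 0L) {
      pos <- pool[((i - 1L) * k + 1L):(i * k)]
      s[pos] <- cycle[s[pos]]
    }
    seq_i <- paste(s, collapse = "")
    for (p in forbidden) {
      hits <- str_find_all(p, seq_i)
      for (h in hits) {  # break the motif without touching mutated positions
        j <- h + 2L
        substr(seq_i, j, j) <- cycle[[substr(seq_i, j, j)]]
      }
    }
    ltr_seqs[[ltr_names[i]]] <- seq_i
  }

  # Primer-site contents (plus-strand sequence at the annotated interval).
  primer_names <- c("su23", "su47", "su48", "su42")
  primer_seqs <- list()
  for (nm in primer_names) {
    len <- diff(feats[[nm]])
    primer_seqs[[nm]] <- rand_clean(len, extra = unlist(primer_seqs, use.names = FALSE))
  }

  chars <- strsplit(rand_dna(total), "")[[1]]
  plant <- function(chars, start, s) {
    chars[(start + 1L):(start + nchar(s))] <- strsplit(s, "")[[1]]
    chars
  }
  chars <- plant(chars, r0, strrep(cfg$repeat_unit, cfg$n_triplets))
  chars <- plant(chars, re, "TGG")  # PAM at the repeat / non-repeat border
  for (nm in ltr_names) chars <- plant(chars, feats[[nm]][1], ltr_seqs[[nm]])
  for (nm in primer_names) chars <- plant(chars, feats[[nm]][1], primer_seqs[[nm]])
  for (cut in ecorv_cuts) chars <- plant(chars, cut - 3L, ECORV_SITE)
  for (cut in sspi_cuts) chars <- plant(chars, cut - 3L, SSPI_SITE)

  # Protected intervals that the cleanup pass must not mutate.
  protected <- rbind(
    c(r0, re + 3L),
    do.call(rbind, lapply(c(ltr_names, primer_names), function(nm) feats[[nm]])),
    motif_ivs
  )
  in_protected <- rep(FALSE, total)
  for (i in seq_len(nrow(protected))) {
    in_protected[(protected[i, 1] + 1L):protected[i, 2]] <- TRUE
  }

  # Cleanup: remove every forbidden-motif occurrence outside its sanctioned
  # location by mutating one unprotected base inside the match.
  allowed_starts <- list()
  allowed_starts[[ECORV_SITE]] <- ecorv_cuts - 3L
  allowed_starts[[SSPI_SITE]] <- sspi_cuts - 3L
  scan_targets <- c(forbidden, unlist(primer_seqs, use.names = FALSE),
                    vapply(primer_seqs, revcomp, character(1)))
  names(scan_targets) <- NULL
  for (nm in primer_names) {
    allowed_starts[[primer_seqs[[nm]]]] <- feats[[nm]][1]
  }
  unit3 <- strrep(cfg$repeat_unit, 3L)
  for (iter in 1:100) {
    seq_str <- paste(chars, collapse = "")
    dirty <- FALSE
    for (p in scan_targets) {
      hits <- str_find_all(p, seq_str) - 1L  # 0-based starts
      ok <- allowed_starts[[p]] %||% integer(0)
      for (h in hits) {
        if (h %in% ok) next
        # repeat-unit runs overlapping the tract itself are fine
        if (p == unit3 && intervals_intersect(h, h + nchar(p), r0, re)) next
        cand <- (h + 1L):(h + nchar(p))
        cand <- cand[!in_protected[cand]]
        if (!length(cand)) {
          stop("placement conflict: forbidden motif '", p,
               "' at ", h, " overlaps only protected features")
        }
        j <- cand[ceiling(length(cand) / 2)]
        chars[j] <- cycle[[chars[j]]]
        dirty <- TRUE
      }
    }
    if (!dirty) break
    if (iter == 100L) stop("placement conflict: motif cleanup did not converge")
  }
  seq_str <- paste(chars, collapse = "")

  cut_site <- re - 3L * cfg$cut_offset_triplets_3p +
    if (cfg$guide_id == "gRNA2") 2L else 0L

  strand_of <- c(KCH1 = "+", delta16 = "+", delta17 = "+", su23 = "+",
                 delta18 = "+", delta19 = "+", su47 = "+", probe_dsb = "+",
                 probe = "+", su48 = "-", delta20 = "+", su42 = "-",
                 CDC8 = "+", ARS = "+")
  strands <- unname(strand_of[names(feats)])
  strands[is.na(strands)] <- "+"
  features <- data.frame(
    name = c(names(feats), "repeat"),
    start = as.integer(c(vapply(feats, `[`, numeric(1), 1L), r0)),
    end = as.integer(c(vapply(feats, `[`, numeric(1), 2L), re)),
    strand = c(strands, "+"),
    stringsAsFactors = FALSE
  )
  features <- features[order(features$start), , drop = FALSE]
  rownames(features) <- NULL

  map <- list(
    sequence = seq_str,
    features = features,
    cut_site = as.integer(cut_site),
    repeat_interval = c(r0, re),
    enzyme_sites = list(EcoRV = as.integer(ecorv_cuts), SspI = as.integer(sspi_cuts)),
    config = cfg,
    aux = list(ty_internal = rand_clean(500L))
  )
  class(map) <- "locus_map"
  validate_locus_map(map)
  map
}

validate_locus_map <- function(map) {
  n <- nchar(map$sequence)
  if (any(map$features$start < 0L) || any(map$features$end > n)) {
    stop("invalid locus map: feature outside sequence bounds")
  }
  r <- map$repeat_interval
  if (map$cut_site <= r[1] || map$cut_site >= r[2]) {
    stop("invalid locus map: cut site outside the repeat interval")
  }
  ec <- map$enzyme_sites$EcoRV
  if (sum(ec < r[1]) != 2L || sum(ec >= r[2]) != 2L) {
    stop("invalid locus map: need exactly 2 EcoRV sites on each side of the repeat")
  }
  invisible(map)
}

#' @export
print.locus_map <- function(x, ...) {
  cat("Synthetic SUP4-like locus:", nchar(x$sequence), "bp\n")
  cat("  repeat:", x$repeat_interval[1], "-", x$repeat_interval[2],
      sprintf("(%d x %s)", x$config$n_triplets %||% NA, x$config$repeat_unit %||% "?"), "\n")
  cat("  cut site:", x$cut_site, "\n")
  cat("  EcoRV cuts:", paste(x$enzyme_sites$EcoRV, collapse = ", "), "\n")
  cat("  features:", nrow(x$features), "\n")
  invisible(x)
}

#' Look up a feature interval
#'
#' @param locus A `locus_map`.
#' @param name Feature name.
#' @return `c(start, end)`, 0-based half-open.
#' @export
locus_feature <- function(locus, name) {
  i <- match(name, locus$features$name)
  if (is.na(i)) stop("unknown feature: ", name)
  c(locus$features$start[i], locus$features$end[i])
}

#' Primer oligo sequence for an annotated primer site
#'
#' Returns the oligonucleotide as synthesised (reverse-complemented for
#' minus-strand primers).
#'
#' @param locus A `locus_map`.
#' @param name Primer feature name (e.g. "su47").
#' @return Character oligo.
#' @export
locus_primer_oligo <- function(locus, name) {
  iv <- locus_feature(locus, name)
  s <- seq0(locus$sequence, iv[1], iv[2])
  strand <- locus$features$strand[match(name, locus$features$name)]
  if (strand == "-") revcomp(s) else s
}

#' Write a locus to FASTA + BED
#'
#' The BED file (0-based half-open) carries all features plus a 1 bp
#' `cut_site` marker; enzyme sites are re-derivable from the sequence and are
#' not serialized. An optional TSV of enzyme cut positions can be written.
#'
#' @param locus A `locus_map`.
#' @param fasta,bed Output paths.
#' @param enzymes_tsv Optional path for the enzyme-site table.
#' @return Invisibly, the paths written.
#' @export
write_locus <- function(locus, fasta, bed, enzymes_tsv = NULL) {
  dna <- Biostrings::DNAStringSet(locus$sequence)
  names(dna) <- "locusX"
  Biostrings::writeXStringSet(dna, fasta, width = 70L)
  feats <- locus$features
  bed_df <- data.frame(
    chrom = "locusX",
    start = c(feats$start, locus$cut_site),
    end = c(feats$end, locus$cut_site + 1L),
    name = c(feats$name, "cut_site"),
    score = 0L,
    strand = c(feats$strand, "+")
  )
  utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(enzymes_tsv)) {
    enz <- data.frame(
      enzyme = rep(names(locus$enzyme_sites), lengths(locus$enzyme_sites)),
      cut_position = unlist(locus$enzyme_sites, use.names = FALSE)
    )
    utils::write.table(enz, enzymes_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(fasta = fasta, bed = bed))
}

#' Read a locus from FASTA + BED
#'
#' Inverse of [write_locus()]: reconstructs the sequence, features, cut site
#' and enzyme sites (by motif scan). `config` and `aux` are not serialized
#' and come back `NULL`.
#'
#' @param fasta,bed Input paths.
#' @return A `locus_map`.
#' @export
read_locus <- function(fasta, bed) {
  dna <- tryCatch(Biostrings::readDNAStringSet(fasta),
                  error = function(e) stop("FASTA parse error in '", fasta, "': ",
                                           conditionMessage(e)))
  if (length(dna) != 1L) stop("FASTA parse error: expected exactly one record, got ", length(dna))
  seq_str <- as.character(dna[[1]])

  lines <- readLines(bed)
  lines <- lines[nzchar(lines)]
  feats <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L) stop("BED parse error at line ", i, ": expected 6 fields, got ", length(f))
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end) || start < 0L || end <= start) {
      stop("BED parse error at line ", i, ": invalid interval [", f[2], ", ", f[3], ")")
    }
    if (!f[6] %in% c("+", "-", ".")) stop("BED parse error at line ", i, ": bad strand '", f[6], "'")
    feats[[i]] <- data.frame(name = f[4], start = start, end = end,
                             strand = f[6], stringsAsFactors = FALSE)
  }
  features <- if (length(feats)) do.call(rbind, feats) else {
    data.frame(name = character(0), start = integer(0), end = integer(0),
               strand = character(0), stringsAsFactors = FALSE)
  }

  cut_i <- which(features$name == "cut_site")
  cut_site <- if (length(cut_i)) features$start[cut_i[1]] else NA_integer_
  features <- features[features$name != "cut_site", , drop = FALSE]
  rownames(features) <- NULL

  rep_i <- which(features$name == "repeat")
  repeat_interval <- if (length(rep_i)) {
    c(features$start[rep_i[1]], features$end[rep_i[1]])
  } else c(NA_integer_, NA_integer_)

  map <- list(
    sequence = seq_str,
    features = features,
    cut_site = cut_site,
    repeat_interval = repeat_interval,
    enzyme_sites = list(
      EcoRV = str_find_all(ECORV_SITE, seq_str) - 1L + 3L,
      SspI = str_find_all(SSPI_SITE, seq_str) - 1L + 3L
    ),
    config = NULL,
    aux = NULL
  )
  class(map) <- "locus_map"
  map
}
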