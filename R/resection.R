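#' Raw resection fraction from qPCR Ct values
#'
#' A resected (single-stranded) restriction site resists digestion and stays
#' amplifiable; the estimator is `raw = 2 / (1 + 2^deltaCt)` with
#' `deltaCt = mean(Ct_digested) - mean(Ct_mock)` over replicates. If no
#' digested well amplified, the site was fully digested (double-stranded):
#' raw resection is 0.
#'
#' @param ct_digested Numeric replicate Ct values of the digested fraction;
#'   all-`NA` means "no amplification".
#' @param ct_mock Numeric replicate Ct values of the mock digestion.
#' @return Raw resected fraction in `[0, 1]`.
#' @examples
#' raw_resection(23, 22)  # deltaCt = 1 -> 2/3
#' @export
raw_resection <- function(ct_digested, ct_mock) {
  mock <- ct_mock[!is.na(ct_mock)]
  if (!length(mock)) stop("estimation error: no mock Ct replicate available")
  dig <- ct_digested[!is.na(ct_digested)]
  if (!length(dig)) return(0)
  dct <- mean(dig) - mean(mock)
  2 / (1 + 2^dct)
}

#' Relative resection: raw resection over the DSB fraction
#'
#' Raw resection counts resected molecules among all molecules; dividing by
#' the fraction of broken molecules rescales it to the broken population.
#' Values slightly above 1 (sampling noise) are clamped to 1 with a warning;
#' values above `1 + tolerance` indicate inconsistent inputs and are an
#' error.
#'
#' @param raw Raw resected fraction.
#' @param dsb DSB fraction at the same time point (> 0).
#' @param tolerance Clamping tolerance (default 0.1).
#' @return Relative resection in `[0, 1]`.
#' @export
relative_resection <- function(raw, dsb, tolerance = 0.1) {
  if (dsb <= 0) stop("undefined resection: DSB fraction must be > 0")
  rel <- raw / dsb
  if (rel > 1 + tolerance) {
    stop("relative resection ", signif(rel, 4),
         " exceeds 1 + tolerance; raw and DSB inputs are inconsistent")
  }
  if (rel > 1) {
    warning("relative resection ", signif(rel, 4), " clamped to 1")
    rel <- 1
  }
  max(0, rel)
}

#' Relative copy number by the delta-delta-Ct method
#'
#' `2^-ddCt` with `ddCt = (target - control)_sample -
#' (target - control)_calibrator`; a sample target one cycle late relative to
#' its control corresponds to half the copy number.
#'
#' @param ct_target_sample,ct_control_sample,ct_target_calibrator,ct_control_calibrator
#'   Mean Ct values (replicate vectors are averaged).
#' @return Copy-number ratio.
#' @export
copy_number <- function(ct_target_sample, ct_control_sample,
                        ct_target_calibrator, ct_control_calibrator) {
  vals <- list(ct_target_sample, ct_control_sample,
               ct_target_calibrator, ct_control_calibrator)
  if (any(vapply(vals, function(x) all(is.na(x)), logical(1)))) {
    stop("all four Ct values are required")
  }
  m <- vapply(vals, function(x) mean(x, na.rm = TRUE), numeric(1))
  ddct <- (m[1] - m[2]) - (m[3] - m[4])
  2^(-ddct)
}

#' Resection profile from a replicate-level Ct table
#'
#' Aggregates a tidy Ct table (one row per site, time point and replicate)
#' into per-(site, timepoint) delta-Ct, raw resection and, when a DSB
#' fraction is supplied, relative resection.
#'
#' @param ct_table data.frame with columns `site_id`, `ct_mock`,
#'   `ct_digested` and optionally `timepoint` and `dsb_fraction`
#'   (`ct_digested = NA` marks no amplification).
#' @param tolerance Passed to [relative_resection()].
#' @return data.frame: `site_id`, `timepoint`, `delta_ct`, `raw_resection`,
#'   `dsb_fraction`, `relative_resection`.
#' @export
quantify_resection <- function(ct_table, tolerance = 0.1) {
  need <- c("site_id", "ct_mock", "ct_digested")
  missing <- setdiff(need, names(ct_table))
  if (length(missing)) stop("ct_table lacks columns: ", paste(missing, collapse = ", "))
  if (is.null(ct_table$timepoint)) ct_table$timepoint <- 0
  keys <- unique(ct_table[, c("site_id", "timepoint")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- ct_table$site_id == keys$site_id[i] & ct_table$timepoint == keys$timepoint[i]
    sub <- ct_table[sel, , drop = FALSE]
    raw <- raw_resection(sub$ct_digested, sub$ct_mock)
    dig <- sub$ct_digested[!is.na(sub$ct_digested)]
    dct <- if (length(dig)) mean(dig) - mean(sub$ct_mock, na.rm = TRUE) else Inf
    dsb <- if (!is.null(sub$dsb_fraction)) sub$dsb_fraction[1] else NA_real_
    rel <- if (!is.na(dsb)) relative_resection(raw, dsb, tolerance) else NA_real_
    data.frame(site_id = keys$site_id[i], timepoint = keys$timepoint[i],
               delta_ct = dct, raw_resection = raw, dsb_fraction = dsb,
               relative_resection = rel, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write replicate-level Ct tables
#'
#' @param path TSV path with columns `site_id`, `timepoint`, `replicate`,
#'   `ct_digested`, `ct_mock` ("NA" for no amplification).
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("site_id", "ct_mock", "ct_digested")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("Ct table lacks columns: ", paste(missing, collapse = ", "))
  df
}

#' @rdname read_ct_table
#' @param ct_table data.frame to write.
#' @export
write_ct_table <- function(ct_table, path) {
  utils::write.table(ct_table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
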