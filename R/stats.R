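#' Survival rate from CFU counts
#'
#' Survival after nuclease induction is the ratio of colony-forming units on
#' inducing (galactose) plates over repressing (glucose) plates, per
#' replicate, with a t-based 95% confidence interval across replicates.
#'
#' @param cfu_galactose,cfu_glucose Replicate CFU counts.
#' @param conf_level Confidence level (default 0.95).
#' @return List: `rates` (per replicate; NA where the glucose count is 0),
#'   `mean`, `ci_half` (half-width; NA with a single usable replicate).
#' @export
survival_rate <- function(cfu_galactose, cfu_glucose, conf_level = 0.95) {
  stopifnot(length(cfu_galactose) == length(cfu_glucose),
            all(cfu_galactose >= 0), all(cfu_glucose >= 0))
  if (all(cfu_glucose == 0)) {
    stop("undefined rate: no replicate has a non-zero glucose CFU count")
  }
  rates <- ifelse(cfu_glucose > 0, cfu_galactose / cfu_glucose, NA_real_)
  if (any(is.na(rates))) {
    warning("replicates with zero glucose CFU dropped from the rate estimate")
  }
  ok <- rates[!is.na(rates)]
  ci <- if (length(ok) > 1L) {
    stats::qt(1 - (1 - conf_level) / 2, df = length(ok) - 1L) *
      stats::sd(ok) / sqrt(length(ok))
  } else NA_real_
  list(rates = rates, mean = mean(ok), ci_half = ci)
}

#' Compare survival of strains against a reference with Bonferroni control
#'
#' Two-sample t-tests (Welch by default; the pooled-variance Student test is
#' available) of each group's replicate rates against the reference group,
#' with Bonferroni adjustment `p_adj = min(1, p * m)` over the `m`
#' comparisons and significance stars at adjusted 0.05 / 0.01 / 0.001.
#'
#' @param groups Named list; each element a numeric vector of replicate
#'   survival rates (or a data.frame with `cfu_galactose` / `cfu_glucose`
#'   columns, converted via [survival_rate()]).
#' @param reference Name of the reference group.
#' @param welch Use Welch's unequal-variance t-test (default TRUE).
#' @return data.frame: `strain`, `mean`, `p_raw`, `p_adj`, `signif`. Groups
#'   with fewer than 2 replicates are skipped with a warning.
#' @export
compare_survival <- function(groups, reference, welch = TRUE) {
  as_rates <- function(g) {
    if (is.data.frame(g)) {
      r <- survival_rate(g$cfu_galactose, g$cfu_glucose)$rates
      r[!is.na(r)]
    } else g
  }
  if (!reference %in% names(groups)) stop("unknown reference group: ", reference)
  ref <- as_rates(groups[[reference]])
  if (length(ref) < 2L) stop("reference group needs >= 2 replicates")
  others <- setdiff(names(groups), reference)
  rows <- list()
  for (nm in others) {
    x <- as_rates(groups[[nm]])
    if (length(x) < 2L) {
      warning("group '", nm, "' has < 2 replicates; skipped")
      next
    }
    p <- stats::t.test(x, ref, var.equal = !welch)$p.value
    rows[[nm]] <- data.frame(strain = nm, mean = mean(x), p_raw = p,
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no comparable groups")
  out <- do.call(rbind, rows)
  m <- nrow(out)
  out$p_adj <- pmin(1, out$p_raw * m)
  out$signif <- cut(out$p_adj, c(-Inf, 0.001, 0.01, 0.05, Inf),
                    labels = c("***", "**", "*", ""))
  rownames(out) <- NULL
  out
}

#' Chi-squared comparison of rearrangement-type distributions
#'
#' Pearson chi-squared on the strain x type contingency table, without
#' continuity correction by default (switchable). Categories observed in no
#' strain are dropped before testing.
#'
#' @param table Matrix or data.frame of counts, strains in rows, types in
#'   columns.
#' @param correct Yates continuity correction (default FALSE).
#' @return List: `statistic`, `df`, `p_value`, `expected`.
#' @export
compare_types <- function(table, correct = FALSE) {
  m <- as.matrix(table)
  if (nrow(m) < 2L) stop("need counts for at least 2 groups")
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (ncol(m) < 2L || nrow(m) < 2L) stop("degenerate contingency table after dropping empty categories")
  ht <- suppressWarnings(stats::chisq.test(m, correct = correct))
  if (any(ht$expected == 0)) {
    warning("expected count of 0 in a retained cell; consider collapsing categories")
  }
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, expected = ht$expected)
}

#' Fisher exact and Mann-Whitney-Wilcoxon convenience wrappers
#'
#' Two-sided p-values for small-count 2x2 comparisons and rank comparisons.
#'
#' @param table A 2x2 count matrix.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(table) {
  m <- as.matrix(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate table: empty margin")
  }
  stats::fisher.test(m, alternative = "two.sided")$p.value
}

#' @rdname fisher_exact
#' @param x,y Numeric samples.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("degenerate input: empty sample")
  suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))$p.value
}

#' Write a deterministic cohort report
#'
#' Emits the per-strain type-proportion table, the survival table and the
#' resection profile as TSV, plus a short plain-text summary. Re-running on
#' identical inputs reproduces the files byte-identically.
#'
#' @param type_summary data.frame from [summarize_types()] (may be NULL).
#' @param survival data.frame (strain, mean, ci_half, ...) or NULL.
#' @param resection data.frame from [quantify_resection()] or NULL.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
report <- function(type_summary = NULL, survival = NULL, resection = NULL,
                   out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  if (!is.null(type_summary)) paths <- c(paths, wr(type_summary, "type_proportions.tsv"))
  if (!is.null(survival)) paths <- c(paths, wr(survival, "survival.tsv"))
  if (!is.null(resection)) paths <- c(paths, wr(resection, "resection_profile.tsv"))
  summary_path <- file.path(out_dir, "summary.txt")
  lines <- c("Cohort report")
  if (!is.null(type_summary) && nrow(type_summary)) {
    for (s in unique(type_summary$strain)) {
      sub <- type_summary[type_summary$strain == s & type_summary$count > 0, ]
      lines <- c(lines, sprintf("strain %s: n = %d; %s", s, sum(sub$count),
                                paste(sprintf("%s %.1f%%", sub$type, 100 * sub$proportion),
                                      collapse = ", ")))
    }
  } else {
    lines <- c(lines, "no type calls")
  }
  writeLines(lines, summary_path)
  invisible(c(paths, summary_path))
}
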