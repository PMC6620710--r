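# Colocalization statistics: probe dichotomization (MET+/MET-), proximity
# labeling (AGO+/AGO-), 2x2 contingency tables with odds ratio, Wald 95% CI
# and chi-square test, promoter-level Pearson correlation, and the
# proximity / TSS-relative positional profiles.

#' Keep promoters bound by at most one protein
#'
#' A promoter is retained if its boundary (start of probe 1 to end of
#' probe 15) overlaps binding sites of exactly one protein, or none at all
#' (unbound promoters stay in as the AGO- background). Promoters touched
#' by two or more distinct proteins are excluded to avoid attributing
#' methylation to the wrong protein.
#'
#' @param promoters promoter data.frame from [build_promoters()].
#' @param sites site data.frame carrying an `ago` protein label.
#' @return the retained promoter rows, with attribute `n_excluded`.
#' @export
select_exclusive_promoters <- function(promoters, sites) {
  if (is.null(sites) || nrow(sites) == 0L) {
    attr(promoters, "n_excluded") <- 0L
    return(promoters)
  }
  pg <- intervals_to_granges(promoters)
  sg <- intervals_to_granges(sites)
  hits <- GenomicRanges::findOverlaps(pg, sg, ignore.strand = TRUE)
  prot <- tapply(sites$ago[S4Vectors::subjectHits(hits)],
                 S4Vectors::queryHits(hits),
                 function(x) length(unique(x)))
  multi <- as.integer(names(prot)[prot > 1])
  keep <- !(seq_len(nrow(promoters)) %in% multi)
  out <- promoters[keep, , drop = FALSE]
  attr(out, "n_excluded") <- length(multi)
  out
}

#' Split probes into high (MET+) and low (MET-) methylation classes
#'
#' Median rule (default): MET+ iff the value is strictly greater than the
#' median of all classified probes, so ties at the median fall to MET-.
#' Absolute rule: MET+ iff value > `threshold`.
#'
#' @param values finite numeric methylation values.
#' @param rule `"median"` or `"threshold"`.
#' @param threshold cutoff for the absolute rule.
#' @return logical vector (TRUE = MET+) with attributes `n_met_pos`,
#'   `n_met_neg` and `cutoff`.
#' @export
dichotomize_methylation <- function(values, rule = c("median", "threshold"),
                                    threshold = NULL) {
  rule <- match.arg(rule)
  if (length(values) < 1L || any(!is.finite(values)))
    stop("need at least one finite methylation value")
  cutoff <- if (rule == "median") stats::median(values) else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    threshold
  }
  met <- values > cutoff
  if (rule == "median" && !any(met))
    warning("all values at or below the median; every probe labeled MET-")
  structure(met, n_met_pos = sum(met), n_met_neg = sum(!met),
            cutoff = cutoff)
}

#' Label probes AGO+/AGO- by proximity to binding sites
#'
#' A probe is AGO+ iff the center-to-center distance from the probe to its
#' nearest binding site is at most `d_max` bp; each probe is labeled
#' exactly once no matter how many sites are near. With no sites every
#' probe is AGO-.
#'
#' @param probes probe data.frame.
#' @param sites site data.frame (may be empty).
#' @param d_max proximity threshold in bp (>= 0).
#' @return logical vector (TRUE = AGO+).
#' @export
label_probes_by_proximity <- function(probes, sites, d_max) {
  stopifnot(d_max >= 0)
  nearest_center_distance(probes, sites) <= d_max
}

#' Build the MET/AGO 2x2 contingency table
#'
#' Cell a counts MET+ & AGO+ probes, b MET- & AGO+, c MET+ & AGO-,
#' d MET- & AGO-; every classified probe falls in exactly one cell.
#'
#' @param met,ago logical vectors of equal length.
#' @return list of class `contingency_table` with counts a, b, c, d.
#' @export
contingency_table <- function(met, ago) {
  stopifnot(length(met) == length(ago),
            is.logical(met), is.logical(ago))
  structure(list(a = sum(met & ago), b = sum(!met & ago),
                 c = sum(met & !ago), d = sum(!met & !ago)),
            class = "contingency_table")
}

#' Odds ratio, Wald 95% CI and chi-square test for a 2x2 table
#'
#' OR = ad/(bc). If any cell is zero and `correct_zero` is TRUE, 0.5 is
#' added to all four cells (Haldane-Anscombe) before the OR and CI are
#' computed, and the result is flagged. The Wald interval is
#' `exp(ln OR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))` on the (possibly
#' corrected) cells. The chi-square statistic is the uncorrected Pearson
#' form `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on the raw cells (no
#' Yates continuity correction unless `yates = TRUE`), with the p-value
#' from the upper tail of chi-square on 1 df. A zero row or column margin
#' leaves the chi-square undefined (NA, with a note) while the OR is still
#' reported with the correction.
#'
#' @param tab a `contingency_table` (or list with a, b, c, d).
#' @param correct_zero apply the +0.5 zero-cell correction (default TRUE).
#' @param yates apply the Yates continuity correction (default FALSE).
#' @return list of class `association_result`: odds_ratio, ci_low, ci_high,
#'   chi_square, p_value, corrected (zero-cell flag), note.
#' @export
association_stats <- function(tab, correct_zero = TRUE, yates = FALSE) {
  cells <- as.numeric(c(tab$a, tab$b, tab$c, tab$d))
  if (any(cells < 0) || sum(cells) < 1)
    stop("contingency cells must be non-negative with at least one probe")
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  n <- a + b + c + d
  corrected <- correct_zero && any(cells == 0)
  cc <- cells + if (corrected) 0.5 else 0
  or <- (cc[1] * cc[4]) / (cc[2] * cc[3])
  se <- sqrt(sum(1 / cc))
  ci <- exp(log(or) + c(-1, 1) * 1.96 * se)

  margins <- c(a + b, c + d, a + c, b + d)
  note <- NA_character_
  if (any(margins == 0)) {
    chi <- NA_real_
    p <- NA_real_
    note <- "zero row or column margin; chi-square undefined"
  } else {
    num <- abs(a * d - b * c)
    if (yates) num <- max(0, num - n / 2)
    chi <- n * num^2 / prod(margins)
    p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  }
  structure(list(odds_ratio = or, ci_low = ci[1], ci_high = ci[2],
                 chi_square = chi, p_value = p,
                 corrected = corrected, note = note),
            class = "association_result")
}

#' Pearson correlation between promoter methylation and site count
#'
#' x is the number of binding sites overlapping each promoter boundary,
#' y the promoter methylation summary (sum of the 15 probe values by
#' default). The two-sided p-value comes from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 df (stats::cor.test).
#'
#' @param probes probe data.frame.
#' @param sites site data.frame.
#' @param summary promoter summary rule, `"sum"` (default) or `"mean"`.
#' @param promoters optional pre-built promoter table (skips validation).
#' @return list of class `correlation_result`: r, p_value, n, note.
#' @export
promoter_correlation <- function(probes, sites, summary = c("sum", "mean"),
                                 promoters = NULL) {
  summary <- match.arg(summary)
  if (is.null(promoters)) promoters <- build_promoters(probes)
  if (nrow(promoters) < 3L) stop("need at least 3 promoters")
  y <- promoter_methylation(probes, summary)[promoters$promoter_id]
  x <- if (is.null(sites) || nrow(sites) == 0L) {
    rep(0L, nrow(promoters))
  } else {
    GenomicRanges::countOverlaps(intervals_to_granges(promoters),
                                 intervals_to_granges(sites),
                                 ignore.strand = TRUE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(r = NA_real_, p_value = NA_real_,
                          n = nrow(promoters),
                          note = "zero variance in x or y; r undefined"),
                     class = "correlation_result"))
  }
  ct <- stats::cor.test(x, as.numeric(y), method = "pearson")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n = nrow(promoters), note = NA_character_),
            class = "correlation_result")
}

#' Mean probe methylation within increasing proximity thresholds
#'
#' For each threshold d, the mean methylation over probes whose nearest
#' binding-site center lies within d bp. Membership is cumulative: the
#' probe set at a smaller threshold is a subset of the set at any larger
#' one. Empty bins report NA with a zero count.
#'
#' @param probes probe data.frame.
#' @param sites site data.frame.
#' @param thresholds strictly increasing distances in bp.
#' @return data.frame: threshold, n_probes, mean_methylation.
#' @export
proximity_profile <- function(probes, sites,
                              thresholds = c(50, 100, 200, 500, 1000)) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  d <- nearest_center_distance(probes, sites)
  rows <- lapply(thresholds, function(t) {
    sel <- d <= t
    data.frame(threshold = t, n_probes = sum(sel),
               mean_methylation = if (any(sel))
                 mean(probes$methylation[sel]) else NA_real_)
  })
  do.call(rbind, rows)
}

#' TSS-relative, strand-aware binding-site histogram
#'
#' Each site overlapping a promoter boundary contributes at the signed
#' offset of its center from the promoter TSS, measured along the gene's
#' transcriptional orientation (positive = downstream). Sites are
#' partitioned into sense (site strand equals gene strand) and antisense;
#' unstranded sites are labeled "unstranded". Offsets are binned at
#' `bin_width` bp, each bin covering `[bin_start, bin_start + bin_width)`.
#'
#' @param sites site data.frame.
#' @param promoters promoter data.frame with tss and strand.
#' @param bin_width bin width in bp (default 50).
#' @return data.frame: bin_start, orientation, count.
#' @export
tss_binding_profile <- function(sites, promoters, bin_width = 50L) {
  stopifnot(bin_width >= 1)
  empty <- data.frame(bin_start = integer(), orientation = character(),
                      count = integer(), stringsAsFactors = FALSE)
  if (is.null(sites) || nrow(sites) == 0L) return(empty)
  hits <- GenomicRanges::findOverlaps(intervals_to_granges(sites),
                                      intervals_to_granges(promoters),
                                      ignore.strand = TRUE)
  if (length(hits) == 0L) return(empty)
  si <- S4Vectors::queryHits(hits)
  pi <- S4Vectors::subjectHits(hits)
  centers <- interval_center(sites$start, sites$end)[si]
  sign <- ifelse(promoters$strand[pi] == "-", -1L, 1L)
  offset <- (centers - promoters$tss[pi]) * sign
  orientation <- ifelse(sites$strand[si] == "*", "unstranded",
                        ifelse(sites$strand[si] == promoters$strand[pi],
                               "sense", "antisense"))
  bin <- as.integer(floor(offset / bin_width) * bin_width)
  agg <- stats::aggregate(list(count = bin),
                          by = list(bin_start = bin,
                                    orientation = orientation),
                          FUN = length)
  agg[order(agg$orientation, agg$bin_start), , drop = FALSE]
}

#' Two-sided t-test between two groups of replicate values
#'
#' Thin wrapper over [stats::t.test()] reproducing figure-style paired or
#' unpaired comparisons. Degenerate inputs (paired differences with zero
#' variance, including identical vectors) yield an undefined p-value,
#' reported as NA with a note rather than a number.
#'
#' @param values_a,values_b numeric vectors; equal length when paired.
#' @param paired paired-sample test (default FALSE).
#' @return list: p_value, statistic, note.
#' @export
compare_groups <- function(values_a, values_b, paired = FALSE) {
  if (paired && length(values_a) != length(values_b))
    stop("paired test requires equal-length groups")
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("need at least two values per group")
  res <- tryCatch(
    stats::t.test(values_a, values_b, paired = paired),
    error = function(e)
      structure(list(p.value = NA_real_, statistic = NA_real_),
                note = conditionMessage(e)))
  note <- attr(res, "note")
  if (paired && is.null(note) && stats::sd(values_a - values_b) == 0)
    note <- "zero-variance differences; test undefined"
  list(p_value = if (is.null(note)) res$p.value else NA_real_,
       statistic = unname(res$statistic),
       note = if (is.null(note)) NA_character_ else note)
}
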