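# Promoter probe tables. Each promoter carries exactly 15 tiling-array
# probes of 50 bp, indexed 1..15 in genomic order; the promoter boundary is
# the region from the start of probe 1 to the end of probe 15.

PROBES_PER_PROMOTER <- 15L
PROBE_LENGTH <- 50L

#' Validate a probe table
#'
#' Enforces the probe-level invariants of the promoter tiling design:
#' exactly 15 probes per promoter with indices 1..15, 50-bp probes ordered
#' and non-overlapping along the chromosome, and finite non-negative
#' methylation values.
#'
#' @param probes data.frame with columns promoter_id, gene, probe_index,
#'   chrom, start, end, strand, methylation.
#' @return the input, invisibly, if valid.
#' @export
validate_probe_table <- function(probes) {
  need <- c("promoter_id", "probe_index", "chrom", "start", "end",
            "strand", "methylation")
  if (!all(need %in% names(probes)))
    stop("probe table must have columns: ", paste(need, collapse = ", "))
  validate_intervals(probes)
  if (any(probes$end - probes$start != PROBE_LENGTH))
    stop("every probe must be exactly ", PROBE_LENGTH, " bp")
  if (any(!is.finite(probes$methylation)) || any(probes$methylation < 0))
    stop("probe methylation values must be finite and >= 0")
  sp <- split(probes, probes$promoter_id)
  for (p in sp) {
    if (nrow(p) != PROBES_PER_PROMOTER)
      stop("promoter ", p$promoter_id[1], " has ", nrow(p),
           " probes; exactly ", PROBES_PER_PROMOTER, " required")
    o <- order(p$start)
    if (!identical(sort(as.integer(p$probe_index)), 1:PROBES_PER_PROMOTER))
      stop("promoter ", p$promoter_id[1],
           " probe indices must be exactly 1..", PROBES_PER_PROMOTER)
    if (!identical(as.integer(p$probe_index[o]), 1:PROBES_PER_PROMOTER))
      stop("promoter ", p$promoter_id[1],
           " probe indices must follow genomic order")
    if (length(unique(p$chrom)) != 1L)
      stop("promoter ", p$promoter_id[1], " spans multiple chromosomes")
    if (any(p$start[o][-1] < p$end[o][-PROBES_PER_PROMOTER]))
      stop("promoter ", p$promoter_id[1], " has overlapping probes")
  }
  invisible(probes)
}

#' Assemble a promoter table from a validated probe table
#'
#' One row per promoter with the promoter boundary (start of probe 1 to end
#' of probe 15). The TSS is placed at the boundary edge facing the gene:
#' the boundary start for `+`-strand promoters and the boundary end for
#' `-`-strand promoters, matching the tiling layout the generator emits.
#'
#' @param probes probe data.frame (see [validate_probe_table()]).
#' @param validate run the full probe-table validation first (default TRUE).
#' @return data.frame with promoter_id, gene, chrom, start, end, strand, tss.
#' @export
build_promoters <- function(probes, validate = TRUE) {
  if (validate) validate_probe_table(probes)
  sp <- split(probes, probes$promoter_id)
  out <- do.call(rbind, lapply(sp, function(p) {
    data.frame(promoter_id = p$promoter_id[1],
               gene = if ("gene" %in% names(p)) p$gene[1] else p$promoter_id[1],
               chrom = p$chrom[1],
               start = min(p$start),
               end = max(p$end),
               strand = p$strand[1],
               stringsAsFactors = FALSE)
  }))
  out$tss <- ifelse(out$strand == "-", out$end, out$start)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Promoter-level methylation summary
#'
#' The methylation of a promoter is summarised over its 15 probes; the
#' default summary is the sum (scale-equivalent to the mean for
#' correlation purposes).
#'
#' @param probes probe data.frame.
#' @param summary `"sum"` (default) or `"mean"`.
#' @return named numeric vector, one value per promoter_id.
#' @export
promoter_methylation <- function(probes, summary = c("sum", "mean")) {
  summary <- match.arg(summary)
  f <- if (summary == "sum") sum else mean
  tapply(probes$methylation, probes$promoter_id, f)
}
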