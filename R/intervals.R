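# Genomic intervals are plain data.frames with columns chrom, start, end,
# strand (one of "+", "-", "*") and optionally assembly. Coordinates are
# 0-based half-open throughout (BED-compatible); conversion to the 1-based
# closed convention happens only at the GenomicRanges/rtracklayer boundary.

#' Construct a validated table of genomic intervals
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; 0-based half-open, so `start < end`.
#' @param strand strand per interval: `"+"`, `"-"` or `"*"` (unstranded).
#' @param assembly free-text assembly tag (e.g. `"hg17"`, `"synth1"`).
#' @return data.frame with columns chrom, start, end, strand, assembly.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*",
                              assembly = NA_character_) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   assembly = rep_len(as.character(assembly), length(chrom)),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

#' Validate an interval table
#'
#' Checks the interval invariants: `0 <= start < end` and a legal strand
#' code. Called by every operation that consumes intervals.
#'
#' @param df data.frame with chrom, start, end (and optionally strand).
#' @return the input, invisibly, if valid; otherwise an error.
#' @export
validate_intervals <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("chrom", "start", "end") %in% names(df)))
  if (any(!is.finite(df$start)) || any(!is.finite(df$end)))
    stop("interval coordinates must be finite")
  if (any(df$start < 0))
    stop("interval start must be >= 0")
  if (any(df$start >= df$end))
    stop("intervals must satisfy start < end (0-based half-open)")
  if ("strand" %in% names(df) &&
      !all(df$strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  invisible(df)
}

#' Center of an interval
#'
#' The center of `[start, end)` is `floor((start + end) / 2)`; for
#' odd-length intervals the midpoint is rounded down to an integer bp.
#'
#' @param start,end integer vectors (0-based half-open).
#' @return integer vector of center positions.
#' @export
interval_center <- function(start, end) {
  as.integer((as.numeric(start) + as.numeric(end)) %/% 2)
}

#' Center-to-center distance between two interval tables
#'
#' Element-wise distance between the centers of `a` and `b` (recycled to a
#' common length). Pairs on different chromosomes get the infinite-distance
#' sentinel `Inf`, never a finite number.
#'
#' @param a,b interval data.frames (see [genomic_intervals()]).
#' @return numeric vector of non-negative distances; `Inf` across chromosomes.
#' @export
center_distance <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  n <- max(nrow(a), nrow(b))
  ca <- rep_len(interval_center(a$start, a$end), n)
  cb <- rep_len(interval_center(b$start, b$end), n)
  same <- rep_len(a$chrom, n) == rep_len(b$chrom, n)
  ifelse(same, abs(as.numeric(ca) - as.numeric(cb)), Inf)
}

#' Distance from each query interval to its nearest subject center
#'
#' For every row of `query`, the minimum center-to-center distance to any
#' row of `subject` on the same chromosome; `Inf` where no subject interval
#' shares the chromosome (or `subject` is empty).
#'
#' @param query,subject interval data.frames.
#' @return numeric vector, one distance per query row.
#' @export
nearest_center_distance <- function(query, subject) {
  validate_intervals(query)
  out <- rep(Inf, nrow(query))
  if (is.null(subject) || nrow(subject) == 0L) return(out)
  validate_intervals(subject)
  qc <- interval_center(query$start, query$end)
  sc <- interval_center(subject$start, subject$end)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    s <- sort(sc[subject$chrom == ch])
    if (length(s) == 0L) next
    idx <- findInterval(qc[qi], s)
    lo <- s[pmax(idx, 1L)]
    hi <- s[pmin(idx + 1L, length(s))]
    out[qi] <- pmin(abs(as.numeric(qc[qi]) - lo),
                    abs(as.numeric(qc[qi]) - hi))
  }
  out
}

# 0-based half-open data.frame -> GRanges (1-based closed)
intervals_to_granges <- function(df) {
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end),
                         strand = strand)
}

granges_to_intervals <- function(gr, assembly = NA_character_) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             assembly = assembly,
             stringsAsFactors = FALSE)
}
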