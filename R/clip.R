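# CLIP ingest: turn CLIPZ-style mapped-read records into filtered,
# classified AGO binding sites. The input dialect is a two-file TSV pair:
# a "mapped sequences" table (read_id, sequence, copies) and a "genome
# mappings" table (read_id, chrom, start, end, strand, mismatches,
# insertions, deletions), one row per mapped location. Edit counts are
# taken from the mapping records and never recomputed from sequence.

#' Bundle the two CLIP tables into a mapped-reads object
#'
#' @param reads data.frame with read_id, sequence, copies (copies >= 1).
#' @param mappings data.frame with read_id, chrom, start, end, strand,
#'   mismatches, insertions, deletions (counts >= 0).
#' @return list of class `mapped_reads` with elements `reads`, `mappings`.
#' @export
mapped_reads <- function(reads, mappings) {
  stopifnot(all(c("read_id", "copies") %in% names(reads)),
            all(c("read_id", "chrom", "start", "end", "strand",
                  "mismatches", "insertions", "deletions") %in%
                  names(mappings)))
  if (any(reads$copies < 1)) stop("read copy counts must be >= 1")
  ed <- as.matrix(mappings[, c("mismatches", "insertions", "deletions")])
  if (any(!is.finite(ed)) || any(ed < 0))
    stop("edit counts must be finite and >= 0")
  if (!all(reads$read_id %in% mappings$read_id))
    stop("every read must have at least one mapped location")
  validate_intervals(mappings)
  structure(list(reads = reads, mappings = mappings),
            class = "mapped_reads")
}

#' Drop reads mapping to more than `max_locations` genomic locations
#'
#' Reads whose location count exceeds the cutoff (default 30, so a read
#' with exactly 30 locations is retained and one with 31 is removed) are
#' discarded together with all their mappings. The number of removed reads
#' is reported as attribute `n_removed` and via a message.
#'
#' @param mr a `mapped_reads` object.
#' @param max_locations integer >= 1; retain reads with at most this many
#'   mapped locations.
#' @return filtered `mapped_reads` with attribute `n_removed`.
#' @export
filter_multimappers <- function(mr, max_locations = 30L) {
  stopifnot(inherits(mr, "mapped_reads"), max_locations >= 1)
  n_loc <- table(mr$mappings$read_id)
  bad <- names(n_loc)[n_loc > max_locations]
  out <- mapped_reads(
    mr$reads[!mr$reads$read_id %in% bad, , drop = FALSE],
    mr$mappings[!mr$mappings$read_id %in% bad, , drop = FALSE])
  attr(out, "n_removed") <- length(bad)
  message(length(bad), " read(s) removed as >", max_locations,
          "-location multimappers")
  out
}

#' Classify a mapped location as a perfect or approximate genome match
#'
#' Perfect means zero mismatches, insertions and deletions; anything else
#' is approximate. Vectorized over locations.
#'
#' @param mismatches,insertions,deletions non-negative integer vectors.
#' @return character vector, `"perfect"` or `"approximate"`.
#' @export
classify_match <- function(mismatches, insertions, deletions) {
  ifelse(mismatches == 0 & insertions == 0 & deletions == 0,
         "perfect", "approximate")
}

#' Collapse mapped read locations into binding sites
#'
#' One candidate site per retained read-location; sites shorter than
#' `min_length` are dropped. Under `match_mode = "perfect_only"` only
#' perfectly matched locations contribute; `"include_approximate"` keeps
#' all locations (a superset that contains every perfect-mode site).
#' Identical intervals (chrom, start, end, strand) are aggregated into one
#' site whose support is the sum of the contributing reads' copy counts; an
#' aggregated site is classed perfect only if every supporting location is
#' perfect.
#'
#' @param mr a `mapped_reads` object (typically multimapper-filtered).
#' @param ago protein label attached to the sites (e.g. `"AGO4"`; any
#'   protein label is accepted so control proteins can run the same path).
#' @param min_length minimum site length in bp (default 15).
#' @param match_mode `"include_approximate"` (default) or `"perfect_only"`.
#' @return data.frame of sites: chrom, start, end, strand, ago,
#'   match_class, length, support.
#' @export
reads_to_sites <- function(mr, ago,
                           min_length = 15L,
                           match_mode = c("include_approximate",
                                          "perfect_only")) {
  stopifnot(inherits(mr, "mapped_reads"), min_length >= 1)
  match_mode <- match.arg(match_mode)
  m <- mr$mappings
  m$match_class <- classify_match(m$mismatches, m$insertions, m$deletions)
  if (match_mode == "perfect_only")
    m <- m[m$match_class == "perfect", , drop = FALSE]
  m$length <- m$end - m$start
  m <- m[m$length >= min_length, , drop = FALSE]
  if (nrow(m) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      ago = character(), match_class = character(),
                      length = integer(), support = integer(),
                      stringsAsFactors = FALSE))
  copies <- mr$reads$copies[match(m$read_id, mr$reads$read_id)]
  key <- paste(m$chrom, m$start, m$end, m$strand, sep = "\r")
  agg_support <- tapply(copies, key, sum)
  agg_perfect <- tapply(m$match_class == "perfect", key, all)
  first <- m[!duplicated(key), , drop = FALSE]
  fkey <- paste(first$chrom, first$start, first$end, first$strand,
                sep = "\r")
  out <- data.frame(chrom = first$chrom, start = first$start,
                    end = first$end, strand = first$strand,
                    ago = ago,
                    match_class = ifelse(agg_perfect[fkey],
                                         "perfect", "approximate"),
                    length = first$length,
                    support = as.integer(agg_support[fkey]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}
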