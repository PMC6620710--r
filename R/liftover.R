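# Chain-file coordinate liftover (assembly conversion).
#
# Chains are read with rtracklayer (UCSC chain format: header line
# "chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart
# qEnd id", block lines "size dt dq", terminal bare "size"); the source
# assembly is the chain's target (t) side, following UCSC liftOver files.
# The mapping itself enforces UCSC liftOver's default reject behaviour:
# an interval maps only if it lands in a single target range of preserved
# length (i.e. lies wholly inside one aligned block); anything straddling a
# gap, split across blocks, or outside all blocks is reported unmapped,
# never truncated. Reverse-strand chains re-express coordinates on the
# forward strand of the target assembly and flip the strand field.

#' Read a UCSC chain file
#'
#' @param path path to an uncompressed UCSC chain file.
#' @return an `rtracklayer` Chain object usable with [liftover_intervals()].
#' @export
read_chain <- function(path) {
  rtracklayer::import.chain(path)
}

#' Lift intervals to another assembly through a chain
#'
#' @param intervals interval data.frame (0-based half-open; see
#'   [genomic_intervals()]).
#' @param chain a Chain object from [read_chain()], or a file path.
#' @param target_assembly tag recorded in the output `assembly` column.
#' @return the input table with columns chrom, start, end, strand replaced
#'   by target coordinates, plus a logical `mapped` column; unmapped rows
#'   keep `NA` coordinates and are retained (reported, not dropped).
#' @export
liftover_intervals <- function(intervals, chain,
                               target_assembly = NA_character_) {
  validate_intervals(intervals)
  if (is.character(chain)) chain <- read_chain(chain)
  gr <- intervals_to_granges(intervals)
  hits <- rtracklayer::liftOver(gr, chain)
  hits <- GenomicRanges::reduce(hits)   # merge block-adjacent pieces
  n_pieces <- S4Vectors::elementNROWS(hits)
  widths <- rep(NA_integer_, length(gr))
  one <- n_pieces == 1L
  flat <- unlist(hits[one])
  widths[one] <- GenomicRanges::width(flat)
  mapped <- one & widths == GenomicRanges::width(gr)

  out <- intervals
  out$chrom <- NA_character_
  out$start <- NA_integer_
  out$end <- NA_integer_
  if ("strand" %in% names(intervals)) out$strand <- NA_character_
  out$assembly <- target_assembly
  if (any(mapped)) {
    m <- unlist(hits[mapped])
    out$chrom[mapped] <- as.character(GenomicRanges::seqnames(m))
    out$start[mapped] <- GenomicRanges::start(m) - 1L
    out$end[mapped] <- GenomicRanges::end(m)
    if ("strand" %in% names(intervals)) {
      s <- as.character(GenomicRanges::strand(m))
      # liftOver leaves '*' input as '*'; stranded input is flipped by
      # reverse-strand chains
      out$strand[mapped] <- s
    }
  }
  out$mapped <- mapped
  out
}

#' Write a UCSC chain file from an explicit block table
#'
#' Emits one alignment chain whose source (t) side is `source_chrom` and
#' whose target (q) side is `target_chrom`, with the given aligned blocks.
#' Blocks must be ordered and non-overlapping on both sides; the identity
#' chain is a single block covering the chromosome with equal coordinates.
#'
#' @param path output file path.
#' @param source_chrom,source_size source chromosome name and size (bp).
#' @param target_chrom,target_size target chromosome name and size (bp).
#' @param blocks data.frame with columns src_start, size, tgt_start
#'   (0-based), one row per aligned block, ordered by src_start.
#' @param score chain score (informational).
#' @param id chain id (informational).
#' @return `path`, invisibly.
#' @export
write_chain <- function(path, source_chrom, source_size,
                        target_chrom, target_size, blocks,
                        score = 1000, id = 1) {
  stopifnot(is.data.frame(blocks),
            all(c("src_start", "size", "tgt_start") %in% names(blocks)),
            nrow(blocks) >= 1, all(blocks$size > 0))
  b <- blocks[order(blocks$src_start), , drop = FALSE]
  src_end <- b$src_start + b$size
  tgt_end <- b$tgt_start + b$size
  if (nrow(b) > 1) {
    dt <- b$src_start[-1] - src_end[-nrow(b)]
    dq <- b$tgt_start[-1] - tgt_end[-nrow(b)]
    if (any(dt < 0) || any(dq < 0))
      stop("chain blocks overlap or are out of order")
  } else {
    dt <- dq <- integer(0)
  }
  if (src_end[nrow(b)] > source_size || tgt_end[nrow(b)] > target_size)
    stop("chain blocks exceed chromosome size")
  header <- paste("chain", score,
                  source_chrom, source_size, "+", b$src_start[1],
                  src_end[nrow(b)],
                  target_chrom, target_size, "+", b$tgt_start[1],
                  tgt_end[nrow(b)], id)
  body <- if (nrow(b) > 1) {
    c(paste(b$size[-nrow(b)], dt, dq), as.character(b$size[nrow(b)]))
  } else {
    as.character(b$size)
  }
  writeLines(c(header, body, ""), path)
  invisible(path)
}
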