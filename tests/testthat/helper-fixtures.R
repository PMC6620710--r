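# Shared fixtures, all generated in code at test time.

# one-row interval table
iv <- function(chrom, start, end, strand = "*") {
  genomic_intervals(chrom, start, end, strand)
}

# random interval table on the given chromosomes
random_intervals <- function(n, chroms = "chrS1", max_pos = 100000L,
                             max_len = 200L) {
  start <- sample.int(max_pos - max_len, n, replace = TRUE)
  genomic_intervals(sample(chroms, n, replace = TRUE),
                    start, start + sample.int(max_len, n, replace = TRUE))
}

# minimal mapped_reads with explicit per-read location counts and edits
make_reads <- function(n_loc, edits = NULL, lengths = 20L,
                       copies = 1L, chrom = "chr1") {
  n <- length(n_loc)
  lengths <- rep_len(lengths, n)
  copies <- rep_len(copies, n)
  ids <- sprintf("r%03d", seq_len(n))
  reads <- data.frame(read_id = ids,
                      sequence = strrep("A", lengths),
                      copies = copies, stringsAsFactors = FALSE)
  ri <- rep(seq_len(n), n_loc)
  m <- length(ri)
  if (is.null(edits)) edits <- matrix(0L, m, 3)
  start <- seq_len(m) * 1000L
  mappings <- data.frame(read_id = ids[ri], chrom = chrom,
                         start = start, end = start + lengths[ri],
                         strand = "+",
                         mismatches = edits[, 1], insertions = edits[, 2],
                         deletions = edits[, 3], stringsAsFactors = FALSE)
  mapped_reads(reads, mappings)
}

# tiny promoter array + planted association bundle
small_assoc_fixture <- function(seed = 42, promoter_count = 120, ...) {
  tr <- synthetic_truth(seed = seed, promoter_count = promoter_count, ...)
  arr <- gen_promoter_array(tr)
  c(gen_probe_association(tr, arr$probes),
    list(truth = tr, promoters = arr$promoters))
}
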