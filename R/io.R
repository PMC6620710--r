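# Readers and writers for the tab-delimited dialects the pipeline
# consumes: the probe-methylation matrix, the two-file CLIP pair, the gel
# lane table, Ct tables, BED6 binding sites (via rtracklayer) and JSON
# manifests. All TSVs are UTF-8, header required, with optional leading
# '#' comment lines carrying provenance (seed, generator settings).

.read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

.write_tsv <- function(df, path, comments = character(0)) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a probe-methylation TSV
#'
#' Columns: promoter_id, gene, probe_index, chrom, start, end, strand,
#' methylation (tab-delimited, header required; '#' lines are comments).
#'
#' @param path file path.
#' @param validate run [validate_probe_table()] (default TRUE).
#' @return probe data.frame.
#' @export
read_probe_table <- function(path, validate = TRUE) {
  df <- .read_tsv(path)
  if (validate) validate_probe_table(df)
  df
}

#' Write a probe-methylation TSV
#' @param probes probe data.frame.
#' @param path file path.
#' @param comments optional '#' header comment lines (e.g. the seed).
#' @export
write_probe_table <- function(probes, path, comments = character(0)) {
  .write_tsv(probes, path, comments)
}

#' Read binding sites from a BED6 file
#'
#' BED name = protein label, score = read support. Coordinates come back
#' 0-based half-open.
#'
#' @param path BED file path.
#' @return site data.frame: chrom, start, end, strand, ago, support.
#' @export
read_sites_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- granges_to_intervals(gr)
  df$ago <- if (!is.null(gr$name)) gr$name else NA_character_
  df$support <- if (!is.null(gr$score)) as.integer(gr$score) else 1L
  df$length <- df$end - df$start
  df$assembly <- NULL
  df
}

#' Write binding sites to a BED6 file
#' @param sites site data.frame with ago and support columns.
#' @param path output BED path.
#' @export
write_sites_bed <- function(sites, path) {
  gr <- intervals_to_granges(sites)
  gr$name <- sites$ago
  gr$score <- sites$support
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read the two-file CLIP TSV pair into a `mapped_reads` object
#'
#' `mapped` has columns read_id, sequence, copies; `mappings` has read_id,
#' chrom, start, end, strand, mismatches, insertions, deletions (one row
#' per mapped location).
#'
#' @param mapped_path,mappings_path file paths.
#' @return a `mapped_reads` object.
#' @export
read_clip_tables <- function(mapped_path, mappings_path) {
  mapped_reads(.read_tsv(mapped_path), .read_tsv(mappings_path))
}

#' Write a `mapped_reads` object as the two-file CLIP TSV pair
#' @param mr a `mapped_reads` object.
#' @param mapped_path,mappings_path output paths.
#' @param comments optional '#' header comment lines.
#' @export
write_clip_tables <- function(mr, mapped_path, mappings_path,
                              comments = character(0)) {
  .write_tsv(mr$reads, mapped_path, comments)
  .write_tsv(mr$mappings, mappings_path, comments)
  invisible(c(mapped_path, mappings_path))
}

#' Read a gel-lane band-intensity TSV
#'
#' Columns: replicate_id, assay, band_size, intensity.
#' @param path file path.
#' @return lane data.frame.
#' @export
read_lane_table <- function(path) {
  df <- .read_tsv(path)
  need <- c("replicate_id", "assay", "band_size", "intensity")
  if (!all(need %in% names(df)))
    stop("lane table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Write a gel-lane band-intensity TSV
#' @param lanes lane data.frame.
#' @param path output path.
#' @param comments optional '#' header comment lines.
#' @export
write_lane_table <- function(lanes, path, comments = character(0)) {
  .write_tsv(lanes, path, comments)
}

#' Write a generator manifest (planted ground truth) as JSON
#' @param manifest named list.
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a generator manifest
#' @param path JSON path.
#' @return named list.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
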