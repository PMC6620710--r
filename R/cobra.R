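# COBRA (combined bisulfite restriction analysis) quantification of global
# LINE-1 and Alu methylation from gel band intensities, plus the
# delta-delta-Ct qPCR fold change.
#
# Each assay reads five bands. Every band intensity is divided by its
# printed divisor to give the molar-equivalent components A..E, and a
# derived component F completes the set:
#   LINE-1: bands 92, 60, 50, 42, 32 bp with divisors 92, 56, 48, 40, 28
#           (A..E in that order), F = ((D + E) - (B + C)) / 2,
#           percent = (A + 2C + F) * 100 / (2A + 2B + 2C + 2F).
#   Alu:    bands 133, 90, 75, 58, 43 bp; the letters map A=133, B=58,
#           C=75, D=90, E=43 with divisors equal to the sizes,
#           F = ((E + B) - (C + D)) / 2,
#           percent = (2F + D + C) * 100 / (2A + 2C + 2D + 2F).
# Note the LINE-1 divisors differ from the fragment sizes and the Alu
# letters are not in size order; both follow the printed normalization.

.cobra_schema <- list(
  LINE1 = list(
    letters = c(A = "92", B = "60", C = "50", D = "42", E = "32"),
    divisors = c(`92` = 92, `60` = 56, `50` = 48, `42` = 40, `32` = 28)),
  ALU = list(
    letters = c(A = "133", B = "58", C = "75", D = "90", E = "43"),
    divisors = c(`133` = 133, `90` = 90, `75` = 75, `58` = 58, `43` = 43)))

#' Band sizes recognised for a COBRA assay
#' @param assay `"LINE1"` or `"ALU"`.
#' @return integer vector of fragment sizes (bp).
#' @export
cobra_band_sizes <- function(assay = c("LINE1", "ALU")) {
  assay <- match.arg(assay)
  as.integer(names(.cobra_schema[[assay]]$divisors))
}

#' Construct one COBRA gel lane
#'
#' @param assay `"LINE1"` or `"ALU"`.
#' @param intensities numeric vector of raw band intensities named by
#'   fragment size (e.g. `c("92" = 410, "60" = 0, ...)`). Unknown sizes
#'   are rejected; missing bands are treated as intensity 0 (reported via
#'   attribute `missing_bands`); negative values (over-subtracted
#'   background) are clamped to 0 with a warning.
#' @param replicate_id lane label.
#' @return list of class `gel_lane`: assay, bands (full named vector),
#'   replicate_id.
#' @export
gel_lane <- function(assay = c("LINE1", "ALU"), intensities,
                     replicate_id = "lane1") {
  assay <- match.arg(assay)
  sizes <- names(.cobra_schema[[assay]]$divisors)
  got <- names(intensities)
  if (is.null(got) || !all(got %in% sizes))
    stop("unknown band size(s) for ", assay, " lane: ",
         paste(setdiff(got, sizes), collapse = ", "))
  if (any(!is.finite(intensities)))
    stop("band intensities must be finite")
  if (any(intensities < 0)) {
    warning("negative band intensity clamped to 0 (replicate ",
            replicate_id, ")")
    intensities <- pmax(intensities, 0)
  }
  bands <- stats::setNames(rep(0, length(sizes)), sizes)
  bands[got] <- intensities
  structure(list(assay = assay, bands = bands,
                 replicate_id = replicate_id,
                 missing_bands = setdiff(sizes, got)),
            class = "gel_lane")
}

#' Normalized components A..F of a gel lane
#'
#' Divides each band intensity by its printed divisor and derives F by the
#' assay's formula (see the file header for the exact letter/size/divisor
#' mapping).
#'
#' @param lane a `gel_lane`.
#' @return named numeric vector with components A, B, C, D, E, F.
#' @export
normalize_lane <- function(lane) {
  stopifnot(inherits(lane, "gel_lane"))
  sch <- .cobra_schema[[lane$assay]]
  comp <- lane$bands[sch$letters] / sch$divisors[sch$letters]
  names(comp) <- names(sch$letters)
  f <- if (lane$assay == "LINE1") {
    ((comp["D"] + comp["E"]) - (comp["B"] + comp["C"])) / 2
  } else {
    ((comp["E"] + comp["B"]) - (comp["C"] + comp["D"])) / 2
  }
  c(comp, F = unname(f))
}

.methylation_estimate <- function(percent, comp, lane, denom) {
  flags <- character(0)
  if (denom == 0) flags <- c(flags, "zero_denominator")
  if (is.finite(percent) && (percent < 0 || percent > 100))
    flags <- c(flags, "out_of_range")   # reported as-is, never clamped
  if (length(lane$missing_bands))
    flags <- c(flags, paste0("missing_band_", lane$missing_bands))
  structure(list(percent = percent, components = comp,
                 assay = lane$assay, replicate_id = lane$replicate_id,
                 flags = flags),
            class = "methylation_estimate")
}

#' LINE-1 methylation percentage from a gel lane
#'
#' `percent = (A + 2C + F) * 100 / (2A + 2B + 2C + 2F)` on the normalized
#' components. A zero denominator yields an undefined (NA) percent with a
#' `zero_denominator` flag; values outside \[0, 100\] from inconsistent
#' real lanes are reported as-is with an `out_of_range` flag.
#'
#' @param lane a `gel_lane` with `assay = "LINE1"`.
#' @return `methylation_estimate`: percent, components A..F, flags.
#' @export
line1_methylation <- function(lane) {
  stopifnot(inherits(lane, "gel_lane"), lane$assay == "LINE1")
  comp <- normalize_lane(lane)
  denom <- 2 * (comp["A"] + comp["B"] + comp["C"] + comp["F"])
  percent <- if (denom == 0) NA_real_ else
    unname((comp["A"] + 2 * comp["C"] + comp["F"]) * 100 / denom)
  .methylation_estimate(percent, comp, lane, unname(denom))
}

#' Alu methylation percentage from a gel lane
#'
#' `percent = (2F + D + C) * 100 / (2A + 2C + 2D + 2F)` on the normalized
#' components; error handling as in [line1_methylation()].
#'
#' @param lane a `gel_lane` with `assay = "ALU"`.
#' @return `methylation_estimate`: percent, components A..F, flags.
#' @export
alu_methylation <- function(lane) {
  stopifnot(inherits(lane, "gel_lane"), lane$assay == "ALU")
  comp <- normalize_lane(lane)
  denom <- 2 * (comp["A"] + comp["C"] + comp["D"] + comp["F"])
  percent <- if (denom == 0) NA_real_ else
    unname((2 * comp["F"] + comp["D"] + comp["C"]) * 100 / denom)
  .methylation_estimate(percent, comp, lane, unname(denom))
}

#' Methylation estimates for a table of gel lanes
#'
#' @param lanes data.frame with columns replicate_id, assay, band_size,
#'   intensity (one row per band).
#' @return data.frame with one row per (replicate_id, assay): percent,
#'   components A..F, flags (";"-joined).
#' @export
cobra_estimates <- function(lanes) {
  stopifnot(all(c("replicate_id", "assay", "band_size", "intensity")
                %in% names(lanes)))
  keys <- unique(lanes[, c("replicate_id", "assay")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- lanes$replicate_id == keys$replicate_id[i] &
      lanes$assay == keys$assay[i]
    lane <- gel_lane(keys$assay[i],
                     stats::setNames(lanes$intensity[sel],
                                     lanes$band_size[sel]),
                     replicate_id = keys$replicate_id[i])
    est <- if (lane$assay == "LINE1") line1_methylation(lane)
           else alu_methylation(lane)
    data.frame(replicate_id = est$replicate_id, assay = est$assay,
               percent = est$percent, t(est$components),
               flags = paste(est$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative quantification by the delta-delta-Ct method
#'
#' `fold = 2 ^ -((Ct_target_case - Ct_ref_case) -
#'               (Ct_target_control - Ct_ref_control))`.
#' Vectorized over replicates.
#'
#' @param ct_target_case,ct_reference_case Ct values in the case sample
#'   for the target and the reference (housekeeping) amplicon.
#' @param ct_target_control,ct_reference_control the same in the control.
#' @return numeric fold change(s).
#' @export
ddct_fold_change <- function(ct_target_case, ct_reference_case,
                             ct_target_control, ct_reference_control) {
  cts <- cbind(ct_target_case, ct_reference_case,
               ct_target_control, ct_reference_control)
  if (any(!is.finite(cts))) stop("Ct values must be finite")
  ddct <- (ct_target_case - ct_reference_case) -
    (ct_target_control - ct_reference_control)
  2^(-ddct)
}
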