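# Seeded synthetic-data generators with planted ground truth. They emulate
# the statistical structure of the study inputs -- a promoter tiling array
# (15 x 50-bp probes per promoter over ~1.5 kb), CLIP-style mapped reads
# with multimapping and imperfect matches, COBRA gel lanes built from
# per-molecule two-CpG methylation patterns, and UCSC chain files -- and
# record every planted parameter in a manifest so the pipeline's estimates
# can be checked against the truth. All generators are deterministic under
# the manifest seed; sub-generators use fixed offsets from the base seed.

#' Assemble the synthetic-truth parameter set
#'
#' Returns the full generator configuration with the study-condition
#' defaults; any field can be overridden by name. Derived quantities
#' (planted odds ratio, implied correlation) are recomputed after merging.
#'
#' Key defaults: 15 probes of 50 bp tiled at 100-bp steps over a 1.5-kb
#' promoter; conditional MET+ probabilities 0.6367 (AGO+ arm) and 0.3000
#' (AGO- arm), giving a planted odds ratio of about 4.09; correlation
#' plant y = 300 + 5 k + N(0, 41) with k ~ Poisson(2), implying a Pearson
#' r of about 0.17; CLIP multimapping up to 60 locations with the >30
#' filter boundary straddled; noiseless gel lanes.
#'
#' @param seed base RNG seed.
#' @param ... named overrides of any default field.
#' @return list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(seed = 1L, ...) {
  truth <- list(
    seed = as.integer(seed),
    chrom = "chrS1", assembly = "synth1",
    promoter_count = 500L,
    probes_per_promoter = 15L,
    probe_length = 50L,
    promoter_span = 1500L,
    intergenic_gap = c(500L, 2000L),
    first_tss = 1000L,
    # probe-level MET/AGO association plant
    ago = "AGO4",
    ago_fraction = 0.5,
    ago_count = NULL,           # exact AGO+ probe count; overrides fraction
    p_met_given_ago = 0.6367,
    p_met_given_noago = 0.3,
    assoc_d_max = 50L,          # labeling threshold the plant guarantees
    site_jitter = 25L,          # site center offset from the probe center
    site_length = 30L,
    met_means = c(neg = 20, pos = 80),
    met_sd = 5,
    met_threshold = 50,         # separates the two methylation components
    # promoter-level correlation plant
    corr_slope = 5,
    corr_noise_sd = 41,
    corr_site_mean = 2,
    corr_intercept = 300,
    # CLIP read generator
    n_reads = 400L,
    clip_chrom_size = 1000000L,
    multimap_fraction = 0.15,
    multiplicity_range = c(2L, 60L),
    read_length_range = c(10L, 40L),
    edit_fraction = 0.3,
    copies_rate = 1,            # copies = 1 + Poisson(copies_rate)
    # gel lanes
    gel_molecules = 1000L,
    line1_pattern_probs = c(mm = 0.6, hemi = 0.2, uu = 0.2),
    alu_pattern_probs = c(mm = 0.25, mu = 0.25, um = 0.25, uu = 0.25),
    gel_cv = 0)
  over <- list(...)
  unknown <- setdiff(names(over), names(truth))
  if (length(unknown))
    stop("unknown synthetic_truth field(s): ", paste(unknown, collapse = ", "))
  truth[names(over)] <- over
  p1 <- truth$p_met_given_ago; p0 <- truth$p_met_given_noago
  stopifnot(p1 > 0, p1 < 1, p0 > 0, p0 < 1)
  truth$planted_or <- (p1 / (1 - p1)) / (p0 / (1 - p0))
  vk <- truth$corr_site_mean   # Poisson variance
  truth$implied_r <- truth$corr_slope * sqrt(vk) /
    sqrt(truth$corr_slope^2 * vk + truth$corr_noise_sd^2)
  if (abs(sum(truth$line1_pattern_probs) - 1) > 1e-9 ||
      abs(sum(truth$alu_pattern_probs) - 1) > 1e-9)
    stop("gel pattern probabilities must sum to 1")
  class(truth) <- "synthetic_truth"
  truth
}

#' Generate a synthetic promoter tiling array
#'
#' Non-overlapping promoters laid along one synthetic chromosome, each
#' with 15 probes of 50 bp placed at the start of consecutive
#' `promoter_span / 15` bp steps (contiguous tiling when the span is
#' exactly 750 bp). Strand is random; the TSS sits at the
#' transcription-proximal boundary edge. Probe methylation is filled with
#' a background draw and is overwritten by the association or correlation
#' generators. Deterministic under the truth seed.
#'
#' @param truth a `synthetic_truth`.
#' @return list: probes (data.frame), promoters (data.frame),
#'   chrom_size, truth.
#' @export
gen_promoter_array <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(truth$seed)
  np <- truth$promoter_count
  k <- truth$probes_per_promoter
  step <- truth$promoter_span %/% k
  if (step < truth$probe_length)
    stop("promoter_span too small: 15 probes of ", truth$probe_length,
         " bp need a span of at least ", k * truth$probe_length, " bp")
  width <- (k - 1L) * step + truth$probe_length
  gaps <- sample(truth$intergenic_gap[1]:truth$intergenic_gap[2], np,
                 replace = TRUE)
  pstart <- truth$first_tss + cumsum(c(0L, (width + gaps)[-np]))
  strand <- sample(c("+", "-"), np, replace = TRUE)
  ids <- sprintf("P%05d", seq_len(np))
  probes <- data.frame(
    promoter_id = rep(ids, each = k),
    gene = rep(sprintf("GENE%05d", seq_len(np)), each = k),
    probe_index = rep(1:k, np),
    chrom = truth$chrom,
    start = rep(pstart, each = k) + (rep(1:k, np) - 1L) * step,
    stringsAsFactors = FALSE)
  probes$end <- probes$start + truth$probe_length
  probes$strand <- rep(strand, each = k)
  probes$methylation <- pmax(0, stats::rnorm(nrow(probes),
                                             truth$met_means["neg"],
                                             truth$met_sd))
  list(probes = probes,
       promoters = build_promoters(probes, validate = FALSE),
       chrom_size = max(probes$end) + 10000L,
       truth = truth)
}

#' Plant a probe-level methylation/binding association
#'
#' Designates an exact number of probes AGO+ by placing one binding site
#' whose center lies within `site_jitter` bp of the probe center; latent
#' MET+ status is drawn with P(MET+ | AGO+) and P(MET+ | AGO-), and the
#' continuous methylation values are emitted as two well-separated
#' Gaussian components (means `met_means`, sd `met_sd`) around the latent
#' status so the threshold rule at `met_threshold` recovers it exactly.
#' The probe tiling step minus the jitter must exceed `assoc_d_max`, so
#' labeling probes at `assoc_d_max` recovers exactly the planted AGO+ set.
#'
#' @param truth a `synthetic_truth`.
#' @param probes probe table from [gen_promoter_array()].
#' @return list: probes (methylation overwritten), sites, manifest.
#' @export
gen_probe_association <- function(truth, probes) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(truth$seed + 1L)
  n <- nrow(probes)
  centers <- interval_center(probes$start, probes$end)
  spacing <- min(diff(sort(unique(centers))))
  if (spacing - truth$site_jitter - 1L <= truth$assoc_d_max)
    stop("probe spacing ", spacing, " bp too small for jitter ",
         truth$site_jitter, " and d_max ", truth$assoc_d_max,
         ": planted AGO+ labels would leak to neighboring probes")
  n_ago <- if (!is.null(truth$ago_count)) as.integer(truth$ago_count)
           else as.integer(round(truth$ago_fraction * n))
  stopifnot(n_ago >= 0, n_ago <= n)
  ago_idx <- sort(sample.int(n, n_ago))
  ago <- seq_len(n) %in% ago_idx

  jit <- sample((-truth$site_jitter):truth$site_jitter, n_ago,
                replace = TRUE)
  sc <- centers[ago_idx] + jit
  half <- as.integer(truth$site_length) %/% 2L
  sites <- data.frame(chrom = probes$chrom[ago_idx],
                      start = as.integer(sc - half),
                      end = as.integer(sc - half + truth$site_length),
                      strand = sample(c("+", "-"), n_ago, replace = TRUE),
                      ago = truth$ago,
                      match_class = "perfect",
                      length = truth$site_length,
                      support = 1L,
                      stringsAsFactors = FALSE)

  p <- ifelse(ago, truth$p_met_given_ago, truth$p_met_given_noago)
  met <- stats::rbinom(n, 1L, p) == 1L
  probes$methylation <- pmax(0, stats::rnorm(
    n, ifelse(met, truth$met_means["pos"], truth$met_means["neg"]),
    truth$met_sd))

  manifest <- list(
    type = "probe_association",
    seed = truth$seed,
    n_probes = n,
    n_ago_pos = sum(ago), n_ago_neg = sum(!ago),
    n_met_pos_ago = sum(met & ago), n_met_pos_noago = sum(met & !ago),
    table = list(a = sum(met & ago), b = sum(!met & ago),
                 c = sum(met & !ago), d = sum(!met & !ago)),
    p_met_given_ago = truth$p_met_given_ago,
    p_met_given_noago = truth$p_met_given_noago,
    planted_or = truth$planted_or,
    assoc_d_max = truth$assoc_d_max,
    met_threshold = truth$met_threshold,
    forward_model_note = paste(
      "one binding site per AGO+ probe, center within", truth$site_jitter,
      "bp of the probe center; methylation bimodal around the latent",
      "MET status"))
  list(probes = probes, sites = sites, manifest = manifest)
}

#' Plant a promoter-level methylation ~ site-count linear relation
#'
#' Per promoter, the binding-site count is k ~ Poisson(`corr_site_mean`)
#' and the promoter methylation is
#' `y = corr_intercept + corr_slope * k + N(0, corr_noise_sd)`, spread
#' evenly over the 15 probes (each probe gets y / 15, so the promoter sum
#' recovers y). Sites are materialized as k intervals inside the promoter
#' boundary. The manifest records the closed-form implied Pearson r,
#' `slope * sd(k) / sqrt(slope^2 var(k) + noise_sd^2)`, and the realized
#' sample r of the drawn (k, y) pairs.
#'
#' @param truth a `synthetic_truth`.
#' @param promoters promoter table from [gen_promoter_array()].
#' @param probes matching probe table.
#' @return list: probes (methylation overwritten), sites, manifest.
#' @export
gen_promoter_correlation_data <- function(truth, promoters, probes) {
  stopifnot(inherits(truth, "synthetic_truth"), truth$corr_noise_sd >= 0)
  set.seed(truth$seed + 2L)
  np <- nrow(promoters)
  k <- stats::rpois(np, truth$corr_site_mean)
  y <- truth$corr_intercept + truth$corr_slope * k +
    stats::rnorm(np, 0, truth$corr_noise_sd)
  n_clamped <- sum(y < 0)
  y <- pmax(y, 0)

  idx <- rep(seq_len(np), k)
  sl <- truth$site_length
  sstart <- promoters$start[idx] +
    floor(stats::runif(length(idx)) *
            (promoters$end[idx] - promoters$start[idx] - sl))
  sites <- data.frame(chrom = promoters$chrom[idx],
                      start = as.integer(sstart),
                      end = as.integer(sstart) + sl,
                      strand = sample(c("+", "-"), length(idx),
                                      replace = TRUE),
                      ago = truth$ago, match_class = "perfect",
                      length = sl, support = 1L,
                      stringsAsFactors = FALSE)

  per_probe <- stats::setNames(y / truth$probes_per_promoter,
                               promoters$promoter_id)
  probes$methylation <- unname(per_probe[probes$promoter_id])

  manifest <- list(
    type = "promoter_correlation",
    seed = truth$seed,
    n_promoters = np,
    total_sites = sum(k),
    slope = truth$corr_slope, noise_sd = truth$corr_noise_sd,
    site_count_mean = truth$corr_site_mean,
    intercept = truth$corr_intercept,
    implied_r = truth$implied_r,
    realized_r = if (stats::sd(k) > 0 && stats::sd(y) > 0)
      stats::cor(k, y) else NA_real_,
    n_clamped = n_clamped)
  list(probes = probes, sites = sites, manifest = manifest)
}

#' Generate CLIP-style mapped reads (two-table dialect)
#'
#' Unique-mapping reads plus a `multimap_fraction` of reads with
#' `multiplicity_range` locations (straddling the 30-location filter
#' cutoff); read lengths straddle the 15-bp site-length filter; a fraction
#' of locations carry mismatches/insertions/deletions. The manifest
#' records the number of reads exceeding 30 locations and how many
#' aggregated sites survive each (min_length, match_mode) combination.
#'
#' @param truth a `synthetic_truth`.
#' @return list: reads (a `mapped_reads`), manifest.
#' @export
gen_clip_reads <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"),
            truth$multiplicity_range[1] >= 1,
            truth$multiplicity_range[2] <= 60)
  set.seed(truth$seed + 3L)
  n <- truth$n_reads
  len <- sample(truth$read_length_range[1]:truth$read_length_range[2],
                n, replace = TRUE)
  copies <- 1L + stats::rpois(n, truth$copies_rate)
  n_loc <- ifelse(stats::runif(n) < truth$multimap_fraction,
                  sample(truth$multiplicity_range[1]:
                           truth$multiplicity_range[2], n, replace = TRUE),
                  1L)
  ids <- sprintf("R%06d", seq_len(n))
  seqs <- vapply(len, function(l)
    paste(sample(c("A", "C", "G", "U"), l, replace = TRUE),
          collapse = ""), character(1))
  reads <- data.frame(read_id = ids, sequence = seqs, copies = copies,
                      stringsAsFactors = FALSE)

  ri <- rep(seq_len(n), n_loc)
  m <- length(ri)
  start <- sample.int(truth$clip_chrom_size - max(len), m, replace = TRUE)
  edited <- stats::runif(m) < truth$edit_fraction
  mism <- ifelse(edited, stats::rpois(m, 0.8), 0L)
  ins <- ifelse(edited, stats::rpois(m, 0.3), 0L)
  del <- ifelse(edited, stats::rpois(m, 0.3), 0L)
  fix <- edited & (mism + ins + del == 0)
  mism[fix] <- 1L   # "edited" locations carry at least one edit
  mappings <- data.frame(read_id = ids[ri],
                         chrom = truth$chrom,
                         start = start,
                         end = start + len[ri],
                         strand = sample(c("+", "-"), m, replace = TRUE),
                         mismatches = mism, insertions = ins,
                         deletions = del,
                         stringsAsFactors = FALSE)
  mr <- mapped_reads(reads, mappings)

  # survivor bookkeeping straight from the drawn vectors
  keep_loc <- n_loc[ri] <= 30L
  perfect <- mism == 0 & ins == 0 & del == 0
  combos <- expand.grid(min_length = c(1L, 5L, 10L, 15L, 20L, 25L),
                        match_mode = c("perfect_only",
                                       "include_approximate"),
                        stringsAsFactors = FALSE)
  combos$n_sites <- vapply(seq_len(nrow(combos)), function(i) {
    sel <- keep_loc & len[ri] >= combos$min_length[i] &
      (combos$match_mode[i] == "include_approximate" | perfect)
    length(unique(paste(mappings$start[sel], mappings$end[sel],
                        mappings$strand[sel])))
  }, integer(1))

  manifest <- list(
    type = "clip_reads",
    seed = truth$seed,
    n_reads = n,
    n_locations = m,
    n_over30 = sum(n_loc > 30L),
    n_multimapped = sum(n_loc > 1L),
    total_copies = sum(copies),
    sites_by_combination = combos)
  list(reads = mr, manifest = manifest)
}

# pattern -> band molar-count mapping; chosen so the printed estimator
# recovers the true methylated-CpG fraction exactly (see the methods
# vignette); a modeling construct, not a claim about restriction chemistry
.gel_forward <- function(assay, counts) {
  if (assay == "LINE1") {
    c(`92` = counts[["hemi"]],                 # uncut, hemimethylated
      `60` = counts[["uu"]], `32` = counts[["uu"]],
      `50` = counts[["mm"]], `42` = counts[["mm"]])
  } else {
    c(`133` = counts[["uu"]],                  # uncut
      `58` = counts[["mm"]] + counts[["mu"]],
      `43` = counts[["mm"]] + counts[["um"]],
      `75` = counts[["mu"]],
      `90` = counts[["um"]])
    # mm also yields an uncounted 32-bp middle fragment
  }
}

.gel_true_fraction <- function(assay, counts) {
  n <- sum(unlist(counts))
  if (assay == "LINE1") (2 * counts[["mm"]] + counts[["hemi"]]) / (2 * n)
  else (2 * counts[["mm"]] + counts[["mu"]] + counts[["um"]]) / (2 * n)
}

#' Generate a COBRA gel lane from per-molecule methylation patterns
#'
#' Draws molecule counts over the assay's two-CpG methylation patterns
#' (LINE-1: mm / hemi / uu; Alu: mm / mu / um / uu), maps patterns to
#' bands through the assay forward model, and emits
#' `intensity = molar count x printed divisor`, optionally with
#' multiplicative log-normal noise of coefficient of variation `cv`
#' (mean 1). The exact true methylated-CpG fraction of the drawn
#' molecules is returned alongside the lane.
#'
#' @param assay `"LINE1"` or `"ALU"`.
#' @param molecule_count number of molecules (>= 1).
#' @param pattern_probs named probabilities summing to 1
#'   (LINE-1: mm, hemi, uu; Alu: mm, mu, um, uu).
#' @param seed RNG seed.
#' @param cv multiplicative noise coefficient of variation (default 0,
#'   noiseless).
#' @param replicate_id lane label.
#' @return list: lane (a `gel_lane`), true_fraction, manifest.
#' @export
gen_gel_lane <- function(assay = c("LINE1", "ALU"), molecule_count,
                         pattern_probs, seed = 1L, cv = 0,
                         replicate_id = "lane1") {
  assay <- match.arg(assay)
  if (molecule_count < 1) stop("molecule_count must be >= 1")
  want <- if (assay == "LINE1") c("mm", "hemi", "uu")
          else c("mm", "mu", "um", "uu")
  stopifnot(setequal(names(pattern_probs), want),
            abs(sum(pattern_probs) - 1) < 1e-12)
  set.seed(seed)
  counts <- stats::setNames(
    as.integer(stats::rmultinom(1, molecule_count, pattern_probs[want])),
    want)
  molar <- .gel_forward(assay, as.list(counts))
  divisors <- .cobra_schema[[assay]]$divisors[names(molar)]
  noise <- if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(length(molar), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else rep(1, length(molar))
  lane <- gel_lane(assay, molar * divisors * noise,
                   replicate_id = replicate_id)
  manifest <- list(type = "gel_lane", seed = seed, assay = assay,
                   molecule_count = molecule_count,
                   pattern_counts = as.list(counts),
                   cv = cv,
                   true_fraction = .gel_true_fraction(assay,
                                                      as.list(counts)),
                   forward_model_note = paste(
                     "band assignment chosen so the printed formula",
                     "recovers the true methylated-CpG fraction exactly;",
                     "not a claim about restriction-site chemistry"))
  list(lane = lane, true_fraction = manifest$true_fraction,
       manifest = manifest)
}

#' Generate a UCSC chain file fixture
#'
#' Single-chain file over one synthetic chromosome; with no explicit
#' blocks it emits one whole-chromosome block shifted by `offset`
#' (identity chain when `offset = 0`).
#'
#' @param path output path.
#' @param source_size source chromosome size (bp).
#' @param blocks optional data.frame (src_start, size, tgt_start).
#' @param offset target shift for the default single block.
#' @param source_chrom,target_chrom chromosome names.
#' @param target_size target chromosome size; defaults to fit the blocks.
#' @return `path`, invisibly.
#' @export
gen_chain <- function(path, source_size, blocks = NULL, offset = 0L,
                      source_chrom = "chrS1", target_chrom = "chrT1",
                      target_size = NULL) {
  if (is.null(blocks))
    blocks <- data.frame(src_start = 0L, size = source_size,
                         tgt_start = offset)
  if (is.null(target_size))
    target_size <- max(blocks$tgt_start + blocks$size)
  write_chain(path, source_chrom, source_size, target_chrom, target_size,
              blocks)
}

#' Check that a generator manifest is recomputable from the emitted data
#'
#' Re-derives the manifest's planted quantities from the generated objects
#' using the analysis modules and stops on any mismatch. Supported bundle
#' types: `probe_association`, `promoter_correlation`, `clip_reads`,
#' `gel_lane`.
#'
#' @param bundle a generator output list holding `manifest` plus its data.
#' @return TRUE, invisibly, if everything matches.
#' @export
verify_manifest <- function(bundle) {
  man <- bundle$manifest
  stopifnot(!is.null(man$type))
  ok <- function(cond, what) if (!cond) stop("manifest mismatch: ", what)
  switch(
    man$type,
    probe_association = {
      ago <- label_probes_by_proximity(bundle$probes, bundle$sites,
                                       man$assoc_d_max)
      met <- dichotomize_methylation(bundle$probes$methylation,
                                     "threshold",
                                     threshold = man$met_threshold)
      tab <- contingency_table(as.logical(met), ago)
      ok(sum(ago) == man$n_ago_pos, "AGO+ count")
      ok(tab$a == man$table$a && tab$b == man$table$b &&
           tab$c == man$table$c && tab$d == man$table$d,
         "contingency table")
    },
    promoter_correlation = {
      ok(nrow(bundle$sites) == man$total_sites, "total site count")
      cr <- promoter_correlation(bundle$probes, bundle$sites,
                                 summary = "sum")
      ok(isTRUE(all.equal(cr$r, man$realized_r, tolerance = 1e-8)),
         "realized correlation")
    },
    clip_reads = {
      filt <- suppressMessages(filter_multimappers(bundle$reads, 30L))
      ok(attr(filt, "n_removed") == man$n_over30, ">30-location count")
      combos <- man$sites_by_combination
      for (i in seq_len(nrow(combos))) {
        s <- reads_to_sites(filt, "AGO", combos$min_length[i],
                            combos$match_mode[i])
        ok(nrow(s) == combos$n_sites[i],
           paste("site count at min_length", combos$min_length[i],
                 combos$match_mode[i]))
      }
    },
    gel_lane = {
      cnt <- as.list(man$pattern_counts)
      ok(sum(unlist(cnt)) == man$molecule_count, "molecule count")
      ok(isTRUE(all.equal(.gel_true_fraction(man$assay, cnt),
                          man$true_fraction)), "true fraction")
      if (man$cv == 0) {
        est <- if (man$assay == "LINE1") line1_methylation(bundle$lane)
               else alu_methylation(bundle$lane)
        ok(isTRUE(all.equal(est$percent, 100 * man$true_fraction)),
           "noiseless estimator identity")
      }
    },
    stop("unknown manifest type: ", man$type))
  invisible(TRUE)
}
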