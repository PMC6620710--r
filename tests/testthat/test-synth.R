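test_that("the promoter array has 15 x 50-bp probes per promoter, tiles
           contiguously at span 750, and rejects impossible spans", {
  tr <- synthetic_truth(seed = 2, promoter_count = 100)
  arr <- gen_promoter_array(tr)
  expect_identical(nrow(arr$probes), 1500L)
  expect_true(all(arr$probes$end - arr$probes$start == 50L))
  expect_silent(validate_probe_table(arr$probes))

  tight <- synthetic_truth(seed = 2, promoter_count = 20,
                           promoter_span = 750L,
                           site_jitter = 0L, assoc_d_max = 20L)
  probes <- gen_promoter_array(tight)$probes
  for (id in unique(probes$promoter_id)) {
    p <- probes[probes$promoter_id == id, ]
    p <- p[order(p$start), ]
    expect_identical(p$start[-1], p$end[-15])   # gapless adjacency
  }

  expect_error(gen_promoter_array(
    synthetic_truth(seed = 2, promoter_span = 600L)), "span")
})

test_that("generators are byte-identical across reruns at a fixed seed", {
  tr <- synthetic_truth(seed = 99, promoter_count = 30, n_reads = 50)
  out <- replicate(2, {
    arr <- gen_promoter_array(tr)
    plant <- gen_probe_association(tr, arr$probes)
    cl <- gen_clip_reads(tr)
    f <- withr::local_tempfile(fileext = ".tsv")
    write_probe_table(plant$probes, f, comments = paste("seed", tr$seed))
    f2 <- withr::local_tempfile(fileext = ".tsv")
    write_clip_tables(cl$reads, f2,
                      withr::local_tempfile(fileext = ".tsv"))
    c(tools::md5sum(f), tools::md5sum(f2))
  })
  expect_identical(out[1, 1], out[1, 2])
  expect_identical(out[2, 1], out[2, 2])
})

test_that("the association plant records its own truth: odds arithmetic,
           exact AGO+ counts, and a recomputable manifest", {
  fx <- small_assoc_fixture(seed = 8)
  expect_equal(fx$truth$planted_or,
               (0.6367 / 0.3633) / (0.3 / 0.7), tolerance = 1e-12)

  # manifest AGO+ count equals the labeling module's count at the
  # generator's d_max (round trip)
  ago <- label_probes_by_proximity(fx$probes, fx$sites,
                                   fx$manifest$assoc_d_max)
  expect_identical(sum(ago), fx$manifest$n_ago_pos)
  expect_true(verify_manifest(fx))
})

test_that("a null plant (equal MET probabilities) estimates an odds ratio
           near 1", {
  fx <- small_assoc_fixture(seed = 12, promoter_count = 400,
                            p_met_given_ago = 0.45,
                            p_met_given_noago = 0.45)
  expect_equal(fx$truth$planted_or, 1)
  ago <- label_probes_by_proximity(fx$probes, fx$sites,
                                   fx$manifest$assoc_d_max)
  met <- as.logical(dichotomize_methylation(
    fx$probes$methylation, "threshold",
    threshold = fx$manifest$met_threshold))
  tab <- contingency_table(met, ago)
  st <- association_stats(tab)
  # planted ln OR = 0; estimate within 3 SE of it
  expect_lt(abs(log(st$odds_ratio)), 3 * sqrt(sum(1 / unlist(tab))))
})

test_that("the correlation plant's implied r follows the closed form and
           its sites are recoverable by overlap counting", {
  expect_equal(synthetic_truth(corr_noise_sd = 0)$implied_r, 1)
  expect_equal(synthetic_truth(corr_slope = 0)$implied_r, 0)
  expect_equal(synthetic_truth(corr_slope = 5, corr_site_mean = 2,
                               corr_noise_sd = 41)$implied_r,
               10 / (sqrt(2) * sqrt(1731)), tolerance = 1e-12)

  tr <- synthetic_truth(seed = 14, promoter_count = 80)
  arr <- gen_promoter_array(tr)
  co <- gen_promoter_correlation_data(tr, arr$promoters, arr$probes)
  expect_true(verify_manifest(co))
})

test_that("the CLIP generator straddles the multimapper boundary and its
           manifest survivor counts round-trip through the pipeline", {
  tr0 <- synthetic_truth(seed = 19, n_reads = 120, multimap_fraction = 0)
  cl0 <- gen_clip_reads(tr0)
  expect_identical(cl0$manifest$n_over30, 0L)
  filt <- suppressMessages(filter_multimappers(cl0$reads))
  expect_identical(attr(filt, "n_removed"), 0L)
  expect_identical(filt$mappings, cl0$reads$mappings)  # no-op

  tr <- synthetic_truth(seed = 19, n_reads = 200)
  cl <- gen_clip_reads(tr)
  expect_gt(cl$manifest$n_over30, 0L)
  expect_true(verify_manifest(cl))

  # with no edits anywhere, perfect- and approximate-mode sites coincide
  tr2 <- synthetic_truth(seed = 20, n_reads = 100, edit_fraction = 0)
  mr2 <- suppressMessages(filter_multimappers(gen_clip_reads(tr2)$reads))
  expect_identical(reads_to_sites(mr2, "AGO1", 15, "perfect_only"),
                   reads_to_sites(mr2, "AGO1", 15, "include_approximate"))
})

test_that("gel lanes contain only the bands their pattern mix allows and
           noiseless lanes invert exactly", {
  mm <- gen_gel_lane("LINE1", 300, c(mm = 1, hemi = 0, uu = 0), seed = 6)
  expect_setequal(names(mm$lane$bands[mm$lane$bands > 0]),
                  c("50", "42"))
  uu <- gen_gel_lane("ALU", 300, c(mm = 0, mu = 0, um = 0, uu = 1),
                     seed = 6)
  expect_setequal(names(uu$lane$bands[uu$lane$bands > 0]), "133")

  g <- gen_gel_lane("ALU", 1000,
                    c(mm = 0.3, mu = 0.3, um = 0.2, uu = 0.2), seed = 7)
  expect_equal(alu_methylation(g$lane)$percent, 100 * g$true_fraction)
  expect_true(verify_manifest(g))

  expect_error(gen_gel_lane("LINE1", 0, c(mm = 1, hemi = 0, uu = 0)),
               ">= 1")
  expect_error(gen_gel_lane("LINE1", 10, c(mm = 0.5, hemi = 0.1,
                                           uu = 0.1)),
               "pattern_probs")
})

test_that("probe and site tables survive a TSV/BED round trip", {
  fx <- small_assoc_fixture(seed = 26, promoter_count = 20)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_probe_table(fx$probes, f, comments = "seed 26")
  back <- read_probe_table(f)
  expect_equal(back$methylation, fx$probes$methylation)
  expect_identical(back$start, fx$probes$start)

  b <- withr::local_tempfile(fileext = ".bed")
  write_sites_bed(fx$sites, b)
  sb <- read_sites_bed(b)
  expect_identical(sb$start, fx$sites$start)
  expect_identical(sb$end, fx$sites$end)
  expect_identical(sb$ago, fx$sites$ago)
  expect_identical(sb$support, fx$sites$support)
})
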