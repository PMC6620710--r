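test_that("lane normalization divides by the printed divisors and derives
           F by the assay formula", {
  l1 <- gel_lane("LINE1", c(`92` = 920))
  expect_equal(normalize_lane(l1),
               c(A = 10, B = 0, C = 0, D = 0, E = 0, F = 0))

  alu <- gel_lane("ALU", c(`58` = 58, `43` = 43))
  comp <- normalize_lane(alu)
  expect_equal(comp[["B"]], 1)
  expect_equal(comp[["E"]], 1)
  expect_equal(comp[["F"]], 1)   # ((E + B) - (C + D)) / 2

  zero <- gel_lane("LINE1", c(`92` = 0, `60` = 0, `50` = 0, `42` = 0,
                              `32` = 0))
  expect_true(all(normalize_lane(zero) == 0))
})

test_that("lanes reject unknown band sizes, clamp negative intensities
           and treat missing bands as zero", {
  expect_error(gel_lane("LINE1", c(`92` = 1, `133` = 1)), "unknown band")
  expect_warning(l <- gel_lane("ALU", c(`133` = -5, `90` = 10)),
                 "clamped")
  expect_equal(unname(l$bands["133"]), 0)
  expect_true("58" %in% l$missing_bands)
})

test_that("LINE-1 percentages hit the fully methylated, fully
           unmethylated and mixed closed forms", {
  for (x in c(1, 7, 0.3)) {
    full <- line1_methylation(gel_lane("LINE1",
                                       c(`50` = 48 * x, `42` = 40 * x)))
    expect_equal(full$percent, 100)
    none <- line1_methylation(gel_lane("LINE1",
                                       c(`60` = 56 * x, `32` = 28 * x)))
    expect_equal(none$percent, 0)
  }
  mixed <- line1_methylation(gel_lane("LINE1",
                                      c(`50` = 48 * 600, `42` = 40 * 600,
                                        `92` = 92 * 200, `60` = 56 * 200,
                                        `32` = 28 * 200)))
  expect_equal(mixed$percent, 70)
})

test_that("Alu percentages hit the closed-form patterns", {
  for (x in c(1, 3)) {
    full <- alu_methylation(gel_lane("ALU", c(`58` = 58 * x,
                                              `43` = 43 * x)))
    expect_equal(full$percent, 100)
  }
  none <- alu_methylation(gel_lane("ALU", c(`133` = 133 * 4)))
  expect_equal(none$percent, 0)
  even <- alu_methylation(gel_lane("ALU",
                                   c(`133` = 133 * 250, `58` = 58 * 500,
                                     `75` = 75 * 250, `90` = 90 * 250,
                                     `43` = 43 * 500)))
  expect_equal(even$percent, 50)
})

test_that("both estimators are scale-invariant and continuous in the
           intensities, with out-of-range values flagged not clamped", {
  set.seed(61)
  lane <- gen_gel_lane("LINE1", 500, c(mm = 0.5, hemi = 0.3, uu = 0.2),
                       seed = 2)$lane
  base <- line1_methylation(lane)$percent
  for (k in c(0.01, 3, 1e4)) {
    scaled <- gel_lane("LINE1", lane$bands * k)
    expect_equal(line1_methylation(scaled)$percent, base,
                 tolerance = 1e-12)
  }
  # small perturbation moves the estimate continuously
  bumped <- lane$bands; bumped["50"] <- bumped["50"] * (1 + 1e-9)
  expect_equal(line1_methylation(gel_lane("LINE1", bumped))$percent,
               base, tolerance = 1e-6)

  # inconsistent lane (only the 60-bp band): F < 0 drives the percent
  # below 0; it is reported as-is with a flag, never clamped
  odd <- line1_methylation(gel_lane("LINE1", c(`60` = 56)))
  expect_lt(odd$percent, 0)
  expect_true("out_of_range" %in% odd$flags)

  empty <- line1_methylation(gel_lane("LINE1", c(`92` = 0)))
  expect_true(is.na(empty$percent))     # 2A+2B+2C+2F = 0
  expect_true("zero_denominator" %in% empty$flags)
})

test_that("the lane-table interface reproduces per-lane estimates", {
  g <- gen_gel_lane("ALU", 800, c(mm = 0.4, mu = 0.2, um = 0.2, uu = 0.2),
                    seed = 5, replicate_id = "rep1")
  lanes <- data.frame(replicate_id = "rep1", assay = "ALU",
                      band_size = as.integer(names(g$lane$bands)),
                      intensity = unname(g$lane$bands))
  est <- cobra_estimates(lanes)
  expect_identical(nrow(est), 1L)
  expect_equal(est$percent, 100 * g$true_fraction)
})

test_that("delta-delta-Ct fold changes follow the closed form", {
  expect_equal(ddct_fold_change(20, 15, 22, 15), 4)
  expect_equal(ddct_fold_change(20, 15, 20, 15), 1)
  expect_equal(ddct_fold_change(25, 15, 20, 15), 2^-5)
  expect_equal(ddct_fold_change(c(20, 25), c(15, 15), c(22, 20),
                                c(15, 15)),
               c(4, 0.03125))
  expect_error(ddct_fold_change(NA, 15, 20, 15), "finite")
})
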