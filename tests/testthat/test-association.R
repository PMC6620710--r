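test_that("the median split labels values above the median MET+ with
           ties falling to MET-", {
  met <- dichotomize_methylation(c(1, 2, 3, 4))
  expect_identical(as.logical(met), c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(attr(met, "n_met_pos"), 2L)

  tied <- dichotomize_methylation(c(1, 2, 2, 3))  # median = 2
  expect_identical(as.logical(tied), c(FALSE, FALSE, FALSE, TRUE))

  expect_warning(flat <- dichotomize_methylation(rep(7, 5)), "MET-")
  expect_false(any(flat))

  thr <- dichotomize_methylation(c(0.1, 5, 80), "threshold",
                                 threshold = 0)
  expect_true(all(thr))
})

test_that("proximity labeling crosses the threshold at the exact
           center distance and no sites means all AGO-", {
  probes <- iv("chr1", 100, 150)
  sites <- iv("chr1", 300, 320)   # center distance 185
  expect_false(label_probes_by_proximity(probes, sites, 100))
  expect_true(label_probes_by_proximity(probes, sites, 200))
  expect_true(label_probes_by_proximity(probes, sites, 185))
  expect_false(any(label_probes_by_proximity(probes, sites[0, ], 10000)))
})

test_that("every classified probe lands in exactly one contingency cell", {
  set.seed(13)
  for (i in 1:10) {
    n <- sample(10:500, 1)
    met <- runif(n) > 0.5; ago <- runif(n) > 0.4
    tab <- contingency_table(met, ago)
    expect_identical(tab$a + tab$b + tab$c + tab$d, as.integer(n))
  }
})

test_that("odds ratio, CI and chi-square match closed forms and an
           independent numerical oracle", {
  st <- association_stats(list(a = 30, b = 10, c = 10, d = 30))
  expect_equal(st$odds_ratio, 9)
  expect_equal(st$chi_square, 20)
  expect_false(st$corrected)

  # independent oracle: direct arithmetic + normal-tail chi-square(1)
  se <- sqrt(1 / 30 + 1 / 10 + 1 / 10 + 1 / 30)
  expect_equal(st$ci_low, exp(log(9) - 1.96 * se), tolerance = 1e-4)
  expect_equal(st$ci_high, exp(log(9) + 1.96 * se), tolerance = 1e-4)
  expect_equal(st$p_value, 2 * pnorm(-sqrt(20)), tolerance = 1e-4)
})

test_that("a zero cell triggers the +0.5 correction and is flagged", {
  st <- association_stats(list(a = 10, b = 0, c = 5, d = 5))
  expect_equal(st$odds_ratio, (10.5 * 5.5) / (0.5 * 5.5))
  expect_equal(st$odds_ratio, 21)
  expect_true(st$corrected)
})

test_that("a zero margin leaves chi-square undefined but still reports a
           corrected odds ratio", {
  st <- association_stats(list(a = 10, b = 10, c = 0, d = 0))
  expect_true(is.na(st$chi_square))
  expect_true(is.na(st$p_value))
  expect_match(st$note, "margin")
  expect_true(is.finite(st$odds_ratio))
})

test_that("the odds ratio of the row-swapped table is the reciprocal and
           chi-square is invariant under transposition", {
  set.seed(29)
  for (i in 1:20) {
    cells <- as.list(sample(1:200, 4))
    names(cells) <- c("a", "b", "c", "d")
    st <- association_stats(cells)
    swapped <- association_stats(list(a = cells$c, b = cells$d,
                                      c = cells$a, d = cells$b))
    transposed <- association_stats(list(a = cells$a, b = cells$c,
                                         c = cells$b, d = cells$d))
    expect_equal(swapped$odds_ratio, 1 / st$odds_ratio)
    expect_equal(transposed$chi_square, st$chi_square)
    # cross-check the Pearson statistic against stats::chisq.test
    ref <- suppressWarnings(
      chisq.test(matrix(unlist(cells), 2, byrow = TRUE),
                 correct = FALSE))
    expect_equal(st$chi_square, unname(ref$statistic))
    expect_equal(st$p_value, ref$p.value)
  }
})

test_that("promoter correlation recovers exact linearity and reports
           undefined r under zero variance", {
  tr <- synthetic_truth(seed = 17, promoter_count = 60,
                        corr_noise_sd = 0)
  arr <- gen_promoter_array(tr)
  co <- gen_promoter_correlation_data(tr, arr$promoters, arr$probes)
  cr <- promoter_correlation(co$probes, co$sites)
  expect_equal(cr$r, 1, tolerance = 1e-10)

  # zero variance in x: no sites at all
  cr0 <- promoter_correlation(arr$probes, co$sites[0, ])
  expect_true(is.na(cr0$r))
  expect_match(cr0$note, "zero variance")
})

test_that("promoter correlation equals the hand-computed Pearson r and
           t-transform p-value on a small fixture", {
  tr <- synthetic_truth(seed = 23, promoter_count = 40)
  arr <- gen_promoter_array(tr)
  co <- gen_promoter_correlation_data(tr, arr$promoters, arr$probes)
  cr <- promoter_correlation(co$probes, co$sites)
  # independent route: rebuild x and y by direct counting/summation
  y <- tapply(co$probes$methylation, co$probes$promoter_id, sum)
  y <- as.numeric(y[arr$promoters$promoter_id])
  x <- apply(arr$promoters[, c("start", "end")], 1, function(p)
    sum(co$sites$start < p[2] & co$sites$end > p[1]))
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cr$r, r, tolerance = 1e-12)
  tstat <- r * sqrt((length(x) - 2) / (1 - r^2))
  expect_equal(cr$p_value, 2 * pt(-abs(tstat), length(x) - 2),
               tolerance = 1e-12)
})

test_that("proximity profile membership is cumulative and reflects a
           planted near-site methylation boost", {
  fx <- small_assoc_fixture(seed = 31)
  prof <- proximity_profile(fx$probes, fx$sites,
                            thresholds = c(50, 100, 200, 500))
  expect_true(all(diff(prof$n_probes) >= 0))
  # only planted AGO+ probes (high-methylation enriched) lie within 50 bp
  expect_gt(prof$mean_methylation[1], prof$mean_methylation[4])

  expect_error(proximity_profile(fx$probes, fx$sites, c(100, 50)),
               "increasing")
})

test_that("proximity profile reports empty and single-probe bins", {
  probes <- data.frame(promoter_id = "P1", probe_index = 1,
                       chrom = "chr1", start = 0L, end = 50L,
                       strand = "+", methylation = 42)
  far <- data.frame(chrom = "chr1", start = 5000L, end = 5020L,
                    strand = "+", ago = "AGO4")
  prof <- proximity_profile(probes, far, thresholds = c(10, 100))
  expect_true(all(is.na(prof$mean_methylation)))
  expect_identical(prof$n_probes, c(0L, 0L))

  near <- data.frame(chrom = "chr1", start = 30L, end = 50L,
                     strand = "+", ago = "AGO4")
  prof2 <- proximity_profile(probes, near, thresholds = c(50, 100))
  expect_equal(prof2$mean_methylation, c(42, 42))
})

test_that("TSS-relative offsets are strand-aware and sense/antisense is
           judged against the gene strand", {
  promoters <- data.frame(promoter_id = c("P1", "P2"), gene = c("g1", "g2"),
                          chrom = "chr1", start = c(1000L, 3000L),
                          end = c(2500L, 4500L), strand = c("+", "-"),
                          tss = c(1000L, 4500L))
  sites <- data.frame(chrom = "chr1",
                      start = c(1090L, 4390L, 995L),
                      end = c(1110L, 4410L, 1005L),
                      strand = c("+", "-", "-"),
                      ago = "AGO4")
  prof <- tss_binding_profile(sites, promoters, bin_width = 50)
  # + gene: center 1100, offset +100, sense
  # - gene: center 4400 is 100 bp 5'-ward in genome coords -> offset +100,
  #   site strand matches gene strand -> sense (manual coordinate walk)
  sense <- prof[prof$orientation == "sense", ]
  expect_identical(sense$bin_start, 100L)
  expect_identical(sense$count, 2L)
  # site centered exactly at the TSS of the + gene, opposite strand
  anti <- prof[prof$orientation == "antisense", ]
  expect_identical(anti$bin_start, 0L)
})

test_that("group comparison reports undefined p for degenerate paired
           inputs and holds its type-I error rate", {
  x <- c(1, 2, 3, 4, 5)
  same <- compare_groups(x, x, paired = TRUE)
  expect_true(is.na(same$p_value))
  expect_false(is.na(same$note))

  shifted <- compare_groups(x, x + 3, paired = TRUE)
  expect_true(is.na(shifted$p_value))

  set.seed(41)
  rej <- mean(replicate(1000, {
    compare_groups(rnorm(10), rnorm(10))$p_value < 0.05
  }))
  # 99% binomial bounds around the nominal 5% at 1000 simulations
  expect_gt(rej, 0.032)
  expect_lt(rej, 0.068)
})

test_that("promoters bound by more than one protein are excluded while
           single-protein and unbound promoters are retained", {
  tr <- synthetic_truth(seed = 47, promoter_count = 50)
  arr <- gen_promoter_array(tr)
  prom <- arr$promoters
  mid <- function(i) interval_center(prom$start[i], prom$end[i])
  site <- function(i, ago) data.frame(chrom = prom$chrom[i],
                                      start = mid(i) - 10L,
                                      end = mid(i) + 10L, strand = "+",
                                      ago = ago)
  multi <- do.call(rbind, lapply(1:12, function(i)
    rbind(site(i, "AGO1"), site(i, "AGO4"))))
  single <- do.call(rbind, lapply(13:40, function(i) site(i, "AGO4")))
  kept <- select_exclusive_promoters(prom, rbind(multi, single))
  expect_identical(nrow(kept), 38L)
  expect_identical(attr(kept, "n_excluded"), 12L)
  expect_true(all(prom$promoter_id[41:50] %in% kept$promoter_id))
})
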