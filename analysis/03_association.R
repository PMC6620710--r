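#!/usr/bin/env Rscript
# The colocalization analysis proper: lift the binding sites through the
# (identity) chain, filter to single-protein promoters, label probes
# MET+/- and AGO+/-, sweep the 2x2 contingency analysis over proximity
# thresholds, and compute the promoter-level Pearson correlation between
# methylation and binding-site count on a separately planted fixture.

suppressMessages(library(rddmcoloc))

src <- "results/synthetic"
out <- "results/association"
seed <- 20260926L

report <- run_association_study(default_config(
  probes = file.path(src, "probes.tsv"),
  sites = file.path(src, "sites_ago4.bed"),
  chain = file.path(src, "synth1ToSynth2.chain"),
  target_assembly = "synth2",
  met_rule = "threshold", met_threshold = 50,
  d_max = c(50L, 100L, 200L, 500L, 1000L),
  out_dir = out))

man <- read_manifest(file.path(src, "association_manifest.json"))
cat("\nContingency sweep (threshold MET split at 50):\n")
print(report$association[, c("d_max", "a", "b", "c", "d", "odds_ratio",
                             "ci_low", "ci_high", "p_value")],
      row.names = FALSE, digits = 4)
head_row <- report$association[report$association$d_max == man$assoc_d_max, ]
cat(sprintf(paste0(
  "\nAt the generator's proximity threshold (%d bp) the estimated OR is ",
  "%.3f\nagainst a planted OR of %.3f (realized table OR %.3f); larger ",
  "thresholds\ndilute the AGO+ class with unplanted neighbor probes and ",
  "the OR decays\ntoward 1, mirroring a distance-dependent association.\n"),
  man$assoc_d_max, head_row$odds_ratio, man$planted_or,
  (man$table$a * man$table$d) / (man$table$b * man$table$c)))

# promoter-level correlation on the planted Poisson/linear fixture
truth <- synthetic_truth(seed = seed + 1L, promoter_count = 20000L)
arr <- gen_promoter_array(truth)
co <- gen_promoter_correlation_data(truth, arr$promoters, arr$probes)
cr <- promoter_correlation(co$probes, co$sites, promoters = arr$promoters)
corr_tab <- data.frame(n_promoters = cr$n,
                       implied_r = truth$implied_r,
                       realized_r = co$manifest$realized_r,
                       estimated_r = cr$r, p_value = cr$p_value)
utils::write.table(corr_tab, file.path(out, "promoter_correlation.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf(paste0(
  "\nPromoter-level Pearson correlation over %d promoters: r = %.4f\n",
  "(implied by the plant: %.4f), p = %.3g\n"),
  cr$n, cr$r, truth$implied_r, cr$p_value))

cat("\nProximity profile (mean probe methylation within d bp of a site):\n")
print(report$proximity_profile, row.names = FALSE, digits = 4)
cat("Report bundle written under", out, "\n")
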