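#!/usr/bin/env Rscript
# Generate the synthetic study inputs with planted ground truth:
# a promoter tiling array with a planted probe-level MET/AGO association,
# a CLIP-style mapped-read pair, a chain file, and COBRA gel lanes.
# Everything downstream (02-04) consumes these files.

suppressMessages(library(rddmcoloc))

out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260926L

truth <- synthetic_truth(seed = seed, promoter_count = 2000L)
cat("Planted odds ratio:", round(truth$planted_or, 4),
    "| implied promoter-level r:", round(truth$implied_r, 4), "\n")

arr <- gen_promoter_array(truth)
plant <- gen_probe_association(truth, arr$probes)
write_probe_table(plant$probes, file.path(out, "probes.tsv"),
                  comments = c(paste("seed", seed),
                               "planted probe-level MET/AGO association"))
write_sites_bed(plant$sites, file.path(out, "sites_ago4.bed"))
write_manifest(plant$manifest, file.path(out, "association_manifest.json"))
cat("Probe array:", nrow(plant$probes), "probes /",
    nrow(arr$promoters), "promoters;",
    plant$manifest$n_ago_pos, "planted AGO+ probes\n")

cl <- gen_clip_reads(truth)
write_clip_tables(cl$reads,
                  file.path(out, "mapped_sequences.tsv"),
                  file.path(out, "genome_mappings.tsv"),
                  comments = paste("seed", seed))
write_manifest(cl$manifest, file.path(out, "clip_manifest.json"))
cat("CLIP reads:", cl$manifest$n_reads, "reads,",
    cl$manifest$n_locations, "locations,",
    cl$manifest$n_over30, "reads exceeding 30 locations\n")

gen_chain(file.path(out, "synth1ToSynth2.chain"),
          source_size = arr$chrom_size, offset = 0L,
          target_chrom = truth$chrom)

lanes <- do.call(rbind, lapply(1:6, function(i) {
  g <- gen_gel_lane("LINE1", truth$gel_molecules,
                    truth$line1_pattern_probs, seed = seed + i,
                    cv = 0.03, replicate_id = sprintf("L1_rep%d", i))
  data.frame(replicate_id = g$lane$replicate_id, assay = "LINE1",
             band_size = as.integer(names(g$lane$bands)),
             intensity = unname(g$lane$bands))
}))
lanes <- rbind(lanes, do.call(rbind, lapply(1:6, function(i) {
  g <- gen_gel_lane("ALU", truth$gel_molecules,
                    truth$alu_pattern_probs, seed = seed + 100 + i,
                    cv = 0.03, replicate_id = sprintf("Alu_rep%d", i))
  data.frame(replicate_id = g$lane$replicate_id, assay = "ALU",
             band_size = as.integer(names(g$lane$bands)),
             intensity = unname(g$lane$bands))
})))
write_lane_table(lanes, file.path(out, "gel_lanes.tsv"),
                 comments = c(paste("seed", seed), "cv 0.03"))
cat("Gel lanes: 6 LINE-1 + 6 Alu replicates written\n")
cat("All synthetic inputs under", out, "\n")
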