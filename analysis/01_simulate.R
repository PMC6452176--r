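#!/usr/bin/env Rscript
# Simulate the study's raw materials with recorded ground truth:
#  - a 5-day, 5-minute-interval time-lapse of two cell lines in triplicate
#    (eccentricity traces; 1440 frames/well, 8640 frames in total),
#  - a small rendered phase-contrast demo series (reduced schedule) plus a
#    handful of immunofluorescence fields,
#  - negative-binomial count matrices for the three sequencing batches
#    (48 + 24 + 18 = 90 samples) with a designated suppressed gene set,
#  - the gene-set collection (GMT).
# Everything downstream (02-04) consumes these files.

suppressPackageStartupMessages(library(myodyn))
seed <- 20260926L
dir.create("results/simulated", recursive = TRUE, showWarnings = FALSE)

## full-schedule eccentricity traces -----------------------------------------
tl <- gen_timelapse(trajectory_spec(), seed = child_seed(seed, 1))
utils::write.csv(tl$truth, "results/simulated/traces.csv", row.names = FALSE)
message(sprintf("time-lapse: %d frames (%d per well, %d wells)",
                nrow(tl$manifest), sum(tl$manifest$well == tl$manifest$well[1]),
                length(unique(tl$manifest$well))))

## rendered demo frames (reduced schedule: 75-min interval over 2 days) ------
demo <- gen_timelapse(
  trajectory_spec(interval_min = 75, duration_min = 3000, wells_per_line = 2),
  seed = child_seed(seed, 2), render_dir = "results/simulated/frames")
message(sprintf("rendered %d demo frames", nrow(demo$manifest)))
utils::write.csv(demo$truth, "results/simulated/demo_truth.csv",
                 row.names = FALSE)

## immunofluorescence fields: a high- and a low-myotube condition ------------
if_dir <- "results/simulated/if_fields"
dir.create(if_dir, showWarnings = FALSE)
rows <- list(); i <- 0
for (cond in c("ctrl", "fshd")) for (w in 1:3) for (fld in 1:3) {
  i <- i + 1
  n <- if (cond == "ctrl") 10 else 4    # hypotrophic: less marker-positive area
  f <- gen_if_image(ellipse_field_spec(n_objects = n, noise_sd = 0.03),
                    seed = child_seed(seed, 100 + i))
  p <- file.path(if_dir, sprintf("%s_w%d_%d_marker.tif", cond, w, fld))
  write_field_tiff(f$marker, p)
  rows[[i]] <- data.frame(well = sprintf("%s_w%d", cond, w), condition = cond,
                          path = p, truth_area = f$area_fraction)
}
utils::write.csv(do.call(rbind, rows), "results/simulated/if_manifest.csv",
                 row.names = FALSE)

## count matrices for the three batches --------------------------------------
truth <- counts_ground_truth(n_genes = 10000, seed = child_seed(seed, 3))
designs <- fshd_batch_designs()
for (nm in names(designs)) {
  cm <- gen_counts(designs[[nm]], truth, seed = child_seed(seed, 4 + match(nm, names(designs))))
  tab <- data.frame(gene = rownames(cm$counts), cm$counts, check.names = FALSE)
  utils::write.table(tab, sprintf("results/simulated/counts_%s.tsv", nm),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cm$design, sprintf("results/simulated/meta_%s.tsv", nm),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("batch %-20s %d samples", nm, nrow(cm$design)))
}
utils::write.table(truth$genes, "results/simulated/counts_truth.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

## gene sets ------------------------------------------------------------------
sets <- gen_gene_sets(truth, seed = child_seed(seed, 9))
write_gmt(sets, "results/simulated/gene_sets.gmt")
message(sprintf("wrote %d gene sets (designated: %s, %d genes)",
                length(sets), names(sets)[1], length(sets[[1]])))
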