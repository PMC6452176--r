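#!/usr/bin/env Rscript
# Quantify the simulated images and check the quantifiers against the
# recorded ground truth:
#  - marker-positive area fraction per immunofluorescence field, aggregated
#    per well, with the control-vs-disease Welch t-test,
#  - per-frame mean cell eccentricity from the rendered phase-contrast demo,
#    compared with the trajectory the frames were drawn from.

suppressPackageStartupMessages(library(myodyn))
dir.create("results/image_quant", recursive = TRUE, showWarnings = FALSE)

## marker-positive area -------------------------------------------------------
man <- utils::read.csv("results/simulated/if_manifest.csv")
q <- quantify_wells(man, mode = "area")
print(q$groups)
message(sprintf("area t-test: t = %.2f, df = %.1f, p = %.3g",
                q$test$statistic, q$test$df, q$test$p.value))
message(sprintf("max |estimate - rendered truth| = %.4f",
                max(abs(q$fields$value - man$truth_area))))
myodyn:::write_tsv_prov(q$fields, "results/image_quant/if_fields.tsv",
                        list(mode = "area"))
myodyn:::write_tsv_prov(q$groups, "results/image_quant/if_groups.tsv",
                        list(mode = "area", t = q$test$statistic,
                             p = q$test$p.value))

## phase-contrast eccentricity ------------------------------------------------
dm <- utils::read.csv("results/simulated/frames/manifest.csv")
truth <- utils::read.csv("results/simulated/demo_truth.csv")
params <- segmentation_params(min_object_area = 100)
dm$mean_eccentricity <- vapply(dm$path, function(p)
  frame_mean_eccentricity(segment_cells(read_field_image(p), params)),
  numeric(1))
cmp <- merge(dm, truth, by = c("well", "line", "time_min"),
             suffixes = c("_est", "_true"))
err <- cmp$mean_eccentricity_est - cmp$mean_eccentricity_true
message(sprintf("eccentricity recovery over %d frames: mean err %.4f, RMSE %.4f",
                nrow(cmp), mean(err), sqrt(mean(err^2))))
myodyn:::write_tsv_prov(
  cmp[c("well", "line", "time_min", "mean_eccentricity_est",
        "mean_eccentricity_true")],
  "results/image_quant/demo_traces.tsv",
  list(min_object_area = params$min_object_area))
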