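#!/usr/bin/env Rscript
# Step 3 — accuracy assessment.
#
# Two assessments: (a) the published Bao'an Lake validation counts shipped
# with the package, reproducing the reported overall accuracy and kappa;
# (b) a fresh point-sampling assessment of one simulated classified scene
# against its ground truth, using randomly placed reference points.

suppressPackageStartupMessages(library(vbimap))

SEED <- 20240403
N_POINTS <- 600

## (a) published validation counts ----------------------------------------
cm_pub <- baoan_reference_confusion()
rep_pub <- accuracy_report(cm_pub)
cat(sprintf("published validation counts (n = %d): OA %.2f%%, kappa %.2f\n",
            rep_pub$n, 100 * rep_pub$overall_accuracy, rep_pub$kappa))

## (b) point sampling of a simulated scene --------------------------------
scene_files <- sort(Sys.glob("scratch/scenes/scene_????????.tif"))
if (!length(scene_files))
  stop("no simulated scenes found; run analysis/01_simulate.R first")
f <- scene_files[1]
truth <- read_classmap(sub("\\.tif$", "_truth.tif", f))
cmap <- read_classmap(sub("\\.tif$", "_classmap.tif", f))

set.seed(SEED)
ctr <- pixel_centers(truth$geo)
pts <- data.frame(x = sample(ctr$x, N_POINTS, replace = TRUE),
                  y = sample(ctr$y, N_POINTS, replace = TRUE))
lab <- class_labels(truth)
cell <- point_to_cell(truth$geo, pts$x, pts$y)
pts$class <- lab[cbind(cell$row, cell$col)]
pts <- pts[!is.na(pts$class), ]

pairs <- sample_classmap(cmap, pts)
rep_sim <- accuracy_report(build_confusion(pairs$reference, pairs$predicted))
cat(sprintf("simulated scene (%d points): OA %.2f%%, kappa %.2f\n",
            rep_sim$n, 100 * rep_sim$overall_accuracy, rep_sim$kappa))

out <- list(
  published = list(confusion = unclass(rep_pub$confusion),
                   overall_accuracy = rep_pub$overall_accuracy,
                   kappa = rep_pub$kappa),
  simulated = list(confusion = unclass(rep_sim$confusion),
                   overall_accuracy = rep_sim$overall_accuracy,
                   kappa = rep_sim$kappa,
                   producers_accuracy = rep_sim$producers_accuracy,
                   users_accuracy = rep_sim$users_accuracy))
write_outputs(out, "results/accuracy_report.json",
              config = list(seed = SEED, n_points = N_POINTS,
                            scene = basename(f)))
cat("wrote results/accuracy_report.json\n")
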