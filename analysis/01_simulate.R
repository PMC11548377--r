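#!/usr/bin/env Rscript
# Step 1 — simulate a multi-decade lake series with known ground truth.
#
# Emulates the observing situation of a macrophyte-losing shallow lake:
# one cloud-free spring scene per year from 2000, submerged vegetation
# shrinking from 60% of the lake to 5% over 24 years while an emergent
# fringe stays put.  Scenes go to scratch/ (bulky rasters); the true
# coverage table goes to results/.

suppressPackageStartupMessages(library(vbimap))

SEED <- 20240401
N_YEARS <- 24

dir.create("scratch/scenes", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

series <- generate_lake_timeseries(N_YEARS, sav_start = 0.60,
                                   sav_end = 0.05, seed = SEED,
                                   width = 96, height = 96,
                                   noise_sd = 0.01, start_year = 2000)

truth_recs <- list()
for (entry in series) {
  stem <- file.path("scratch/scenes", format(entry$date, "scene_%Y%m%d"))
  write_scene(entry$scene, paste0(stem, ".tif"))
  write_classmap(entry$truth, paste0(stem, "_truth.tif"))
  truth_recs[[length(truth_recs) + 1]] <-
    coverage_fraction(entry$truth, date = entry$date)
}
truth_ts <- build_timeseries(truth_recs)
write_outputs(truth_ts, "results/simulated_truth_coverage.csv",
              config = list(seed = SEED, n_years = N_YEARS,
                            sav_start = 0.60, sav_end = 0.05,
                            noise_sd = 0.01, grid = "96x96"))

sav <- truth_ts[truth_ts$class == "SAV", ]
cat(sprintf("simulated %d spring scenes (96x96, noise sd 0.01)\n", N_YEARS))
cat(sprintf("true SAV coverage: %.1f%% (2000) -> %.1f%% (%d)\n",
            100 * sav$fraction[1], 100 * sav$fraction[nrow(sav)],
            max(sav$year)))
cat("wrote results/simulated_truth_coverage.csv and scratch/scenes/*.tif\n")
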