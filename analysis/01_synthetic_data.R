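#!/usr/bin/env Rscript
# Generate the synthetic inputs used throughout the analysis: speckle movies
# advected by known flows, expanding-disk spheroid masks, and a TMA cohort
# with known ECM/YAP ground truth.  Large binary artifacts (TIFF movies) go
# to scratch/; the tables land in results/.

library(collmot)

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)
seed <- 1L

# --- monolayer movies -------------------------------------------------------
# a flocking-like monolayer: strong uniform drift
flock <- make_speckle_movie(
  flow_spec("uniform", drift = c(1.5, 0.5), seed = seed),
  shape = c(320, 320), n_frames = 12
)
write_movie_tiff(flock, "scratch/movie_flocking.tif")

# a jamming-like monolayer: spatially correlated flow whose amplitude decays
jam <- make_speckle_movie(
  flow_spec("correlated", xi_true = 40, vrms = 1.5, half_life = 6,
            seed = seed + 1L),
  shape = c(320, 320), n_frames = 16
)
write_movie_tiff(jam, "scratch/movie_jamming.tif")
cat("wrote monolayer movies (flocking, jamming) to scratch/\n")

# --- spheroid wetting masks -------------------------------------------------
# deterministic geometry: recorded as conditions, regenerated on demand
wet_summary <- data.frame(r0_um = 100, true_speed_um_per_h = c(2, 5, 10, 20),
                          t_max_h = 48, pixel_size_um = 2)
write.csv(wet_summary, "results/wetting_conditions.csv", row.names = FALSE)
cat("spheroid series: r0 = 100 um over 48 h at speeds 2/5/10/20 um/h\n")

# --- TMA cohort -------------------------------------------------------------
cohort <- make_tma_cohort(cohort_spec(n_patients = 198L, n_low_cell = 5L,
                                      hazard_ratio = 2, seed = seed + 2L))
write.csv(cohort$survival, "results/cohort_survival.csv", row.names = FALSE)
write.csv(cohort$truth, "results/cohort_truth.csv", row.names = FALSE)
# the full per-cell table is ~600k rows; keep it in scratch/
write.csv(cohort$cells, "scratch/cohort_cells.csv", row.names = FALSE)
cat(sprintf("cohort: %d patients, %d cell-marker rows\n",
            nrow(cohort$truth), nrow(cohort$cells)))
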