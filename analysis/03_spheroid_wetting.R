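#!/usr/bin/env Rscript
# Quantify spheroid wetting on the synthetic expanding-disk series: the
# normalized spreading area A(t)/A(0) and the average wetting speed from the
# slope of the equivalent-circle radius, compared with the imposed speeds.

library(collmot)
dir.create("results", showWarnings = FALSE)

cond <- read.csv("results/wetting_conditions.csv")

rows <- lapply(seq_len(nrow(cond)), function(i) {
  s <- make_spheroid_series(cond$r0_um[i], cond$true_speed_um_per_h[i],
                            times_h = seq(0, cond$t_max_h[i], by = 2),
                            pixel_size_um = cond$pixel_size_um[i])
  res <- wetting_analysis(s)
  areas <- res$areas
  areas$true_speed_um_per_h <- cond$true_speed_um_per_h[i]
  list(summary = data.frame(
    true_speed_um_per_h = cond$true_speed_um_per_h[i],
    measured_speed_um_per_h = res$speed_um_per_h,
    norm_area_48h = areas$norm_area[nrow(areas)]
  ), areas = areas)
})

speeds <- do.call(rbind, lapply(rows, `[[`, "summary"))
areas <- do.call(rbind, lapply(rows, `[[`, "areas"))
write.csv(speeds, "results/wetting_speeds.csv", row.names = FALSE)
write.csv(areas, "results/wetting_areas.csv", row.names = FALSE)

for (i in seq_len(nrow(speeds))) {
  cat(sprintf("imposed %g um/h -> measured %.2f um/h (A48/A0 = %.1f)\n",
              speeds$true_speed_um_per_h[i], speeds$measured_speed_um_per_h[i],
              speeds$norm_area_48h[i]))
}
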