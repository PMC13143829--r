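test_that("correlated fields have the requested moments and are deterministic", {
  f <- make_correlated_field(c(64, 64), xi_true = 20, vrms = 1, seed = 7)
  expect_lt(abs(mean(f$vx)), 0.05)
  expect_lt(abs(mean(f$vy)), 0.05)
  expect_equal(sqrt(mean(f$vx^2 + f$vy^2)), 1, tolerance = 0.01)

  f2 <- make_correlated_field(c(64, 64), xi_true = 20, vrms = 1, seed = 7)
  expect_identical(f, f2)

  expect_error(make_correlated_field(c(64, 64), xi_true = -1, vrms = 1, seed = 1),
               class = "collmot_parameter_error")
})

test_that("larger xi_true yields a longer fitted correlation length", {
  f20 <- make_correlated_field(c(256, 256), xi_true = 20, vrms = 1, seed = 3)
  f5 <- make_correlated_field(c(256, 256), xi_true = 5, vrms = 1, seed = 3)
  xi20 <- oracle_field_xi(f20$vx, f20$vy, 20)
  xi5 <- oracle_field_xi(f5$vx, f5$vy, 5)
  expect_gt(xi20, xi5)
})

test_that("oracle autocorrelation fit recovers xi_true within 15% over seeds", {
  for (xi in c(20, 40)) {
    est <- vapply(1:5, function(s) {
      f <- make_correlated_field(c(480, 480), xi_true = xi, vrms = 1, seed = s)
      oracle_field_xi(f$vx, f$vy, xi)
    }, numeric(1))
    expect_lt(abs(median(est) - xi) / xi, 0.15)
  }
  # the largest scale needs a proportionally larger domain for the same
  # relative finite-size error
  est80 <- vapply(1:5, function(s) {
    f <- make_correlated_field(c(960, 960), xi_true = 80, vrms = 1, seed = s)
    oracle_field_xi(f$vx, f$vy, 80)
  }, numeric(1))
  expect_lt(abs(median(est80) - 80) / 80, 0.15)
})

test_that("uniform-drift movies store the prescribed true fields", {
  fl <- flow_spec("uniform", drift = c(3, 0), seed = 5)
  mv <- make_speckle_movie(fl, shape = c(160, 160), n_frames = 4)
  for (tf in mv$true_fields) {
    expect_true(all(tf$vx == 3))
    expect_true(all(tf$vy == 0))
  }
  expect_true(all(is.finite(mv$frames)))
})

test_that("zero flow gives frames identical across time", {
  fl <- flow_spec("uniform", drift = c(0, 0), seed = 5)
  mv <- make_speckle_movie(fl, shape = c(160, 160), n_frames = 3)
  expect_identical(mv$frames[, , 1], mv$frames[, , 2])
  expect_identical(mv$frames[, , 1], mv$frames[, , 3])
})

test_that("movie generation is deterministic and validates its inputs", {
  fl <- flow_spec("uniform", drift = c(1, 0), seed = 9)
  m1 <- make_speckle_movie(fl, shape = c(160, 160), n_frames = 3)
  m2 <- make_speckle_movie(fl, shape = c(160, 160), n_frames = 3)
  expect_identical(m1$frames, m2$frames)

  expect_error(make_speckle_movie(fl, shape = c(120, 160), n_frames = 3),
               class = "collmot_sizing_error")
  expect_error(flow_spec("correlated", vrms = 1, xi_true = 0),
               class = "collmot_parameter_error")
})

test_that("correlated movies declare the requested r.m.s. speed", {
  fl <- flow_spec("correlated", xi_true = 30, vrms = 1.2, seed = 2)
  mv <- make_speckle_movie(fl, shape = c(256, 256), n_frames = 3)
  tf <- mv$true_fields[[1]]
  expect_equal(sqrt(mean(tf$vx^2 + tf$vy^2)), 1.2, tolerance = 0.01)
})

test_that("movies round-trip through TIFF plus sidecar", {
  fl <- flow_spec("uniform", drift = c(1, 0), seed = 4)
  mv <- make_speckle_movie(fl, shape = c(160, 160), n_frames = 3)
  path <- file.path(tempdir(), "movie.tif")
  write_movie_tiff(mv, path)
  rt <- read_movie_tiff(path)
  expect_equal(dim(rt$frames), dim(mv$frames))
  expect_equal(rt$frames, mv$frames, tolerance = 1e-4)  # 16-bit quantization
  expect_equal(rt$pixel_size_um, mv$pixel_size_um)
  expect_equal(rt$frame_interval_min, mv$frame_interval_min)
  unlink(c(path, paste0(path, ".yaml")))
})

test_that("spheroid series follow the prescribed disk geometry", {
  s0 <- make_spheroid_series(100, 0, times_h = c(0, 12, 24), pixel_size_um = 2)
  expect_identical(s0$masks[[1]], s0$masks[[3]])

  s <- make_spheroid_series(100, 10, times_h = seq(0, 48, by = 4),
                            pixel_size_um = 2)
  areas <- normalized_area(s)
  expect_equal(areas$area_um2[1], pi * 100^2, tolerance = 0.02)
  r48 <- areas$radius_um[areas$t_h == 48]
  expect_lt(abs(r48 - 580), 2 * s$pixel_size_um)

  expect_error(make_spheroid_series(100, -10, times_h = c(0, 20), pixel_size_um = 2),
               class = "collmot_parameter_error")
  expect_error(make_spheroid_series(-5, 1, times_h = c(0, 1)),
               class = "collmot_parameter_error")
})

test_that("synthetic cohorts carry recoverable ground truth", {
  spec <- cohort_spec(n_patients = 40, n_low_cell = 3, cells_per_compartment = 150,
                      seed = 11)
  ch <- make_tma_cohort(spec)
  expect_identical(ch$cells, make_tma_cohort(spec)$cells)

  counts <- exclude_low_cell_patients(ch$cells)$counts
  expect_equal(sum(counts$n_stromal < 100), 3)

  # every passing patient's assigned groups equal the generator's truth
  scored <- score_cohort(ch$cells, ch$survival)
  truth <- ch$truth[match(scored$cohort$patient_id, ch$truth$patient_id), ]
  expect_equal(scored$cohort$ecm_score, truth$true_score)
  expect_equal(scored$cohort$ecm_group, truth$true_ecm_group)
  expect_equal(scored$cohort$yap_group, truth$true_yap_group)
})

test_that("cohort spec validates its parameters", {
  expect_error(cohort_spec(n_patients = 1), class = "collmot_parameter_error")
  expect_error(cohort_spec(hazard_ratio = 0), class = "collmot_parameter_error")
  expect_error(cohort_spec(censoring_rate = 1.2), class = "collmot_parameter_error")
})
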