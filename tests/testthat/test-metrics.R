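test_that("r.m.s. velocity matches closed forms", {
  f <- make_test_field(matrix(3, 2, 2), matrix(4, 2, 2))
  expect_equal(rms_velocity(f), 5)

  f2 <- make_test_field(matrix(c(3, 0), 1, 2), matrix(c(0, 4), 1, 2))
  expect_equal(rms_velocity(f2), sqrt((9 + 16) / 2))

  f0 <- make_test_field(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_equal(rms_velocity(f0), 0)

  f$valid[] <- FALSE
  expect_warning(out <- rms_velocity(f))
  expect_true(is.na(out))
})

test_that("drift correction removes the spatial mean", {
  const <- make_test_field(matrix(5, 3, 3), matrix(-2, 3, 3))
  dc <- drift_correct(const)
  expect_equal(max(abs(c(dc$vx, dc$vy))), 0)

  balanced <- make_test_field(matrix(c(1, -1), 1, 2), matrix(0, 1, 2))
  dcb <- drift_correct(balanced)
  expect_equal(dcb$vx, balanced$vx)

  set.seed(4)
  f <- make_test_field(matrix(rnorm(25), 5), matrix(rnorm(25), 5))
  d <- drift_velocity(drift_correct(f))
  expect_lt(max(abs(d)), 1e-10)
})

test_that("total, drift-corrected r.m.s. and drift satisfy Pythagoras", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    f <- make_test_field(matrix(rnorm(n^2, sd = 2), n),
                         matrix(rnorm(n^2, sd = 2), n))
    if (i %% 3 == 0) f$valid[sample(n^2, n)] <- FALSE
    tot <- rms_velocity(f)
    dc <- rms_velocity(drift_correct(f))
    dr <- drift_velocity(f)
    expect_equal(tot^2, dc^2 + sum(dr^2), tolerance = 1e-9)
    expect_lte(dc, tot + 1e-12)
  }
})

test_that("the velocity correlation self-bin is exactly 1", {
  set.seed(5)
  f <- make_test_field(matrix(rnorm(36), 6), matrix(rnorm(36), 6))
  cur <- velocity_correlation(drift_correct(f))
  expect_identical(cur$cvv[cur$r_px == 0], 1)
})

test_that("a drift-corrected uniform field has undefined correlation", {
  f <- drift_correct(make_test_field(matrix(2, 3, 3), matrix(1, 3, 3)))
  expect_error(velocity_correlation(f), class = "collmot_degenerate_field")
})

test_that("an anti-aligned pair gives C_vv = -1 in its separation bin", {
  # two nodes with vectors (1,0) and (-1,0): the single off-origin bin holds
  # the two cross pairs, each with dot product -1, over a unit denominator
  f <- make_test_field(matrix(c(1, -1), 2, 1), matrix(0, 2, 1))
  cur <- velocity_correlation(f)
  expect_equal(cur$cvv[cur$r_px == 0], 1)
  expect_equal(cur$cvv[cur$r_px > 0], -1)
})

test_that("correlation matches the direct pair-enumeration oracle", {
  set.seed(17)
  for (n in c(4, 6, 8)) {
    f <- drift_correct(make_test_field(matrix(rnorm(n^2), n),
                                       matrix(rnorm(n^2), n)))
    cur <- velocity_correlation(f, bin_width_px = 40)
    oracle <- cvv_enumerate(f, 40)
    merged <- merge(as.data.frame(cur), oracle, by = "r_px")
    expect_equal(merged$cvv.x, merged$cvv.y, tolerance = 1e-9)
    expect_equal(merged$n_pairs.x, merged$n_pairs.y)
  }
})

test_that("i.i.d. random fields decorrelate beyond the self-bin", {
  set.seed(23)
  f <- drift_correct(make_test_field(matrix(rnorm(400), 20),
                                     matrix(rnorm(400), 20)))
  cur <- velocity_correlation(f)
  off <- cur[cur$r_px > 0, ]
  expect_true(all(abs(off$cvv) <= 3 / sqrt(off$n_pairs)))
})

test_that("exponential curves are fitted to their generating length", {
  r <- seq(0, 450, by = 50)
  curve <- data.frame(r_um = r, r_px = r, cvv = exp(-r / 50),
                      n_pairs = rep(100L, length(r)))
  fit <- fit_correlation_length(curve)
  expect_true(fit$fit_ok)
  expect_equal(fit$xi_um, 50, tolerance = 0.01)

  flat <- data.frame(r_um = r, r_px = r, cvv = rep(1, length(r)),
                     n_pairs = rep(100L, length(r)))
  peg <- fit_correlation_length(flat)
  expect_true(peg$pegged)
  expect_gte(peg$xi_um, max(r))

  few <- data.frame(r_um = c(0, 50), r_px = c(0, 50), cvv = c(1, 0.4),
                    n_pairs = c(10L, 10L))
  expect_false(fit_correlation_length(few)$fit_ok)
})

test_that("alignment index hits the aligned/orthogonal/anti-aligned poles", {
  f <- make_test_field(matrix(2, 3, 3), matrix(0, 3, 3))
  expect_true(all(alignment_index(f) == 1))

  # mean (1, 0): the node carrying (-2, 0) is perfectly anti-aligned
  f2 <- make_test_field(matrix(c(2, 3, -2), 1, 3), matrix(0, 1, 3))
  a2 <- alignment_index(f2)
  expect_equal(a2[1, 3], -1)
  expect_equal(a2[1, 1], 1)

  # mean (1, 0): node 3's vector (0, 2) is exactly orthogonal to the mean
  vx3 <- matrix(c(1, 2, 0), 1, 3)
  vy3 <- matrix(c(1, -3, 2), 1, 3)
  a3 <- alignment_index(make_test_field(vx3, vy3))
  expect_equal(a3[1, 3], 0)

  zero <- make_test_field(matrix(c(1, -1), 1, 2), matrix(0, 1, 2))
  expect_warning(az <- alignment_index(zero))
  expect_true(all(is.na(az)))
})

test_that("flocking and disorder are separated by the mean alignment", {
  set.seed(3)
  drifted <- make_test_field(matrix(3, 6, 6) + matrix(rnorm(36, sd = 0.01), 6),
                             matrix(rnorm(36, sd = 0.01), 6))
  expect_gte(mean(alignment_index(drifted)), 0.99)

  iid <- make_test_field(matrix(rnorm(900), 30), matrix(rnorm(900), 30))
  expect_lte(abs(mean(alignment_index(iid), na.rm = TRUE)), 0.1)
})

test_that("the phase trajectory is time-ordered and empty-safe", {
  empty <- phase_trajectory(data.frame())
  expect_equal(nrow(empty), 0)

  m <- data.frame(t_min = c(200, 0, 100), vrms_dc_umh = 1:3, xi_um = 4:6,
                  vrms_tot_umh = 0, drift_x_umh = 0, drift_y_umh = 0,
                  fit_ok = TRUE, pegged = FALSE, mean_alignment = 1)
  tr <- phase_trajectory(m)
  expect_equal(tr$t_min, c(0, 100, 200))
  expect_named(tr, c("t_min", "vrms_dc_umh", "xi_um"))
})

test_that("windowed-exponential inversion recovers the flow scale from raw fields", {
  est <- vapply(1:3, function(s) {
    f <- make_correlated_field(c(480, 480), 40, 1.5, seed = s)
    ys <- seq(1, 480, by = 20)
    ft <- velocity_field(f$vx[ys, ys], f$vy[ys, ys], ys - 1, ys - 1)
    cur <- velocity_correlation(drift_correct(ft), bin_width_px = 20)
    fit_flow_xi(cur, window_px = 1, domain_px = 480, texture_sigma_px = 0)$xi_px
  }, numeric(1))
  expect_lt(abs(median(est) - 40) / 40, 0.25)
})
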