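test_that("phantom geometry is rasterised by the voxel-centre rule", {
  gt <- recovery_phantom(radius = 1.5)
  grid <- gt$grid
  # exhaustive voxel-centre inclusion oracle for the tumour sphere
  n_oracle <- 0L
  ctr <- gt$spec$tumour_centre_mm
  ys <- (seq_len(grid$nrow) - (grid$nrow + 1) / 2) * grid$spacing_mm[1]
  xs <- (seq_len(grid$ncol) - (grid$ncol + 1) / 2) * grid$spacing_mm[2]
  zs <- (seq_len(grid$n_slices) - (grid$n_slices + 1) / 2) * grid$slice_pitch_mm
  for (i in seq_along(ys)) for (j in seq_along(xs)) for (k in seq_along(zs))
    if ((xs[j] - ctr[1])^2 + (ys[i] - ctr[2])^2 + (zs[k] - ctr[3])^2 <= 1.5^2)
      n_oracle <- n_oracle + 1L
  expect_equal(sum(gt$label == 2L), n_oracle)

  # zero tumour radius removes the tumour and leaves the brain unchanged
  tis <- gt$spec$tissue["brain"]
  gt0 <- build_phantom(phantom_spec(tumour_radius_mm = 0, tissue = tis))
  expect_equal(sum(gt0$label == 2L), 0L)
  expect_equal(sum(gt0$label == 1L), sum(gt$label > 0L))

  # tumour outside the brain is a geometry error
  expect_error(build_phantom(phantom_spec(tumour_centre_mm = c(6, 0, 0),
                                          tumour_radius_mm = 1.5,
                                          tissue = gt$spec$tissue)),
               "geometry")
})

test_that("contralateral brain ROI matches the study's ~18 mm^2 size on central slices", {
  gt <- recovery_phantom()
  pa <- prod(gt$grid$spacing_mm)
  central <- gt$grid$n_slices / 2 + c(-1L, 0L, 1L, 2L)
  areas <- vapply(central, function(s) sum(gt$roi$label[, , s] == 1L) * pa,
                  numeric(1))
  expect_true(all(areas >= 16 & areas <= 20))
  # tumour cross-section sits inside the observed 13 +/- 10 mm^2 range
  tum <- vapply(seq_len(gt$grid$n_slices),
                function(s) sum(gt$roi$label[, , s] == 2L) * pa, numeric(1))
  expect_true(all(tum[tum > 0] >= 3 & tum[tum > 0] <= 23))
})

test_that("simulated series follow the saturation forward model exactly", {
  gt <- recovery_phantom()
  proto <- spin_lock_protocol()
  ser <- simulate_series(gt, proto, 1000, noise = "none")
  # background voxels carry exactly zero signal
  bg <- gt$label == 0L
  for (k in seq_along(proto$tsl_ms))
    expect_true(all(ser$data[, , , k][bg] == 0))
  # brain voxel values equal S0 * Mz/M0 * exp(-TSL/T1rho) at every TSL
  vox <- which(gt$label == 1L)[1]
  mz <- saturation_factor(882, 120, proto$tsl_ms, 2000)$mz_over_m0
  expected <- 100 * mz * exp(-proto$tsl_ms / 98)
  got <- vapply(seq_along(proto$tsl_ms),
                function(k) ser$data[, , , k][vox], numeric(1))
  expect_equal(got, expected, tolerance = 1e-12)
  # correcting recovers the pure exponential to machine precision
  corr <- correct_series(decay_curve(proto$tsl_ms, got), 882, 120, 2000)
  expect_lt(max(abs(corr$signal - 100 * exp(-proto$tsl_ms / 98)) /
                  (100 * exp(-proto$tsl_ms / 98))), 1e-12)

  # unknown FSL is a key error, negative noise rejected
  expect_error(simulate_series(gt, proto, 750, noise = "none"), "unknown FSL")
  expect_error(simulate_series(gt, proto, 1000, sigma = -1), ">= 0")
})

test_that("the alternative saturation model exposes a correction bias", {
  gt <- recovery_phantom()
  proto <- spin_lock_protocol()
  ser <- simulate_series(gt, proto, 1000, noise = "none",
                         sat_model = "t1rho_decay")
  map <- fit_t1rho_map(ser, gt$roi, c(brain = 882, tumour = 988),
                       c(brain = 120, tumour = 139))
  sel <- gt$roi$label == 1L & !is.na(map$t1rho_ms)
  bias <- map$t1rho_ms[sel] - 98
  expect_true(all(abs(bias) > 0.1))  # nominal correction no longer exact
})

test_that("Rician noise is seed-deterministic and shows the expected floor", {
  gt <- recovery_phantom()
  proto <- spin_lock_protocol()
  s1 <- simulate_series(gt, proto, 1000, noise = "rician", sigma = 2, seed = 5)
  s2 <- simulate_series(gt, proto, 1000, noise = "rician", sigma = 2, seed = 5)
  expect_identical(s1$data, s2$data)
  s3 <- simulate_series(gt, proto, 1000, noise = "rician", sigma = 2, seed = 6)
  expect_false(identical(s1$data, s3$data))
  # zero-signal background magnitude has mean sigma * sqrt(pi/2)
  bg <- which(gt$label == 0L)
  vals <- s1$data[, , , 1][bg]
  expect_equal(mean(vals), 2 * sqrt(pi / 2), tolerance = 0.02)
})

test_that("cohort generator reproduces the pooled study counts and distributions", {
  design <- cohort_design()
  co <- generate_cohort(design, seed = 1, imaging = FALSE)
  tr <- co$truth
  pooled <- tr[tr$week %in% 2:4 & tr$fsl_hz == 1000, ]
  brain_n <- as.vector(table(factor(pooled$group, levels = 1:3)))
  tum_n <- as.vector(table(factor(pooled$group[pooled$has_tumour], levels = 1:3)))
  expect_equal(brain_n, c(15L, 14L, 12L))
  expect_equal(tum_n, c(0L, 9L, 7L))

  # empty design gives an empty study table
  empty <- cohort_design(schedule = default_schedule()[0, ])
  co0 <- generate_cohort(empty, seed = 1, imaging = FALSE)
  expect_equal(nrow(co0$truth), 0L)

  # over 200 seeded replicates the drawn mutant-group brain T1rho at 1000 Hz
  # recovers its configured mean within 3 standard errors
  vals <- numeric(0)
  for (r in 1:200) {
    t <- generate_cohort(design, seed = 20000 + r, imaging = FALSE)$truth
    vals <- c(vals, t$true_brain_t1rho_ms[t$group == 3 & t$fsl_hz == 1000])
  }
  tab <- study_t1rho_tables()
  mu <- tab$brain_mean[tab$group == 3 & tab$fsl_hz == 1000]
  sdv <- tab$brain_sd[tab$group == 3 & tab$fsl_hz == 1000]
  se <- sdv / sqrt(length(vals))
  expect_lt(abs(mean(vals) - mu), 3 * se)
})

test_that("cohort imaging output is byte-identical for identical seeds", {
  design <- cohort_design(schedule = subset(default_schedule(),
                                            group == 3 & mouse == 1 & week == 3))
  c1 <- generate_cohort(design, seed = 77)
  c2 <- generate_cohort(design, seed = 77)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$measurements[[1]]$series[["1000"]]$data,
                   c2$measurements[[1]]$series[["1000"]]$data)
})
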