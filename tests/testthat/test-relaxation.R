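test_that("effective saturation relaxation time follows the harmonic combination", {
  # identity and symmetry
  for (T in c(10, 79, 669, 1500)) expect_equal(t2rho_effective(T, T), T)
  expect_equal(t2rho_effective(669, 79), t2rho_effective(79, 669))
  # frozen arbitrary-precision reference for the control-group brain values
  expect_equal(t2rho_effective(669, 79), 141.31283422459893, tolerance = 1e-12)
  # monotone in t2, bracketed between t2 and 2*t2 for t2 <= t1
  expect_gt(t2rho_effective(669, 120), t2rho_effective(669, 79))
  for (t1 in c(300, 669, 900)) for (t2 in c(50, 79, 120)) {
    v <- t2rho_effective(t1, t2)
    expect_lte(v, min(2 * t2, 2 * t1))
    expect_gte(v, t2)
  }
  expect_error(t2rho_effective(-1, 79), "positive")
  expect_error(t2rho_effective(669, 0), "positive")
})

test_that("steady-state saturation factor matches its closed form and limits", {
  # frozen arbitrary-precision value: control-group brain, longest lock time
  sf <- saturation_factor(669, 79, 105, 2000)
  expect_equal(sf$mz_over_m0, 0.46281380214494649, tolerance = 1e-9)
  expect_equal(sf$msat, exp(-105 / t2rho_effective(669, 79)), tolerance = 1e-12)

  # no-saturation limit: TSL -> 0+ gives Msat -> 1 and Mz/M0 -> 1
  sf0 <- saturation_factor(669, 79, 1e-9, 2000)
  expect_equal(sf0$msat, 1, tolerance = 1e-9)
  expect_equal(sf0$mz_over_m0, 1, tolerance = 1e-9)

  # full-recovery limit: tau >> T1 gives Mz/M0 -> Msat
  sfr <- saturation_factor(669, 79, 60, 669 * 60)
  expect_equal(sfr$mz_over_m0, sfr$msat, tolerance = 1e-12)

  # strictly decreasing in TSL, strictly increasing in tau
  tsl <- c(1, 15, 30, 60, 105)
  mz <- saturation_factor(669, 79, tsl, 2000)$mz_over_m0
  expect_true(all(diff(mz) < 0))
  taus <- c(500, 1000, 2000, 4000)
  mzt <- vapply(taus, function(tau)
    saturation_factor(669, 79, 60, tau)$mz_over_m0, numeric(1))
  expect_true(all(diff(mzt) > 0))
  # bounds: 0 < Msat <= 1, Msat*(1-e) <= Mz/M0 <= 1
  e1 <- exp(-2000 / 669)
  expect_true(all(mz > saturation_factor(669, 79, tsl, 2000)$msat * (1 - e1) - 1e-15))
  expect_true(all(mz <= 1))

  expect_error(saturation_factor(669, 79, -5, 2000), "positive")
  expect_error(saturation_factor(669, 79, 60, 0), "positive")
})

test_that("series correction inverts the steady-state forward model", {
  tsl <- study_tsl
  mz <- saturation_factor(670, 98, tsl, 2000)$mz_over_m0
  truth <- 100 * exp(-tsl / 119)
  curve <- decay_curve(tsl, truth * mz)
  corr <- correct_series(curve, 670, 98, 2000)
  expect_equal(corr$tsl_ms, tsl)
  expect_lt(max(abs(corr$signal - truth) / truth), 1e-12)

  # near-identity when saturation is negligible (tiny TSL, tau >> T1)
  c2 <- correct_series(decay_curve(c(1e-8, 2e-8, 3e-8), c(5, 5, 5)),
                       669, 79, 669 * 100)
  expect_equal(c2$signal, c(5, 5, 5), tolerance = 1e-8)

  expect_error(decay_curve(c(1, 15), c(1, 2, 3)), "equal length")
  expect_error(decay_curve(c(15, 1), c(1, 2)), "increasing")
})

test_that("monoexponential fit recovers exact curves and matches the log-linear closed form", {
  tsl <- study_tsl
  y <- 100 * exp(-tsl / 100)
  fit <- t1rho_fit(tsl, signal = y)
  expect_true(fit$converged)
  expect_lt(abs(coef(fit)[["s0"]] - 100) / 100, 1e-6)
  expect_lt(abs(coef(fit)[["t1rho_ms"]] - 100) / 100, 1e-6)
  expect_gt(fit$r.squared, 1 - 1e-12)

  # closed-form log-linear oracle agrees on noiseless data
  ll <- lm(log(y) ~ tsl)
  expect_lt(abs(coef(fit)[["t1rho_ms"]] - (-1 / coef(ll)[[2]])) /
              coef(fit)[["t1rho_ms"]], 1e-6)
  expect_lt(abs(coef(fit)[["s0"]] - exp(coef(ll)[[1]])) / 100, 1e-6)
})

test_that("monoexponential fit agrees with an independent nonlinear solver on noisy data", {
  skip_if_not_installed("minpack.lm")
  tsl <- study_tsl
  for (seed in 1:5) {
    set.seed(seed)
    truth_t <- runif(1, 60, 160)
    y <- pmax(100 * exp(-tsl / truth_t) + rnorm(8, sd = 2), 0.05)
    fit <- t1rho_fit(tsl, signal = y)
    ref <- minpack.lm::nlsLM(
      y ~ s0 * exp(-tsl / T), data = data.frame(tsl = tsl, y = y),
      start = list(s0 = max(y), T = 80),
      control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14))
    expect_equal(coef(fit)[["t1rho_ms"]], coef(ref)[["T"]], tolerance = 1e-6)
    expect_equal(coef(fit)[["s0"]], coef(ref)[["s0"]], tolerance = 1e-6)
  }
})

test_that("degenerate decay curves give a bounded, flagged solution", {
  tsl <- study_tsl
  fit <- t1rho_fit(tsl, signal = rep(5, 8))
  expect_equal(coef(fit)[["t1rho_ms"]], fit$bounds[2])
  expect_true(fit$at_bound)
  expect_true(is.na(fit$r.squared))

  expect_error(t1rho_fit(c(1, 15), signal = c(3, 2)), "insufficient|at least 3")
  expect_error(t1rho_fit(c(1, 1, 1), signal = c(3, 3, 2)), "distinct")
  expect_error(t1rho_fit(tsl, signal = rep(0, 8)), "all zero")
})

test_that("fit is scale-equivariant and supports the standard model interface", {
  tsl <- study_tsl
  set.seed(4)
  y <- pmax(80 * exp(-tsl / 90) + rnorm(8, sd = 1), 0.05)
  f1 <- t1rho_fit(tsl, signal = y)
  for (c in c(0.01, 3.7, 250)) {
    f2 <- t1rho_fit(tsl, signal = c * y)
    expect_equal(f2$coefficients[["t1rho_ms"]], f1$coefficients[["t1rho_ms"]],
                 tolerance = 1e-9)
    expect_equal(f2$coefficients[["s0"]], c * f1$coefficients[["s0"]],
                 tolerance = 1e-9)
  }
  # formula + data interface and methods
  d <- data.frame(sig = y, lock = tsl)
  ff <- t1rho_fit(sig ~ lock, data = d)
  expect_equal(coef(ff), coef(f1))
  expect_equal(unname(fitted(ff) + residuals(ff)), y[order(tsl)])
  expect_equal(predict(ff, list(tsl_ms = c(10, 20))),
               coef(ff)[["s0"]] * exp(-c(10, 20) / coef(ff)[["t1rho_ms"]]))
  s <- summary(ff)
  expect_s3_class(s, "summary.t1rho_fit")
  expect_output(print(s), "T1rho")
  expect_output(print(ff), "Monoexponential")
})

test_that("voxelwise map fitting recovers truth and flags the uncorrected bias", {
  gt <- recovery_phantom()
  proto <- spin_lock_protocol()
  # noiseless round trip at one FSL
  ser <- simulate_series(gt, proto, 1000, noise = "none")
  map <- fit_t1rho_map(ser, gt$roi, c(brain = 882, tumour = 988),
                       c(brain = 120, tumour = 139))
  err <- abs(map$t1rho_ms - gt$t1rho_ms[["1000"]]) / gt$t1rho_ms[["1000"]]
  expect_lt(max(err[gt$roi$label > 0]), 1e-6)

  # leaving out the correction on saturation-forward data biases T1rho low
  map0 <- fit_t1rho_map(ser, gt$roi, c(brain = 882, tumour = 988),
                        c(brain = 120, tumour = 139), correction = FALSE)
  sel <- gt$roi$label > 0 & !is.na(map0$t1rho_ms)
  expect_true(all(map0$t1rho_ms[sel] < gt$t1rho_ms[["1000"]][sel]))

  # missing class parameters is a configuration error
  expect_error(fit_t1rho_map(ser, gt$roi, c(brain = 882), c(brain = 120)),
               "configuration")
  # TSL axis mismatch
  bad <- ser
  bad$protocol <- spin_lock_protocol(tsl_ms = c(1, 15, 30))
  expect_error(fit_t1rho_map(bad, gt$roi, c(brain = 882, tumour = 988),
                             c(brain = 120, tumour = 139)), "TSL")
})
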