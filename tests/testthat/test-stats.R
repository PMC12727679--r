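test_that("Mann-Whitney U behaves at its anchor cases", {
  # identical samples: U = n1*n2/2 and no evidence of a shift
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  mw <- mann_whitney(x, x, mode = "approx")
  expect_equal(mw$u, length(x)^2 / 2)
  expect_gte(mw$p_value, 0.99)

  # tiny exact case equals full enumeration
  mw2 <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw2$method, "exact")
  expect_equal(mw2$p_value, enumerate_mw(c(1, 2), c(3, 4)))
  expect_equal(mw2$p_value, 2 / 6)

  # complete separation at the mutant-group tumour sample size
  x7 <- 1:7; y7 <- 8:14
  mw3 <- mann_whitney(x7, y7)
  expect_equal(mw3$method, "exact")
  expect_equal(mw3$p_value, 2 / choose(14, 7))
  expect_equal(mw3$p_value, enumerate_mw(x7, y7))

  # ties force the approximate mode even below the cutoff
  mw4 <- mann_whitney(c(1, 2, 2), c(2, 3, 4))
  expect_equal(mw4$method, "approx")
  expect_true(mw4$ties)
  # large samples use the approximation
  mw5 <- mann_whitney(rnorm(15), rnorm(15))
  expect_equal(mw5$method, "approx")

  expect_error(mann_whitney(numeric(0), 1:3), "insufficient")
})

test_that("Mann-Whitney exact p equals exhaustive enumeration for moderate sizes", {
  set.seed(11)
  for (n1 in c(2, 4, 7)) for (n2 in c(3, 5, 8)) {
    x <- sample(seq_len(100), n1); y <- sample(setdiff(seq_len(100), x), n2)
    expect_equal(mann_whitney(x, y)$p_value, enumerate_mw(x, y),
                 tolerance = 1e-12,
                 info = sprintf("n1=%d n2=%d", n1, n2))
  }
})

test_that("BH adjustment implements the step-up rule", {
  # step-up on {.01,.02,.04,.20}: p(3)=.04 exceeds 3*.05/4=.0375, so exactly
  # the two smallest are rejected (adjusted p = .04, .04, .0533, .20)
  r <- bh_adjust(c(0.01, 0.02, 0.04, 0.20), fdr = 0.05)
  expect_equal(r$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$adjusted, c(0.04, 0.04, 0.16 / 3, 0.20), tolerance = 1e-12)
  expect_equal(r$reject, bh_oracle(c(0.01, 0.02, 0.04, 0.20))$reject)

  # single p-value: rejected iff p <= fdr
  expect_true(bh_adjust(0.05, fdr = 0.05)$reject)
  expect_false(bh_adjust(0.051, fdr = 0.05)$reject)

  # monotonicity: lowering any p never un-rejects another hypothesis
  set.seed(13)
  for (rep in 1:20) {
    p <- runif(6)
    before <- bh_adjust(p)$reject
    i <- sample(6, 1)
    p2 <- p; p2[i] <- p[i] * runif(1)
    after <- bh_adjust(p2)$reject
    expect_true(all(after[-i][before[-i]]))
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("Bonferroni threshold is alpha/m", {
  thr <- bonferroni_threshold(0.05, 6)
  expect_equal(thr, 0.05 / 6)
  expect_equal(round(thr, 4), 0.0083)
  expect_equal(bonferroni_threshold(0.03, 1), 0.03)
  ms <- 1:10
  expect_true(all(diff(vapply(ms, function(m)
    bonferroni_threshold(0.05, m), numeric(1))) < 0))
  expect_error(bonferroni_threshold(0.05, 0), ">= 1")
  expect_error(bonferroni_threshold(1.5, 4), "alpha")
})

test_that("age-trend regression matches the closed-form OLS slope", {
  set.seed(17)
  for (rep in 1:10) {
    w <- 1:6
    v <- 130 + rnorm(1, 0, 2) * w + rnorm(6, sd = 5)
    tr <- age_trend_test(w, v)
    slope_cf <- sum((w - mean(w)) * (v - mean(v))) / sum((w - mean(w))^2)
    expect_equal(tr$slope_ms_per_week, slope_cf, tolerance = 1e-12)
    expect_equal(tr$p_value, summary(lm(v ~ w))$coefficients[2, 4],
                 tolerance = 1e-12)
  }
  # constant values: zero slope, p = 1
  trc <- age_trend_test(1:5, rep(120, 5))
  expect_equal(trc$slope_ms_per_week, 0)
  expect_equal(trc$p_value, 1)
  # exact collinear increase: positive slope, p = 0 by the documented contract
  trl <- age_trend_test(1:5, 100 + 3 * (1:5))
  expect_equal(trl$slope_ms_per_week, 3, tolerance = 1e-10)
  expect_equal(trl$p_value, 0)
  expect_error(age_trend_test(1:2, c(1, 2)), "insufficient")
})

test_that("week pooling filters without altering measurements", {
  tab <- toy_measurement_table()
  pooled <- merge_weeks(tab, 2:4)
  expect_true(all(pooled$week %in% 2:4))
  expect_equal(nrow(pooled), sum(tab$week %in% 2:4))
  # idempotence on a single-week table
  w2 <- merge_weeks(tab, 2)
  expect_identical(merge_weeks(w2, 2)$value, w2$value)
  # empty in, empty out
  expect_equal(nrow(merge_weeks(tab[0, ], 2:4)), 0L)
  # the input is untouched
  expect_equal(nrow(tab), 144L)
})

test_that("measurement-table validation enforces its invariants", {
  tab <- toy_measurement_table()
  expect_s3_class(tab, "measurement_table")
  dup <- rbind(as.data.frame(tab), as.data.frame(tab)[1, ])
  expect_error(as_measurement_table(dup), "duplicate")
  bad <- as.data.frame(tab)
  bad$roi[bad$group == 1][1] <- "tumour"
  expect_error(as_measurement_table(bad), "naive|tumour rows")
})

test_that("group comparison families have the study's shape", {
  tab <- toy_measurement_table()
  res <- run_group_comparisons(tab)
  # six T1rho families x four amplitudes
  expect_equal(nrow(res$t1rho), 24L)
  expect_equal(as.integer(table(res$t1rho$family)), rep(4L, 6L))
  # four delta tests, six dispersion pairs with the Bonferroni threshold
  expect_equal(nrow(res$delta), 4L)
  expect_equal(nrow(res$dispersion), 6L)
  expect_equal(unique(res$dispersion$p_threshold), 0.05 / 6)
  # brain-only toy table: tumour comparisons are reported absent, brain ones run
  expect_true(all(res$t1rho$note[res$t1rho$family == "tumour_vs_brain_G2"] ==
                    "no comparison possible"))
  expect_true(all(res$t1rho$note[res$t1rho$family == "brain_G1_vs_G2"] == ""))

  # permutation invariance to input row order
  perm <- tab[sample(nrow(tab)), ]
  class(perm) <- class(tab)
  res2 <- run_group_comparisons(perm)
  expect_equal(res$t1rho, res2$t1rho)
  expect_equal(res$delta, res2$delta)

  # a table with only Group 1 yields no testable comparison
  g1 <- tab[tab$group == 1L, ]
  class(g1) <- class(tab)
  res3 <- run_group_comparisons(g1)
  expect_true(all(is.na(res3$t1rho$p)))
})

test_that("control-group age-trend analysis adjusts within mouse across amplitudes", {
  tab <- toy_measurement_table()
  tr <- run_age_trend(tab, group = 1L)
  expect_equal(nrow(tr), 3L * 4L)  # 3 mice x 4 amplitudes
  expect_true(all(tr$p >= 0 & tr$p <= 1))
  # BH is applied per mouse over the four amplitudes
  for (m in unique(tr$mouse)) {
    sub <- tr[tr$mouse == m, ]
    expect_equal(sub$p_adj, bh_oracle(sub$p)$adjusted)
  }
})
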