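#' Mann-Whitney U test with explicit mode selection
#'
#' Two-sided rank-sum comparison of two independent samples. The exact null
#' distribution is used when the combined sample size is at most
#' `exact_cutoff` and there are no ties; otherwise the normal approximation
#' with midranks, tie-corrected variance and continuity correction is used.
#' The mode actually used is recorded in the result (exact mode refuses ties
#' and falls back to the approximation).
#'
#' @param x,y numeric samples, each non-empty.
#' @param mode `"auto"` (default), `"exact"` or `"approx"`.
#' @param exact_cutoff combined-sample-size cutoff for the exact mode.
#' @return An object of class `mw_test`: list with `u` (the U statistic of
#'   `x` over `y`), `p_value`, `n1`, `n2`, `method` (`"exact"` or
#'   `"approx"`), `ties`.
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "approx"),
                         exact_cutoff = 20L) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y))
    stop("insufficient data: both samples must be non-empty", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0L
  want_exact <- switch(mode,
                       auto = (n1 + n2) <= exact_cutoff,
                       exact = TRUE,
                       approx = FALSE)
  use_exact <- want_exact && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE,
                       alternative = "two.sided"))
  structure(list(u = unname(wt$statistic), p_value = wt$p.value,
                 n1 = n1, n2 = n2,
                 method = if (use_exact) "exact" else "approx",
                 ties = ties),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s): U = %g, n = %d/%d, p = %.4g%s\n",
              x$method, x$u, x$n1, x$n2, x$p_value,
              if (x$ties) " (ties present)" else ""))
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up procedure: order the m p-values ascending, find the largest k with
#' `p(k) <= k * fdr / m`, and reject hypotheses 1..k. Adjusted p-values are
#' `min over j >= i of m * p(j) / j`, capped at 1; a hypothesis is rejected
#' iff its adjusted p-value is at most `fdr`.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param fdr target false discovery rate.
#' @return A list with `adjusted` (BH-adjusted p-values) and `reject`
#'   (logical flags), in the input order.
#' @export
bh_adjust <- function(p, fdr = 0.05) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  adj <- stats::p.adjust(p, method = "BH")
  list(adjusted = adj, reject = adj <= fdr)
}

#' Bonferroni significance threshold
#'
#' `alpha / m` for a family of m comparisons; with alpha = 0.05 and the six
#' dispersion-ratio comparisons this is 0.05/6 = 0.00833... (printed 0.0083).
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m number of comparisons, >= 1.
#' @return The per-comparison significance threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  if (!is.finite(m) || m < 1) stop("'m' must be >= 1", call. = FALSE)
  alpha / m
}

#' Age-trend test: OLS slope of T1rho against study week
#'
#' Ordinary least-squares regression of an ROI T1rho value on study week with
#' a two-sided t test of zero slope, used per mouse and spin-lock amplitude
#' on the control group. An exactly collinear (zero-residual) fit with a
#' non-zero slope is reported with p = 0; constant values give slope 0 and
#' p = 1.
#'
#' @param week numeric study weeks (>= 3 points).
#' @param value T1rho values in ms, same length.
#' @return An object of class `trend_test`: list with `slope_ms_per_week`,
#'   `intercept_ms`, `p_value`, `n`.
#' @export
age_trend_test <- function(week, value) {
  if (length(week) != length(value))
    stop("'week' and 'value' must have equal length", call. = FALSE)
  ok <- !is.na(week) & !is.na(value)
  week <- week[ok]; value <- value[ok]
  if (length(week) < 3L)
    stop("insufficient data: need >= 3 (week, value) points", call. = FALSE)
  if (length(unique(week)) < 2L)
    stop("insufficient data: need >= 2 distinct weeks", call. = FALSE)
  fit <- stats::lm(value ~ week)
  slope <- unname(coef(fit)[2L])
  rss <- sum(residuals(fit)^2)
  tss <- sum((value - mean(value))^2)
  if (rss <= max(tss, 1) * 1e-14) {
    # zero-residual fit: perfectly collinear (p = 0) or constant (p = 1)
    p <- if (abs(slope) > 1e-12 * max(abs(value), 1)) 0 else 1
  } else {
    p <- summary(fit)$coefficients[2L, 4L]
    if (is.na(p)) p <- 1
  }
  structure(list(slope_ms_per_week = slope,
                 intercept_ms = unname(coef(fit)[1L]),
                 p_value = p, n = length(week)),
            class = "trend_test")
}

#' @export
print.trend_test <- function(x, ...) {
  cat(sprintf("Age trend: slope = %.3f ms/week (n = %d, p = %.4g)\n",
              x$slope_ms_per_week, x$n, x$p_value))
  invisible(x)
}

# pooled sample for one (group, roi, metric, fsl[, fsl_high]) cell
pool_values <- function(table, group, roi, metric, fsl, fsl_high = NA) {
  sel <- table$group == group & table$roi == roi & table$metric == metric &
    table$fsl_hz == fsl
  sel <- sel & if (is.na(fsl_high)) is.na(table$fsl_high_hz) else
    !is.na(table$fsl_high_hz) & table$fsl_high_hz == fsl_high
  table$value[sel]
}

#' Run the study's group-comparison families
#'
#' Reproduces the comparison layout of the study on a pooled measurement
#' table. T1rho families (each tested at every spin-lock amplitude, BH
#' adjustment within the four-amplitude family): tumour vs brain within
#' Groups 2 and 3; tumour Group 2 vs 3; brain Group 1 vs 2, 1 vs 3, 2 vs 3.
#' delta-T1rho family: Group 2 vs 3 at each amplitude with BH. Dispersion
#' ratios: Group 2 vs 3 at the six amplitude pairs, judged against the
#' Bonferroni threshold `alpha/6` (the six ratios share amplitudes, so BH's
#' independence-type condition is not appropriate there).
#'
#' Comparisons impossible for lack of data are reported as rows with `NA`
#' statistics, not errors. Results are independent of the row order of the
#' input table.
#'
#' @param table a pooled `measurement_table` (see [merge_weeks()]).
#' @param fdr false discovery rate for the BH families.
#' @param alpha family-wise rate for the Bonferroni dispersion family.
#' @return An object of class `group_comparisons`: list of data frames
#'   `t1rho`, `delta`, `dispersion`, each with per-test U, n, p, adjusted
#'   p-value (or threshold) and significance flags, plus a `note` column
#'   marking unavailable comparisons and the test mode used.
#' @export
run_group_comparisons <- function(table, fdr = 0.05, alpha = 0.05) {
  fsl <- sort(unique(table$fsl_hz[is.na(table$fsl_high_hz)]))
  families <- list(
    list(family = "tumour_vs_brain_G2", metric = "t1rho",
         a = list(group = 2L, roi = "tumour"), b = list(group = 2L, roi = "brain")),
    list(family = "tumour_vs_brain_G3", metric = "t1rho",
         a = list(group = 3L, roi = "tumour"), b = list(group = 3L, roi = "brain")),
    list(family = "tumour_G2_vs_G3", metric = "t1rho",
         a = list(group = 2L, roi = "tumour"), b = list(group = 3L, roi = "tumour")),
    list(family = "brain_G1_vs_G2", metric = "t1rho",
         a = list(group = 1L, roi = "brain"), b = list(group = 2L, roi = "brain")),
    list(family = "brain_G1_vs_G3", metric = "t1rho",
         a = list(group = 1L, roi = "brain"), b = list(group = 3L, roi = "brain")),
    list(family = "brain_G2_vs_G3", metric = "t1rho",
         a = list(group = 2L, roi = "brain"), b = list(group = 3L, roi = "brain")),
    list(family = "delta_G2_vs_G3", metric = "delta",
         a = list(group = 2L, roi = "tumour"), b = list(group = 3L, roi = "tumour"))
  )
  test_family <- function(fam) {
    rows <- lapply(fsl, function(f) {
      xa <- pool_values(table, fam$a$group, fam$a$roi, fam$metric, f)
      xb <- pool_values(table, fam$b$group, fam$b$roi, fam$metric, f)
      if (!length(xa) || !length(xb))
        return(data.frame(family = fam$family, fsl_hz = f, n1 = length(xa),
                          n2 = length(xb), u = NA_real_, p = NA_real_,
                          method = NA_character_,
                          note = "no comparison possible"))
      mw <- mann_whitney(xa, xb)
      data.frame(family = fam$family, fsl_hz = f, n1 = mw$n1, n2 = mw$n2,
                 u = mw$u, p = mw$p_value, method = mw$method, note = "")
    })
    out <- do.call(rbind, rows)
    ok <- !is.na(out$p)
    out$p_adj <- NA_real_; out$significant <- NA
    if (any(ok)) {
      bh <- bh_adjust(out$p[ok], fdr = fdr)
      out$p_adj[ok] <- bh$adjusted
      out$significant[ok] <- bh$reject
    }
    out
  }
  res <- lapply(families, test_family)
  t1rho_tab <- do.call(rbind, res[1:6])
  delta_tab <- res[[7L]]

  pairs <- expand.grid(fsl_low_hz = fsl, fsl_high_hz = fsl)
  pairs <- pairs[pairs$fsl_high_hz > pairs$fsl_low_hz, ]
  pairs <- pairs[order(pairs$fsl_low_hz, pairs$fsl_high_hz), ]
  thr <- bonferroni_threshold(alpha, max(nrow(pairs), 1L))
  disp_rows <- lapply(seq_len(nrow(pairs)), function(j) {
    f1 <- pairs$fsl_low_hz[j]; f2 <- pairs$fsl_high_hz[j]
    xa <- pool_values(table, 2L, "tumour", "dispersion_ratio", f1, f2)
    xb <- pool_values(table, 3L, "tumour", "dispersion_ratio", f1, f2)
    if (!length(xa) || !length(xb))
      return(data.frame(family = "dispersion_G2_vs_G3", fsl_low_hz = f1,
                        fsl_high_hz = f2, n1 = length(xa), n2 = length(xb),
                        u = NA_real_, p = NA_real_, method = NA_character_,
                        p_threshold = thr, significant = NA,
                        note = "no comparison possible"))
    mw <- mann_whitney(xa, xb)
    data.frame(family = "dispersion_G2_vs_G3", fsl_low_hz = f1,
               fsl_high_hz = f2, n1 = mw$n1, n2 = mw$n2, u = mw$u,
               p = mw$p_value, method = mw$method, p_threshold = thr,
               significant = mw$p_value < thr, note = "")
  })
  disp_tab <- if (length(disp_rows)) do.call(rbind, disp_rows) else
    data.frame()
  structure(list(t1rho = t1rho_tab, delta = delta_tab, dispersion = disp_tab,
                 fdr = fdr, alpha = alpha),
            class = "group_comparisons")
}

#' @export
print.group_comparisons <- function(x, ...) {
  cat("Group comparisons (Mann-Whitney U)\n\nT1rho families (BH per family, FDR =",
      x$fdr, "):\n")
  print(x$t1rho, row.names = FALSE)
  cat("\ndelta-T1rho family (BH, FDR =", x$fdr, "):\n")
  print(x$delta, row.names = FALSE)
  cat("\nDispersion ratios (Bonferroni threshold",
      format(x$dispersion$p_threshold[1L], digits = 2), "):\n")
  print(x$dispersion, row.names = FALSE)
  invisible(x)
}

#' Age-trend analysis of control-group brain T1rho
#'
#' For every control-group mouse and spin-lock amplitude, regresses the brain
#' T1rho on study week ([age_trend_test()]) and applies the BH adjustment
#' across the four amplitudes within each mouse.
#'
#' @param table a `measurement_table` covering all imaged weeks.
#' @param group group to analyse (default 1, the naive controls).
#' @param fdr false discovery rate for the per-mouse BH family.
#' @return Data frame with columns `mouse`, `fsl_hz`, `n`,
#'   `slope_ms_per_week`, `p`, `p_adj`, `significant`.
#' @export
run_age_trend <- function(table, group = 1L, fdr = 0.05) {
  t <- table[table$group == group & table$roi == "brain" &
               table$metric == "t1rho", ]
  if (!nrow(t)) return(data.frame())
  rows <- list()
  for (m in sort(unique(t$mouse))) {
    sub_rows <- lapply(sort(unique(t$fsl_hz)), function(f) {
      tm <- t[t$mouse == m & t$fsl_hz == f, ]
      if (nrow(tm) < 3L)  # too few imaged weeks for a trend
        return(data.frame(mouse = m, fsl_hz = f, n = nrow(tm),
                          slope_ms_per_week = NA_real_, p = NA_real_))
      tr <- age_trend_test(tm$week, tm$value)
      data.frame(mouse = m, fsl_hz = f, n = tr$n,
                 slope_ms_per_week = tr$slope_ms_per_week, p = tr$p_value)
    })
    sub <- do.call(rbind, sub_rows)
    sub$p_adj <- NA_real_; sub$significant <- NA
    ok <- !is.na(sub$p)
    if (any(ok)) {
      bh <- bh_adjust(sub$p[ok], fdr = fdr)
      sub$p_adj[ok] <- bh$adjusted
      sub$significant[ok] <- bh$reject
    }
    rows[[length(rows) + 1L]] <- sub
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
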