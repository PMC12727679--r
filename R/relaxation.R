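#' Effective relaxation time under spin-lock saturation
#'
#' The effective transverse-like relaxation time governing residual saturation
#' of longitudinal magnetisation in a multislice spin-lock acquisition:
#' `1/T2rho_eff = (1/T1 + 1/T2) / 2`, i.e. the harmonic-mean combination
#' `2 * t1 * t2 / (t1 + t2)`. Symmetric in its arguments.
#'
#' @param t1_ms,t2_ms relaxation times in ms (vectorised, recycled).
#' @return Effective relaxation time in ms.
#' @examples
#' t2rho_effective(669, 79) # ~141.3 ms
#' @export
t2rho_effective <- function(t1_ms, t2_ms) {
  if (any(!is.finite(t1_ms)) || any(t1_ms <= 0))
    stop("'t1_ms' must be positive and finite", call. = FALSE)
  if (any(!is.finite(t2_ms)) || any(t2_ms <= 0))
    stop("'t2_ms' must be positive and finite", call. = FALSE)
  2 * t1_ms * t2_ms / (t1_ms + t2_ms)
}

#' Steady-state multislice saturation correction factor
#'
#' In a multislice spin-lock acquisition with a per-slice recovery delay tau on
#' the order of T1, longitudinal magnetisation does not fully recover between
#' excitations. Assuming a steady state, the residual saturation after the
#' locking pulse is `Msat = exp(-TSL / T2rho_eff)` and the available
#' longitudinal magnetisation is
#' `Mz/M0 = Msat * (1 - exp(-tau/T1)) / (1 - Msat * exp(-tau/T1))`.
#' Measured signals are divided by `Mz/M0` before T1rho mapping.
#'
#' @param t1_ms,t2_ms tissue T1 and T2 in ms.
#' @param tsl_ms spin-lock duration(s) in ms (vectorised).
#' @param tau_ms per-slice recovery delay in ms.
#' @return An object of class `correction_factor`: list with `t2rho_eff_ms`,
#'   `msat` and `mz_over_m0` (the latter two vectorised along `tsl_ms`).
#' @examples
#' saturation_factor(669, 79, tsl_ms = 105, tau_ms = 2000)$mz_over_m0 # ~0.463
#' @export
saturation_factor <- function(t1_ms, t2_ms, tsl_ms, tau_ms) {
  if (any(!is.finite(tsl_ms)) || any(tsl_ms <= 0))
    stop("'tsl_ms' must be positive and finite", call. = FALSE)
  if (!is.finite(tau_ms) || tau_ms <= 0)
    stop("'tau_ms' must be positive and finite", call. = FALSE)
  t2r <- t2rho_effective(t1_ms, t2_ms)  # validates t1, t2
  msat <- exp(-tsl_ms / t2r)
  e1 <- exp(-tau_ms / t1_ms)
  mz <- msat * (1 - e1) / (1 - msat * e1)
  structure(list(t2rho_eff_ms = t2r, msat = msat, mz_over_m0 = mz),
            class = "correction_factor")
}

#' @export
print.correction_factor <- function(x, ...) {
  cat(sprintf("Multislice saturation correction (T2rho_eff = %.2f ms)\n",
              x$t2rho_eff_ms))
  print(data.frame(msat = x$msat, mz_over_m0 = x$mz_over_m0))
  invisible(x)
}

#' Spin-lock decay curve
#'
#' A sampled signal-vs-TSL decay curve for one voxel or ROI.
#'
#' @param tsl_ms spin-lock durations in ms, strictly increasing.
#' @param signal observed magnitudes (arbitrary units), same length, all >= 0.
#' @return An object of class `decay_curve`.
#' @export
decay_curve <- function(tsl_ms, signal) {
  if (length(tsl_ms) != length(signal))
    stop("'tsl_ms' and 'signal' must have equal length", call. = FALSE)
  if (any(!is.finite(tsl_ms)) || any(tsl_ms <= 0))
    stop("'tsl_ms' must be positive and finite", call. = FALSE)
  if (is.unsorted(tsl_ms, strictly = TRUE))
    stop("'tsl_ms' must be strictly increasing", call. = FALSE)
  if (any(!is.finite(signal)) || any(signal < 0))
    stop("'signal' must be non-negative and finite", call. = FALSE)
  structure(list(tsl_ms = as.numeric(tsl_ms), signal = as.numeric(signal)),
            class = "decay_curve")
}

#' Apply the multislice saturation correction to a decay curve
#'
#' Divides the signal at each TSL by the steady-state correction factor
#' `Mz/M0` computed from the tissue T1/T2 and the per-slice recovery delay.
#' Data simulated with the same steady-state forward factor become a pure
#' monoexponential `S0 * exp(-TSL/T1rho)` after correction.
#'
#' @param curve a [decay_curve()].
#' @param t1_ms,t2_ms tissue T1 and T2 in ms.
#' @param tau_ms per-slice recovery delay in ms.
#' @return A corrected `decay_curve` (TSL axis unchanged).
#' @export
correct_series <- function(curve, t1_ms, t2_ms, tau_ms) {
  if (!inherits(curve, "decay_curve"))
    curve <- decay_curve(curve$tsl_ms, curve$signal)
  cf <- saturation_factor(t1_ms, t2_ms, curve$tsl_ms, tau_ms)
  if (any(!is.finite(cf$mz_over_m0)) || any(cf$mz_over_m0 <= 0))
    stop("degenerate correction factor (Mz/M0 <= 0)", call. = FALSE)
  decay_curve(curve$tsl_ms, curve$signal / cf$mz_over_m0)
}

# Vectorised bounded nonlinear least-squares fit of S(TSL) = S0*exp(-TSL/T1rho)
# for many voxels at once (Y is V x K, voxels x TSL). S0 is linear in the
# model and profiled out in closed form (variable projection); T1rho is
# updated by a damped Gauss-Newton step with bound projection. The
# closed-form log-linear fit initialises T1rho.
fit_monoexp_matrix <- function(Y, tsl_ms,
                               t1rho_bounds = c(1, 2000),
                               s0_max_mult = 10,
                               tol = 1e-8, max_iter = 200L) {
  Y <- matrix(as.numeric(Y), nrow = NROW(Y))
  V <- nrow(Y); K <- ncol(Y)
  stopifnot(K == length(tsl_ms))
  tsl <- as.numeric(tsl_ms)
  ymax <- apply(Y, 1L, max)
  s0_hi <- pmax(s0_max_mult * ymax, .Machine$double.eps)
  s0_lo <- .Machine$double.xmin

  # log-linear initialisation: OLS of log(y) on tsl
  eps <- pmax(ymax * 1e-12, .Machine$double.xmin)
  L <- log(pmax(Y, eps))
  tbar <- mean(tsl)
  sxx <- sum((tsl - tbar)^2)
  slope <- as.vector(L %*% (tsl - tbar)) / sxx
  T0 <- ifelse(is.finite(slope) & slope < 0, -1 / slope, t1rho_bounds[2])
  Tc <- pmin(pmax(T0, t1rho_bounds[1]), t1rho_bounds[2])

  # profiled S0 and objective at a given T1rho vector (over rows 'rows')
  profile <- function(T1, rows) {
    Ysub <- Y[rows, , drop = FALSE]
    E <- exp(-outer(1 / T1, tsl))
    u <- rowSums(Ysub * E); v <- rowSums(E * E)
    S0 <- pmin(pmax(u / v, s0_lo), s0_hi[rows])
    R <- Ysub - S0 * E
    list(E = E, S0 = S0, R = R, sse = rowSums(R * R))
  }
  cur <- profile(Tc, seq_len(V))
  lambda <- rep(1e-3, V)
  converged <- rep(FALSE, V)
  iters <- rep(0L, V)
  active <- rep(TRUE, V)

  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    a <- which(active)
    E <- cur$E[a, , drop = FALSE]
    R <- cur$R[a, , drop = FALSE]
    Ta <- Tc[a]
    # dS/dT1rho = S0 * (tsl/T^2) * exp(-tsl/T)
    J <- (cur$S0[a] / Ta^2) * E * rep(tsl, each = length(a))
    num <- rowSums(J * R); den <- rowSums(J * J)
    delta <- num / (pmax(den, .Machine$double.xmin) * (1 + lambda[a]))
    Tn <- pmin(pmax(Ta + delta, t1rho_bounds[1]), t1rho_bounds[2])
    prn <- profile(Tn, a)
    ok <- prn$sse <= cur$sse[a] + 1e-300
    step <- abs(Tn - Ta) / (abs(Ta) + 1e-12)
    if (any(ok)) {
      ia <- a[ok]
      Tc[ia] <- Tn[ok]
      cur$E[ia, ] <- prn$E[ok, , drop = FALSE]
      cur$R[ia, ] <- prn$R[ok, , drop = FALSE]
      cur$S0[ia] <- prn$S0[ok]
      cur$sse[ia] <- prn$sse[ok]
      lambda[ia] <- pmax(lambda[ia] / 3, 1e-12)
      done <- ok & step < tol
      converged[a[done]] <- TRUE
      active[a[done]] <- FALSE
    }
    if (any(!ok)) {
      ir <- a[!ok]
      lambda[ir] <- lambda[ir] * 7
      stuck <- lambda[ir] > 1e10
      # damping maxed out: no improving step exists to machine precision,
      # the current (possibly boundary) point is the solution
      converged[ir[stuck]] <- TRUE
      active[ir[stuck]] <- FALSE
    }
    iters[a] <- it
  }

  cur <- profile(Tc, seq_len(V))
  sst <- rowSums((Y - rowMeans(Y))^2)
  r2 <- ifelse(sst > 0, 1 - cur$sse / sst, NA_real_)
  at_bound <- Tc <= t1rho_bounds[1] | Tc >= t1rho_bounds[2]
  list(s0_hat = cur$S0, t1rho_hat = Tc, r_squared = r2, sse = cur$sse,
       converged = converged, at_bound = at_bound, iterations = iters)
}

#' Fit a monoexponential T1rho decay model
#'
#' Fits `signal = S0 * exp(-TSL / T1rho)` to a spin-lock decay curve by
#' bounded nonlinear least squares (Levenberg-Marquardt with parameter
#' projection), initialised by the closed-form log-linear fit. `S0` and
#' `T1rho` are free parameters.
#'
#' @param formula a formula of the form `signal ~ tsl` (any variable names),
#'   or a [decay_curve()] / numeric vector of TSL values.
#' @param data a data frame in which to evaluate `formula`; ignored otherwise.
#' @param signal numeric vector of magnitudes, used when `formula` is a
#'   numeric TSL vector.
#' @param t1rho_bounds lower/upper bounds for T1rho in ms.
#' @param s0_max_mult upper bound for S0 as a multiple of the largest signal.
#' @param tol relative-step convergence tolerance.
#' @param max_iter maximum number of iterations.
#'
#' @return An object of class `t1rho_fit` with components `coefficients`
#'   (`s0`, `t1rho_ms`), `r.squared`, `converged`, `at_bound`, `fitted.values`,
#'   `residuals`, `curve`, `iterations`. Non-convergence is reported through
#'   `converged`/diagnostics, not as an error.
#' @examples
#' tsl <- c(1, 15, 30, 45, 60, 75, 90, 105)
#' fit <- t1rho_fit(tsl, signal = 100 * exp(-tsl / 100))
#' coef(fit)
#' @export
t1rho_fit <- function(formula, data = NULL, signal = NULL,
                      t1rho_bounds = c(1, 2000), s0_max_mult = 10,
                      tol = 1e-8, max_iter = 200L) {
  cl <- match.call()
  if (inherits(formula, "formula")) {
    mf <- model.frame(formula, data = data)
    y <- model.response(mf)
    tsl <- mf[[2L]]
  } else if (inherits(formula, "decay_curve")) {
    tsl <- formula$tsl_ms; y <- formula$signal
  } else {
    tsl <- as.numeric(formula); y <- as.numeric(signal)
  }
  if (length(tsl) != length(y))
    stop("TSL and signal must have equal length", call. = FALSE)
  if (length(y) < 3L)
    stop("insufficient data: need at least 3 samples", call. = FALSE)
  if (length(unique(tsl)) < 2L)
    stop("insufficient data: need at least 2 distinct TSL values", call. = FALSE)
  if (all(y == 0))
    stop("signals are all zero", call. = FALSE)
  ord <- order(tsl)
  tsl <- tsl[ord]; y <- y[ord]
  res <- fit_monoexp_matrix(matrix(y, nrow = 1L), tsl,
                            t1rho_bounds = t1rho_bounds,
                            s0_max_mult = s0_max_mult,
                            tol = tol, max_iter = max_iter)
  fitted <- res$s0_hat * exp(-tsl / res$t1rho_hat)
  structure(list(
    coefficients = c(s0 = res$s0_hat, t1rho_ms = res$t1rho_hat),
    r.squared = res$r_squared,
    converged = res$converged,
    at_bound = res$at_bound,
    iterations = res$iterations,
    fitted.values = fitted,
    residuals = y - fitted,
    curve = list(tsl_ms = tsl, signal = y),
    bounds = t1rho_bounds,
    call = cl), class = "t1rho_fit")
}

#' @export
print.t1rho_fit <- function(x, digits = 4, ...) {
  cat("Monoexponential T1rho fit\n")
  cat(sprintf("  S0 = %.*g, T1rho = %.*g ms (R^2 = %.*g)\n",
              digits, x$coefficients[["s0"]],
              digits, x$coefficients[["t1rho_ms"]],
              digits, x$r.squared))
  if (!x$converged) cat("  warning: fit did not converge\n")
  if (x$at_bound) cat("  note: T1rho estimate at a bound\n")
  invisible(x)
}

#' @export
summary.t1rho_fit <- function(object, ...) {
  n <- length(object$curve$signal)
  rse <- sqrt(sum(object$residuals^2) / max(n - 2L, 1L))
  out <- list(coefficients = object$coefficients,
              r.squared = object$r.squared,
              sigma = rse, n = n,
              converged = object$converged, at_bound = object$at_bound,
              iterations = object$iterations, call = object$call)
  class(out) <- "summary.t1rho_fit"
  out
}

#' @export
print.summary.t1rho_fit <- function(x, digits = 4, ...) {
  cat("Monoexponential T1rho fit\n\nCall:\n")
  print(x$call)
  cat(sprintf("\nCoefficients:\n  S0    = %.*g\n  T1rho = %.*g ms\n",
              digits, x$coefficients[["s0"]], digits, x$coefficients[["t1rho_ms"]]))
  cat(sprintf("\nResidual standard error: %.*g on %d samples\n",
              digits, x$sigma, x$n))
  cat(sprintf("R-squared: %.*g; converged: %s (%d iterations)\n",
              digits, x$r.squared, x$converged, x$iterations))
  invisible(x)
}

#' @export
coef.t1rho_fit <- function(object, ...) object$coefficients

#' @export
fitted.t1rho_fit <- function(object, ...) object$fitted.values

#' @export
residuals.t1rho_fit <- function(object, ...) object$residuals

#' @rdname t1rho_fit
#' @param object,newdata a fitted `t1rho_fit` and an optional data frame (or
#'   list) with a `tsl_ms` column of TSL values at which to predict.
#' @param ... unused.
#' @export
predict.t1rho_fit <- function(object, newdata = NULL, ...) {
  tsl <- if (is.null(newdata)) object$curve$tsl_ms else
    if (is.list(newdata)) newdata$tsl_ms else as.numeric(newdata)
  object$coefficients[["s0"]] * exp(-tsl / object$coefficients[["t1rho_ms"]])
}

#' @export
plot.t1rho_fit <- function(x, ...) {
  graphics::plot(x$curve$tsl_ms, x$curve$signal, xlab = "TSL (ms)",
                 ylab = "signal", main = "Monoexponential T1rho fit", ...)
  tt <- seq(min(x$curve$tsl_ms), max(x$curve$tsl_ms), length.out = 200L)
  graphics::lines(tt, predict(x, list(tsl_ms = tt)))
  invisible(x)
}
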