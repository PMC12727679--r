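#' ROI label mask
#'
#' A label volume on an imaging grid: 0 = outside, 1 = brain ROI, 2 = tumour
#' ROI. Brain and tumour labels are disjoint by construction.
#'
#' @param label integer array (rows x cols x slices) of labels in 0:2.
#' @param grid the [grid_spec()] the labels live on.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(label, grid) {
  if (!inherits(grid, "grid_spec")) stop("'grid' must be a grid_spec", call. = FALSE)
  label <- array(as.integer(label), dim = dim(label))
  if (!all(label %in% 0:2)) stop("labels must be 0, 1 or 2", call. = FALSE)
  d <- dim(label)
  if (length(d) != 3L || any(d != c(grid$nrow, grid$ncol, grid$n_slices)))
    stop("label dimensions do not match the grid", call. = FALSE)
  structure(list(label = label, grid = grid), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("ROI mask on %dx%dx%d grid: %d brain, %d tumour voxels\n",
              x$grid$nrow, x$grid$ncol, x$grid$n_slices,
              sum(x$label == 1L), sum(x$label == 2L)))
  invisible(x)
}

# 1-D overlap-length matrix between source cells (n_src cells of width h_src)
# and target cells (n_tgt of width h_tgt) sharing the same extent
overlap_matrix <- function(n_tgt, h_tgt, n_src, h_src) {
  W <- matrix(0, n_tgt, n_src)
  for (i in seq_len(n_tgt)) {
    lo_t <- (i - 1) * h_tgt; hi_t <- i * h_tgt
    j0 <- max(1L, floor(lo_t / h_src) + 1L)
    j1 <- min(n_src, ceiling(hi_t / h_src))
    for (j in j0:j1) {
      ov <- min(hi_t, j * h_src) - max(lo_t, (j - 1) * h_src)
      if (ov > 0) W[i, j] <- ov
    }
  }
  W
}

#' Resample an ROI mask between grids sharing a field of view
#'
#' Transfers labels between the anatomical and T1rho grids by exact
#' area-overlap: a target voxel takes a label if at least 50% (inclusive) of
#' its in-plane area is covered by source voxels carrying that label. When two
#' labels both reach 50% (an exact tie), the tumour label wins. Deterministic;
#' slices map one-to-one.
#'
#' @param mask a [roi_mask()].
#' @param target_grid the [grid_spec()] to resample onto; must share the FOV
#'   (within 1e-6 mm) and slice count with the source grid.
#' @return A `roi_mask` on `target_grid`.
#' @export
resample_mask <- function(mask, target_grid) {
  src <- mask$grid
  if (abs(src$fov_mm - target_grid$fov_mm) > 1e-6)
    stop("grid error: source and target FOV differ", call. = FALSE)
  if (src$n_slices != target_grid$n_slices)
    stop("grid error: slice counts differ", call. = FALSE)
  if (src$nrow == target_grid$nrow && src$ncol == target_grid$ncol)
    return(roi_mask(mask$label, target_grid))
  Wr <- overlap_matrix(target_grid$nrow, target_grid$spacing_mm[1],
                       src$nrow, src$spacing_mm[1])
  Wc <- overlap_matrix(target_grid$ncol, target_grid$spacing_mm[2],
                       src$ncol, src$spacing_mm[2])
  cell_area <- target_grid$spacing_mm[1] * target_grid$spacing_mm[2]
  out <- array(0L, c(target_grid$nrow, target_grid$ncol, target_grid$n_slices))
  for (s in seq_len(src$n_slices)) {
    sl <- mask$label[, , s]
    for (lab in c(1L, 2L)) {  # tumour (2) assigned last, wins exact ties
      if (!any(sl == lab)) next
      cov <- (Wr %*% (sl == lab) %*% t(Wc)) / cell_area
      out[, , s][cov >= 0.5 - 1e-12] <- lab
    }
  }
  roi_mask(out, target_grid)
}

#' Fit a voxelwise T1rho map from a spin-lock series
#'
#' Applies the multislice saturation correction (one scalar factor per tissue
#' class per TSL, from group-average T1/T2) and then fits the bounded
#' monoexponential model to every in-mask voxel. Voxels failing quality
#' control (non-convergence or R^2 below `r2_threshold`) are set to missing in
#' the T1rho map; diagnostics are retained.
#'
#' @param series a [simulate_series()] / [read_series()] object.
#' @param mask a [roi_mask()] on the series grid; classes 1 (brain) and 2
#'   (tumour) are fitted.
#' @param t1_by_class,t2_by_class named numeric vectors (`brain`, `tumour`)
#'   of group-average T1/T2 in ms; every class present in the mask must have
#'   entries.
#' @param tau_ms per-slice recovery delay (defaults to the series protocol).
#' @param correction apply the saturation correction (`FALSE` reproduces the
#'   uncorrected analysis path).
#' @param r2_threshold QC threshold on the coefficient of determination.
#' @param t1rho_bounds,tol fit bounds (ms) and convergence tolerance.
#' @return An object of class `t1rho_map`: list of arrays `t1rho_ms` (NA where
#'   unfitted or QC-failed), `s0`, `r_squared`, `converged`, `qc_pass`, plus
#'   `fsl_hz`, `grid`, `n_fitted`, `n_excluded`.
#' @export
fit_t1rho_map <- function(series, mask, t1_by_class, t2_by_class,
                          tau_ms = NULL, correction = TRUE,
                          r2_threshold = 0.5,
                          t1rho_bounds = c(1, 2000), tol = 1e-8) {
  if (is.null(tau_ms)) tau_ms <- series$protocol$tau_ms
  d <- dim(series$data)
  if (any(d[1:3] != dim(mask$label)))
    stop("series and mask are on different grids", call. = FALSE)
  tsl <- series$protocol$tsl_ms
  if (d[4] != length(tsl))
    stop("series TSL axis does not match the protocol", call. = FALSE)
  dims <- d[1:3]
  nvox <- prod(dims)
  classes <- c(brain = 1L, tumour = 2L)
  t1rho <- array(NA_real_, dims); s0 <- array(NA_real_, dims)
  r2 <- array(NA_real_, dims); conv <- array(NA, dims); qc <- array(NA, dims)
  n_fitted <- 0L; n_excluded <- 0L
  for (cls in names(classes)) {
    idx <- which(mask$label == classes[[cls]])
    if (!length(idx)) next
    if (correction && (!cls %in% names(t1_by_class) || !cls %in% names(t2_by_class)))
      stop(sprintf("configuration error: no T1/T2 for masked class '%s'", cls),
           call. = FALSE)
    Y <- matrix(0, length(idx), d[4])
    for (k in seq_len(d[4])) Y[, k] <- series$data[idx + (k - 1L) * nvox]
    if (correction) {
      mz <- saturation_factor(t1_by_class[[cls]], t2_by_class[[cls]],
                              tsl, tau_ms)$mz_over_m0
      if (any(!is.finite(mz)) || any(mz <= 0))
        stop("degenerate correction factor", call. = FALSE)
      Y <- sweep(Y, 2L, mz, "/")
    }
    fit <- fit_monoexp_matrix(Y, tsl, t1rho_bounds = t1rho_bounds, tol = tol)
    pass <- fit$converged & !is.na(fit$r_squared) & fit$r_squared >= r2_threshold
    t1rho[idx] <- ifelse(pass, fit$t1rho_hat, NA_real_)
    s0[idx] <- fit$s0_hat
    r2[idx] <- fit$r_squared
    conv[idx] <- fit$converged
    qc[idx] <- pass
    n_fitted <- n_fitted + sum(pass)
    n_excluded <- n_excluded + sum(!pass)
  }
  structure(list(t1rho_ms = t1rho, s0 = s0, r_squared = r2,
                 converged = conv, qc_pass = qc,
                 fsl_hz = series$fsl_hz, grid = series$grid,
                 n_fitted = n_fitted, n_excluded = n_excluded),
            class = "t1rho_map")
}

#' @export
print.t1rho_map <- function(x, ...) {
  cat(sprintf("T1rho map at FSL %g Hz: %d voxels fitted, %d excluded by QC\n",
              x$fsl_hz, x$n_fitted, x$n_excluded))
  invisible(x)
}

#' ROI summary of a T1rho map
#'
#' Mean and standard deviation of the fitted T1rho over in-mask voxels that
#' passed quality control; QC-excluded voxels are counted.
#'
#' @param map a [fit_t1rho_map()] result.
#' @param mask a [roi_mask()] on the same grid.
#' @param label which ROI, `"brain"` (1) or `"tumour"` (2), or an integer.
#' @return An object of class `roi_summary`: list with `label`,
#'   `mean_t1rho_ms`, `sd_ms`, `n_voxels`, `n_excluded`.
#' @export
roi_mean <- function(map, mask, label = c("brain", "tumour")) {
  if (is.character(label)) {
    label <- match.arg(label)
    code <- c(brain = 1L, tumour = 2L)[[label]]
  } else {
    code <- as.integer(label)
    label <- c("brain", "tumour")[code]
  }
  if (any(dim(map$t1rho_ms) != dim(mask$label)))
    stop("map and mask are on different grids", call. = FALSE)
  sel <- mask$label == code
  vals <- map$t1rho_ms[sel]
  usable <- vals[!is.na(vals)]
  if (!length(usable))
    stop(sprintf("empty ROI: no usable voxels for label '%s'", label), call. = FALSE)
  structure(list(label = label,
                 mean_t1rho_ms = mean(usable),
                 sd_ms = if (length(usable) > 1L) sd(usable) else 0,
                 n_voxels = length(usable),
                 n_excluded = sum(is.na(vals))),
            class = "roi_summary")
}

#' @export
print.roi_summary <- function(x, ...) {
  cat(sprintf("%s ROI: T1rho = %.2f +/- %.2f ms (n = %d voxels, %d excluded)\n",
              x$label, x$mean_t1rho_ms, x$sd_ms, x$n_voxels, x$n_excluded))
  invisible(x)
}

#' Tumour-to-brain normalised T1rho difference (percent)
#'
#' The per-measurement biomarker: the percent difference between the mean
#' tumour and mean contralateral-brain T1rho,
#' `100 * (tumour - brain) / brain`. Scale-invariant; its sign is the sign of
#' the tumour-brain difference.
#'
#' @param tumour_mean_ms,brain_mean_ms ROI mean T1rho values in ms
#'   (vectorised); `brain_mean_ms` must be positive.
#' @return Percent difference(s).
#' @examples
#' delta_t1rho(126, 98) # ~ +28.6
#' @export
delta_t1rho <- function(tumour_mean_ms, brain_mean_ms) {
  if (any(!is.finite(brain_mean_ms)) || any(brain_mean_ms <= 0))
    stop("'brain_mean_ms' must be positive", call. = FALSE)
  100 * (tumour_mean_ms - brain_mean_ms) / brain_mean_ms
}

#' Spin-lock dispersion ratios
#'
#' Quantifies T1rho dispersion as the relative ratio between T1rho values
#' measured at two spin-lock amplitudes:
#' `(T1rho(FSL_high) - T1rho(FSL_low)) / T1rho(FSL_low)` for every ordered
#' pair with `FSL_high > FSL_low`. Four amplitudes yield six ratios.
#'
#' @param t1rho_by_fsl named numeric vector of T1rho (ms), names the
#'   spin-lock amplitudes in Hz; at least two entries, all positive.
#' @return A data frame with columns `fsl_low_hz`, `fsl_high_hz`, `ratio`,
#'   ordered by (low, high).
#' @export
dispersion_ratios <- function(t1rho_by_fsl) {
  if (length(t1rho_by_fsl) < 2L)
    stop("insufficient data: need T1rho at >= 2 spin-lock amplitudes", call. = FALSE)
  if (is.null(names(t1rho_by_fsl)))
    stop("'t1rho_by_fsl' must be named by FSL (Hz)", call. = FALSE)
  if (any(!is.finite(t1rho_by_fsl)) || any(t1rho_by_fsl <= 0))
    stop("all T1rho values must be positive", call. = FALSE)
  fsl <- as.numeric(names(t1rho_by_fsl))
  ord <- order(fsl)
  fsl <- fsl[ord]; v <- as.numeric(t1rho_by_fsl)[ord]
  k <- length(fsl)
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  data.frame(fsl_low_hz = fsl[pairs[, 1L]],
             fsl_high_hz = fsl[pairs[, 2L]],
             ratio = (v[pairs[, 2L]] - v[pairs[, 1L]]) / v[pairs[, 1L]])
}
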