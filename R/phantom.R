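#' Imaging grid specification
#'
#' In-plane matrix size and field of view plus the slice stack. Both the
#' anatomical (60x60) and the T1rho (34x34) grids of the study share the same
#' 15.94 x 15.94 mm FOV and slice stack (10 slices, 1 mm thick, 0.2 mm gap),
#' pixel-centre aligned with the FOV origin at the volume corner.
#'
#' @param nrow,ncol in-plane matrix size.
#' @param n_slices number of slices.
#' @param fov_mm in-plane field of view (square), mm.
#' @param slice_thickness_mm,slice_gap_mm slice geometry, mm.
#' @return An object of class `grid_spec` with derived `spacing_mm`
#'   (in-plane pixel size) and `slice_pitch_mm`.
#' @export
grid_spec <- function(nrow, ncol, n_slices = 10L, fov_mm = 15.94,
                      slice_thickness_mm = 1, slice_gap_mm = 0.2) {
  nrow <- as.integer(nrow); ncol <- as.integer(ncol)
  n_slices <- as.integer(n_slices)
  if (nrow < 1L || ncol < 1L || n_slices < 1L)
    stop("grid dimensions must be positive", call. = FALSE)
  if (!is.finite(fov_mm) || fov_mm <= 0)
    stop("'fov_mm' must be positive", call. = FALSE)
  structure(list(nrow = nrow, ncol = ncol, n_slices = n_slices,
                 fov_mm = fov_mm,
                 spacing_mm = c(fov_mm / nrow, fov_mm / ncol),
                 slice_thickness_mm = slice_thickness_mm,
                 slice_gap_mm = slice_gap_mm,
                 slice_pitch_mm = slice_thickness_mm + slice_gap_mm),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("Grid %dx%dx%d, FOV %g mm (%.4f x %.4f mm pixels), slice pitch %g mm\n",
              x$nrow, x$ncol, x$n_slices, x$fov_mm,
              x$spacing_mm[1], x$spacing_mm[2], x$slice_pitch_mm))
  invisible(x)
}

# voxel-centre coordinates (mm), volume centred on the FOV centre;
# rows index y, columns index x, slice index 1 = most inferior
grid_coords <- function(grid) {
  list(y = (seq_len(grid$nrow) - (grid$nrow + 1) / 2) * grid$spacing_mm[1],
       x = (seq_len(grid$ncol) - (grid$ncol + 1) / 2) * grid$spacing_mm[2],
       z = (seq_len(grid$n_slices) - (grid$n_slices + 1) / 2) * grid$slice_pitch_mm)
}

#' Default study grids
#'
#' @return A list with the `anatomical` (60x60) and `t1rho` (34x34) grids of
#'   the study, both on the shared 15.94 mm FOV and 10-slice stack.
#' @export
study_grids <- function() {
  list(anatomical = grid_spec(60, 60), t1rho = grid_spec(34, 34))
}

#' Digital mouse-brain phantom specification
#'
#' Geometry and tissue parameters of the synthetic phantom: a whole-brain
#' ellipsoid, a contralateral brain ROI ellipse on the left of midline sized to
#' the study's ~18 mm^2 brain ROIs, and an optional spherical tumour right of
#' midline (the implantation side). Tissue classes carry
#' [tissue_relaxation()] parameters.
#'
#' @param grid a [grid_spec()] (defaults to the 34x34 T1rho grid).
#' @param brain_semiaxes_mm ellipsoid semi-axes (x, y, z) in mm.
#' @param brain_centre_mm ellipsoid centre (x, y, z) in mm.
#' @param roi_centre_x_mm,roi_semiaxes_mm in-plane centre offset and semi-axes
#'   (x, y) of the contralateral brain-ROI ellipse.
#' @param tumour_centre_mm tumour sphere centre (x, y, z) in mm.
#' @param tumour_radius_mm tumour radius in mm; 0 means no tumour.
#' @param tissue named list with `brain` and (if a tumour is present) `tumour`
#'   [tissue_relaxation()] entries.
#' @param noise_sigma Rician channel noise standard deviation (arbitrary
#'   units) used by [simulate_series()] when not overridden.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = grid_spec(34, 34),
                         brain_semiaxes_mm = c(4.5, 3.5, 4.0),
                         brain_centre_mm = c(0, 0, 0),
                         roi_centre_x_mm = -1.8,
                         roi_semiaxes_mm = c(2.0, 2.9),
                         tumour_centre_mm = c(1.8, 0, 0),
                         tumour_radius_mm = 1.5,
                         tissue = NULL,
                         noise_sigma = 2) {
  if (!inherits(grid, "grid_spec")) stop("'grid' must be a grid_spec", call. = FALSE)
  if (tumour_radius_mm < 0) stop("'tumour_radius_mm' must be >= 0", call. = FALSE)
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0", call. = FALSE)
  structure(list(grid = grid,
                 brain_semiaxes_mm = brain_semiaxes_mm,
                 brain_centre_mm = brain_centre_mm,
                 roi_centre_x_mm = roi_centre_x_mm,
                 roi_semiaxes_mm = roi_semiaxes_mm,
                 tumour_centre_mm = tumour_centre_mm,
                 tumour_radius_mm = tumour_radius_mm,
                 tissue = tissue,
                 noise_sigma = noise_sigma),
            class = "phantom_spec")
}

#' Build a ground-truth phantom volume
#'
#' Rasterises the phantom geometry onto a grid by the voxel-centre rule (a
#' voxel takes a class if its centre lies inside the shape; tumour overrides
#' brain) and broadcasts per-class relaxation parameters to voxels. Also
#' builds the ROI label volume (1 = contralateral brain ROI, 2 = tumour) used
#' for metric extraction.
#'
#' @param spec a [phantom_spec()].
#' @param grid optional [grid_spec()] to rasterise onto (defaults to
#'   `spec$grid`); masks for the anatomical grid are produced by passing the
#'   anatomical grid here.
#' @return An object of class `ground_truth_volume`: list with `label`
#'   (0 background / 1 brain / 2 tumour), `roi` ([roi_mask()]), per-voxel
#'   `t1_ms`, `t2_ms`, `s0` arrays, `t1rho_ms` (list of arrays, one per FSL,
#'   when the tissue parameters carry T1rho values), `grid` and `spec`.
#' @export
build_phantom <- function(spec, grid = NULL) {
  if (is.null(grid)) grid <- spec$grid
  co <- grid_coords(grid)
  dims <- c(grid$nrow, grid$ncol, grid$n_slices)
  # voxel-centre coordinate arrays (row = y, col = x)
  Y <- array(rep(co$y, times = dims[2] * dims[3]), dim = dims)
  X <- array(rep(rep(co$x, each = dims[1]), times = dims[3]), dim = dims)
  Z <- array(rep(co$z, each = dims[1] * dims[2]), dim = dims)

  a <- spec$brain_semiaxes_mm; c0 <- spec$brain_centre_mm
  brain <- ((X - c0[1]) / a[1])^2 + ((Y - c0[2]) / a[2])^2 +
    ((Z - c0[3]) / a[3])^2 <= 1

  tumour <- array(FALSE, dims)
  if (spec$tumour_radius_mm > 0) {
    tc <- spec$tumour_centre_mm
    tumour <- (X - tc[1])^2 + (Y - tc[2])^2 + (Z - tc[3])^2 <=
      spec$tumour_radius_mm^2
    if (any(tumour & !brain))
      stop("geometry error: tumour extends outside the brain", call. = FALSE)
  }

  label <- array(0L, dims)
  label[brain] <- 1L
  label[tumour] <- 2L

  ra <- spec$roi_semiaxes_mm
  roi_brain <- ((X - spec$roi_centre_x_mm) / ra[1])^2 + (Y / ra[2])^2 <= 1
  roi <- array(0L, dims)
  roi[roi_brain & label == 1L] <- 1L
  roi[label == 2L] <- 2L

  out <- list(label = label, roi = roi_mask(roi, grid), grid = grid, spec = spec)
  tissue <- spec$tissue
  if (!is.null(tissue)) {
    t1 <- array(NA_real_, dims); t2 <- array(NA_real_, dims)
    s0 <- array(0, dims)
    classes <- c(brain = 1L, tumour = 2L)
    for (cls in names(classes)) {
      sel <- label == classes[[cls]]
      if (!any(sel)) next
      if (is.null(tissue[[cls]]))
        stop(sprintf("missing tissue parameters for class '%s'", cls), call. = FALSE)
      t1[sel] <- tissue[[cls]]$t1_ms
      t2[sel] <- tissue[[cls]]$t2_ms
      s0[sel] <- tissue[[cls]]$s0
    }
    out$t1_ms <- t1; out$t2_ms <- t2; out$s0 <- s0
    fsl <- names(tissue$brain$t1rho_ms)
    if (!is.null(fsl)) {
      out$t1rho_ms <- lapply(fsl, function(f) {
        v <- array(NA_real_, dims)
        for (cls in names(classes)) {
          sel <- label == classes[[cls]]
          if (!any(sel)) next
          tr <- tissue[[cls]]$t1rho_ms[[f]]
          if (is.null(tr) || is.na(tr))
            stop(sprintf("missing T1rho for class '%s' at FSL %s Hz", cls, f),
                 call. = FALSE)
          v[sel] <- tr
        }
        v
      })
      names(out$t1rho_ms) <- fsl
    }
  }
  class(out) <- "ground_truth_volume"
  out
}

#' @export
print.ground_truth_volume <- function(x, ...) {
  cat(sprintf("Ground-truth phantom on %dx%dx%d grid: %d brain, %d tumour voxels\n",
              x$grid$nrow, x$grid$ncol, x$grid$n_slices,
              sum(x$label == 1L), sum(x$label == 2L)))
  invisible(x)
}

#' Simulate a multislice spin-lock image series
#'
#' Generates the observed 4-D magnitude series for one spin-lock amplitude.
#' The noiseless voxel signal is
#' `S0 * f_sat(TSL) * exp(-TSL / T1rho(FSL))`, where `f_sat` is the
#' steady-state multislice saturation factor `Mz/M0` (`sat_model = "msat"`,
#' exactly invertible by [correct_series()]), or the same steady-state form
#' with `exp(-TSL/T1rho)` substituted for `Msat` (`sat_model = "t1rho_decay"`,
#' used to probe the bias of the nominal correction). Background voxels carry
#' zero mean signal. Rician noise applies independent Gaussian noise of
#' standard deviation `sigma` to both quadrature channels before taking the
#' magnitude.
#'
#' @param gt a [build_phantom()] ground-truth volume with tissue parameters.
#' @param protocol a [spin_lock_protocol()].
#' @param fsl_hz spin-lock amplitude; must be one of the ground-truth T1rho
#'   entries.
#' @param noise `"rician"`, `"gaussian"` or `"none"`.
#' @param sat_model `"msat"` or `"t1rho_decay"`.
#' @param sigma channel noise standard deviation; defaults to the phantom
#'   spec's `noise_sigma`.
#' @param seed optional integer seed (local to this call).
#' @return An object of class `spin_lock_series`: list with `data` (array
#'   rows x cols x slices x TSL), `fsl_hz`, `protocol`, `grid`.
#' @export
simulate_series <- function(gt, protocol, fsl_hz,
                            noise = c("rician", "gaussian", "none"),
                            sat_model = c("msat", "t1rho_decay"),
                            sigma = NULL, seed = NULL) {
  noise <- match.arg(noise)
  sat_model <- match.arg(sat_model)
  if (is.null(sigma)) sigma <- gt$spec$noise_sigma
  if (sigma < 0) stop("'sigma' must be >= 0", call. = FALSE)
  key <- as.character(fsl_hz)
  if (is.null(gt$t1rho_ms) || !key %in% names(gt$t1rho_ms))
    stop(sprintf("unknown FSL %s Hz: not among the ground-truth T1rho keys", key),
         call. = FALSE)
  tsl <- protocol$tsl_ms
  dims <- dim(gt$label)
  K <- length(tsl)
  data <- array(0, c(dims, K))
  tissue <- gt$spec$tissue
  classes <- c(brain = 1L, tumour = 2L)
  e1 <- function(t1) exp(-protocol$tau_ms / t1)
  for (cls in names(classes)) {
    sel <- gt$label == classes[[cls]]
    if (!any(sel)) next
    tp <- tissue[[cls]]
    trho <- tp$t1rho_ms[[key]]
    if (sat_model == "msat") {
      fsat <- saturation_factor(tp$t1_ms, tp$t2_ms, tsl, protocol$tau_ms)$mz_over_m0
    } else {
      m <- exp(-tsl / trho)
      fsat <- m * (1 - e1(tp$t1_ms)) / (1 - m * e1(tp$t1_ms))
    }
    mean_sig <- tp$s0 * fsat * exp(-tsl / trho)
    idx <- which(sel)
    nvox <- prod(dims)
    for (k in seq_len(K)) data[idx + (k - 1L) * nvox] <- mean_sig[k]
  }
  if (noise != "none" && sigma > 0) {
    apply_noise <- function() {
      n <- length(data)
      if (noise == "rician") {
        data <<- sqrt((data + rnorm(n, sd = sigma))^2 + rnorm(n, sd = sigma)^2)
      } else {
        data <<- data + rnorm(n, sd = sigma)
      }
    }
    with_local_seed(seed, apply_noise())
  }
  structure(list(data = data, fsl_hz = as.numeric(fsl_hz),
                 protocol = protocol, grid = gt$grid),
            class = "spin_lock_series")
}

#' @export
print.spin_lock_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Spin-lock series at FSL %g Hz: %dx%dx%d voxels, %d TSL samples\n",
              x$fsl_hz, d[1], d[2], d[3], d[4]))
  invisible(x)
}
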