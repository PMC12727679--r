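#' Spin-lock acquisition protocol
#'
#' Container for the constants of a multislice spin-lock acquisition: the
#' sampled spin-lock durations (TSL), the spin-lock amplitudes (FSL), the
#' per-slice recovery delay tau, and the slice geometry.
#'
#' @param tsl_ms numeric vector of spin-lock durations in ms; strictly
#'   increasing, all positive.
#' @param fsl_hz numeric vector of spin-lock amplitudes in Hz; strictly
#'   increasing, all positive.
#' @param tau_ms per-slice recovery delay in ms.
#' @param te_ms echo time in ms (metadata only, not used in any computation).
#' @param n_slices number of axial slices.
#' @param slice_thickness_mm slice thickness in mm.
#' @param slice_gap_mm gap between slices in mm.
#'
#' @return An object of class `spin_lock_protocol`.
#' @examples
#' p <- spin_lock_protocol()
#' p$tsl_ms
#' @export
spin_lock_protocol <- function(tsl_ms = c(1, 15, 30, 45, 60, 75, 90, 105),
                               fsl_hz = c(100, 500, 1000, 2000),
                               tau_ms = 2000,
                               te_ms = 4.59,
                               n_slices = 10L,
                               slice_thickness_mm = 1,
                               slice_gap_mm = 0.2) {
  if (length(tsl_ms) < 1L || any(!is.finite(tsl_ms)) || any(tsl_ms <= 0))
    stop("'tsl_ms' must be positive and finite", call. = FALSE)
  if (is.unsorted(tsl_ms, strictly = TRUE))
    stop("'tsl_ms' must be strictly increasing", call. = FALSE)
  if (length(fsl_hz) < 1L || any(!is.finite(fsl_hz)) || any(fsl_hz <= 0))
    stop("'fsl_hz' must be positive and finite", call. = FALSE)
  if (is.unsorted(fsl_hz, strictly = TRUE))
    stop("'fsl_hz' must be strictly increasing", call. = FALSE)
  if (!is.finite(tau_ms) || tau_ms <= 0)
    stop("'tau_ms' must be positive", call. = FALSE)
  n_slices <- as.integer(n_slices)
  if (n_slices < 1L) stop("'n_slices' must be >= 1", call. = FALSE)
  structure(list(tsl_ms = as.numeric(tsl_ms), fsl_hz = as.numeric(fsl_hz),
                 tau_ms = as.numeric(tau_ms), te_ms = as.numeric(te_ms),
                 n_slices = n_slices,
                 slice_thickness_mm = as.numeric(slice_thickness_mm),
                 slice_gap_mm = as.numeric(slice_gap_mm)),
            class = "spin_lock_protocol")
}

#' @export
print.spin_lock_protocol <- function(x, ...) {
  cat("Spin-lock protocol\n")
  cat("  TSL (ms):", paste(x$tsl_ms, collapse = ", "), "\n")
  cat("  FSL (Hz):", paste(x$fsl_hz, collapse = ", "), "\n")
  cat(sprintf("  tau = %g ms, TE = %g ms\n", x$tau_ms, x$te_ms))
  cat(sprintf("  %d slices, %g mm thick, %g mm gap\n",
              x$n_slices, x$slice_thickness_mm, x$slice_gap_mm))
  invisible(x)
}

#' Tissue relaxation parameters
#'
#' Relaxation times of one tissue class: longitudinal T1, transverse T2, the
#' rotating-frame relaxation time T1rho at each spin-lock amplitude, and the
#' equilibrium signal S0.
#'
#' @param t1_ms T1 in ms.
#' @param t2_ms T2 in ms; must not exceed `t1_ms`.
#' @param t1rho_ms named numeric vector, T1rho in ms per spin-lock amplitude;
#'   names are the amplitudes in Hz.
#' @param s0 equilibrium signal (arbitrary units).
#'
#' @return An object of class `tissue_relaxation`.
#' @export
tissue_relaxation <- function(t1_ms, t2_ms, t1rho_ms = NULL, s0 = 100) {
  if (!is.finite(t1_ms) || t1_ms <= 0) stop("'t1_ms' must be positive", call. = FALSE)
  if (!is.finite(t2_ms) || t2_ms <= 0) stop("'t2_ms' must be positive", call. = FALSE)
  if (t2_ms > t1_ms) stop("'t2_ms' must not exceed 't1_ms'", call. = FALSE)
  if (!is.null(t1rho_ms)) {
    if (is.null(names(t1rho_ms)) || any(!nzchar(names(t1rho_ms))))
      stop("'t1rho_ms' must be named by spin-lock amplitude (Hz)", call. = FALSE)
    if (any(!is.finite(t1rho_ms)) || any(t1rho_ms <= 0))
      stop("all 't1rho_ms' values must be positive", call. = FALSE)
  }
  if (!is.finite(s0) || s0 <= 0) stop("'s0' must be positive", call. = FALSE)
  structure(list(t1_ms = as.numeric(t1_ms), t2_ms = as.numeric(t2_ms),
                 t1rho_ms = t1rho_ms, s0 = as.numeric(s0)),
            class = "tissue_relaxation")
}

#' Group-average tissue T1/T2 lookup for the three study groups
#'
#' Group-average T1 and T2 (ms) of brain and tumour ROIs in the glioma mouse
#' study: Group 1 naive controls, Group 2 IDH1-wild-type, Group 3 IDH1-mutant.
#' These feed the multislice saturation correction.
#'
#' @return Named list, one element per group (`"1"`, `"2"`, `"3"`), each a list
#'   with `brain` and (for tumour-bearing groups) `tumour` entries carrying
#'   `t1_ms` and `t2_ms`.
#' @export
study_tissue_t1t2 <- function() {
  list(
    `1` = list(brain  = list(t1_ms = 669, t2_ms = 79)),
    `2` = list(brain  = list(t1_ms = 670, t2_ms = 98),
               tumour = list(t1_ms = 827, t2_ms = 120)),
    `3` = list(brain  = list(t1_ms = 882, t2_ms = 120),
               tumour = list(t1_ms = 988, t2_ms = 139))
  )
}

#' Group-level T1rho and delta-T1rho distributions for the three study groups
#'
#' Per-FSL mean and standard deviation of brain-ROI T1rho (ms) for all groups
#' and of the per-measurement tumour-to-brain percent difference delta-T1rho
#' (%) for the two tumour-bearing groups. These are the measurement-level
#' distributions the cohort simulator draws from.
#'
#' @return A data frame with columns `group`, `fsl_hz`, `brain_mean`,
#'   `brain_sd`, `delta_mean`, `delta_sd` (delta columns `NA` for Group 1).
#' @export
study_t1rho_tables <- function() {
  data.frame(
    group      = rep(1:3, each = 4L),
    fsl_hz     = rep(c(100, 500, 1000, 2000), 3L),
    brain_mean = c(159, 141, 136, 148,
                   115, 119, 119, 127,
                   119, 100, 98, 108),
    brain_sd   = c(36, 22, 20, 26,
                   16, 21, 15, 16,
                   22, 10, 9, 10),
    delta_mean = c(NA, NA, NA, NA,
                   2, 6, 3, 2,
                   27, 31, 29, 28),
    delta_sd   = c(NA, NA, NA, NA,
                   13, 13, 11, 14,
                   18, 15, 13, 15)
  )
}

# Restore the RNG state on exit and seed locally, so seeded helpers are
# reproducible without disturbing the caller's stream.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
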