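#' Default weekly imaging schedule of the study cohort
#'
#' Which mouse is imaged at which week and when a tumour is present, for the
#' three groups (1 = naive, 2 = IDH1 wild type, 3 = IDH1 mutant). Controls are
#' imaged Weeks 1-6; tumour-bearing mice are terminated on Week 3 or 4; the
#' earliest visible tumour appears at Week 2 in the mutant group, most by
#' Week 3, and one mutant-group mouse never develops a tumour. Pooling
#' Weeks 2-4 yields exactly 0/15, 9/14 and 7/12 tumour/brain measurements for
#' Groups 1-3.
#'
#' @return A data frame with columns `group`, `mouse`, `week`, `has_tumour`.
#' @export
default_schedule <- function() {
  rows <- list()
  for (m in 1:5)
    rows[[length(rows) + 1L]] <- data.frame(group = 1L, mouse = m, week = 1:6,
                                            has_tumour = FALSE)
  g2 <- list(`1` = list(weeks = 1:4, tum = 3:4), `2` = list(weeks = 1:4, tum = 3:4),
             `3` = list(weeks = 1:4, tum = 3:4), `4` = list(weeks = 1:4, tum = 3:4),
             `5` = list(weeks = 1:3, tum = 3L))
  g3 <- list(`1` = list(weeks = 1:4, tum = 2:4), `2` = list(weeks = 1:4, tum = 3:4),
             `3` = list(weeks = 1:3, tum = 3L), `4` = list(weeks = 1:3, tum = 3L),
             `5` = list(weeks = 1:3, tum = integer(0)))
  for (g in 2:3) {
    sched <- if (g == 2L) g2 else g3
    for (m in names(sched))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, mouse = as.integer(m), week = sched[[m]]$weeks,
        has_tumour = sched[[m]]$weeks %in% sched[[m]]$tum)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort design for the synthetic glioma study
#'
#' Bundles everything the cohort simulator needs: the imaging protocol, the
#' weekly schedule, the per-group measurement-level distributions of brain
#' T1rho and of the per-measurement tumour-to-brain percent difference
#' (delta-T1rho) at each spin-lock amplitude, group-average tissue T1/T2, the
#' tumour-size distribution and the image noise level.
#'
#' Per measurement, brain T1rho and delta-T1rho are drawn per FSL from the
#' configured normal distributions, with a latent-factor correlation
#' `fsl_corr` across amplitudes (the four amplitudes are measured in one
#' session on the same tissue); the tumour value is derived as
#' `brain * (1 + delta/100)`, which reproduces the group-level brain and
#' delta-T1rho statistics and induces the within-mouse brain-tumour
#' correlation.
#'
#' @param protocol a [spin_lock_protocol()].
#' @param schedule data frame as [default_schedule()].
#' @param t1rho_tables data frame as [study_t1rho_tables()].
#' @param tissue_t1t2 list as [study_tissue_t1t2()].
#' @param fsl_corr latent correlation of draws across spin-lock amplitudes
#'   within one measurement, in [0, 1].
#' @param tumour_area_mm2 mean, SD and truncation range (min, max) of the
#'   central-slice tumour area in mm^2.
#' @param s0 equilibrium signal (arbitrary units).
#' @param snr signal-to-noise ratio `s0 / sigma` defining the Rician channel
#'   noise.
#' @param weeks_pooled weeks merged for the group statistics.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(protocol = spin_lock_protocol(),
                          schedule = default_schedule(),
                          t1rho_tables = study_t1rho_tables(),
                          tissue_t1t2 = study_tissue_t1t2(),
                          fsl_corr = 0.8,
                          tumour_area_mm2 = c(mean = 13, sd = 10, min = 4, max = 15),
                          s0 = 100, snr = 50,
                          weeks_pooled = 2:4) {
  if (fsl_corr < 0 || fsl_corr > 1) stop("'fsl_corr' must be in [0, 1]", call. = FALSE)
  if (any(schedule$has_tumour & schedule$group == 1L))
    stop("group 1 (naive) must never bear tumours", call. = FALSE)
  structure(list(protocol = protocol, schedule = schedule,
                 t1rho_tables = t1rho_tables, tissue_t1t2 = tissue_t1t2,
                 fsl_corr = fsl_corr, tumour_area_mm2 = tumour_area_mm2,
                 s0 = s0, snr = snr, weeks_pooled = weeks_pooled),
            class = "cohort_design")
}

# draw measurement-level truth for every schedule row; returns the study table
# with one row per (measurement, fsl) carrying true brain/tumour T1rho
draw_cohort_truth <- function(design) {
  sched <- design$schedule
  tab <- design$t1rho_tables
  fsl <- design$protocol$fsl_hz
  nf <- length(fsl)
  rho <- design$fsl_corr
  rows <- vector("list", nrow(sched))
  for (i in seq_len(nrow(sched))) {
    g <- sched$group[i]
    gt <- tab[tab$group == g, ]
    gt <- gt[match(fsl, gt$fsl_hz), ]
    if (any(is.na(gt$brain_mean)))
      stop(sprintf("no T1rho distribution for group %d at some FSL", g), call. = FALSE)
    zb <- sqrt(rho) * rnorm(1L) + sqrt(1 - rho) * rnorm(nf)
    brain <- pmax(gt$brain_mean + gt$brain_sd * zb, 5)
    delta <- rep(NA_real_, nf); tumour <- rep(NA_real_, nf)
    if (sched$has_tumour[i]) {
      zd <- sqrt(rho) * rnorm(1L) + sqrt(1 - rho) * rnorm(nf)
      delta <- gt$delta_mean + gt$delta_sd * zd
      tumour <- pmax(brain * (1 + delta / 100), 5)
    }
    ta <- design$tumour_area_mm2
    area <- if (sched$has_tumour[i])
      min(max(rnorm(1L, ta[["mean"]], ta[["sd"]]), ta[["min"]]), ta[["max"]])
    else 0
    rows[[i]] <- data.frame(
      group = g, mouse = sched$mouse[i], week = sched$week[i],
      has_tumour = sched$has_tumour[i], fsl_hz = fsl,
      true_brain_t1rho_ms = brain, true_tumour_t1rho_ms = tumour,
      tumour_area_mm2 = area,
      tumour_radius_mm = if (area > 0) sqrt(area / pi) else 0)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# phantom spec for one measurement row set (one mouse-week)
measurement_phantom_spec <- function(design, truth_rows, grid = NULL) {
  g <- as.character(truth_rows$group[1L])
  tt <- design$tissue_t1t2[[g]]
  brain_t1rho <- truth_rows$true_brain_t1rho_ms
  names(brain_t1rho) <- as.character(truth_rows$fsl_hz)
  tissue <- list(brain = tissue_relaxation(tt$brain$t1_ms, tt$brain$t2_ms,
                                           brain_t1rho, s0 = design$s0))
  radius <- truth_rows$tumour_radius_mm[1L]
  if (truth_rows$has_tumour[1L] && radius > 0) {
    tum_t1rho <- truth_rows$true_tumour_t1rho_ms
    names(tum_t1rho) <- as.character(truth_rows$fsl_hz)
    tissue$tumour <- tissue_relaxation(tt$tumour$t1_ms, tt$tumour$t2_ms,
                                       tum_t1rho, s0 = design$s0)
  } else radius <- 0
  phantom_spec(grid = if (is.null(grid)) grid_spec(34, 34) else grid,
               tumour_radius_mm = radius, tissue = tissue,
               noise_sigma = design$s0 / design$snr)
}

#' Generate a synthetic imaging cohort
#'
#' Draws measurement-level ground truth for every mouse-week in the schedule,
#' and (optionally) builds a phantom per measurement, simulates the multislice
#' spin-lock series at every spin-lock amplitude, and rasterises the ROI masks
#' on the anatomical grid. With `out_dir` set, series and masks are written as
#' NIfTI-1 with JSON sidecars and the study table as CSV.
#'
#' @param design a [cohort_design()].
#' @param out_dir optional output directory; created if needed.
#' @param seed optional integer seed (local to this call).
#' @param imaging simulate images (`TRUE`) or only draw the ground-truth
#'   study table (`FALSE`, fast path for distribution-level checks).
#' @param noise noise model passed to [simulate_series()].
#' @return An object of class `synthetic_cohort`: list with `truth` (the study
#'   table), `design`, and when `imaging` is on a list `measurements`, each
#'   with `series` (one per FSL), `anat_mask`, `gt`, identifiers, and `files`
#'   when written.
#' @export
generate_cohort <- function(design, out_dir = NULL, seed = NULL,
                            imaging = TRUE, noise = "rician") {
  force(design)
  run <- function() {
    truth <- if (nrow(design$schedule)) draw_cohort_truth(design) else
      data.frame(group = integer(0), mouse = integer(0), week = integer(0),
                 has_tumour = logical(0), fsl_hz = numeric(0),
                 true_brain_t1rho_ms = numeric(0),
                 true_tumour_t1rho_ms = numeric(0),
                 tumour_area_mm2 = numeric(0), tumour_radius_mm = numeric(0))
    out <- list(truth = truth, design = design)
    if (imaging && nrow(truth)) {
      grids <- study_grids()
      keys <- unique(truth[, c("group", "mouse", "week")])
      meas <- vector("list", nrow(keys))
      for (i in seq_len(nrow(keys))) {
        tr <- truth[truth$group == keys$group[i] & truth$mouse == keys$mouse[i] &
                      truth$week == keys$week[i], ]
        spec <- measurement_phantom_spec(design, tr, grid = grids$t1rho)
        gt <- build_phantom(spec)
        anat_mask <- build_phantom(spec, grid = grids$anatomical)$roi
        series <- lapply(design$protocol$fsl_hz, function(f)
          simulate_series(gt, design$protocol, f, noise = noise))
        names(series) <- as.character(design$protocol$fsl_hz)
        meas[[i]] <- list(group = keys$group[i], mouse = keys$mouse[i],
                          week = keys$week[i], has_tumour = tr$has_tumour[1L],
                          gt = gt, anat_mask = anat_mask, series = series)
      }
      out$measurements <- meas
    }
    class(out) <- "synthetic_cohort"
    if (!is.null(out_dir)) write_cohort(out, out_dir)
    out
  }
  with_local_seed(seed, run())
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  n_meas <- length(unique(interaction(x$truth$group, x$truth$mouse, x$truth$week)))
  cat(sprintf("Synthetic cohort: %d measurements (%s imaging data)\n", n_meas,
              if (is.null(x$measurements)) "without" else "with"))
  invisible(x)
}

#' Compute per-measurement ROI metrics for a cohort
#'
#' Runs the analysis stage of the pipeline on a simulated (or loaded) cohort:
#' per measurement, the anatomical-grid ROI mask is transferred to the T1rho
#' grid, a T1rho map is fitted per spin-lock amplitude (with or without the
#' multislice saturation correction), ROI means are extracted, the
#' per-measurement delta-T1rho computed at each amplitude, and the six tumour
#' dispersion ratios formed.
#'
#' @param cohort a [generate_cohort()] result with imaging data.
#' @param correction apply the multislice saturation correction (`FALSE`
#'   gives the uncorrected analysis path).
#' @param r2_threshold QC threshold forwarded to [fit_t1rho_map()].
#' @return A long-format measurement table (class `measurement_table`):
#'   data frame with columns `mouse`, `group`, `week`, `fsl_hz`,
#'   `fsl_high_hz` (NA except for dispersion rows), `roi`, `metric`
#'   (`"t1rho"`, `"delta"`, `"dispersion_ratio"`), `value`.
#' @export
compute_cohort_metrics <- function(cohort, correction = TRUE, r2_threshold = 0.5) {
  if (is.null(cohort$measurements))
    stop("cohort has no imaging data; rerun generate_cohort(imaging = TRUE)",
         call. = FALSE)
  design <- cohort$design
  rows <- list()
  add <- function(group, mouse, week, fsl, fsl_high, roi, metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      mouse = mouse, group = group, week = week, fsl_hz = fsl,
      fsl_high_hz = fsl_high, roi = roi, metric = metric, value = value)
  for (m in cohort$measurements) {
    g <- as.character(m$group)
    tt <- design$tissue_t1t2[[g]]
    t1c <- c(brain = tt$brain$t1_ms)
    t2c <- c(brain = tt$brain$t2_ms)
    if (!is.null(tt$tumour)) {
      t1c["tumour"] <- tt$tumour$t1_ms
      t2c["tumour"] <- tt$tumour$t2_ms
    }
    mask <- resample_mask(m$anat_mask, m$gt$grid)
    tum_means <- c()
    for (f in names(m$series)) {
      map <- fit_t1rho_map(m$series[[f]], mask, t1c, t2c,
                           correction = correction, r2_threshold = r2_threshold)
      br <- roi_mean(map, mask, "brain")
      add(m$group, m$mouse, m$week, as.numeric(f), NA, "brain", "t1rho",
          br$mean_t1rho_ms)
      if (m$has_tumour && any(mask$label == 2L)) {
        tu <- roi_mean(map, mask, "tumour")
        add(m$group, m$mouse, m$week, as.numeric(f), NA, "tumour", "t1rho",
            tu$mean_t1rho_ms)
        add(m$group, m$mouse, m$week, as.numeric(f), NA, "tumour", "delta",
            delta_t1rho(tu$mean_t1rho_ms, br$mean_t1rho_ms))
        tum_means[f] <- tu$mean_t1rho_ms
      }
    }
    if (length(tum_means) >= 2L) {
      dr <- dispersion_ratios(tum_means)
      for (j in seq_len(nrow(dr)))
        add(m$group, m$mouse, m$week, dr$fsl_low_hz[j], dr$fsl_high_hz[j],
            "tumour", "dispersion_ratio", dr$ratio[j])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  as_measurement_table(out)
}

#' Validate and class a long-format measurement table
#'
#' @param x data frame with columns `mouse`, `group`, `week`, `fsl_hz`,
#'   `fsl_high_hz`, `roi`, `metric`, `value`.
#' @return `x` with class `measurement_table`, after checking for duplicate
#'   measurement keys and that Group 1 carries no tumour rows.
#' @export
as_measurement_table <- function(x) {
  need <- c("mouse", "group", "week", "fsl_hz", "fsl_high_hz", "roi",
            "metric", "value")
  if (!all(need %in% names(x)))
    stop("missing measurement-table columns: ",
         paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
  key <- do.call(paste, c(x[c("mouse", "group", "week", "fsl_hz",
                              "fsl_high_hz", "roi", "metric")], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (mouse, week, fsl, roi, metric) keys", call. = FALSE)
  if (any(x$group == 1L & x$roi == "tumour"))
    stop("group 1 (naive) must have no tumour rows", call. = FALSE)
  class(x) <- c("measurement_table", "data.frame")
  x
}

#' Restrict a measurement table to the pooled analysis weeks
#'
#' Measurements from the given weeks are retained and subsequently treated as
#' one pooled sample per (group, FSL, ROI, metric); the input is unmodified.
#'
#' @param table a `measurement_table`.
#' @param weeks weeks to keep (default Weeks 2-4, the study's pooling).
#' @return The filtered `measurement_table` (possibly empty).
#' @export
merge_weeks <- function(table, weeks = 2:4) {
  out <- table[table$week %in% weeks, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("measurement_table", "data.frame")
  out
}

#' Group-level summary in the layout of the study's metric table
#'
#' Mean and SD of pooled brain/tumour T1rho and delta-T1rho per group and
#' spin-lock amplitude.
#'
#' @param table a pooled `measurement_table` (see [merge_weeks()]).
#' @return Data frame with columns `group`, `fsl_hz`, `roi`, `metric`,
#'   `mean`, `sd`, `n`.
#' @export
group_summary <- function(table) {
  t <- table[table$metric %in% c("t1rho", "delta"), ]
  if (!nrow(t))
    return(data.frame(group = integer(0), fsl_hz = numeric(0),
                      roi = character(0), metric = character(0),
                      mean = numeric(0), sd = numeric(0), n = integer(0)))
  agg <- aggregate(value ~ group + fsl_hz + roi + metric, data = t,
                   FUN = function(v) c(mean = mean(v), sd = sd(v), n = length(v)))
  out <- data.frame(agg[c("group", "fsl_hz", "roi", "metric")],
                    mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                    n = as.integer(agg$value[, "n"]))
  out[order(out$metric, out$group, out$roi, out$fsl_hz), ]
}
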