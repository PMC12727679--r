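#' Write / read a spin-lock series as NIfTI-1 with a JSON sidecar
#'
#' The 4-D magnitude series (rows x cols x slices x TSL) is stored as a
#' NIfTI-1 volume (`.nii.gz`) and the acquisition metadata as a BIDS-like
#' JSON sidecar next to it: `tsl_ms` (list), `fsl_hz`, `tau_ms`, `te_ms`,
#' plus the grid geometry. The round trip is lossless for data and metadata.
#'
#' @param series a `spin_lock_series`.
#' @param path output path; `.nii.gz` is appended if absent, the sidecar
#'   replaces that extension by `.json`.
#' @return `write_series` returns the NIfTI path invisibly; `read_series`
#'   returns a `spin_lock_series`.
#' @export
write_series <- function(series, path) {
  path <- nifti_path(path)
  g <- series$grid
  img <- RNifti::asNifti(series$data)
  img <- RNifti::`pixdim<-`(img, c(g$spacing_mm, g$slice_pitch_mm, 1))
  RNifti::writeNifti(img, path)
  p <- series$protocol
  meta <- list(tsl_ms = p$tsl_ms, fsl_hz = series$fsl_hz, tau_ms = p$tau_ms,
               te_ms = p$te_ms, fov_mm = g$fov_mm,
               slice_thickness_mm = g$slice_thickness_mm,
               slice_gap_mm = g$slice_gap_mm,
               slice_convention = "slice index 1 = most inferior; pixel-centre aligned, FOV origin at volume corner")
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_series
#' @param path_in path of a series written by [write_series()].
#' @export
read_series <- function(path_in) {
  path <- nifti_path(path_in)
  side <- sidecar_path(path)
  if (!file.exists(side))
    stop("format error: missing JSON sidecar ", side, call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim = dim(img))
  d <- dim(data)
  if (length(d) != 4L)
    stop("format error: expected a 4-D series", call. = FALSE)
  if (d[4] != length(meta$tsl_ms))
    stop("format error: sidecar TSL length does not match the 4th dimension",
         call. = FALSE)
  grid <- grid_spec(d[1], d[2], d[3], fov_mm = meta$fov_mm,
                    slice_thickness_mm = meta$slice_thickness_mm,
                    slice_gap_mm = meta$slice_gap_mm)
  protocol <- spin_lock_protocol(tsl_ms = meta$tsl_ms,
                                 fsl_hz = sort(unique(c(meta$fsl_hz))),
                                 tau_ms = meta$tau_ms, te_ms = meta$te_ms,
                                 n_slices = d[3],
                                 slice_thickness_mm = meta$slice_thickness_mm,
                                 slice_gap_mm = meta$slice_gap_mm)
  structure(list(data = data, fsl_hz = meta$fsl_hz, protocol = protocol,
                 grid = grid),
            class = "spin_lock_series")
}

nifti_path <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) path else paste0(path, ".nii.gz")
}
sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Write / read an ROI label mask as a NIfTI label volume
#'
#' @param mask a [roi_mask()].
#' @param path output path (`.nii.gz` appended if absent); the sidecar
#'   carries the grid geometry.
#' @return `write_mask` returns the path invisibly; `read_mask` a `roi_mask`.
#' @export
write_mask <- function(mask, path) {
  path <- nifti_path(path)
  g <- mask$grid
  img <- RNifti::asNifti(mask$label)
  img <- RNifti::`pixdim<-`(img, c(g$spacing_mm, g$slice_pitch_mm))
  RNifti::writeNifti(img, path, datatype = "int16")
  jsonlite::write_json(list(fov_mm = g$fov_mm,
                            slice_thickness_mm = g$slice_thickness_mm,
                            slice_gap_mm = g$slice_gap_mm,
                            labels = list(`1` = "brain", `2` = "tumour")),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask
#' @param path_in path of a mask written by [write_mask()].
#' @export
read_mask <- function(path_in) {
  path <- nifti_path(path_in)
  side <- sidecar_path(path)
  if (!file.exists(side))
    stop("format error: missing JSON sidecar ", side, call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  img <- RNifti::readNifti(path)
  lab <- array(as.integer(img), dim = dim(img))
  grid <- grid_spec(dim(lab)[1], dim(lab)[2], dim(lab)[3],
                    fov_mm = meta$fov_mm,
                    slice_thickness_mm = meta$slice_thickness_mm,
                    slice_gap_mm = meta$slice_gap_mm)
  roi_mask(lab, grid)
}

# write a simulated cohort's files: per-measurement series + masks + table
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("I/O error: cannot create output directory ", out_dir, call. = FALSE)
  utils::write.csv(cohort$truth, file.path(out_dir, "study_table.csv"),
                   row.names = FALSE)
  paths <- character(0)
  for (m in cohort$measurements) {
    stem <- sprintf("g%d_m%d_w%d", m$group, m$mouse, m$week)
    for (f in names(m$series)) {
      p <- file.path(out_dir, sprintf("%s_fsl%s", stem, f))
      write_series(m$series[[f]], p)
      paths <- c(paths, nifti_path(p))
    }
    pm <- file.path(out_dir, sprintf("%s_mask", stem))
    write_mask(m$anat_mask, pm)
    paths <- c(paths, nifti_path(pm))
  }
  invisible(paths)
}

#' Study configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys are rejected.
#'
#' @param protocol a [spin_lock_protocol()].
#' @param design a [cohort_design()] (built from `protocol` by default).
#' @param correction apply the multislice saturation correction.
#' @param r2_threshold voxel QC threshold.
#' @param fdr false discovery rate for BH families.
#' @param alpha family-wise rate for the Bonferroni dispersion family.
#' @param exact_cutoff combined-n cutoff for exact Mann-Whitney tests.
#' @param seed integer seed for the simulation.
#' @param out_dir optional output directory for result CSVs and the manifest.
#' @param save_series also write every simulated series/mask to `out_dir`.
#' @return An object of class `study_config`.
#' @export
study_config <- function(protocol = spin_lock_protocol(),
                         design = cohort_design(protocol = protocol),
                         correction = TRUE, r2_threshold = 0.5,
                         fdr = 0.05, alpha = 0.05, exact_cutoff = 20L,
                         seed = 1L, out_dir = NULL, save_series = FALSE) {
  cfg <- structure(list(protocol = protocol, design = design,
                        correction = correction, r2_threshold = r2_threshold,
                        fdr = fdr, alpha = alpha,
                        exact_cutoff = as.integer(exact_cutoff),
                        seed = as.integer(seed), out_dir = out_dir,
                        save_series = isTRUE(save_series)),
                   class = "study_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  known <- c("protocol", "design", "correction", "r2_threshold", "fdr",
             "alpha", "exact_cutoff", "seed", "out_dir", "save_series")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "), call. = FALSE)
  missing <- setdiff(known, names(cfg))
  if (length(missing))
    stop("missing config keys: ", paste(missing, collapse = ", "), call. = FALSE)
  if (!inherits(cfg$protocol, "spin_lock_protocol"))
    stop("'protocol' must be a spin_lock_protocol", call. = FALSE)
  if (!inherits(cfg$design, "cohort_design"))
    stop("'design' must be a cohort_design", call. = FALSE)
  if (cfg$fdr <= 0 || cfg$fdr >= 1) stop("'fdr' must be in (0, 1)", call. = FALSE)
  if (cfg$r2_threshold < 0 || cfg$r2_threshold > 1)
    stop("'r2_threshold' must be in [0, 1]", call. = FALSE)
  invisible(cfg)
}

#' Read a study configuration from a YAML file
#'
#' Scalar options (`correction`, `r2_threshold`, `fdr`, `alpha`,
#' `exact_cutoff`, `seed`, `out_dir`, `save_series`) and protocol overrides
#' (`tsl_ms`, `fsl_hz`, `tau_ms`) are read from YAML; unknown keys are
#' rejected before any stage runs.
#'
#' @param path YAML file path.
#' @return A [study_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("tsl_ms", "fsl_hz", "tau_ms", "correction", "r2_threshold",
             "fdr", "alpha", "exact_cutoff", "seed", "out_dir", "save_series",
             "snr", "fsl_corr")
  extra <- setdiff(names(y), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "), call. = FALSE)
  proto_args <- y[intersect(names(y), c("tsl_ms", "fsl_hz", "tau_ms"))]
  protocol <- do.call(spin_lock_protocol, proto_args)
  design_args <- list(protocol = protocol)
  if (!is.null(y$snr)) design_args$snr <- y$snr
  if (!is.null(y$fsl_corr)) design_args$fsl_corr <- y$fsl_corr
  design <- do.call(cohort_design, design_args)
  cfg_args <- y[intersect(names(y), c("correction", "r2_threshold", "fdr",
                                      "alpha", "exact_cutoff", "seed",
                                      "out_dir", "save_series"))]
  do.call(study_config, c(list(protocol = protocol, design = design), cfg_args))
}

#' Hash of a study configuration
#'
#' MD5 digest of the canonical JSON serialisation of the configuration; any
#' change to any option changes the hash. Recorded in every output manifest.
#'
#' @param config a [study_config()].
#' @return A character MD5 hash.
#' @export
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, canon)
      if (!is.null(names(x))) x[order(names(x))] else x
    } else x
  }
  js <- jsonlite::toJSON(canon(unclass(config)), auto_unbox = TRUE,
                         digits = NA, null = "null", force = TRUE)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

#' Run the full study pipeline
#'
#' Chains the stages end to end: simulate the cohort, transfer ROIs and fit
#' T1rho maps (with or without the saturation correction), extract the
#' per-measurement metrics, pool Weeks 2-4 and run the group statistics and
#' the control-group age-trend analysis. With `out_dir` set, the study table,
#' metrics, group summaries, comparison tables, trend table and a manifest
#' (config hash, seed, stage record) are written as CSV/JSON. A rerun with
#' the same configuration is identical.
#'
#' @param config a [study_config()].
#' @param stages which stages to run (a prefix of
#'   `c("simulate", "fit", "stats")`); later stages require the earlier ones.
#' @param cohort optionally, a pre-simulated cohort (skips the simulate
#'   stage).
#' @return An object of class `study_results`: list with `cohort`, `metrics`,
#'   `pooled`, `summary`, `comparisons`, `age_trend`, `config`, `hash` (the
#'   later elements `NULL` when their stage was not run).
#' @export
run_pipeline <- function(config, stages = c("simulate", "fit", "stats"),
                         cohort = NULL) {
  validate_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  hash <- config_hash(config)
  res <- list(config = config, hash = hash)
  stage_run <- character(0)
  fail <- function(stage, e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  if ("simulate" %in% stages && is.null(cohort)) {
    cohort <- tryCatch(
      generate_cohort(config$design,
                      out_dir = if (config$save_series) config$out_dir else NULL,
                      seed = config$seed),
      error = function(e) fail("simulate", e))
    stage_run <- c(stage_run, "simulate")
  }
  res$cohort <- cohort
  if ("fit" %in% stages) {
    if (is.null(cohort)) stop("stage 'fit' requires a simulated cohort", call. = FALSE)
    res$metrics <- tryCatch(
      compute_cohort_metrics(cohort, correction = config$correction,
                             r2_threshold = config$r2_threshold),
      error = function(e) fail("fit", e))
    stage_run <- c(stage_run, "fit")
  }
  if ("stats" %in% stages && !is.null(res$metrics)) {
    res$pooled <- merge_weeks(res$metrics, config$design$weeks_pooled)
    res$summary <- group_summary(res$pooled)
    res$comparisons <- tryCatch(
      run_group_comparisons(res$pooled, fdr = config$fdr, alpha = config$alpha),
      error = function(e) fail("stats", e))
    res$age_trend <- run_age_trend(res$metrics, fdr = config$fdr)
    stage_run <- c(stage_run, "stats")
  }
  class(res) <- "study_results"
  if (!is.null(config$out_dir)) write_results(res, config$out_dir, stage_run)
  res
}

write_results <- function(res, out_dir, stages_run) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) if (!is.null(x))
    utils::write.csv(x, file.path(out_dir, name), row.names = FALSE)
  if (!is.null(res$cohort)) wr(res$cohort$truth, "study_table.csv")
  wr(res$metrics, "metrics.csv")
  wr(res$summary, "group_means.csv")
  if (!is.null(res$comparisons)) {
    wr(res$comparisons$t1rho, "comparisons_t1rho.csv")
    wr(res$comparisons$delta, "comparisons_delta.csv")
    wr(res$comparisons$dispersion, "comparisons_dispersion.csv")
  }
  wr(res$age_trend, "age_trend.csv")
  manifest <- list(config_hash = res$hash, seed = res$config$seed,
                   correction = res$config$correction,
                   stages = as.list(stages_run),
                   n_measurements = if (!is.null(res$cohort))
                     length(res$cohort$measurements) else 0L,
                   timestamp_utc = format(Sys.time(), tz = "UTC",
                                          "%Y-%m-%dT%H:%M:%SZ"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.study_results <- function(x, ...) {
  cat("Study pipeline results (config hash", substr(x$hash, 1, 8), ")\n")
  if (!is.null(x$summary)) {
    cat("\nGroup means (pooled weeks):\n")
    print(x$summary, row.names = FALSE)
  }
  if (!is.null(x$comparisons)) print(x$comparisons)
  invisible(x)
}
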