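# Configuration files, reports, provenance and the pipeline glue.

.known_keys <- list(
  top = c("optics", "scan", "phantom", "analysis", "seed", "output_dir"),
  optics = c("preset", "lens_distance_mm", "wavelength_nm", "etl_power_dpt",
             "max_optical_half_angle_deg"),
  scan = c("n_lines", "pixels_per_line", "line_period_ms", "extent_um",
           "z_profile", "sample_rate_hz", "turnaround_fraction"),
  phantom = c("preset", "n_emitters", "volume_um", "lattice_spacing_um", "brightness"),
  analysis = c("neighbourhood", "bead_threshold_sd"))

.config_defaults <- list(
  optics = list(preset = "nTC2", lens_distance_mm = 5, wavelength_nm = 927,
                etl_power_dpt = 0),
  scan = list(n_lines = 64, pixels_per_line = 64, line_period_ms = 1,
              extent_um = 100, sample_rate_hz = 100e3,
              turnaround_fraction = 0.1),
  phantom = list(preset = "beads", n_emitters = 10, volume_um = c(30, 30, 20)),
  analysis = list(neighbourhood = 8, bead_threshold_sd = 8),
  seed = 1)

.check_keys <- function(x, section) {
  known <- .known_keys[[section]]
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop(sprintf("unknown key(s) in %s: %s (known: %s)",
                 section, paste(bad, collapse = ", "),
                 paste(known, collapse = ", ")))
}

#' Load and validate a run configuration
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON document, rejects unknown keys
#' (naming them), fills documented defaults and computes a provenance hash
#' of the normalized configuration.
#'
#' @param path Configuration file.
#' @return An object of class `ntc_runconfig`: the normalized configuration
#'   list with a `hash` field.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  normalize_config(raw)
}

#' @rdname load_config
#' @param config A raw configuration list.
#' @export
normalize_config <- function(config) {
  .check_keys(config, "top")
  for (sec in c("optics", "scan", "phantom", "analysis")) {
    if (!is.null(config[[sec]])) .check_keys(config[[sec]], sec)
    defs <- .config_defaults[[sec]]
    for (k in names(defs))
      if (is.null(config[[sec]][[k]])) config[[sec]][[k]] <- defs[[k]]
  }
  if (is.null(config$seed)) config$seed <- .config_defaults$seed
  config <- config[order(match(names(config),
                               c(.known_keys$top)))]
  config$hash <- .hash_obj(as.character(jsonlite::toJSON(
    config[setdiff(names(config), "hash")], auto_unbox = TRUE, digits = NA)))
  structure(config, class = "ntc_runconfig")
}

#' @rdname load_config
#' @param file Output path (`.yaml` or `.json` by extension).
#' @export
save_config <- function(config, file) {
  x <- unclass(config)
  x$hash <- NULL
  if (grepl("\\.ya?ml$", file, ignore.case = TRUE))
    yaml::write_yaml(x, file)
  else jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(file)
}

# Deterministic per-stage child seeds from the global seed.
.stage_seed <- function(seed, stage) {
  offsets <- c(optics = 0L, scan = 1L, phantom = 2L, render = 3L,
               analysis = 4L)
  (as.integer(seed) * 101L + offsets[[stage]]) %% .Machine$integer.max
}

#' Optics report for a configuration
#'
#' Collects field of view, effective N.A., predicted PSF, focal shift, IFP
#' position and field-curvature sagitta into one unit-annotated record.
#'
#' @param config An [optical_config()].
#' @param etl_power_dpt ETL power, diopters.
#' @return A nested list, each numeric entry paired with a `units` field.
#' @export
optics_report <- function(config, etl_power_dpt = 0) {
  fv <- fov_diameter(config, etl_power_dpt = etl_power_dpt)
  fs <- focus_solution(config, etl_power_dpt = etl_power_dpt)
  psf <- predict_psf(config, etl_power_dpt)
  sag <- field_curvature_sagitta(config, etl_power_dpt = etl_power_dpt)
  list(preset = config$preset,
       lens_distance = list(value = config$lens_distance_mm, units = "mm"),
       fov = list(value = fv$diameter_mm, units = "mm",
                  mirror_limited = fv$mirror_limited_mm,
                  vignetting_limited = fv$vignetting_limited_mm,
                  binding = fv$binding),
       effective_na = list(value = fs$effective_na, units = "dimensionless"),
       focal_shift = list(value = unname(fs$focus_point_um["z"]), units = "um"),
       psf = list(lateral = psf$lateral_fwhm_um, axial = psf$axial_fwhm_um,
                  units = "um"),
       ifp = list(value = fs$ifp$rel_tube_lens_mm, units = "mm",
                  collimated_after_tube_lens = fs$ifp$collimated_after_tube_lens),
       field_curvature_sagitta = list(value = sag, units = "um"),
       vignetting_fraction = list(value = fs$vignetting_fraction,
                                  units = "fraction"),
       wavelength = list(value = config$input_beam$wavelength_nm, units = "nm"))
}

#' Write a report (or any list) as JSON
#'
#' @param x List to serialize.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write an acquired stack or movie as TIFF
#'
#' Requires the `tiff` package; pixel size and z-step metadata are stored in
#' the image description.
#'
#' @param acq An `ntc_acquired`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_acquired_tiff <- function(acq, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF output")
  d <- dim(acq$pixels)
  mx <- max(acq$pixels, 1e-12)
  frames <- lapply(seq_len(d[1]), function(f) acq$pixels[f, , ] / mx)
  tiff::writeTIFF(frames, path,
                  reduce = TRUE)
  meta <- list(pixel_size_um = as.list(acq$pixel_size_um),
               z_step_um = acq$z_step_um,
               intensity_scale = mx,
               provenance = acq$provenance)
  write_report_json(meta, paste0(path, ".json"))
  invisible(path)
}

#' Run the configured pipeline end to end
#'
#' Stages: optics report, scan build (timing + waveforms), phantom render,
#' analysis.  Every output carries the configuration hash and the seed; the
#' deterministic stages are byte-identical across reruns, and changing the
#' seed changes only the phantom-dependent outputs.
#'
#' @param config An `ntc_runconfig` (or path to one).
#' @param output_dir Output directory; defaults to the configuration's
#'   `output_dir` or a temporary directory.
#' @return Named list of written file paths.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- load_config(config)
  out <- output_dir %||% config$output_dir %||% tempfile("ntcsim-run-")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  prov <- list(config_hash = config$hash, seed = config$seed)
  paths <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  oc <- run_stage("optics", optical_config(
    preset = config$optics$preset,
    lens_distance_mm = config$optics$lens_distance_mm,
    wavelength_nm = config$optics$wavelength_nm))
  rep_opt <- run_stage("optics", optics_report(oc, config$optics$etl_power_dpt))
  rep_opt$provenance <- prov
  paths$optics <- write_report_json(rep_opt, file.path(out, "optics_report.json"))

  sc <- config$scan
  zp <- if (is.null(sc$z_profile)) z_profile("flat")
  else do.call(z_profile, sc$z_profile)
  pat <- run_stage("scan", build_raster(sc$n_lines, sc$pixels_per_line,
                                        sc$line_period_ms, sc$extent_um,
                                        zprofile = zp))
  tim <- run_stage("scan", timing_report(pat))
  paths$timing <- write_report_json(c(unclass(tim), list(provenance = prov)),
                                    file.path(out, "timing_report.json"))
  wf <- run_stage("scan", emit_waveforms(pat, sc$sample_rate_hz,
                                         sc$turnaround_fraction))
  paths$waveforms <- write_waveforms_csv(wf, file.path(out, "waveforms.csv"))

  ph <- run_stage("phantom", make_phantom(
    preset = config$phantom$preset, n = config$phantom$n_emitters,
    volume_um = config$phantom$volume_um,
    seed = .stage_seed(config$seed, "phantom")))
  acq <- run_stage("render", render_scan(oc, pat, ph,
                                         seed = .stage_seed(config$seed, "render")))
  paths$render <- file.path(out, "acquired.json")
  write_report_json(list(dims = dim(acq$pixels),
                         pixel_size_um = as.list(acq$pixel_size_um),
                         total_signal = sum(acq$pixels),
                         max_signal = max(acq$pixels),
                         provenance = c(prov, acq$provenance)),
                    paths$render)
  img <- acq$pixels[1, , ]
  rb <- run_stage("analysis", radial_brightness(img))
  paths$analysis <- file.path(out, "radial_brightness.csv")
  utils::write.csv(rb, paths$analysis, row.names = FALSE)
  paths
}
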