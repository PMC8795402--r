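# Calibration of the model's free parameters against printed observables.
#
# The instrument description fixes every lens focal length and distance, but
# not the input beam size at the mirrors, the usable mirror angular range,
# the ETL current-to-power gain, or the curvature of the focal surface.
# These four are calibration parameters, anchored by default to printed
# observables of the real system:
#   * input waist       <- DL axial two-photon FWHM 3.15 um
#   * mirror half-angle <- DL square field of view 0.5 mm
#   * ETL diopter gain  <- 50 mA step -> 600 um focal shift (nTC1)
#   * focal sphere      <- least squares on the 1.2 mm / 2.5 mm field
#                          curvature values (20 um and 87 um)

.ntc_env <- new.env(parent = emptyenv())

#' Printed calibration anchors used for the default parameter set
#'
#' @return A list of observable descriptors (see [calibrate_optics()]).
#' @export
calibration_anchors <- function() {
  list(
    list(name = "axial_fwhm_um", value = 3.15, preset = "DL"),
    list(name = "square_fov_mm", value = 0.5, preset = "DL"),
    list(name = "etl_shift_um", value = 600, current_mA = 50,
         preset = "nTC1", lens_distance_mm = 5),
    list(name = "field_sagitta_um", value = 20, fov_mm = 1.2),
    list(name = "field_sagitta_um", value = 87, fov_mm = 2.5)
  )
}

.obs_config <- function(obs, params) {
  optical_config(
    preset = obs$preset %||% "DL",
    lens_distance_mm = obs$lens_distance_mm %||% 5,
    objective = objective_model(),
    mirrors = scan_mirror_model(params$max_optical_half_angle_deg %||% NA_real_),
    etl = etl_model(diopter_per_mA = params$diopter_per_mA %||% NA_real_),
    input_beam = beam_state(waist_radius_mm = params$waist_radius_mm %||% NA_real_),
    field_sphere_radius_mm = params$field_sphere_radius_mm %||% NA_real_,
    calibrated = FALSE)
}

# Which parameter an observable constrains.
.obs_param <- function(name) {
  switch(name,
    square_fov_mm = , usable_fov_mm = "max_optical_half_angle_deg",
    lateral_fwhm_um = , axial_fwhm_um = "waist_radius_mm",
    etl_shift_um = "diopter_per_mA",
    field_sagitta_um = "field_sphere_radius_mm",
    stop("unknown observable: ", name))
}

# Model prediction of one observable under a candidate parameter set.
.obs_predict <- function(obs, params) {
  cfg <- .obs_config(obs, params)
  switch(obs$name,
    square_fov_mm = ,
    usable_fov_mm = fov_diameter(cfg)$diameter_mm,
    lateral_fwhm_um = predict_psf(cfg)$lateral_fwhm_um,
    axial_fwhm_um = predict_psf(cfg)$axial_fwhm_um,
    etl_shift_um = abs(etl_current_to_focus_shift(cfg, obs$current_mA %||% 50)),
    field_sagitta_um = {
      r <- (obs$fov_mm %||% stop("field_sagitta_um observable needs fov_mm")) / 2
      R <- params$field_sphere_radius_mm
      1000 * (R - sqrt(R^2 - r^2))
    })
}

#' Calibrate free model parameters against observables
#'
#' Least-squares fit of the requested free parameters to a set of printed (or
#' synthetic) observables.  Each observable is a list with a `name`, a
#' `value`, and whatever context it needs (`preset`, `lens_distance_mm`,
#' `current_mA`, `fov_mm`).  Supported names: `square_fov_mm`,
#' `usable_fov_mm` (constrain the mirror half-angle); `lateral_fwhm_um`,
#' `axial_fwhm_um` (constrain the input beam waist); `etl_shift_um`
#' (constrains the ETL diopter gain); `field_sagitta_um` (constrains the
#' focal-sphere radius).
#'
#' The fit is deterministic: each parameter is solved by a bounded
#' one-dimensional least squares over its own observables (the model is
#' separable in these parameters), in the fixed order waist, mirror range,
#' ETL gain, sphere radius.  Residuals are reported for every supplied
#' observable; contradictory duplicates surface as nonzero residuals rather
#' than silent averaging into an apparent success.
#'
#' @param config An [optical_config()] providing the geometry (its preset is
#'   not otherwise used: each observable names its own preset).
#' @param observables List of observable descriptors (see above).
#' @param parameters Character vector of parameters to fit; default = all
#'   parameters constrained by the supplied observables.
#' @return An object of class `ntc_calibration`: list with `fitted` (named
#'   list of parameter values), `residuals` (data.frame with one row per
#'   observable) and `parameters`.
#' @export
calibrate_optics <- function(config = optical_config("DL", calibrated = FALSE),
                             observables,
                             parameters = NULL) {
  if (length(observables) == 0) stop("no observables supplied")
  if (!is.null(names(observables)) && all(nzchar(names(observables))) &&
      !is.list(observables[[1]]))
    observables <- lapply(seq_along(observables), function(i)
      list(name = names(observables)[i], value = observables[[i]]))
  obs_params <- vapply(observables, function(o) .obs_param(o$name), character(1))
  if (is.null(parameters)) parameters <- unique(obs_params)
  missing_p <- setdiff(parameters, obs_params)
  if (length(missing_p))
    stop("no observable constrains parameter(s): ",
         paste(missing_p, collapse = ", "))
  params <- list(waist_radius_mm = config$input_beam$waist_radius_mm,
                 max_optical_half_angle_deg = config$mirrors$max_optical_half_angle_deg,
                 diopter_per_mA = config$etl$diopter_per_mA,
                 field_sphere_radius_mm = config$field_sphere_radius_mm)
  # parameters that are neither supplied nor fitted fall back to the cached
  # defaults (when available) so that residuals remain computable
  if (!is.null(.ntc_env$defaults))
    for (p in names(params))
      if (is.na(params[[p]]) && !(p %in% parameters))
        params[[p]] <- .ntc_env$defaults[[p]]
  bounds <- list(waist_radius_mm = c(0.2, 3.5),
                 max_optical_half_angle_deg = c(0.05, 30),
                 diopter_per_mA = c(1e-4, 0.2),
                 field_sphere_radius_mm = c(2, 100))
  order_p <- intersect(c("waist_radius_mm", "max_optical_half_angle_deg",
                         "diopter_per_mA", "field_sphere_radius_mm"),
                       parameters)
  for (p in order_p) {
    sub <- observables[obs_params == p]
    if (p == "max_optical_half_angle_deg") {
      # mirror-limited diameter is linear in the half-angle: closed-form LS
      sv <- vapply(sub, function(o) {
        cfg <- .obs_config(o, params)
        abs(.scan_sensitivity(cfg))
      }, numeric(1))
      v <- vapply(sub, `[[`, numeric(1), "value")
      th_rad <- sum(2 * sv * v) / sum((2 * sv)^2)
      params[[p]] <- .rad2deg(th_rad)
    } else {
      sse <- function(x) {
        pp <- params; pp[[p]] <- x
        sum(vapply(sub, function(o)
          (.obs_predict(o, pp) - o$value)^2, numeric(1)))
      }
      # pre-scan a grid so the 1-D optimize starts in the right basin (the
      # ETL focus wraps through infinity at high powers, so the landscape is
      # only locally unimodal)
      grid <- seq(bounds[[p]][1], bounds[[p]][2], length.out = 61)
      gv <- vapply(grid, sse, numeric(1))
      i0 <- which.min(gv)
      lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
      params[[p]] <- stats::optimize(sse, c(lo, hi), tol = 1e-12)$minimum
    }
  }
  resid <- do.call(rbind, lapply(seq_along(observables), function(i) {
    o <- observables[[i]]
    pred <- .obs_predict(o, params)
    data.frame(name = o$name, value = o$value, predicted = pred,
               residual = pred - o$value, stringsAsFactors = FALSE)
  }))
  structure(list(fitted = params[parameters], residuals = resid,
                 parameters = parameters), class = "ntc_calibration")
}

#' @export
print.ntc_calibration <- function(x, ...) {
  cat("<ntc_calibration>\n  fitted:\n")
  for (p in names(x$fitted))
    cat(sprintf("    %-28s %.6g\n", p, x$fitted[[p]]))
  cat("  residuals:\n")
  print(x$residuals, row.names = FALSE)
  invisible(x)
}

#' Default calibrated parameter set
#'
#' Solves the four free model parameters against the printed anchors of
#' [calibration_anchors()] once per session and caches the result.
#'
#' @return Named list: `waist_radius_mm`, `max_optical_half_angle_deg`,
#'   `diopter_per_mA`, `field_sphere_radius_mm`.
#' @export
default_calibration <- function() {
  if (!is.null(.ntc_env$defaults)) return(.ntc_env$defaults)
  cal <- calibrate_optics(observables = calibration_anchors())
  .ntc_env$defaults <- cal$fitted
  .ntc_env$defaults
}
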