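#' kV-CBCT acquisition protocol
#'
#' Holds the acquisition parameters that set the tube output of a pulsed
#' cone-beam CT scan: number of acquisitions N, tube current A (mA),
#' acquisition time T_acq (s), frame rate F (frames/s) and X-ray pulse
#' duration per frame T_pulse (s), plus tube voltage and gantry-arc
#' metadata. The total tube current-time product per acquisition is
#' A x T_acq x F x T_pulse (mAs).
#'
#' Three protocols ship with the package (see [cbct_protocol()]):
#' thorax (20 mA, 60 s, 15 f/s -> 360 mAs), pelvis (80 mA, 60 s, 15 f/s ->
#' 1440 mAs) and fourD (40 mA, 120 s, 7 f/s -> 672 mAs), all with 20 ms
#' pulses at 125 kV over a full rotation in 2 degree steps.
#'
#' @param mode Label: `"thorax"`, `"pelvis"`, `"fourD"` or `"custom"`.
#' @param n_acquisitions Number of CBCT acquisitions N (integer >= 1).
#' @param tube_current_mA Tube current A in mA.
#' @param acquisition_time_s Acquisition time T_acq in seconds.
#' @param frame_rate_fps Frame rate F in frames per second.
#' @param pulse_duration_s X-ray pulse duration per frame T_pulse in
#'   seconds.
#' @param tube_voltage_kV Tube voltage (metadata, default 125).
#' @param gantry_start_deg,gantry_stop_deg,gantry_step_deg Gantry arc
#'   metadata (default full rotation, 2 degree step).
#' @return An object of class `acquisition_protocol`.
#' @export
#' @examples
#' p <- acquisition_protocol("custom", 1, 40, 120, 7, 0.020)
#' total_mas(p)  # 672
acquisition_protocol <- function(mode = "custom", n_acquisitions = 1L,
                                 tube_current_mA, acquisition_time_s,
                                 frame_rate_fps, pulse_duration_s,
                                 tube_voltage_kV = 125,
                                 gantry_start_deg = -180,
                                 gantry_stop_deg = 180,
                                 gantry_step_deg = 2) {
  vals <- c(n_acquisitions, tube_current_mA, acquisition_time_s,
            frame_rate_fps, pulse_duration_s, tube_voltage_kV)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all protocol quantities must be positive and finite",
         call. = FALSE)
  }
  if (n_acquisitions != round(n_acquisitions)) {
    stop("n_acquisitions must be an integer", call. = FALSE)
  }
  structure(
    list(mode = mode, n_acquisitions = as.integer(n_acquisitions),
         tube_current_mA = tube_current_mA,
         acquisition_time_s = acquisition_time_s,
         frame_rate_fps = frame_rate_fps,
         pulse_duration_s = pulse_duration_s,
         tube_voltage_kV = tube_voltage_kV,
         gantry_start_deg = gantry_start_deg,
         gantry_stop_deg = gantry_stop_deg,
         gantry_step_deg = gantry_step_deg),
    class = "acquisition_protocol"
  )
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat("CBCT acquisition protocol [", x$mode, "]\n", sep = "")
  cat(sprintf("  N = %d, A = %g mA, T_acq = %g s, F = %g f/s, T_pulse = %g s\n",
              x$n_acquisitions, x$tube_current_mA, x$acquisition_time_s,
              x$frame_rate_fps, x$pulse_duration_s))
  cat(sprintf("  %g kV, gantry %g..%g deg step %g; total %g mAs/acquisition\n",
              x$tube_voltage_kV, x$gantry_start_deg, x$gantry_stop_deg,
              x$gantry_step_deg, total_mas(x)))
  invisible(x)
}

#' Shipped CBCT acquisition protocols
#'
#' Returns one of the three packaged protocols (optionally with field
#' overrides), read from the editable YAML config shipped with the package.
#'
#' @param mode `"thorax"`, `"pelvis"` or `"fourD"`.
#' @param ... Named overrides for any [acquisition_protocol()] field
#'   (e.g. `n_acquisitions = 2`).
#' @param config Optional path to an alternative protocols YAML.
#' @return An `acquisition_protocol`.
#' @export
#' @examples
#' total_mas(cbct_protocol("pelvis"))  # 1440
cbct_protocol <- function(mode = c("thorax", "pelvis", "fourD"), ...,
                          config = NULL) {
  mode <- match.arg(mode)
  if (is.null(config)) {
    config <- system.file("extdata", "protocols.yaml", package = "cbctrisk",
                          mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(config)[[mode]]
  if (is.null(cfg)) stop("protocol config has no mode: ", mode, call. = FALSE)
  over <- list(...)
  cfg[names(over)] <- over
  acquisition_protocol(
    mode = mode,
    n_acquisitions = cfg$n_acquisitions,
    tube_current_mA = cfg$tube_current_mA,
    acquisition_time_s = cfg$acquisition_time_s,
    frame_rate_fps = cfg$frame_rate_fps,
    pulse_duration_s = cfg$pulse_duration_s,
    tube_voltage_kV = cfg$tube_voltage_kV %||% 125,
    gantry_start_deg = cfg$gantry_start_deg %||% -180,
    gantry_stop_deg = cfg$gantry_stop_deg %||% 180,
    gantry_step_deg = cfg$gantry_step_deg %||% 2
  )
}

#' Total tube current-time product of a protocol
#'
#' mAs per acquisition: A x T_acq x F x T_pulse. The pulse duty cycle
#' (frame rate times pulse duration) converts the wall-clock acquisition
#' time into beam-on time.
#'
#' @param protocol An [acquisition_protocol()].
#' @return Total mAs per acquisition (scalar).
#' @export
total_mas <- function(protocol) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  protocol$tube_current_mA * protocol$acquisition_time_s *
    protocol$frame_rate_fps * protocol$pulse_duration_s
}

#' Beam output calibration factor
#'
#' Relates a per-simulation dose (e.g. Monte Carlo dose per history) to the
#' measured absolute dose at reference conditions:
#' \deqn{f_{cal} = \frac{D_w}{D_{MC} \cdot A_{cal} \cdot T_{cal}}}
#' where \eqn{D_w} is the measured dose to water, \eqn{D_{MC}} the
#' simulated dose under identical geometry, and \eqn{A_{cal}}, \eqn{T_{cal}}
#' the tube current (mA) and exposure time (s) of the calibration exposure.
#' The reference exposure shipped as default is 257 mA for 0.777 s
#' (about 200 mAs). The numeric magnitude of f_cal depends on the
#' per-history normalisation of the simulated dose and is carried as
#' configuration, never recomputed from first principles.
#'
#' @param measured_dose Measured absolute dose D_w (e.g. mGy).
#' @param simulated_dose Simulated dose D_MC under the same geometry.
#' @param reference_current_mA Calibration tube current A_cal (default 257).
#' @param reference_time_s Calibration exposure time T_cal in seconds
#'   (default 0.777; 777 ms).
#' @return An object of class `beam_calibration` with elements `f_cal`,
#'   `reference_current_mA`, `reference_time_s`.
#' @export
#' @examples
#' cal <- calibration_factor(2, 1, 1, 1)  # f_cal = 2
calibration_factor <- function(measured_dose, simulated_dose,
                               reference_current_mA = 257,
                               reference_time_s = 0.777) {
  vals <- c(measured_dose, simulated_dose, reference_current_mA,
            reference_time_s)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all calibration inputs must be positive and finite",
         call. = FALSE)
  }
  structure(
    list(f_cal = measured_dose /
           (simulated_dose * reference_current_mA * reference_time_s),
         reference_current_mA = reference_current_mA,
         reference_time_s = reference_time_s),
    class = "beam_calibration"
  )
}

#' Construct a beam calibration from a known factor
#'
#' @param f_cal Calibration factor (> 0), in absolute-dose units per
#'   (simulated-dose-unit x mAs).
#' @param reference_current_mA,reference_time_s Reference exposure
#'   (defaults 257 mA, 0.777 s).
#' @return A `beam_calibration`.
#' @export
beam_calibration <- function(f_cal, reference_current_mA = 257,
                             reference_time_s = 0.777) {
  if (!is.finite(f_cal) || f_cal <= 0) {
    stop("f_cal must be positive and finite", call. = FALSE)
  }
  structure(list(f_cal = f_cal,
                 reference_current_mA = reference_current_mA,
                 reference_time_s = reference_time_s),
            class = "beam_calibration")
}

#' @export
print.beam_calibration <- function(x, ...) {
  cat(sprintf("Beam calibration: f_cal = %g (reference %g mA x %g s)\n",
              x$f_cal, x$reference_current_mA, x$reference_time_s))
  invisible(x)
}

#' Absolute dose from a simulated dose and a protocol
#'
#' Scales a per-simulation dose to the absolute dose delivered by an
#' acquisition protocol:
#' \deqn{D_{abs} = D_{MC} \cdot f_{cal} \cdot N \cdot A \cdot T_{acq}
#'   \cdot F \cdot T_{pulse}}
#' i.e. simulated dose times calibration factor times number of
#' acquisitions times total mAs. Works elementwise on scalars, vectors or
#' [dose_grid()] objects; for a grid the returned grid is relabelled to
#' mGy. The ratio of two protocols applied to the same simulated dose
#' equals the ratio of their N x total-mAs products exactly.
#'
#' @param simulated_dose Scalar, numeric array, or `dose_grid` of
#'   per-simulation dose.
#' @param calibration A `beam_calibration` (from [calibration_factor()] or
#'   [beam_calibration()]).
#' @param protocol An [acquisition_protocol()].
#' @return Same shape as `simulated_dose`, in absolute dose (mGy).
#' @export
#' @examples
#' cal <- beam_calibration(1)
#' absolute_dose(1, cal, cbct_protocol("pelvis")) /
#'   absolute_dose(1, cal, cbct_protocol("thorax"))  # 4
absolute_dose <- function(simulated_dose, calibration, protocol) {
  stopifnot(inherits(calibration, "beam_calibration"),
            inherits(protocol, "acquisition_protocol"))
  scale <- calibration$f_cal * protocol$n_acquisitions * total_mas(protocol)
  if (inherits(simulated_dose, "dose_grid")) {
    if (identical(simulated_dose$unit, "mGy")) {
      stop("simulated_dose grid is already in mGy; expected per-simulation ",
           "units", call. = FALSE)
    }
    out <- simulated_dose
    out$values <- simulated_dose$values * scale
    out$unit <- "mGy"
    return(out)
  }
  simulated_dose * scale
}
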