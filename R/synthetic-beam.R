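#' Rotational kV beam model
#'
#' Geometry and modulation of the simplified on-board-imager beam used by
#' [simulate_rotational_dose()]: source-to-isocenter distance, the
#' asymmetric field aperture at the isocenter (total 26.5 x 19.8 cm with
#' lateral half-widths x1 = 23.9 and x2 = 2.6 cm and axial half-widths
#' y1 = y2 = 9.9 cm), a half-bowtie lateral transmission profile
#' (monotone exponential modulation across the fan) and a heel-effect
#' axial gradient (monotone modulation along the tube axis), effective
#' linear attenuation coefficients per material, and a reference dose rate
#' that fixes the absolute scale per mAs.
#'
#' @param source_to_iso_cm Source-to-isocenter distance (default 100 cm;
#'   geometry metadata, rays are cast parallel to the beam axis).
#' @param field_x1_cm,field_x2_cm Lateral aperture half-widths at the
#'   isocenter (beam-right and beam-left; defaults 23.9 and 2.6).
#' @param field_y1_cm,field_y2_cm Axial aperture half-widths (inferior and
#'   superior; defaults 9.9 each).
#' @param bowtie_strength Dimensionless attenuation-exponent span of the
#'   half-bowtie across the lateral aperture (0 disables; default 0.4).
#' @param heel_strength Exponent span of the heel-effect gradient along
#'   the axial direction (0 disables; default 0.2).
#' @param mu_per_mm Named numeric vector of effective linear attenuation
#'   coefficients (1/mm) per material; defaults from
#'   [material_properties()].
#' @param absorption_weight Named numeric vector of relative
#'   energy-absorption weights per material; defaults from
#'   [material_properties()].
#' @param reference_dose_rate_mGy_per_mAs Surface dose rate at reference
#'   conditions that sets the absolute output scale (default 0.1).
#' @param half_value_layer_mm Beam-quality metadata (default 8.90 mm).
#' @return Object of class `beam_model`.
#' @export
beam_model <- function(source_to_iso_cm = 100,
                       field_x1_cm = 23.9, field_x2_cm = 2.6,
                       field_y1_cm = 9.9, field_y2_cm = 9.9,
                       bowtie_strength = 0.4, heel_strength = 0.2,
                       mu_per_mm = NULL, absorption_weight = NULL,
                       reference_dose_rate_mGy_per_mAs = 0.1,
                       half_value_layer_mm = 8.90) {
  mats <- material_properties()
  if (is.null(mu_per_mm)) {
    mu_per_mm <- stats::setNames(mats$mu_per_mm, mats$material)
  }
  if (is.null(absorption_weight)) {
    absorption_weight <- stats::setNames(mats$absorption_weight,
                                         mats$material)
  }
  if (any(mu_per_mm < 0) || any(absorption_weight < 0)) {
    stop("attenuation coefficients and absorption weights must be >= 0",
         call. = FALSE)
  }
  if (any(c(field_x1_cm, field_x2_cm, field_y1_cm, field_y2_cm) <= 0) ||
      source_to_iso_cm <= 0 || reference_dose_rate_mGy_per_mAs <= 0) {
    stop("beam geometry and dose rate must be positive", call. = FALSE)
  }
  if (bowtie_strength < 0 || heel_strength < 0) {
    stop("modulation strengths must be >= 0", call. = FALSE)
  }
  structure(
    list(source_to_iso_cm = source_to_iso_cm,
         field_x1_cm = field_x1_cm, field_x2_cm = field_x2_cm,
         field_y1_cm = field_y1_cm, field_y2_cm = field_y2_cm,
         bowtie_strength = bowtie_strength, heel_strength = heel_strength,
         mu_per_mm = mu_per_mm, absorption_weight = absorption_weight,
         reference_dose_rate_mGy_per_mAs = reference_dose_rate_mGy_per_mAs,
         half_value_layer_mm = half_value_layer_mm),
    class = "beam_model"
  )
}

#' @export
print.beam_model <- function(x, ...) {
  cat(sprintf("kV beam model: field %.1f x %.1f cm (x1=%g x2=%g y1=%g y2=%g)\n",
              x$field_x1_cm + x$field_x2_cm, x$field_y1_cm + x$field_y2_cm,
              x$field_x1_cm, x$field_x2_cm, x$field_y1_cm, x$field_y2_cm))
  cat(sprintf("  bowtie %.2f, heel %.2f, ref %.3g mGy/mAs, HVL %.2f mm\n",
              x$bowtie_strength, x$heel_strength,
              x$reference_dose_rate_mGy_per_mAs, x$half_value_layer_mm))
  invisible(x)
}

# Shift a 3-D array by whole voxels in x/y, filling with `fill`.
.shift_xy <- function(a, ox, oy, fill) {
  if (ox == 0L && oy == 0L) return(a)
  d <- dim(a)
  out <- array(fill, d)
  xs <- seq_len(d[1]) - ox
  ys <- seq_len(d[2]) - oy
  okx <- xs >= 1L & xs <= d[1]
  oky <- ys >= 1L & ys <= d[2]
  if (any(okx) && any(oky)) {
    out[which(okx), which(oky), ] <- a[xs[okx], ys[oky], , drop = FALSE]
  }
  out
}

#' Simulate rotational kV dose deposition in a phantom
#'
#' Analytic primary-beam model standing in for full Monte Carlo photon
#' transport. Per gantry angle, parallel rays are cast along the beam axis
#' through the field aperture; fluence attenuates exponentially through
#' the traversed materials (effective attenuation coefficients, no scatter
#' or buildup) and is modulated by the half-bowtie lateral profile and the
#' heel-effect axial gradient; dose deposits proportionally to local
#' fluence times the material energy-absorption weight times the angle's
#' share of the protocol mAs. The output is normalised via the beam's
#' reference dose rate and the protocol's N x total mAs, so doses are
#' exactly linear in every acquisition-protocol factor. Deterministic
#' given its inputs.
#'
#' Gantry angle 0 places the source anterior (beam travelling anterior to
#' posterior, +y); angles follow the gantry convention over
#' \[-180, 180\] degrees.
#'
#' @param phantom A [material_phantom()].
#' @param beam A [beam_model()].
#' @param protocol An [acquisition_protocol()].
#' @param angles_deg Gantry angles in degrees (non-empty, within
#'   \[-180, 180\]). Default: full rotation at the protocol's gantry step.
#' @return A [dose_grid()] in mGy, congruent with the phantom.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(c(8, 6), 6), voxel_size_mm = 10)
#' g <- simulate_rotational_dose(ph$phantom, beam_model(),
#'                               cbct_protocol("thorax"),
#'                               angles_deg = seq(-180, 170, by = 10))
simulate_rotational_dose <- function(phantom, beam, protocol,
                                     angles_deg = NULL) {
  stopifnot(inherits(phantom, "material_phantom"),
            inherits(beam, "beam_model"),
            inherits(protocol, "acquisition_protocol"))
  if (is.null(angles_deg)) {
    angles_deg <- seq(protocol$gantry_start_deg,
                      protocol$gantry_stop_deg - protocol$gantry_step_deg,
                      by = protocol$gantry_step_deg)
  }
  if (!length(angles_deg)) stop("angle list must be non-empty",
                                call. = FALSE)
  if (any(angles_deg < -180 | angles_deg > 180)) {
    stop("gantry angles must lie within [-180, 180] degrees",
         call. = FALSE)
  }
  d <- dim(phantom$labels)
  v <- phantom$voxel_size_mm
  mu <- array(beam$mu_per_mm[phantom$labels], d)
  absorb <- array(beam$absorption_weight[phantom$labels], d)
  mu_air <- beam$mu_per_mm[["air"]]
  # voxel-centre coordinates relative to the isocenter (grid centre)
  cx <- (seq_len(d[1]) - (d[1] + 1) / 2) * v[1]
  cy <- (seq_len(d[2]) - (d[2] + 1) / 2) * v[2]
  cz <- (seq_len(d[3]) - (d[3] + 1) / 2) * v[3]
  X <- matrix(cx, d[1], d[2])
  Y <- matrix(cy, d[1], d[2], byrow = TRUE)
  zax <- array(rep(cz, each = d[1] * d[2]), d)
  x1 <- beam$field_x1_cm * 10; x2 <- beam$field_x2_cm * 10
  y1 <- beam$field_y1_cm * 10; y2 <- beam$field_y2_cm * 10
  # axial (z) aperture and heel gradient are angle-independent
  z_in <- zax >= -y1 & zax <= y2
  heel <- if (beam$heel_strength > 0) {
    array(rep(exp(-beam$heel_strength * (cz + y1) / (y1 + y2)),
              each = d[1] * d[2]), d)
  } else 1
  total <- array(0, d)
  diag_len <- sqrt(sum((d[1:2] * v[1:2])^2))
  for (th in angles_deg * pi / 180) {
    dir <- c(sin(th), cos(th))            # beam travel direction (x, y)
    # march upstream in steps of one voxel along the dominant axis
    h <- min(v[1:2]) / max(abs(dir), 1e-9)
    nstep <- ceiling(diag_len / h)
    # radiological path depends on z through organ placement -> 3-D
    path <- array(0, d)
    for (k in seq_len(nstep)) {
      ox <- as.integer(round(k * h * dir[1] / v[1]))
      oy <- as.integer(round(k * h * dir[2] / v[2]))
      path <- path + .shift_xy(mu, ox, oy, mu_air)
    }
    path <- path * h
    # lateral fan coordinate: component of (x, y) along the beam-right axis
    lat <- X * cos(th) - Y * sin(th)
    lat_in <- lat >= -x2 & lat <= x1
    bowtie <- if (beam$bowtie_strength > 0) {
      exp(-beam$bowtie_strength * (lat + x2) / (x1 + x2))
    } else 1
    aperture2 <- lat_in * bowtie          # matrix over (x, y)
    fl <- exp(-path) * as.vector(aperture2)  # recycles over z
    total <- total + fl
  }
  total <- total * z_in * heel * absorb
  scale <- beam$reference_dose_rate_mGy_per_mAs *
    protocol$n_acquisitions * total_mas(protocol) / length(angles_deg)
  dose_grid(total * scale, voxel_size_mm = v, origin_mm = phantom$origin_mm,
            unit = "mGy")
}
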