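#' Body mass index and WHO class
#'
#' BMI = weight / (height/100)^2 in kg/m^2, classified by the WHO cut
#' points: underweight < 18.50, normal-weight 18.50-24.99, overweight
#' >= 25.00 (each class floor inclusive).
#'
#' @param height_cm Height in cm (> 0).
#' @param weight_kg Weight in kg (> 0).
#' @return data.frame with columns `bmi` (kg/m^2) and `class` (factor
#'   underweight/normal/overweight), one row per input.
#' @export
#' @examples
#' bmi_class(147.3, 49.2)  # 22.7, normal
bmi_class <- function(height_cm, weight_kg) {
  if (any(!is.finite(height_cm)) || any(!is.finite(weight_kg)) ||
      any(height_cm <= 0) || any(weight_kg <= 0)) {
    stop("height and weight must be positive and finite", call. = FALSE)
  }
  bmi <- weight_kg / (height_cm / 100)^2
  cls <- cut(bmi, breaks = c(-Inf, 18.50, 25.00, Inf),
             labels = c("underweight", "normal", "overweight"),
             right = FALSE)
  data.frame(bmi = bmi, class = cls)
}

#' Synthetic body-phantom specification
#'
#' Describes a body as an elliptic cylinder (torso) with ellipsoidal organs
#' placed inside it. A stand-in for a planning-CT-derived phantom: organ
#' positions and radii are parameterizable so that voxelized organ volumes
#' can span realistic ranges.
#'
#' @param body_radii_cm Semi-axes `c(rx, ry)` of the elliptic cross-section
#'   in cm (x lateral, y anterior-posterior).
#' @param length_cm Cylinder length (z, inferior-superior) in cm.
#' @param organs List of organ descriptors, each a list with `organ_id`,
#'   `center_cm` (xyz offset from the body centre, cm), `radii_cm` (xyz
#'   ellipsoid semi-axes, cm) and optional `material` (default
#'   `"tissue"`).
#' @param sex `"male"` or `"female"`.
#' @param height_cm,weight_kg Patient anthropometry carried as metadata.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(body_radii_cm, length_cm, organs = list(),
                         sex = "female", height_cm = NA_real_,
                         weight_kg = NA_real_) {
  body_radii_cm <- rep_len(as.numeric(body_radii_cm), 2L)
  if (any(body_radii_cm <= 0) || length_cm <= 0) {
    stop("body radii and length must be positive", call. = FALSE)
  }
  for (o in organs) {
    if (is.null(o$organ_id) || is.null(o$center_cm) || is.null(o$radii_cm)) {
      stop("each organ needs organ_id, center_cm and radii_cm",
           call. = FALSE)
    }
    if (any(o$radii_cm <= 0)) {
      stop("organ radii must be positive: ", o$organ_id, call. = FALSE)
    }
  }
  structure(
    list(body_radii_cm = body_radii_cm, length_cm = length_cm,
         organs = organs, sex = match.arg(sex, c("male", "female")),
         height_cm = height_cm, weight_kg = weight_kg),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("Phantom spec: body %g x %g cm semi-axes, length %g cm, %d organ(s)\n",
              x$body_radii_cm[1], x$body_radii_cm[2], x$length_cm,
              length(x$organs)))
  invisible(x)
}

#' Voxelize a phantom specification
#'
#' Rasterizes the body cylinder and organ ellipsoids onto a regular voxel
#' lattice (default 2.5 mm isotropic), yielding a [material_phantom()] and
#' a congruent [structure_set()] with one mask per organ. The grid extends
#' a configurable air margin beyond the body so rotational beams clear the
#' surface. An organ whose ellipsoid protrudes outside the body cylinder
#' is an error.
#'
#' @param spec A [phantom_spec()].
#' @param voxel_size_mm Isotropic voxel size in mm (default 2.5).
#' @param margin_cm Air margin around the body (default 2 cm).
#' @return List with elements `phantom` ([material_phantom()]) and
#'   `structures` ([structure_set()]).
#' @export
#' @examples
#' spec <- phantom_spec(c(10, 8), 10, list(
#'   list(organ_id = "liver", center_cm = c(3, 0, 0), radii_cm = c(4, 4, 3))))
#' ph <- generate_phantom(spec, voxel_size_mm = 5)
generate_phantom <- function(spec, voxel_size_mm = 2.5, margin_cm = 2) {
  stopifnot(inherits(spec, "phantom_spec"))
  v <- voxel_size_mm
  rx <- spec$body_radii_cm[1] * 10  # mm
  ry <- spec$body_radii_cm[2] * 10
  hz <- spec$length_cm * 10 / 2
  m <- margin_cm * 10
  nx <- ceiling(2 * (rx + m) / v); ny <- ceiling(2 * (ry + m) / v)
  nz <- ceiling(2 * hz / v)
  # voxel-centre coordinates, body centred on the grid
  cx <- (seq_len(nx) - (nx + 1) / 2) * v
  cy <- (seq_len(ny) - (ny + 1) / 2) * v
  cz <- (seq_len(nz) - (nz + 1) / 2) * v
  X <- array(rep(cx, times = ny * nz), c(nx, ny, nz))
  Y <- array(rep(rep(cy, each = nx), times = nz), c(nx, ny, nz))
  Z <- array(rep(cz, each = nx * ny), c(nx, ny, nz))
  body <- (X / rx)^2 + (Y / ry)^2 <= 1
  labels <- array("air", c(nx, ny, nz))
  labels[body] <- "tissue"
  masks <- list()
  for (o in spec$organs) {
    ctr <- o$center_cm * 10
    rad <- rep_len(o$radii_cm * 10, 3L)
    mk <- ((X - ctr[1]) / rad[1])^2 + ((Y - ctr[2]) / rad[2])^2 +
      ((Z - ctr[3]) / rad[3])^2 <= 1
    if (!any(mk)) {
      stop("organ '", o$organ_id, "' voxelizes to an empty mask",
           call. = FALSE)
    }
    if (any(mk & !body)) {
      stop("organ '", o$organ_id, "' extends outside the body",
           call. = FALSE)
    }
    labels[mk] <- o$material %||% "tissue"
    masks[[o$organ_id]] <- mk
  }
  list(
    phantom = material_phantom(labels, voxel_size_mm = rep(v, 3),
                               origin_mm = c(cx[1], cy[1], cz[1])),
    structures = structure_set(masks)
  )
}

#' Synthetic patient cohort specification
#'
#' Demographic model for a simulated radiotherapy cohort: heights are drawn
#' from a truncated normal, BMI from a truncated normal, weight derived as
#' BMI x (height/100)^2, and sex from a Bernoulli draw. Shipped defaults
#' emulate the demographic structure of a 15-patient lung-cancer cohort
#' (height 154.6 +/- 10.3 cm, BMI 21.7 +/- 3.2 spanning 16.3-25.8, 43%
#' male) and a 15-patient liver-cancer cohort (height 159.0 +/- 7.7 cm,
#' BMI 22.5 +/- 4.4 spanning 17.4-32.1, 80% male), so sampled BMIs cover
#' all three WHO classes.
#'
#' @param n_patients Number of patients (>= 1; default 15).
#' @param site `"lung"` or `"liver"`.
#' @param seed Mandatory integer random seed.
#' @param male_fraction Probability a patient is male.
#' @param height_mean_cm,height_sd_cm Height distribution (cm).
#' @param bmi_mean,bmi_sd BMI distribution (kg/m^2).
#' @param bmi_range Truncation interval for BMI.
#' @param height_range Truncation interval for height (cm).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 15L, site = c("lung", "liver"), seed,
                        male_fraction = NULL,
                        height_mean_cm = NULL, height_sd_cm = NULL,
                        bmi_mean = NULL, bmi_sd = NULL,
                        bmi_range = NULL, height_range = c(130, 190)) {
  site <- match.arg(site)
  if (missing(seed)) stop("cohort_spec requires an explicit seed",
                          call. = FALSE)
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  def <- if (site == "lung") {
    list(male_fraction = 0.43, height_mean_cm = 154.6, height_sd_cm = 10.3,
         bmi_mean = 21.7, bmi_sd = 3.2, bmi_range = c(14, 29))
  } else {
    list(male_fraction = 0.80, height_mean_cm = 159.0, height_sd_cm = 7.7,
         bmi_mean = 22.5, bmi_sd = 4.4, bmi_range = c(15, 35))
  }
  out <- list(
    n_patients = as.integer(n_patients), site = site,
    seed = as.integer(seed),
    male_fraction = male_fraction %||% def$male_fraction,
    height_mean_cm = height_mean_cm %||% def$height_mean_cm,
    height_sd_cm = height_sd_cm %||% def$height_sd_cm,
    bmi_mean = bmi_mean %||% def$bmi_mean,
    bmi_sd = bmi_sd %||% def$bmi_sd,
    bmi_range = bmi_range %||% def$bmi_range,
    height_range = height_range
  )
  if (out$height_sd_cm <= 0 || out$bmi_sd <= 0 ||
      diff(out$bmi_range) <= 0 || diff(out$height_range) <= 0 ||
      out$male_fraction < 0 || out$male_fraction > 1) {
    stop("impossible cohort distribution parameters", call. = FALSE)
  }
  structure(out, class = "cohort_spec")
}

# Truncated-normal sampling by rejection; bounds are wide so this is cheap.
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lo & x <= hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Sample a synthetic patient cohort
#'
#' Draws the cohort described by a [cohort_spec()]: per patient, sex,
#' height, weight (via BMI), WHO BMI class, and a [phantom_spec()] whose
#' torso dimensions follow from the anthropometry (torso length 30% of
#' height; torso volume 40% of body mass at unit density; lateral-to-AP
#' semi-axis ratio 1.4) with a site-specific organ template scaled to the
#' body. Fully reproducible given the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return data.frame of class `synthetic_cohort` with columns `patient`,
#'   `sex`, `height_cm`, `weight_kg`, `bmi`, `bmi_class`, `site`, and a
#'   `phantom` list-column of [phantom_spec()] objects.
#' @export
#' @examples
#' cohort <- sample_cohort(cohort_spec(5, "lung", seed = 1))
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  n <- spec$n_patients
  sex <- ifelse(stats::runif(n) < spec$male_fraction, "male", "female")
  height <- .rtruncnorm(n, spec$height_mean_cm, spec$height_sd_cm,
                        spec$height_range[1], spec$height_range[2])
  bmi <- .rtruncnorm(n, spec$bmi_mean, spec$bmi_sd,
                     spec$bmi_range[1], spec$bmi_range[2])
  weight <- bmi * (height / 100)^2
  cls <- bmi_class(height, weight)
  phantoms <- lapply(seq_len(n), function(i) {
    body_phantom_spec(height[i], weight[i], sex[i], site = spec$site)
  })
  out <- data.frame(patient = seq_len(n), sex = sex,
                    height_cm = round(height, 1),
                    weight_kg = round(weight, 1),
                    bmi = round(cls$bmi, 1),
                    bmi_class = as.character(cls$class),
                    site = spec$site, stringsAsFactors = FALSE)
  out$phantom <- phantoms
  class(out) <- c("synthetic_cohort", "data.frame")
  out
}

#' Derive a body phantom spec from anthropometry
#'
#' Torso modelled as an elliptic cylinder of length 0.30 x height whose
#' volume is 40% of body mass at density 1 g/cm^3, with lateral semi-axis
#' 1.4 x the anterior-posterior one. Organ templates (positions and radii
#' relative to the body) are site-specific and scale with the body
#' semi-axes so that larger patients carry proportionally placed organs.
#'
#' @param height_cm,weight_kg Anthropometry.
#' @param sex `"male"` or `"female"`.
#' @param site `"lung"` or `"liver"` organ template.
#' @return A [phantom_spec()].
#' @export
body_phantom_spec <- function(height_cm, weight_kg, sex = "female",
                              site = c("lung", "liver")) {
  site <- match.arg(site)
  L <- 0.30 * height_cm
  vol <- 0.40 * weight_kg * 1000  # cm^3 at 1 g/cm^3
  ry <- sqrt(vol / (pi * 1.4 * L))
  rx <- 1.4 * ry
  # organ layout as fractions of the body semi-axes / length
  f <- function(id, cx, cy, cz, sx, sy, sz, material = "tissue") {
    list(organ_id = id,
         center_cm = c(cx * rx, cy * ry, cz * L / 2),
         radii_cm = c(sx * rx, sy * ry, sz * L / 2),
         material = material)
  }
  organs <- if (site == "lung") {
    list(
      f("lung", 0.00, -0.15, 0.35, 0.62, 0.52, 0.42, material = "lung"),
      f("heart", -0.12, 0.10, 0.12, 0.26, 0.24, 0.16),
      f("esophagus", 0.02, 0.28, 0.30, 0.06, 0.06, 0.40),
      f("liver", 0.30, 0.10, -0.30, 0.40, 0.42, 0.24),
      f("stomach", -0.28, 0.12, -0.35, 0.22, 0.22, 0.16),
      f("bone_marrow", 0.00, 0.60, 0.00, 0.07, 0.07, 0.85,
        material = "bone")
    )
  } else {
    list(
      f("liver", 0.28, 0.05, 0.25, 0.44, 0.46, 0.30),
      f("stomach", -0.28, 0.10, 0.22, 0.24, 0.24, 0.18),
      f("kidney", 0.35, 0.45, -0.25, 0.14, 0.16, 0.18),
      f("spleen", -0.45, 0.30, 0.18, 0.14, 0.16, 0.14),
      f("pancreas", -0.05, 0.25, 0.02, 0.24, 0.10, 0.08),
      f("bone_marrow", 0.00, 0.60, 0.00, 0.07, 0.07, 0.85,
        material = "bone")
    )
  }
  phantom_spec(c(rx, ry), L, organs, sex = sex, height_cm = height_cm,
               weight_kg = weight_kg)
}

#' Write a cohort manifest as tab-delimited text
#'
#' Mirrors a patient-characteristics table: patient, sex, height, weight,
#' BMI, BMI class, site.
#'
#' @param cohort A `synthetic_cohort` from [sample_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_manifest <- function(cohort, path) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  df <- as.data.frame(cohort)
  df$phantom <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
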