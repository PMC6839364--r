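#' Voxel dose grid
#'
#' A 3-D scalar dose field on a regular voxel lattice. The axis convention
#' is voxel-centered, 0-based indexing with axes x (patient right), y
#' (anterior to posterior) and z (inferior to superior); the default voxel
#' size is 2.5 mm isotropic.
#'
#' @param values Numeric 3-D array of non-negative dose values.
#' @param voxel_size_mm Voxel size triplet in mm (default 2.5 isotropic).
#' @param origin_mm Position of the centre of voxel (0,0,0) in mm.
#' @param unit Dose unit tag: `"mGy"`, `"per_history"` or `"relative"`.
#' @return Object of class `dose_grid`.
#' @export
#' @examples
#' g <- dose_grid(array(1, c(4, 4, 4)))
dose_grid <- function(values, voxel_size_mm = c(2.5, 2.5, 2.5),
                      origin_mm = c(0, 0, 0), unit = "mGy") {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("values must be a 3-D array", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("dose values must be finite and non-negative", call. = FALSE)
  }
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(voxel_size_mm <= 0)) stop("voxel_size_mm must be > 0", call. = FALSE)
  unit <- match.arg(unit, c("mGy", "per_history", "relative"))
  structure(
    list(values = values, voxel_size_mm = voxel_size_mm,
         origin_mm = rep_len(as.numeric(origin_mm), 3L), unit = unit,
         axes = "x:right y:ant->post z:inf->sup"),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Dose grid %dx%dx%d voxels (%g x %g x %g mm), unit %s\n",
              d[1], d[2], d[3], x$voxel_size_mm[1], x$voxel_size_mm[2],
              x$voxel_size_mm[3], x$unit))
  cat(sprintf("  range [%g, %g], origin (%g, %g, %g) mm\n",
              min(x$values), max(x$values), x$origin_mm[1], x$origin_mm[2],
              x$origin_mm[3]))
  invisible(x)
}

#' Organ mask set congruent with a dose grid
#'
#' A named list of logical voxel masks, one per organ, all with the same
#' dimensions.
#'
#' @param masks Named list of logical 3-D arrays; names are organ ids.
#' @return Object of class `structure_set`.
#' @export
structure_set <- function(masks) {
  if (!length(masks) || is.null(names(masks)) || any(names(masks) == "")) {
    masks <- as.list(masks)
    if (length(masks) && (is.null(names(masks)) || any(names(masks) == "")))
      stop("masks must be a named list", call. = FALSE)
  }
  dims <- lapply(masks, dim)
  if (length(masks)) {
    ref <- dims[[1]]
    for (nm in names(masks)) {
      m <- masks[[nm]]
      if (!is.logical(m) || length(dim(m)) != 3L || !identical(dim(m), ref)) {
        stop("mask '", nm, "' must be a logical 3-D array congruent with ",
             "the others", call. = FALSE)
      }
      if (!any(m)) stop("mask '", nm, "' is empty", call. = FALSE)
    }
  }
  structure(masks, class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat("Structure set with", length(x), "organ mask(s)\n")
  for (nm in names(x)) cat(sprintf("  %-22s %d voxels\n", nm, sum(x[[nm]])))
  invisible(x)
}

#' Mean organ dose over a mask
#'
#' Arithmetic mean of the dose-grid values over the voxels of an organ
#' mask. This is the \eqn{D_{T,R}} extraction step between a simulated (or
#' imported) dose distribution and the effective-dose / EAR computations.
#'
#' @param grid A [dose_grid()].
#' @param mask Logical 3-D array congruent with `grid`, or the name of an
#'   organ when `structures` is given.
#' @param structures Optional [structure_set()] to resolve `mask` by name.
#' @return Mean dose over the mask (same unit as the grid).
#' @export
#' @examples
#' g <- dose_grid(array(5, c(3, 3, 3)))
#' m <- array(TRUE, c(3, 3, 3))
#' mean_organ_dose(g, m)  # 5
mean_organ_dose <- function(grid, mask, structures = NULL) {
  stopifnot(inherits(grid, "dose_grid"))
  organ <- "organ"
  if (is.character(mask)) {
    organ <- mask
    if (is.null(structures) || is.null(structures[[organ]])) {
      stop("no mask for organ '", organ, "' in structures", call. = FALSE)
    }
    mask <- structures[[organ]]
  }
  if (!identical(dim(mask), dim(grid$values))) {
    stop("mask for '", organ, "' is not congruent with the dose grid",
         call. = FALSE)
  }
  n <- sum(mask)
  if (n == 0L) {
    stop("empty mask for organ '", organ, "'", call. = FALSE)
  }
  sum(grid$values[mask]) / n
}

#' Extract a full organ dose table from a grid and structure set
#'
#' @param grid A [dose_grid()] in mGy.
#' @param structures A [structure_set()].
#' @return An [organ_dose_table()] with volumes from voxel counts.
#' @export
extract_organ_doses <- function(grid, structures) {
  stopifnot(inherits(structures, "structure_set"))
  voxel_cm3 <- prod(grid$voxel_size_mm) / 1000
  organ_dose_table(
    names(structures),
    vapply(names(structures), function(nm) mean_organ_dose(grid, nm,
                                                           structures),
           numeric(1)),
    volume_cm3 = vapply(structures, sum, numeric(1)) * voxel_cm3
  )
}

#' Material phantom
#'
#' Voxel phantom of material labels over \{air, lung, tissue, bone\} with a
#' congruent mass-density field (g/cm^3).
#'
#' @param labels Character (or factor) 3-D array over the four material
#'   names.
#' @param mass_density_g_cm3 Optional numeric 3-D array of densities;
#'   defaults to the per-material nominal densities.
#' @param voxel_size_mm Voxel size triplet (mm).
#' @param origin_mm Origin (mm).
#' @return Object of class `material_phantom`.
#' @export
material_phantom <- function(labels, mass_density_g_cm3 = NULL,
                             voxel_size_mm = c(2.5, 2.5, 2.5),
                             origin_mm = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop("labels must be a 3-D array", call. = FALSE)
  }
  mats <- material_properties()
  bad <- setdiff(unique(as.vector(labels)), mats$material)
  if (length(bad)) {
    stop("unknown material label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(mass_density_g_cm3)) {
    mass_density_g_cm3 <- array(
      mats$density_g_cm3[match(as.vector(labels), mats$material)],
      dim = dim(labels))
  }
  if (!identical(dim(mass_density_g_cm3), dim(labels)) ||
      any(mass_density_g_cm3 <= 0)) {
    stop("mass density must be positive and congruent with labels",
         call. = FALSE)
  }
  structure(
    list(labels = labels, mass_density_g_cm3 = mass_density_g_cm3,
         voxel_size_mm = rep_len(as.numeric(voxel_size_mm), 3L),
         origin_mm = rep_len(as.numeric(origin_mm), 3L)),
    class = "material_phantom"
  )
}

#' @export
print.material_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("Material phantom %dx%dx%d voxels (%g mm)\n", d[1], d[2], d[3],
              x$voxel_size_mm[1]))
  print(table(x$labels))
  invisible(x)
}

#' Material property defaults
#'
#' Nominal mass density, effective linear attenuation coefficient at 125 kV
#' beam quality, and relative energy-absorption weight for the four phantom
#' materials. The attenuation coefficients are configuration defaults for
#' the simplified primary-beam simulator, not measured beam data.
#'
#' @return data.frame with columns `material`, `density_g_cm3`,
#'   `mu_per_mm`, `absorption_weight`.
#' @export
material_properties <- function() {
  data.frame(
    material = c("air", "lung", "tissue", "bone"),
    density_g_cm3 = c(0.0012, 0.26, 1.00, 1.85),
    mu_per_mm = c(0.00002, 0.0055, 0.021, 0.055),
    absorption_weight = c(0.0, 0.26, 1.00, 2.50),
    stringsAsFactors = FALSE
  )
}

#' Label CT numbers as materials
#'
#' Piecewise-constant conversion of a CT-number field into the four-material
#' phantom via three strictly increasing thresholds (air/lung, lung/tissue,
#' tissue/bone cut points, in HU). A value exactly at a cut point is
#' assigned to the upper class.
#'
#' @param ct_numbers Numeric 3-D array of CT numbers (HU).
#' @param thresholds Strictly increasing numeric triplet of cut points
#'   (default `c(-850, -200, 250)` HU).
#' @param voxel_size_mm,origin_mm Grid geometry passed through.
#' @return A [material_phantom()].
#' @export
#' @examples
#' ct <- array(c(-1000, -500, 0, 1000), c(4, 1, 1))
#' label_materials(ct)$labels[, 1, 1]
label_materials <- function(ct_numbers, thresholds = c(-850, -200, 250),
                            voxel_size_mm = c(2.5, 2.5, 2.5),
                            origin_mm = c(0, 0, 0)) {
  if (length(thresholds) != 3L || any(diff(thresholds) <= 0)) {
    stop("thresholds must be three strictly increasing cut points",
         call. = FALSE)
  }
  mats <- c("air", "lung", "tissue", "bone")
  # findInterval: value == cut point lands in the upper class
  idx <- findInterval(as.vector(ct_numbers), thresholds) + 1L
  labels <- array(mats[idx], dim = dim(ct_numbers))
  material_phantom(labels, voxel_size_mm = voxel_size_mm,
                   origin_mm = origin_mm)
}

#' Insert a treatment-couch slab into a phantom
#'
#' Relabels a posterior slab of voxels as couch material (the couch top is
#' modelled as one or two homogeneous slabs spanning the grid laterally and
#' longitudinally). Body voxels are untouched; a couch placed over
#' non-air voxels is an error.
#'
#' @param phantom A [material_phantom()].
#' @param y_range Integer range `c(from, to)` of y-indices (posterior
#'   voxel rows) occupied by the couch; `from > to` (empty range) leaves
#'   the phantom unchanged.
#' @param material Couch material label (default `"tissue"`; the carbon
#'   shell / foam core pair maps onto tissue and lung).
#' @return The phantom with couch voxels relabelled.
#' @export
attach_couch <- function(phantom, y_range, material = "tissue") {
  stopifnot(inherits(phantom, "material_phantom"))
  material <- match.arg(material, material_properties()$material)
  if (y_range[1] > y_range[2]) return(phantom)  # zero-thickness couch
  d <- dim(phantom$labels)
  if (y_range[1] < 1L || y_range[2] > d[2]) {
    stop("couch slab outside grid extent", call. = FALSE)
  }
  sel <- phantom$labels[, y_range[1]:y_range[2], , drop = FALSE]
  if (any(sel != "air")) {
    stop("couch slab overlaps body voxels", call. = FALSE)
  }
  phantom$labels[, y_range[1]:y_range[2], ] <- material
  mats <- material_properties()
  phantom$mass_density_g_cm3[, y_range[1]:y_range[2], ] <-
    mats$density_g_cm3[mats$material == material]
  phantom
}
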