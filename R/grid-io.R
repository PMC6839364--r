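# Self-describing text container for dose grids.
#
# Two dialects share one header layout:
#  * portable    - full-precision floats; round-trips are bit-exact.
#  - rtdose-like - non-negative 16-bit integers plus a per-file
#    dose-scaling factor to mGy, following the DICOM RTDOSE
#    DoseGridScaling convention; quantization error <= scaling/2
#    (= max/2^16 when the integer range is fully used).

.GRID_MAGIC <- "cbctgrid 1"

#' Write a dose grid to a portable or RTDOSE-like text container
#'
#' @param grid A [dose_grid()].
#' @param path Output path.
#' @param dialect `"portable"` (lossless) or `"rtdose-like"` (16-bit
#'   unsigned integers with a per-file dose-scaling factor, mirroring the
#'   DICOM RTDOSE DoseGridScaling convention).
#' @return `path`, invisibly.
#' @export
#' @examples
#' g <- dose_grid(array(runif(8), c(2, 2, 2)))
#' f <- tempfile(fileext = ".grid")
#' write_grid(g, f)
#' all.equal(read_grid(f)$values, g$values)
write_grid <- function(grid, path, dialect = c("portable", "rtdose-like")) {
  stopifnot(inherits(grid, "dose_grid"))
  dialect <- match.arg(dialect)
  d <- dim(grid$values)
  head <- c(
    .GRID_MAGIC,
    paste("dialect:", dialect),
    paste("dims:", paste(d, collapse = " ")),
    paste("voxel_size_mm:", paste(sprintf("%.17g", grid$voxel_size_mm),
                                  collapse = " ")),
    paste("origin_mm:", paste(sprintf("%.17g", grid$origin_mm),
                              collapse = " ")),
    paste("unit:", grid$unit)
  )
  if (dialect == "portable") {
    body <- sprintf("%.17g", as.vector(grid$values))
  } else {
    m <- max(grid$values)
    scaling <- if (m > 0) m / 65535 else 1
    head <- c(head, paste("dose_grid_scaling:", sprintf("%.17g", scaling)))
    body <- sprintf("%d", as.integer(round(as.vector(grid$values) / scaling)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(head, "values:"), con)
  # 8 values per line keeps files diffable without bloating them
  writeLines(vapply(split(body, ceiling(seq_along(body) / 8)),
                    paste, character(1), collapse = " "), con)
  invisible(path)
}

#' Read a dose grid from a portable or RTDOSE-like text container
#'
#' @param path Path written by [write_grid()].
#' @return A [dose_grid()]; RTDOSE-like files are rescaled back to dose
#'   units via the stored dose-scaling factor.
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines) || lines[1] != .GRID_MAGIC) {
    stop("corrupt grid header: missing '", .GRID_MAGIC, "' magic",
         call. = FALSE)
  }
  sep <- match("values:", lines)
  if (is.na(sep)) stop("corrupt grid header: no values section",
                       call. = FALSE)
  kv <- lines[2:(sep - 1)]
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  get <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) stop("corrupt grid header: missing key '", k, "'",
                       call. = FALSE)
    vals[i]
  }
  dialect <- get("dialect")
  dims <- as.integer(strsplit(get("dims"), " +")[[1]])
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L)) {
    stop("corrupt grid header: bad dims", call. = FALSE)
  }
  x <- as.numeric(scan(text = paste(lines[(sep + 1):length(lines)],
                                    collapse = " "), quiet = TRUE))
  if (length(x) != prod(dims)) {
    stop("grid shape mismatch: header promises ", prod(dims),
         " values, file has ", length(x), call. = FALSE)
  }
  if (dialect == "rtdose-like") {
    scaling <- as.numeric(get("dose_grid_scaling"))
    if (!is.finite(scaling) || scaling <= 0) {
      stop("negative or invalid dose_grid_scaling", call. = FALSE)
    }
    if (any(x < 0) || any(x != round(x))) {
      stop("rtdose-like dialect requires non-negative integer values",
           call. = FALSE)
    }
    x <- x * scaling
  } else if (dialect != "portable") {
    stop("unknown grid dialect: ", dialect, call. = FALSE)
  }
  dose_grid(array(x, dim = dims),
            voxel_size_mm = as.numeric(strsplit(get("voxel_size_mm"),
                                                " +")[[1]]),
            origin_mm = as.numeric(strsplit(get("origin_mm"), " +")[[1]]),
            unit = get("unit"))
}

#' Write a structure set as a label volume
#'
#' Encodes disjoint organ masks as one integer label volume (0 =
#' background) in the portable container, with the organ legend in the
#' header-adjacent legend line.
#'
#' @param structures A [structure_set()] of pairwise disjoint masks.
#' @param path Output path.
#' @param voxel_size_mm,origin_mm Grid geometry.
#' @return `path`, invisibly.
#' @export
write_structure_set <- function(structures, path,
                                voxel_size_mm = c(2.5, 2.5, 2.5),
                                origin_mm = c(0, 0, 0)) {
  stopifnot(inherits(structures, "structure_set"))
  d <- dim(structures[[1]])
  lab <- array(0L, d)
  for (i in seq_along(structures)) {
    m <- structures[[i]]
    if (any(lab[m] != 0L)) {
      stop("masks overlap; label-volume encoding needs disjoint masks",
           call. = FALSE)
    }
    lab[m] <- i
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(.GRID_MAGIC,
               "dialect: labels",
               paste("dims:", paste(d, collapse = " ")),
               paste("voxel_size_mm:", paste(sprintf("%.17g", voxel_size_mm),
                                             collapse = " ")),
               paste("origin_mm:", paste(sprintf("%.17g", origin_mm),
                                         collapse = " ")),
               paste("legend:", paste(names(structures), collapse = " ")),
               "values:"), con)
  body <- sprintf("%d", as.vector(lab))
  writeLines(vapply(split(body, ceiling(seq_along(body) / 16)),
                    paste, character(1), collapse = " "), con)
  invisible(path)
}

#' Read a structure set written by [write_structure_set()]
#'
#' @param path Path to the label-volume container.
#' @return A [structure_set()].
#' @export
read_structure_set <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != .GRID_MAGIC) {
    stop("corrupt structure header", call. = FALSE)
  }
  sep <- match("values:", lines)
  kv <- lines[2:(sep - 1)]
  get <- function(k) {
    i <- grep(paste0("^", k, ":"), kv)
    if (!length(i)) stop("corrupt structure header: missing ", k,
                         call. = FALSE)
    trimws(sub("^[^:]*:", "", kv[i[1]]))
  }
  dims <- as.integer(strsplit(get("dims"), " +")[[1]])
  legend <- strsplit(get("legend"), " +")[[1]]
  x <- as.integer(scan(text = paste(lines[(sep + 1):length(lines)],
                                    collapse = " "), quiet = TRUE))
  if (length(x) != prod(dims)) stop("structure shape mismatch",
                                    call. = FALSE)
  lab <- array(x, dims)
  structure_set(stats::setNames(
    lapply(seq_along(legend), function(i) lab == i), legend))
}
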