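#' Organ mean-dose table
#'
#' Container for per-organ mean absorbed doses (the \eqn{D_{T,R}} entering
#' the effective-dose and EAR calculations). A thin data.frame subclass with
#' validated columns `organ_id`, `mean_dose_mGy` and optionally `volume_cm3`.
#'
#' @param organ_id Character vector of organ ids (see [organ_registry()];
#'   common synonyms are accepted).
#' @param mean_dose_mGy Numeric vector of non-negative mean absorbed doses
#'   in mGy. For photon fields with radiation weighting factor 1 these are
#'   numerically equal to equivalent doses in mSv.
#' @param volume_cm3 Optional numeric vector of organ volumes (cm^3).
#' @return An object of class `organ_dose_table` (also a data.frame).
#' @export
#' @examples
#' organ_dose_table(c("lung", "liver"), c(14.3, 9.1))
organ_dose_table <- function(organ_id, mean_dose_mGy, volume_cm3 = NULL) {
  organ_id <- normalize_organ_id(organ_id)
  mean_dose_mGy <- as.numeric(mean_dose_mGy)
  if (length(organ_id) != length(mean_dose_mGy)) {
    stop("organ_id and mean_dose_mGy must have equal length", call. = FALSE)
  }
  if (anyDuplicated(organ_id)) {
    stop("duplicate organ id(s): ",
         paste(unique(organ_id[duplicated(organ_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(mean_dose_mGy)) || any(mean_dose_mGy < 0)) {
    stop("mean_dose_mGy must be finite and non-negative", call. = FALSE)
  }
  df <- data.frame(organ_id = organ_id, mean_dose_mGy = mean_dose_mGy,
                   stringsAsFactors = FALSE)
  if (!is.null(volume_cm3)) {
    stopifnot(length(volume_cm3) == nrow(df))
    df$volume_cm3 <- as.numeric(volume_cm3)
  }
  class(df) <- c("organ_dose_table", "data.frame")
  df
}

#' @export
print.organ_dose_table <- function(x, ...) {
  cat("Organ mean-dose table (", nrow(x), " organs)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Read an organ dose table from delimited text
#'
#' Expects columns `organ_id`, `mean_dose_mGy` and optionally `volume_cm3`,
#' tab- or comma-separated (autodetected from the header line).
#'
#' @param path Path to the delimited text file.
#' @return An [organ_dose_table()].
#' @export
read_organ_dose_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = TRUE)
  need <- c("organ_id", "mean_dose_mGy")
  if (!all(need %in% names(df))) {
    stop("dose table must have columns organ_id, mean_dose_mGy", call. = FALSE)
  }
  organ_dose_table(df$organ_id, df$mean_dose_mGy, df$volume_cm3)
}

#' Write an organ dose table as tab-delimited text
#'
#' @param x An [organ_dose_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_organ_dose_table <- function(x, path) {
  stopifnot(inherits(x, "organ_dose_table"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
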