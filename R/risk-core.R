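#' ICRP-103 tissue weighting scheme
#'
#' Builds the tissue weighting scheme used to turn organ equivalent doses
#' into an effective dose. The default is the full ICRP publication 103
#' scheme: fourteen explicitly weighted tissues (weights summing to 0.88)
#' plus a collective remainder weight of 0.12 applied to the arithmetic mean
#' equivalent dose over thirteen designated remainder organs. The remainder
#' mean always divides by `remainder_divisor` (13), not by the number of
#' organs actually supplied with doses: unmeasured remainder organs
#' contribute zero, matching the convention used when only a subset of
#' remainder tissues lies inside the imaged volume.
#'
#' @param explicit_weights Named numeric vector mapping organ id to its
#'   tissue weighting factor \eqn{w_T}.
#' @param remainder_organs Character vector of remainder organ ids.
#' @param remainder_weight Collective remainder weight (default 0.12).
#' @param remainder_divisor Fixed divisor for the remainder mean
#'   (default 13).
#' @param radiation_weight Radiation weighting factor \eqn{w_R}
#'   (1.0 for photons).
#' @return An object of class `tissue_weighting`.
#' @export
#' @examples
#' w <- icrp103_weights()
#' sum(w$explicit_weights) + w$remainder_weight  # full scheme sums to 1
icrp103_weights <- function(explicit_weights = NULL,
                            remainder_organs = NULL,
                            remainder_weight = 0.12,
                            remainder_divisor = 13L,
                            radiation_weight = 1.0) {
  if (is.null(explicit_weights)) {
    explicit_weights <- c(
      gonads = 0.08, bone_marrow = 0.12, colon = 0.12, lung = 0.12,
      stomach = 0.12, breast = 0.12, bladder = 0.04, esophagus = 0.04,
      liver = 0.04, thyroid = 0.04, bone_surface = 0.01, brain = 0.01,
      salivary_glands = 0.01, skin = 0.01
    )
  }
  if (is.null(remainder_organs)) {
    remainder_organs <- c(
      "adrenals", "extrathoracic_region", "gallbladder", "heart",
      "intestine", "kidney", "lymphatic_nodes", "muscle", "oral_mucosa",
      "pancreas", "prostate_uterus", "spleen", "thymus"
    )
  }
  names(explicit_weights) <- normalize_organ_id(names(explicit_weights))
  remainder_organs <- normalize_organ_id(remainder_organs)
  w <- unname(explicit_weights)
  if (any(w < 0 | w > 1) || remainder_weight < 0 || remainder_weight > 1) {
    stop("tissue weights must lie in [0, 1]", call. = FALSE)
  }
  if (length(intersect(names(explicit_weights), remainder_organs))) {
    stop("an organ cannot be both explicitly weighted and remainder",
         call. = FALSE)
  }
  remainder_divisor <- as.integer(remainder_divisor)
  if (remainder_divisor < length(remainder_organs)) {
    stop("remainder_divisor must be >= number of remainder organs",
         call. = FALSE)
  }
  if (radiation_weight <= 0) stop("radiation_weight must be > 0", call. = FALSE)
  structure(
    list(explicit_weights = explicit_weights,
         remainder_organs = remainder_organs,
         remainder_weight = remainder_weight,
         remainder_divisor = remainder_divisor,
         radiation_weight = radiation_weight),
    class = "tissue_weighting"
  )
}

#' @export
print.tissue_weighting <- function(x, ...) {
  cat("Tissue weighting scheme\n")
  cat("  explicit tissues: ", length(x$explicit_weights),
      " (sum w_T = ", format(sum(x$explicit_weights)), ")\n", sep = "")
  cat("  remainder: ", length(x$remainder_organs), " organs, weight ",
      x$remainder_weight, " over divisor ", x$remainder_divisor, "\n",
      sep = "")
  cat("  radiation weight w_R =", x$radiation_weight, "\n")
  invisible(x)
}

#' Read a tissue weighting scheme from a YAML config
#'
#' The config carries keys `explicit_weights` (map organ -> w_T),
#' `remainder_organs`, `remainder_weight`, `remainder_divisor` and
#' `radiation_weight`. The packaged default is the ICRP-103 scheme; see
#' `system.file("extdata", "icrp103_weights.yaml", package = "cbctrisk")`.
#'
#' @param path Path to the YAML file.
#' @return A [icrp103_weights()] `tissue_weighting` object.
#' @export
read_weighting_scheme <- function(path) {
  cfg <- yaml::read_yaml(path)
  icrp103_weights(
    explicit_weights = unlist(cfg$explicit_weights),
    remainder_organs = unlist(cfg$remainder_organs),
    remainder_weight = cfg$remainder_weight %||% 0.12,
    remainder_divisor = cfg$remainder_divisor %||% 13L,
    radiation_weight = cfg$radiation_weight %||% 1.0
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Equivalent dose from mean absorbed dose
#'
#' Equivalent dose \eqn{H_T = w_R \cdot D_{T,R}}: the mean absorbed dose to
#' a tissue weighted by the radiation weighting factor, with the unit
#' relabelled mGy to mSv. For the kV photon fields of CBCT imaging
#' \eqn{w_R = 1} and the numbers coincide.
#'
#' @param mean_dose Mean absorbed dose in mGy (scalar or vector).
#' @param radiation_weight Radiation weighting factor (default 1.0).
#' @return Equivalent dose in mSv.
#' @export
#' @examples
#' equivalent_dose(14.3)        # 14.3 mSv
equivalent_dose <- function(mean_dose, radiation_weight = 1.0) {
  mean_dose <- as.numeric(mean_dose)
  if (any(!is.finite(mean_dose)) || any(mean_dose < 0)) {
    stop("mean_dose must be finite and non-negative", call. = FALSE)
  }
  mean_dose * radiation_weight
}

#' Effective dose from an organ dose table
#'
#' Computes the ICRP effective dose
#' \deqn{E = \sum_T w_T \sum_R w_R D_{T,R}}
#' as the weighted sum of organ equivalent doses, with the remainder-tissue
#' contribution \eqn{w_{rem} \cdot \left(\sum_{T \in rem} H_T\right) / n_{rem}}
#' computed as the collective remainder weight times the arithmetic mean of
#' the remainder-organ equivalent doses over the fixed divisor (13 for
#' ICRP 103). Organs in the scheme but absent from `doses` contribute zero;
#' an organ in `doses` that matches neither the explicit weights nor the
#' remainder list is an error.
#'
#' @param doses An [organ_dose_table()] of mean absorbed doses (mGy).
#' @param scheme A `tissue_weighting` scheme; default [icrp103_weights()].
#' @return Effective dose in mSv (scalar).
#' @export
#' @examples
#' doses <- organ_dose_table(c("lung", "heart"), c(14.3, 16.0))
#' effective_dose(doses)
effective_dose <- function(doses, scheme = icrp103_weights()) {
  stopifnot(inherits(doses, "organ_dose_table"),
            inherits(scheme, "tissue_weighting"))
  h <- equivalent_dose(doses$mean_dose_mGy, scheme$radiation_weight)
  names(h) <- doses$organ_id
  known <- c(names(scheme$explicit_weights), scheme$remainder_organs)
  bad <- setdiff(names(h), known)
  if (length(bad)) {
    stop("organ(s) not in weighting scheme: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  idx <- names(h) %in% names(scheme$explicit_weights)
  e_explicit <- sum(scheme$explicit_weights[names(h)[idx]] * h[idx])
  e_remainder <- scheme$remainder_weight *
    sum(h[names(h) %in% scheme$remainder_organs]) / scheme$remainder_divisor
  as.numeric(e_explicit + e_remainder)
}

#' BEIR VII EAR parameter set
#'
#' Per-organ, sex-specific parameters of the BEIR VII excess absolute risk
#' (EAR) incidence model: linear dose coefficients \eqn{\beta_M, \beta_F}
#' (excess cases per 10^4 person-years per Gy), the exposure-age log-linear
#' modifier \eqn{\gamma} (per decade of exposure age relative to age 30),
#' the attained-age power \eqn{\eta}, and the reference attained age
#' \eqn{A_0} (60 y). Organs without organ-specific EAR parameters in BEIR
#' VII (thyroid, esophagus, skin, kidney, pancreas, ...) fall back to the
#' report's "other solid cancer" tuple.
#'
#' @param params Optional data.frame with columns `organ_id`, `beta_m`,
#'   `beta_f`, `gamma`, `eta`; a row with `organ_id == "other_solid"` is the
#'   fallback. Defaults to the packaged parameter table.
#' @param reference_age Reference attained age \eqn{A_0} in years
#'   (default 60).
#' @return An object of class `beir_parameters`.
#' @export
#' @examples
#' p <- beir_parameters()
#' p$params
beir_parameters <- function(params = NULL, reference_age = 60) {
  if (is.null(params)) {
    path <- system.file("extdata", "beir_parameters.tsv",
                        package = "cbctrisk", mustWork = TRUE)
    params <- utils::read.table(path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  }
  need <- c("organ_id", "beta_m", "beta_f", "gamma", "eta")
  stopifnot(all(need %in% names(params)))
  keep <- params$organ_id == "other_solid"
  params$organ_id[!keep] <- normalize_organ_id(params$organ_id[!keep])
  if (any(params$beta_m < 0) || any(params$beta_f < 0)) {
    stop("beta coefficients must be non-negative", call. = FALSE)
  }
  if (reference_age <= 0) stop("reference_age must be > 0", call. = FALSE)
  if (anyDuplicated(params$organ_id)) {
    stop("duplicate organ in BEIR parameter table", call. = FALSE)
  }
  structure(list(params = params, reference_age = reference_age),
            class = "beir_parameters")
}

#' @export
print.beir_parameters <- function(x, ...) {
  cat("BEIR VII EAR parameters (A0 =", x$reference_age, "y)\n")
  print(x$params, row.names = FALSE)
  invisible(x)
}

# Resolve one organ/sex to a (beta, gamma, eta) tuple; falls back to the
# other-solid row when the organ has no specific entry.
.beir_lookup <- function(params, organ_id, sex) {
  sex <- match.arg(sex, c("male", "female"))
  tab <- params$params
  i <- match(organ_id, tab$organ_id)
  if (is.na(i)) i <- match("other_solid", tab$organ_id)
  if (is.na(i)) {
    stop("no BEIR parameters (and no other_solid fallback) for organ: ",
         organ_id, call. = FALSE)
  }
  list(beta = if (sex == "male") tab$beta_m[i] else tab$beta_f[i],
       gamma = tab$gamma[i], eta = tab$eta[i],
       source = tab$organ_id[i])
}

#' Excess absolute risk of secondary cancer incidence
#'
#' Evaluates the BEIR VII excess absolute risk model
#' \deqn{EAR = \beta_{M/F} \cdot D_T \cdot
#'   \exp\!\left(\gamma \frac{e - 30}{10}\right)
#'   \left(\frac{A}{A_0}\right)^{\eta}}
#' where \eqn{D_T} is the organ mean dose, \eqn{e} the age at exposure and
#' \eqn{A} the attained age. Doses enter in mSv (numerically mGy for
#' photons) and are converted to Gy; \eqn{\beta} is per 10^4 person-years
#' per Gy and the result is rescaled to cases per 10^6 person-years. The
#' exposure-age modifier is applied as written for all \eqn{e \ge 30}
#' (no clamping of \eqn{e} at 30).
#'
#' @param dose Organ equivalent dose in mSv (non-negative scalar).
#' @param organ_id Organ identifier (resolved against the parameter table,
#'   with fallback to the other-solid tuple).
#' @param sex `"male"` or `"female"`.
#' @param exposure_age Age at exposure \eqn{e} in years.
#' @param attained_age Attained age \eqn{A} in years; must be \eqn{\ge e}.
#' @param params A [beir_parameters()] set.
#' @return A one-row data.frame of class `ear_result` with columns
#'   `organ_id`, `sex`, `exposure_age`, `attained_age`,
#'   `ear_per_1e6_py` (cases per million person-years).
#' @export
#' @examples
#' excess_absolute_risk(14.3, "lung", "male", 30, 70)
excess_absolute_risk <- function(dose, organ_id, sex = c("male", "female"),
                                 exposure_age = 30, attained_age = 70,
                                 params = beir_parameters()) {
  sex <- match.arg(sex)
  if (!is.finite(dose) || dose < 0) {
    stop("dose must be finite and non-negative", call. = FALSE)
  }
  if (exposure_age < 0) stop("exposure_age must be >= 0", call. = FALSE)
  if (attained_age < exposure_age) {
    stop("attained_age must be >= exposure_age", call. = FALSE)
  }
  organ_id <- normalize_organ_id(organ_id)
  p <- .beir_lookup(params, organ_id, sex)
  # per-10^4 PY/Gy * Gy -> per-10^4 PY; x100 -> per-10^6 PY
  value <- 100 * p$beta * (dose / 1000) *
    exp(p$gamma * (exposure_age - 30) / 10) *
    (attained_age / params$reference_age)^p$eta
  out <- data.frame(organ_id = organ_id, sex = sex,
                    exposure_age = exposure_age, attained_age = attained_age,
                    ear_per_1e6_py = value, stringsAsFactors = FALSE)
  class(out) <- c("ear_result", "data.frame")
  out
}

#' EAR series over exposure ages for all organs in a dose table
#'
#' Evaluates [excess_absolute_risk()] for every organ of a dose table at a
#' fixed attained age over a vector of exposure ages, indexing each result
#' by time since exposure \eqn{A - e}. This reproduces the EAR-versus-time
#' presentation: with attained age 70 and exposure ages 60/50/40/30 the
#' series runs over 10, 20, 30 and 40 years since exposure.
#'
#' @param doses An [organ_dose_table()] (equivalent doses, mSv).
#' @param sex `"male"` or `"female"`.
#' @param attained_age Attained age \eqn{A} in years (default 70).
#' @param exposure_ages Numeric vector of exposure ages, each
#'   \eqn{\le} `attained_age` (default `c(30, 40, 50, 60)`).
#' @param params A [beir_parameters()] set.
#' @return A data.frame of class `ear_result` with one row per
#'   (organ, exposure age), including a `years_since_exposure` column.
#' @export
#' @examples
#' doses <- organ_dose_table("thyroid", 18.8)
#' ear_time_series(doses, "male")
ear_time_series <- function(doses, sex = c("male", "female"),
                            attained_age = 70,
                            exposure_ages = c(30, 40, 50, 60),
                            params = beir_parameters()) {
  sex <- match.arg(sex)
  stopifnot(inherits(doses, "organ_dose_table"))
  if (!length(exposure_ages)) {
    stop("exposure_ages must be non-empty", call. = FALSE)
  }
  if (any(exposure_ages > attained_age)) {
    stop("every exposure age must be <= attained_age", call. = FALSE)
  }
  if (!nrow(doses)) {
    out <- data.frame(organ_id = character(), sex = character(),
                      exposure_age = numeric(), attained_age = numeric(),
                      ear_per_1e6_py = numeric(),
                      years_since_exposure = numeric(),
                      stringsAsFactors = FALSE)
    class(out) <- c("ear_result", "data.frame")
    return(out)
  }
  grid <- expand.grid(i = seq_len(nrow(doses)), e = exposure_ages)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    i <- grid$i[k]
    excess_absolute_risk(doses$mean_dose_mGy[i], doses$organ_id[i], sex,
                         grid$e[k], attained_age, params)
  })
  out <- do.call(rbind, rows)
  out$years_since_exposure <- out$attained_age - out$exposure_age
  class(out) <- c("ear_result", "data.frame")
  out
}

#' @export
print.ear_result <- function(x, ...) {
  cat("Excess absolute risk (cases per 10^6 person-years)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
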