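#' Organ identifier registry
#'
#' Controlled vocabulary of organ identifiers recognised throughout the
#' package. It covers the 15 organs for which kV-CBCT mean doses are
#' typically contoured and extracted (lung, stomach, bone marrow, esophagus,
#' liver, thyroid, bone surface, skin, adrenal glands, gallbladder, heart,
#' intestine, kidney, pancreas, spleen) together with the remaining
#' ICRP-103 tissues so that a full whole-body weighting scheme can be
#' expressed.
#'
#' @return Character vector of canonical organ identifiers.
#' @seealso [icrp103_weights()] for the weighting scheme over this registry.
#' @export
#' @examples
#' organ_registry()
organ_registry <- function() {
  c(
    # ICRP-103 explicitly weighted tissues
    "gonads", "bone_marrow", "colon", "lung", "stomach", "breast",
    "bladder", "esophagus", "liver", "thyroid", "bone_surface", "brain",
    "salivary_glands", "skin",
    # ICRP-103 remainder tissues (prostate/uterus folded into one slot)
    "adrenals", "extrathoracic_region", "gallbladder", "heart", "intestine",
    "kidney", "lymphatic_nodes", "muscle", "oral_mucosa", "pancreas",
    "prostate_uterus", "spleen", "thymus"
  )
}

# Accept a few common synonyms so delimited-text tables written by hand
# (e.g. "adrenal glands", "small intestine") resolve to canonical ids.
.organ_aliases <- c(
  adrenal_glands = "adrenals",
  adrenal = "adrenals",
  small_intestine = "intestine",
  kidneys = "kidney",
  red_bone_marrow = "bone_marrow",
  oesophagus = "esophagus",
  prostate = "prostate_uterus",
  uterus = "prostate_uterus",
  uterus_cervix = "prostate_uterus"
)

#' Normalise an organ identifier
#'
#' Lower-cases, converts spaces/hyphens to underscores and maps recognised
#' synonyms onto the canonical registry id.
#'
#' @param organ_id Character vector of organ names.
#' @param strict If `TRUE` (default), unknown organs raise an error naming
#'   the offending id; if `FALSE` they are returned normalised but unmapped.
#' @return Character vector of canonical organ ids.
#' @export
#' @examples
#' normalize_organ_id(c("Adrenal glands", "Bone marrow"))
normalize_organ_id <- function(organ_id, strict = TRUE) {
  x <- tolower(trimws(as.character(organ_id)))
  x <- gsub("[ -]+", "_", x)
  hit <- match(x, names(.organ_aliases))
  x[!is.na(hit)] <- .organ_aliases[hit[!is.na(hit)]]
  if (strict) {
    bad <- setdiff(unique(x), organ_registry())
    if (length(bad)) {
      stop("unknown organ id(s): ", paste(bad, collapse = ", "),
           "; see organ_registry()", call. = FALSE)
    }
  }
  x
}
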