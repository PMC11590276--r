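#' CKD stage labels
#'
#' `ckd_stages()` returns the KDIGO stage ladder used throughout the package,
#' ordered from least to most severe. `stage_levels()` prepends `"None"`, the
#' no-CKD level used as the reference category in cost models and as a valid
#' value for matched controls.
#'
#' @return Character vector of stage labels.
#' @export
ckd_stages <- function() c("1", "2", "3a", "3b", "4", "5")

#' @rdname ckd_stages
#' @export
stage_levels <- function() c("None", ckd_stages())

#' Severity rank of a CKD stage
#'
#' Maps stage labels to an integer severity (1 = Stage 1 ... 6 = Stage 5);
#' `"None"` maps to 0. Used to enforce the progression-only (ratchet) rule.
#'
#' @param stage character vector of stage labels.
#' @return Integer severity ranks.
#' @export
stage_severity <- function(stage) {
  out <- match(stage, ckd_stages())
  out[stage == "None"] <- 0L
  if (anyNA(out)) stop("unknown stage label(s): ",
                       paste(unique(stage[is.na(out)]), collapse = ", "))
  out
}

#' Cost component names
#'
#' The seven direct-healthcare cost components tracked in every ledger:
#' emergency presentations, hospital admissions excluding dialysis, medication,
#' primary care, community pathology testing, dialysis, and outpatient
#' (renal clinic) services.
#'
#' @return Character vector of length 7.
#' @export
cost_components <- function() {
  c("emergency", "hospital_nondialysis", "medication", "primary_care",
    "pathology", "dialysis", "outpatient")
}

#' Five-year age bands
#'
#' The fixed ordered ladder of 5-year age bands used for matching and as a
#' cost-model predictor, starting at adulthood. `age_band_midpoint()` returns
#' the numeric age attached to a band for eGFR computation (demographics carry
#' bands only; the open-ended top band uses 92).
#'
#' @return `age_bands()`: character vector of band labels.
#' @export
age_bands <- function() {
  c("18-24", "25-29", "30-34", "35-39", "40-44", "45-49", "50-54", "55-59",
    "60-64", "65-69", "70-74", "75-79", "80-84", "85-89", "90+")
}

#' @rdname age_bands
#' @param band character vector of band labels.
#' @return `age_band_midpoint()`: numeric midpoint ages.
#' @export
age_band_midpoint <- function(band) {
  mids <- c(21, 27, 32, 37, 42, 47, 52, 57, 62, 67, 72, 77, 82, 87, 92)
  idx <- match(band, age_bands())
  if (anyNA(idx)) stop("unknown age band(s): ",
                       paste(unique(band[is.na(idx)]), collapse = ", "))
  mids[idx]
}

#' Remoteness categories
#' @return Character vector of the three remoteness levels.
#' @export
remoteness_levels <- function() c("major_cities", "regional", "remote")

# Round half away from zero (base round() is banker's rounding).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Currency: round to exact cents.
round_cents <- function(x) round_half_up(x, 2)

# Internal: check a probability (vector) lies in [0, 1].
check_prob <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop(what, " must be probabilities in [0, 1]", call. = FALSE)
  }
  invisible(p)
}
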