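#' Estimated glomerular filtration rate (CKD-EPI 2009)
#'
#' Computes eGFR from serum creatinine, age and sex using the 2009 CKD-EPI
#' creatinine equation without the race coefficient, consistent with
#' Australian laboratory reporting practice. Creatinine is supplied in
#' micromol/L and converted internally to mg/dL (division by 88.4).
#'
#' @param creatinine serum creatinine in micromol/L (> 0).
#' @param age age in years (>= 18).
#' @param sex `"male"` or `"female"` (recycled).
#' @return eGFR in mL/min/1.73m^2.
#' @examples
#' compute_egfr(61.9, age = 50, sex = "female") # ~ 101
#' compute_egfr(159, age = 70, sex = "male")    # ~ 37
#' @export
compute_egfr <- function(creatinine, age, sex) {
  if (any(!is.finite(creatinine)) || any(creatinine <= 0)) {
    stop("creatinine must be positive and finite")
  }
  if (any(age < 18)) stop("age must be >= 18 (adult cohort)")
  sex <- match_sex(sex, length(creatinine))
  female <- sex == "female"
  scr <- creatinine / 88.4
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  141 * pmin(scr / kappa, 1)^alpha * pmax(scr / kappa, 1)^(-1.209) *
    0.993^age * ifelse(female, 1.018, 1)
}

# Internal: invert compute_egfr() for a target eGFR, used by the synthetic
# generator to build creatinine trajectories backward from a true stage.
invert_egfr <- function(egfr, age, sex) {
  sex <- match_sex(sex, length(egfr))
  female <- sex == "female"
  a <- 141 * 0.993^age * ifelse(female, 1.018, 1)
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  r <- egfr / a
  scr <- ifelse(r >= 1, kappa * r^(1 / alpha), kappa * r^(-1 / 1.209))
  scr * 88.4
}

match_sex <- function(sex, n) {
  sex <- tolower(as.character(sex))
  if (!all(sex %in% c("male", "female"))) {
    stop('sex must be "male" or "female"')
  }
  rep_len(sex, n)
}

#' Sex-specific albuminuria positivity
#'
#' A urine albumin-creatinine ratio counts as albuminuria when
#' uACR >= 2.5 mg/mmol for males or >= 3.5 mg/mmol for females.
#'
#' @param uacr uACR in mg/mmol.
#' @param sex `"male"` or `"female"` (recycled).
#' @return Logical vector.
#' @export
uacr_positive <- function(uacr, sex) {
  sex <- match_sex(sex, length(uacr))
  ifelse(sex == "male", uacr >= 2.5, uacr >= 3.5)
}

#' KDIGO stage from eGFR and albuminuria status
#'
#' Stages 1 and 2 require albuminuria (eGFR >= 90 and 60-89 respectively);
#' stages 3a-5 follow eGFR bands alone (45-59, 30-44, 15-29, < 15). An eGFR
#' of 60 or more without albuminuria is not CKD and returns `NA`.
#'
#' @param egfr eGFR in mL/min/1.73m^2 (> 0).
#' @param albuminuria logical; persistent albuminuria present.
#' @return Character stage label or `NA_character_`.
#' @export
assign_kdigo_stage <- function(egfr, albuminuria) {
  if (any(!is.finite(egfr)) || any(egfr <= 0)) stop("egfr must be positive")
  n <- max(length(egfr), length(albuminuria))
  egfr <- rep_len(egfr, n)
  albuminuria <- rep_len(albuminuria, n)
  out <- rep(NA_character_, n)
  out[egfr < 60] <- as.character(cut(egfr[egfr < 60], c(-Inf, 15, 30, 45, 60),
                                     labels = c("5", "4", "3b", "3a"),
                                     right = FALSE))
  out[egfr >= 60 & egfr < 90 & albuminuria] <- "2"
  out[egfr >= 90 & albuminuria] <- "1"
  out
}

# Internal: all chronically-confirming pairs of qualifying results.
# A pair (i, j) qualifies when both results qualify, the dates are strictly
# more than `gap` days apart, and every result dated within [date_i, date_j]
# also qualifies (the "all other tests within this window" rule).
# Returns a data.frame with columns i, j (indices into `dates`).
qualifying_pairs <- function(dates, qualifies, gap = 90) {
  n <- length(dates)
  if (n < 2) return(data.frame(i = integer(), j = integer()))
  if (is.unsorted(as.numeric(dates))) stop("results must be sorted by date")
  bad <- as.numeric(dates[!qualifies])
  d <- as.numeric(dates)
  out_i <- integer(0); out_j <- integer(0)
  for (j in seq_len(n)[-1]) {
    if (!qualifies[j]) next
    for (i in seq_len(j - 1)) {
      if (!qualifies[i]) next
      if (d[j] - d[i] <= gap) next
      if (length(bad) && any(bad >= d[i] & bad <= d[j])) next
      out_i <- c(out_i, i); out_j <- c(out_j, j)
    }
  }
  data.frame(i = out_i, j = out_j)
}

#' Detect chronic kidney disease from longitudinal labs
#'
#' CKD is confirmed by either criterion: (a) two eGFR results below
#' 60 mL/min/1.73m^2 strictly more than 90 days apart, with every other eGFR
#' result dated within that window also below 60; or (b) the same chronicity
#' rule applied to sex-specific albuminuria (uACR >= 2.5 mg/mmol male,
#' >= 3.5 female). The confirmation (onset) date is the date of the second
#' test of the earliest qualifying pair across both criteria.
#'
#' @param egfr data.frame with columns `date` (Date, sorted ascending) and
#'   `egfr`, or `NULL`.
#' @param uacr data.frame with columns `date` (sorted) and `uacr`, or `NULL`.
#' @param sex `"male"` or `"female"` (for the uACR threshold).
#' @return The onset `Date`, or `as.Date(NA)` when CKD is not confirmed.
#' @export
detect_ckd <- function(egfr = NULL, uacr = NULL, sex) {
  onsets <- as.Date(character())
  if (!is.null(egfr) && nrow(egfr)) {
    p <- qualifying_pairs(egfr$date, egfr$egfr < 60)
    if (nrow(p)) onsets <- c(onsets, min(egfr$date[p$j]))
  }
  if (!is.null(uacr) && nrow(uacr)) {
    p <- qualifying_pairs(uacr$date, uacr_positive(uacr$uacr, sex))
    if (nrow(p)) onsets <- c(onsets, min(uacr$date[p$j]))
  }
  if (!length(onsets)) return(as.Date(NA))
  min(onsets)
}

#' Resolve a person's follow-up window for the analysis year
#'
#' A person is lost to follow-up (excluded) when they have no pathology,
#' hospital, emergency or mortality records dated in the analysis year and
#' none dated after it. For included persons the window runs from 1 January
#' to 31 December, truncated at the death date when death occurs in the year.
#'
#' @param person_id identifier carried through to the result.
#' @param record_dates Date vector of all record dates for the person
#'   (labs, admissions, emergency presentations, prescriptions, billing).
#' @param year analysis calendar year.
#' @param death_date optional death `Date` (counts as a mortality record).
#' @return A `followup_window`: list with `person_id`, `start_date`,
#'   `end_date`, `excluded`, `exclusion_reason`.
#' @export
resolve_followup <- function(person_id, record_dates, year, death_date = NULL) {
  year_start <- as.Date(sprintf("%d-01-01", year))
  year_end <- as.Date(sprintf("%d-12-31", year))
  dates <- as.Date(record_dates)
  if (!is.null(death_date) && !is.na(death_date)) {
    dates <- c(dates, as.Date(death_date))
  }
  dates <- dates[!is.na(dates)]
  in_year <- any(dates >= year_start & dates <= year_end)
  after <- any(dates > year_end)
  excluded <- !in_year && !after
  end_date <- year_end
  if (!is.null(death_date) && !is.na(death_date) &&
      death_date >= year_start && death_date <= year_end) {
    end_date <- as.Date(death_date)
  }
  structure(list(person_id = person_id, start_date = year_start,
                 end_date = end_date, excluded = excluded,
                 exclusion_reason = if (excluded) {
                   sprintf("no records in %d or after", year)
                 } else NA_character_),
            class = "followup_window")
}

#' Evidence-of-diabetes flag from pathology
#'
#' Diabetes is flagged when there are two separate HbA1c results above 6.5%
#' (on distinct dates) or two separate fasting plasma glucose results above
#' 7.0 mmol/L.
#'
#' @param labs data.frame with columns `date`, `analyte` (`"hba1c"`, `"fpg"`,
#'   others ignored) and `value`.
#' @return Logical scalar.
#' @export
derive_diabetes_flag <- function(labs) {
  if (is.null(labs) || !nrow(labs)) return(FALSE)
  hba1c <- labs[labs$analyte == "hba1c" & labs$value > 6.5, , drop = FALSE]
  fpg <- labs[labs$analyte == "fpg" & labs$value > 7.0, , drop = FALSE]
  length(unique(hba1c$date)) >= 2 || length(unique(fpg$date)) >= 2
}

#' Build a person's longitudinal CKD stage history
#'
#' Turns dated eGFR and uACR results plus dialysis-coded admissions into a
#' sequence of stage periods over the follow-up window. Stages are confirmed
#' by chronicity pairs (see [detect_ckd()]); a confirmatory pair spanning two
#' stages contributes the least severe of the two. Stage can only progress
#' (ratchet): the stage on any day is the most severe stage confirmed on or
#' before that day, and improved results never lower it. Any dialysis-coded
#' (Z49) event forces Stage 5 from its date. Stage confirmed in earlier years
#' carries forward into the window. The day a new stage is confirmed belongs
#' to the new stage period.
#'
#' An albuminuria confirmation is staged against the most recent eGFR on or
#' before its date (eGFR >= 90 with albuminuria is Stage 1, 60-89 Stage 2);
#' when no such eGFR exists the confirmation cannot be staged and is skipped.
#' If that leaves a person with confirmed CKD but no stageable confirmation,
#' an empty history with attribute `unstageable = TRUE` is returned.
#'
#' @param egfr data.frame (`date`, `egfr`), sorted by date, or `NULL`.
#' @param uacr data.frame (`date`, `uacr`), sorted by date, or `NULL`.
#' @param dialysis_dates Dates of dialysis-coded hospital events (optional).
#' @param sex `"male"` or `"female"`.
#' @param window a `followup_window` from [resolve_followup()], or a list with
#'   `start_date` and `end_date`.
#' @param person_id identifier carried into the result.
#' @return data.frame with columns `person_id`, `stage`, `start_date`,
#'   `end_date`; zero rows when no CKD is confirmed in or before the window.
#' @export
build_stage_history <- function(egfr = NULL, uacr = NULL,
                                dialysis_dates = NULL, sex, window,
                                person_id = NA_character_) {
  empty <- data.frame(person_id = character(), stage = character(),
                      start_date = as.Date(character()),
                      end_date = as.Date(character()))
  if (isTRUE(window$excluded)) return(empty)
  ev_date <- as.Date(character()); ev_stage <- character()
  unstageable <- FALSE

  if (!is.null(egfr) && nrow(egfr)) {
    p <- qualifying_pairs(egfr$date, egfr$egfr < 60)
    if (nrow(p)) {
      s_i <- assign_kdigo_stage(egfr$egfr[p$i], albuminuria = FALSE)
      s_j <- assign_kdigo_stage(egfr$egfr[p$j], albuminuria = FALSE)
      # least severe of the two endpoint stages
      least <- ifelse(stage_severity(s_i) <= stage_severity(s_j), s_i, s_j)
      ev_date <- c(ev_date, egfr$date[p$j])
      ev_stage <- c(ev_stage, least)
    }
  }
  if (!is.null(uacr) && nrow(uacr)) {
    p <- qualifying_pairs(uacr$date, uacr_positive(uacr$uacr, sex))
    for (k in seq_len(nrow(p))) {
      conf_date <- uacr$date[p$j[k]]
      if (is.null(egfr) || !nrow(egfr)) { unstageable <- TRUE; next }
      prior <- egfr[egfr$date <= conf_date, , drop = FALSE]
      if (!nrow(prior)) { unstageable <- TRUE; next }
      e_now <- prior$egfr[which.max(as.numeric(prior$date))]
      ev_date <- c(ev_date, conf_date)
      ev_stage <- c(ev_stage, assign_kdigo_stage(e_now, albuminuria = TRUE))
    }
  }
  if (!is.null(dialysis_dates) && length(dialysis_dates)) {
    ev_date <- c(ev_date, as.Date(dialysis_dates))
    ev_stage <- c(ev_stage, rep("5", length(dialysis_dates)))
  }

  if (!length(ev_date)) {
    if (unstageable) attr(empty, "unstageable") <- TRUE
    return(empty)
  }
  ord <- order(ev_date, stage_severity(ev_stage))
  ev_date <- ev_date[ord]; ev_stage <- ev_stage[ord]

  w_start <- as.Date(window$start_date); w_end <- as.Date(window$end_date)
  onset <- min(ev_date)
  if (onset > w_end) return(empty)
  start <- max(onset, w_start)

  sev <- cummax(stage_severity(ev_stage))
  stage_at <- function(d) ckd_stages()[max(sev[ev_date <= d])]
  # dates strictly inside the window where the ratcheted severity increases
  inc <- ev_date[c(TRUE, diff(sev) > 0)]
  breaks <- sort(unique(inc[inc > start & inc <= w_end]))

  starts <- c(start, breaks)
  ends <- c(breaks - 1, w_end)
  data.frame(person_id = person_id,
             stage = vapply(starts, stage_at, character(1)),
             start_date = starts, end_date = ends)
}
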