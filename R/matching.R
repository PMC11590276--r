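#' Relaxation ladder for matched controls
#'
#' Matching is exact on five covariates: 5-year age band, sex, indigenous
#' status, remoteness and evidence of diabetes. Where no exact match is
#' available, constraints are relaxed in order: remoteness first, then sex,
#' then indigenous status. Age band and diabetes are never relaxed.
#'
#' @return Character vector of relaxation level labels, strictest first.
#' @export
relaxation_levels <- function() {
  c("none", "remoteness", "remoteness+sex", "remoteness+sex+indigenous")
}

match_key_fields <- function() {
  list("none" = c("age_band", "sex", "indigenous", "remoteness", "diabetes"),
       "remoteness" = c("age_band", "sex", "indigenous", "diabetes"),
       "remoteness+sex" = c("age_band", "indigenous", "diabetes"),
       "remoteness+sex+indigenous" = c("age_band", "diabetes"))
}

#' Match CKD cases 1:1 to non-CKD controls
#'
#' Greedy 1:1 matching without replacement. Cases are processed in a stable
#' order (sorted by `person_id`); each case receives a control from the
#' least-relaxed level at which an unused control exists, selected uniformly
#' at random among the available controls at that level. Cases with no
#' available control at any level are marked `"unmatched"`.
#'
#' @param cases data.frame with columns `person_id`, `age_band`, `sex`,
#'   `indigenous`, `remoteness`, `diabetes` and optionally `followup_days`.
#' @param controls data.frame with the same key columns; must be disjoint
#'   from `cases` by `person_id`.
#' @param seed integer seed controlling the random draw within a level
#'   (`NULL` to use the current RNG state).
#' @return data.frame with columns `case_id`, `control_id` (NA when
#'   unmatched), `relaxation_level`, `case_followup_days`.
#' @export
match_cases <- function(cases, controls, seed = NULL) {
  key_cols <- c("age_band", "sex", "indigenous", "remoteness", "diabetes")
  for (col in c("person_id", key_cols)) {
    if (!col %in% names(cases)) stop("cases lacks column ", col)
    if (!col %in% names(controls) && col != "followup_days") {
      stop("controls lacks column ", col)
    }
  }
  if (length(intersect(cases$person_id, controls$person_id))) {
    stop("control pool must be disjoint from cases")
  }
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  if (!nrow(controls)) {
    warning("empty control pool: all cases unmatched")
  }
  fields <- match_key_fields()
  lvls <- relaxation_levels()
  ctrl_keys <- lapply(fields, function(f) {
    do.call(paste, c(controls[f], sep = "\r"))
  })
  ord <- order(as.character(cases$person_id))
  used <- rep(FALSE, nrow(controls))
  n <- nrow(cases)
  control_id <- rep(NA_character_, n)
  level <- rep("unmatched", n)
  for (ci in ord) {
    for (lv in lvls) {
      key <- paste(unlist(cases[ci, fields[[lv]]]), collapse = "\r")
      cand <- which(!used & ctrl_keys[[lv]] == key)
      if (length(cand)) {
        pick <- cand[sample.int(length(cand), 1L)]
        used[pick] <- TRUE
        control_id[ci] <- as.character(controls$person_id[pick])
        level[ci] <- lv
        break
      }
    }
  }
  fud <- if ("followup_days" %in% names(cases)) cases$followup_days else NA_integer_
  out <- data.frame(case_id = as.character(cases$person_id),
                    control_id = control_id,
                    relaxation_level = level,
                    case_followup_days = fud,
                    stringsAsFactors = FALSE)
  out[order(out$case_id), , drop = FALSE]
}

#' Summary of match quality
#'
#' Counts matched pairs per relaxation level, including unmatched cases.
#'
#' @param pairs result of [match_cases()].
#' @return data.frame with columns `relaxation_level`, `n`, `pct`.
#' @export
match_summary <- function(pairs) {
  lv <- factor(pairs$relaxation_level,
               levels = c(relaxation_levels(), "unmatched"))
  tab <- table(lv)
  data.frame(relaxation_level = names(tab), n = as.integer(tab),
             pct = round_half_up(100 * as.integer(tab) / nrow(pairs), 1))
}

#' Apportion a control's annual costs to the case's follow-up length
#'
#' Each matched control is apportioned the same length of follow-up as its
#' partnered case: every component of the control's annual cost ledger is
#' scaled by `case_followup_days / 365`.
#'
#' @param ledger a `cost_ledger` (see [build_ledger()]) or a named numeric
#'   vector over the seven cost components.
#' @param case_followup_days number of days the case was followed (1-365).
#' @return Same shape as `ledger`, scaled.
#' @export
apportion_control <- function(ledger, case_followup_days) {
  if (!is.numeric(case_followup_days) || length(case_followup_days) != 1 ||
      case_followup_days < 1 || case_followup_days > 365) {
    stop("case_followup_days must be a single value in [1, 365]")
  }
  f <- case_followup_days / 365
  if (inherits(ledger, "cost_ledger")) {
    ledger$components <- ledger$components * f
    return(ledger)
  }
  ledger * f
}
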