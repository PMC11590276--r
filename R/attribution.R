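#' Case-minus-control component cost differences
#'
#' The cost attributable to CKD for a matched pair is the per-component
#' difference between the case's ledger and the control's apportioned ledger
#' over the same window length. Negative differences are retained (truncating
#' them at zero would bias totals upward).
#'
#' @param case_ledger,control_ledger `cost_ledger` objects or named numeric
#'   vectors over [cost_components()]; the control ledger should already be
#'   apportioned to the case's follow-up (see [apportion_control()]).
#' @return Named numeric of component differences (2023 AUD).
#' @export
attributable_difference <- function(case_ledger, control_ledger) {
  a <- ledger_components(case_ledger)
  b <- ledger_components(control_ledger)
  a - b
}

#' Aggregate attributable costs by stage and person-year
#'
#' Builds the headline stage-by-component table: for each stage, the
#' per-component mean attributable cost per person-year (component sums over
#' records divided by total person-years) and the stage total (sum of the
#' component means); overall, the component totals in AUD, the grand total,
#' and integer percentage shares by component.
#'
#' @param records data.frame with one row per matched-pair stage period:
#'   columns `case_id`, `stage`, `person_years` (> 0) and the seven component
#'   difference columns named as [cost_components()].
#' @return An object of class `stage_cost_table`: list with `by_stage`
#'   (stage, person_years, component means per person-year, `total`),
#'   `overall` (component, total, share_pct), `grand_total` and
#'   `total_person_years`.
#' @export
aggregate_by_stage <- function(records) {
  comps <- cost_components()
  need <- c("stage", "person_years", comps)
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack column(s): ", paste(miss, collapse = ", "))
  if (!nrow(records)) {
    return(structure(list(by_stage = records[0, need], overall = NULL,
                          grand_total = 0, total_person_years = 0),
                     class = "stage_cost_table"))
  }
  if (any(records$person_years <= 0)) stop("person_years must be > 0")
  stages <- ckd_stages()[ckd_stages() %in% unique(records$stage)]
  by_stage <- do.call(rbind, lapply(stages, function(s) {
    r <- records[records$stage == s, , drop = FALSE]
    py <- sum(r$person_years)
    means <- vapply(comps, function(cp) sum(r[[cp]]) / py, numeric(1))
    cbind(data.frame(stage = s, person_years = py), as.data.frame(t(means)),
          data.frame(total = sum(means)))
  }))
  totals <- vapply(comps, function(cp) sum(records[[cp]]), numeric(1))
  overall <- data.frame(component = comps, total = unname(totals),
                        share_pct = unname(compute_shares(totals)))
  structure(list(by_stage = by_stage, overall = overall,
                 grand_total = sum(totals),
                 total_person_years = sum(records$person_years)),
            class = "stage_cost_table")
}

#' @export
print.stage_cost_table <- function(x, ...) {
  cat(sprintf("<stage_cost_table> %.0f person-years, grand total $%s\n",
              x$total_person_years,
              format(round(x$grand_total), big.mark = ",")))
  if (!is.null(x$by_stage) && nrow(x$by_stage)) {
    tab <- x$by_stage
    tab[, -1] <- round(tab[, -1], 1)
    cat("\nAttributable cost per person-year by stage:\n")
    print(tab, row.names = FALSE)
  }
  if (!is.null(x$overall)) {
    cat("\nComponent totals:\n")
    ov <- x$overall
    ov$total <- round(ov$total)
    print(ov, row.names = FALSE)
  }
  invisible(x)
}

#' Component percentage shares of the grand total
#'
#' Each component total divided by the grand total, times 100, rounded to the
#' nearest integer (half away from zero).
#'
#' @param component_totals named numeric of component totals, not all zero.
#' @return Named numeric of integer percentages.
#' @export
compute_shares <- function(component_totals) {
  if (all(component_totals == 0)) {
    stop("shares are undefined when all component totals are zero")
  }
  round_half_up(100 * component_totals / sum(component_totals))
}

#' Percentage cost increase of cases over controls
#'
#' How much having CKD increased healthcare costs: `(case - control) /
#' control * 100`.
#'
#' @param case_total total costs of cases (AUD).
#' @param control_total total costs of matched controls (AUD, > 0).
#' @return Percentage increase.
#' @export
cost_ratio_vs_controls <- function(case_total, control_total) {
  if (!is.finite(control_total) || control_total <= 0) {
    stop("control total must be > 0")
  }
  (case_total - control_total) / control_total * 100
}
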