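#' Run the full attributable-cost pipeline on a synthetic cohort
#'
#' Executes the complete bottom-up, matched-control cost-of-illness analysis:
#'
#' 1. generate the linked cohort, unit-cost catalog and population strata;
#' 2. resolve each person's follow-up window (loss-to-follow-up exclusions,
#'    death truncation) and re-derive the diabetes flag from pathology;
#' 3. build longitudinal KDIGO stage histories; persons with a stage period
#'    in the year are cases, persons with no evidence of CKD form the
#'    control pool;
#' 4. match cases 1:1 to controls with ordered constraint relaxation;
#' 5. price utilisation events into component ledgers;
#' 6. fit gamma log-link models for the components only observed on
#'    sub-datasets (medication and GP costs on the general-practice extract,
#'    pathology costs on the near-complete-provider subset) and transfer
#'    predictions to all cases and matched controls;
#' 7. compute case-minus-control attributable differences per stage period,
#'    allocate the outpatient renal-clinic total top-down across stages, and
#'    aggregate into the stage-by-component cost table;
#' 8. extrapolate stratum-specific case counts and per-case costs to the
#'    national population.
#'
#' @param config a [sim_config()].
#' @param model_transfer logical; fit and apply the cost models for
#'   medication, primary care and pathology (the default). When `FALSE`, or
#'   for stage levels absent from a model's training data, observed ledger
#'   costs are used directly.
#' @return An object of class `coi_result`; see the elements documented in
#'   the return value.
#' @export
run_coi_pipeline <- function(config, model_transfer = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  catalog <- generate_cost_catalog(config)
  cohort <- generate_cohort(config)
  strata <- generate_population_strata(config, cohort$persons)
  persons <- cohort$persons
  year <- config$analysis_year

  labs_by <- split(cohort$labs, cohort$labs$person_id)
  events_by <- split(cohort$events, cohort$events$person_id)

  n <- nrow(persons)
  included <- logical(n)
  window_end <- rep(as.Date(NA), n)
  window_start <- rep(as.Date(NA), n)
  diabetes_flag <- logical(n)
  period_list <- vector("list", n)
  unstageable <- logical(n)
  followups <- vector("list", n)

  for (i in seq_len(n)) {
    pid <- persons$person_id[i]
    lb <- labs_by[[pid]]
    evp <- events_by[[pid]]
    fw <- resolve_followup(pid, c(lb$date, evp$date), year,
                           persons$death_date[i])
    followups[[i]] <- fw
    included[i] <- !fw$excluded
    if (fw$excluded) next
    window_start[i] <- fw$start_date
    window_end[i] <- fw$end_date
    diabetes_flag[i] <- derive_diabetes_flag(lb)
    cre <- lb[lb$analyte == "creatinine", , drop = FALSE]
    egfr_tab <- if (nrow(cre)) {
      data.frame(date = cre$date,
                 egfr = compute_egfr(cre$value, persons$age_mid[i],
                                     persons$sex[i]))
    } else NULL
    ua <- lb[lb$analyte == "uacr", , drop = FALSE]
    uacr_tab <- if (nrow(ua)) data.frame(date = ua$date, uacr = ua$value) else NULL
    dial_dates <- if (!is.null(evp)) {
      evp$date[evp$kind == "admission" & isTRUE_vec(evp$dialysis)]
    } else NULL
    hist <- build_stage_history(egfr_tab, uacr_tab, dial_dates,
                                persons$sex[i], fw, pid)
    unstageable[i] <- isTRUE(attr(hist, "unstageable"))
    if (nrow(hist)) period_list[[i]] <- hist
  }

  periods <- do.call(rbind, period_list[!vapply(period_list, is.null, logical(1))])
  is_case <- persons$person_id %in% periods$person_id
  exclusions <- data.frame(
    person_id = persons$person_id[!included],
    reason = sprintf("no records in %d or after", year))

  keys <- data.frame(person_id = persons$person_id, age_band = persons$age_band,
                     sex = persons$sex, indigenous = persons$indigenous,
                     remoteness = persons$remoteness, diabetes = diabetes_flag,
                     followup_days = as.integer(window_end - window_start) + 1L)
  cases_df <- keys[included & is_case, , drop = FALSE]
  controls_df <- keys[included & !is_case & !unstageable, , drop = FALSE]
  pairs <- match_cases(cases_df, controls_df, seed = config$seed)
  matched <- pairs[!is.na(pairs$control_id), , drop = FALSE]

  # observed annual ledgers over each included person's own window
  ledger_of <- function(pid) {
    i <- match(pid, persons$person_id)
    build_ledger(pid, window_start[i], window_end[i], events_by[[pid]], catalog)
  }
  included_ids <- persons$person_id[included]
  ledgers <- lapply(included_ids, ledger_of)
  names(ledgers) <- included_ids
  own_py <- stats::setNames(keys$followup_days[included] / 365, included_ids)

  # dominant stage (longest period) per person, "None" for controls
  dom_stage <- stats::setNames(rep("None", length(included_ids)), included_ids)
  if (!is.null(periods) && nrow(periods)) {
    plen <- as.numeric(periods$end_date - periods$start_date) + 1
    for (pid in unique(periods$person_id)) {
      rows <- periods$person_id == pid
      dom_stage[pid] <- periods$stage[rows][which.max(plen[rows])]
    }
  }

  fits <- list()
  modelled <- c("medication", "primary_care", "pathology")
  if (model_transfer) {
    path_ev <- cohort$events[cohort$events$kind == "pathology_collection" &
                               cohort$events$person_id %in% included_ids, ,
                             drop = FALSE]
    wd_ids <- select_complete_provider_subset(path_ev, provider = "WD",
                                              threshold = 0.95)
    train_ids <- list(
      medication = persons$person_id[included & persons$in_gp_dataset],
      primary_care = persons$person_id[included & persons$in_gp_dataset],
      pathology = intersect(wd_ids, included_ids))
    for (comp in modelled) {
      ids <- train_ids[[comp]]
      df <- data.frame(
        stage = dom_stage[ids],
        sex = persons$sex[match(ids, persons$person_id)],
        age_band = persons$age_band[match(ids, persons$person_id)],
        indigenous = persons$indigenous[match(ids, persons$person_id)],
        remoteness = persons$remoteness[match(ids, persons$person_id)])
      df[[comp]] <- vapply(ids, function(pid) {
        ledgers[[pid]]$components[comp] / own_py[pid]
      }, numeric(1))
      fits[[comp]] <- tryCatch(
        fit_cost_glm(cost_model_spec(comp), df),
        error = function(e) {
          warning("cost model for ", comp, " not fitted (", conditionMessage(e),
                  "); using observed costs", call. = FALSE)
          NULL
        })
    }
  }

  # predicted annual (per person-year) cost for a person at a given stage,
  # falling back to the observed annualized cost when no model applies
  predict_component <- function(comp, pid, stage) {
    fit <- fits[[comp]]
    i <- match(pid, persons$person_id)
    if (!is.null(fit) && stage %in% fit$xlevels$stage) {
      nd <- data.frame(stage = stage, sex = persons$sex[i],
                       age_band = persons$age_band[i],
                       indigenous = persons$indigenous[i],
                       remoteness = persons$remoteness[i])
      ok <- all(vapply(names(fit$xlevels), function(v) {
        as.character(nd[[v]]) %in% fit$xlevels[[v]]
      }, logical(1)))
      if (ok) return(predict_costs(fit, nd))
    }
    ledgers[[pid]]$components[comp] / own_py[pid]
  }

  records <- list()
  tot_case <- 0; tot_control <- 0
  for (r in seq_len(nrow(matched))) {
    cid <- matched$case_id[r]
    ktr <- matched$control_id[r]
    pers <- periods[periods$person_id == cid, , drop = FALSE]
    ctrl_annual <- ledgers[[ktr]]$components / own_py[ktr]
    for (q in seq_len(nrow(pers))) {
      days <- as.numeric(pers$end_date[q] - pers$start_date[q]) + 1
      py <- days / 365
      stage <- pers$stage[q]
      case_comp <- build_ledger(cid, pers$start_date[q], pers$end_date[q],
                                events_by[[cid]], catalog)$components
      ctrl_comp <- apportion_control(ctrl_annual, days)
      for (comp in modelled) {
        case_comp[comp] <- predict_component(comp, cid, stage) * py
        ctrl_comp[comp] <- predict_component(comp, ktr, "None") * py
      }
      diffs <- attributable_difference(case_comp, ctrl_comp)
      tot_case <- tot_case + sum(case_comp)
      tot_control <- tot_control + sum(ctrl_comp)
      i <- match(cid, persons$person_id)
      rec <- data.frame(case_id = cid, control_id = ktr, stage = stage,
                        start_date = pers$start_date[q],
                        end_date = pers$end_date[q], person_years = py,
                        sex = persons$sex[i], age_band = persons$age_band[i],
                        indigenous = persons$indigenous[i],
                        remoteness = persons$remoteness[i])
      rec[cost_components()] <- as.list(diffs)
      records[[length(records) + 1]] <- rec
    }
  }
  records <- do.call(rbind, records)

  # outpatient renal-clinic costs are not observable per person: allocate the
  # aggregate top-down across stages by person-year-weighted frequency
  if (!is.null(records) && nrow(records)) {
    pars <- config$component_cost_params
    m_out <- stats::setNames(
      pars$mean[pars$component == "outpatient"],
      pars$stage[pars$component == "outpatient"])
    py_stage <- tapply(records$person_years, records$stage, sum)
    pool <- m_out[names(py_stage)] * py_stage
    total_out <- sum(pool)
    if (total_out > 0) {
      shares <- allocate_topdown(total_out, pool / total_out)
      add <- as.numeric(shares[records$stage]) *
        records$person_years / as.numeric(py_stage[records$stage])
      records$outpatient <- records$outpatient + add
      tot_case <- tot_case + sum(add)
    }
  }

  stage_table <- aggregate_by_stage(records)
  ratio <- cost_ratio_vs_controls(tot_case, tot_control)

  # local stratum table: cases and mean attributable cost per case by
  # stage x demographics, with local demographic population denominators
  comp_total <- rowSums(records[, cost_components()])
  skey <- as.character(interaction(records$stage, records$sex,
                                   records$indigenous, records$age_band,
                                   records$remoteness, drop = TRUE))
  first <- !duplicated(skey)
  local_tab <- data.frame(stage = records$stage[first], sex = records$sex[first],
                          indigenous = records$indigenous[first],
                          age_band = records$age_band[first],
                          remoteness = records$remoteness[first])
  n_cases <- tapply(records$case_id, skey, function(x) length(unique(x)))
  cost_sum <- tapply(comp_total, skey, sum)
  local_tab$cases <- as.integer(n_cases[skey[first]])
  local_tab$cost_per_case <- as.numeric(cost_sum[skey[first]]) / local_tab$cases
  demo_key <- function(d) paste(d$sex, d$indigenous, d$age_band, d$remoteness)
  local_tab$population <- strata$local$population[
    match(demo_key(local_tab), demo_key(strata$local))]
  # demographic cells with population but no cases contribute a zero rate
  # (they are part of the local denominator, not missing strata)
  empty <- strata$local[!demo_key(strata$local) %in% demo_key(local_tab), ,
                        drop = FALSE]
  if (nrow(empty)) {
    zero <- data.frame(stage = "1", sex = empty$sex,
                       indigenous = empty$indigenous,
                       age_band = empty$age_band,
                       remoteness = empty$remoteness, cases = 0L,
                       cost_per_case = 0, population = empty$population)
    local_tab <- rbind(local_tab, zero)
  }
  national <- extrapolate_national(local_tab, strata$national)

  staged_max <- stats::setNames(rep("None", length(included_ids)), included_ids)
  if (!is.null(periods) && nrow(periods)) {
    mx <- tapply(stage_severity(periods$stage), periods$person_id, max)
    staged_max[names(mx)] <- ckd_stages()[mx]
  }
  truth_inc <- cohort$truth[match(included_ids, cohort$truth$person_id), ]
  stage_recovery <- data.frame(person_id = included_ids,
                               true_stage = truth_inc$true_stage,
                               staged_stage = unname(staged_max))

  structure(list(config = config, catalog = catalog, cohort = cohort,
                 exclusions = exclusions, stage_periods = periods,
                 pairs = pairs, match_summary = match_summary(pairs),
                 fits = fits, records = records, stage_table = stage_table,
                 cost_ratio_pct = ratio, local_strata = local_tab,
                 national = national, stage_recovery = stage_recovery),
            class = "coi_result")
}

#' @export
print.coi_result <- function(x, ...) {
  cat(sprintf("<coi_result> %d persons, %d excluded, %d cases (%d matched)\n",
              nrow(x$cohort$persons), nrow(x$exclusions),
              nrow(x$pairs), sum(!is.na(x$pairs$control_id))))
  cat(sprintf("CKD raised individual healthcare costs by %.0f%% on average\n",
              x$cost_ratio_pct))
  print(x$stage_table)
  cat(sprintf("\nNational extrapolation: %.0f cases, total $%s\n",
              x$national$total_cases,
              format(round(x$national$total_cost), big.mark = ",")))
  invisible(x)
}
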