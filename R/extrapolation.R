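#' Parameters for the undiagnosed early-stage adjustment
#'
#' Early-stage CKD (Stages 1-2) requires uACR testing for diagnosis, which is
#' much less common than creatinine testing, so diagnosed counts understate
#' true prevalence. The adjustment combines population survey proportions of
#' albuminuria (single-measurement) with the persistence of albuminuria
#' beyond 90 days to estimate the true number of Stage 1 and Stage 2 cases.
#'
#' @param p_stage1 proportion of the eGFR >= 90 population with albuminuria
#'   (survey; default 0.057).
#' @param p_stage2 proportion of the eGFR 60-89 population with albuminuria
#'   (survey; default 0.097).
#' @param persistence proportion with a recorded albuminuria measurement who
#'   still had albuminuria at more than 90 days (default 0.66).
#' @param pop_egfr_ge90,pop_egfr_60_89 population counts in the two eGFR
#'   strata.
#' @param observed_stage1,observed_stage2 diagnosed case counts.
#' @return An object of class `undiagnosed_params`.
#' @export
undiagnosed_params <- function(p_stage1 = 0.057, p_stage2 = 0.097,
                               persistence = 0.66,
                               pop_egfr_ge90, pop_egfr_60_89,
                               observed_stage1, observed_stage2) {
  check_prob(c(p_stage1, p_stage2, persistence), "survey proportions")
  counts <- c(pop_egfr_ge90, pop_egfr_60_89, observed_stage1, observed_stage2)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("population and observed counts must be non-negative")
  }
  structure(list(p_stage1 = p_stage1, p_stage2 = p_stage2,
                 persistence = persistence, pop_egfr_ge90 = pop_egfr_ge90,
                 pop_egfr_60_89 = pop_egfr_60_89,
                 observed_stage1 = observed_stage1,
                 observed_stage2 = observed_stage2),
            class = "undiagnosed_params")
}

#' Estimate undiagnosed Stage 1-2 CKD counts
#'
#' Estimated true count per stage = stratum population x survey albuminuria
#' proportion x persistence beyond 90 days, computed in full precision and
#' rounded once; undiagnosed = estimated - observed. A negative difference is
#' floored at zero with a warning.
#'
#' @param params an [undiagnosed_params()].
#' @return data.frame with columns `stage`, `population`, `proportion`,
#'   `estimated`, `observed`, `undiagnosed`.
#' @export
estimate_undiagnosed <- function(params) {
  stopifnot(inherits(params, "undiagnosed_params"))
  est <- round_half_up(c(params$pop_egfr_ge90 * params$p_stage1,
                         params$pop_egfr_60_89 * params$p_stage2) *
                         params$persistence)
  obs <- c(params$observed_stage1, params$observed_stage2)
  und <- est - obs
  if (any(und < 0)) {
    warning("estimated count below observed for stage(s) ",
            paste(c("1", "2")[und < 0], collapse = ", "),
            "; undiagnosed floored at 0")
    und <- pmax(und, 0)
  }
  data.frame(stage = c("1", "2"),
             population = c(params$pop_egfr_ge90, params$pop_egfr_60_89),
             proportion = c(params$p_stage1, params$p_stage2),
             estimated = est, observed = obs, undiagnosed = und)
}

#' Cost the undiagnosed early-stage cases
#'
#' Applies the diagnosed per-person attributable cost of each stage to its
#' undiagnosed count and revises the total cost. Added costs are reported to
#' the nearest million (half away from zero).
#'
#' @param undiagnosed named numeric of undiagnosed counts by stage.
#' @param per_person_cost named numeric of attributable cost per person by
#'   stage (AUD).
#' @param diagnosed_total_million diagnosed total cost in millions of AUD.
#' @return List with `added_cost` (AUD by stage), `added_cost_million`
#'   (rounded, by stage) and `revised_total_million`.
#' @export
cost_undiagnosed <- function(undiagnosed, per_person_cost,
                             diagnosed_total_million) {
  if (any(undiagnosed < 0) || any(per_person_cost < 0)) {
    stop("counts and costs must be non-negative")
  }
  stages <- names(undiagnosed)
  if (is.null(stages) || !all(stages %in% names(per_person_cost))) {
    stop("per_person_cost must be named for every stage in undiagnosed")
  }
  added <- undiagnosed * per_person_cost[stages]
  added_million <- round_half_up(added / 1e6)
  list(added_cost = added, added_cost_million = added_million,
       revised_total_million = diagnosed_total_million + sum(added_million))
}

#' Extrapolate stratum-specific cases and costs to a national population
#'
#' For each combination of stage, sex, indigenous status, 5-year age band and
#' remoteness, the local case count is divided by the local population of
#' that demographic combination and multiplied by the national population of
#' the combination; the resulting national case counts are multiplied by the
#' per-person attributable cost and summed.
#'
#' Demographic cells present nationally but absent from the local table are
#' extrapolated from each stage's marginal local rate and mean cost, with a
#' warning. A local stratum with cases but zero population is a data error.
#'
#' @param local data.frame with columns `stage`, `sex`, `indigenous`,
#'   `age_band`, `remoteness`, `cases`, `population` (local population of the
#'   demographic combination) and `cost_per_case` (AUD).
#' @param national_pop data.frame with columns `sex`, `indigenous`,
#'   `age_band`, `remoteness`, `population`.
#' @return List with `by_stratum`, `by_stage` (stage, cases, total_cost),
#'   `total_cases` and `total_cost`.
#' @export
extrapolate_national <- function(local, national_pop) {
  demo <- c("sex", "indigenous", "age_band", "remoteness")
  miss <- setdiff(c("stage", demo, "cases", "population", "cost_per_case"),
                  names(local))
  if (length(miss)) stop("local table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(local$cases > 0 & local$population <= 0)) {
    stop("local stratum has cases but zero population")
  }
  key <- function(d) do.call(paste, c(d[demo], sep = "\r"))
  nat <- national_pop
  nat_key <- key(nat)
  loc_key <- key(local)
  idx <- match(loc_key, nat_key)
  if (anyNA(idx)) {
    stop("national population missing for ", sum(is.na(idx)),
         " local demographic combination(s)")
  }
  out <- local[, c("stage", demo)]
  rate <- ifelse(local$population > 0, local$cases / local$population, 0)
  out$cases <- rate * nat$population[idx]
  out$total_cost <- out$cases * local$cost_per_case

  # demographic cells with national population but no local representation:
  # borrow each stage's marginal local rate and mean cost
  extra_key <- setdiff(nat_key, unique(loc_key))
  if (length(extra_key)) {
    warning(length(extra_key), " national demographic cell(s) absent from the ",
            "local table; extrapolated from stage marginal rates")
    stage_rate <- tapply(local$cases, local$stage, sum) /
      tapply(local$population, local$stage, sum)
    stage_cost <- tapply(local$cases * local$cost_per_case, local$stage, sum) /
      tapply(local$cases, local$stage, sum)
    for (k in extra_key) {
      row <- nat[match(k, nat_key), , drop = FALSE]
      add <- row[rep(1, length(stage_rate)), demo, drop = FALSE]
      add$stage <- names(stage_rate)
      add$cases <- as.numeric(stage_rate) * row$population
      add$total_cost <- add$cases * ifelse(is.nan(stage_cost), 0,
                                           as.numeric(stage_cost))
      out <- rbind(out, add[, names(out)])
    }
  }
  agg_cases <- tapply(out$cases, out$stage, sum)
  agg_cost <- tapply(out$total_cost, out$stage, sum)
  stages <- ckd_stages()[ckd_stages() %in% names(agg_cases)]
  list(by_stratum = out,
       by_stage = data.frame(stage = stages,
                             cases = as.numeric(agg_cases[stages]),
                             total_cost = as.numeric(agg_cost[stages])),
       total_cases = sum(out$cases), total_cost = sum(out$total_cost))
}
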