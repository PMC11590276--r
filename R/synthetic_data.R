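# Fixed menus behind the synthetic linked records: event codes, their prices
# and the mixture probabilities the generator draws from. Prices are plausible
# Australian unit costs; 2019-based tables are inflated to 2023 at pricing
# time. These menus are shared by generate_cost_catalog(), generate_cohort()
# and expected_event_cost() so that every generated code has a price.
.sim_const <- local({
  med <- rbind(
    data.frame(medication = "M01", tier = c("general", "concessional", "safety_net"),
               price = c(31.60, 7.70, 0.00), weight = c(0.35, 0.50, 0.15)),
    data.frame(medication = "M02", tier = c("general", "concessional", "safety_net"),
               price = c(24.50, 7.70, 0.00), weight = c(0.40, 0.45, 0.15)),
    data.frame(medication = "M03", tier = c("general", "concessional", "safety_net"),
               price = c(57.50, 7.70, 0.00), weight = c(0.50, 0.40, 0.10)),
    data.frame(medication = "M04", tier = c("general", "concessional", "safety_net"),
               price = c(15.30, 7.70, 0.00), weight = c(0.30, 0.55, 0.15)),
    data.frame(medication = "M05", tier = c("general", "concessional", "safety_net"),
               price = c(28.90, 7.70, 0.00), weight = c(0.40, 0.45, 0.15)),
    data.frame(medication = "M06", tier = c("general", "concessional", "safety_net"),
               price = c(310.00, 7.70, 0.00), weight = c(0.45, 0.45, 0.10)))
  list(
    drg = data.frame(code = c("E62B", "F74Z", "G67B", "I68B", "K60B", "A09B"),
                     cost = c(1200, 2100, 3500, 5200, 8000, 16000),
                     prob = c(0.25, 0.25, 0.20, 0.15, 0.10, 0.05)),
    dialysis_drg = "L61Z", dialysis_cost = 650,
    emergency = data.frame(
      status = c("admitted", "discharged", "died", "left_at_own_risk"),
      cost = c(1550, 640, 980, 310), prob = c(0.30, 0.55, 0.02, 0.13)),
    gp_items = data.frame(item = c("23", "36", "44"),
                          fee = c(39.75, 76.95, 113.30),
                          prob = c(0.60, 0.30, 0.10)),
    path_fees = c("66500" = 17.70, "65070" = 16.95, "66512" = 17.70,
                  "66551" = 16.80, "66536" = 11.30),
    path_panels = list(basic = c("66500", "65070"),
                       extended = c("66500", "65070", "66512", "66551", "66536")),
    panel_prob = c(basic = 0.70, extended = 0.30),
    collection_fee = 11.95, bulk_fee = 7.45,
    med = med, med_prob = c(M01 = 0.20, M02 = 0.20, M03 = 0.15,
                            M04 = 0.25, M05 = 0.15, M06 = 0.05),
    repeats = data.frame(n = c(0, 1, 2, 5), prob = c(0.30, 0.20, 0.30, 0.20)),
    dispensing = 7.74, handling = 1.17, safety_net = 1.51,
    inflation = c("2019" = 1.16, "2023" = 1),
    # stage-conditional demographics of the simulated cohort
    band_mu = c(None = 7.5, "1" = 6, "2" = 9, "3a" = 11.5, "3b" = 12.5,
                "4" = 13, "5" = 9.5),
    band_sd = 2.5,
    indig_prob = c(None = 0.03, "1" = 0.32, "2" = 0.18, "3a" = 0.02,
                   "3b" = 0.03, "4" = 0.05, "5" = 0.19),
    remote_prob = rbind(None = c(0.75, 0.19, 0.06), "1" = c(0.55, 0.16, 0.29),
                        "2" = c(0.66, 0.17, 0.17), "3a" = c(0.76, 0.20, 0.04),
                        "3b" = c(0.76, 0.19, 0.05), "4" = c(0.75, 0.19, 0.06),
                        "5" = c(0.69, 0.17, 0.14)),
    # eGFR band (mL/min/1.73m^2) the trajectory is confined to, per true stage
    egfr_band = rbind(None = c(80, 110), "1" = c(92, 110), "2" = c(62, 88),
                      "3a" = c(46, 59), "3b" = c(31, 44), "4" = c(16, 29),
                      "5" = c(5, 14)))
})

#' Default per-stage annual cost means for the generator
#'
#' Mean annual cost per person-year (2023 AUD, including zero-cost years) for
#' each cost component at each true stage. The no-CKD baseline reflects a
#' matched-control population (older, often diabetic), and the per-stage
#' increments over that baseline follow the attributable cost-per-person-year
#' profile reported for the Western Australian CKD cohort: costs rise
#' steadily with stage, medication costs are elevated in Stages 1-2 (the
#' diabetes-enriched early stages), dialysis costs are confined to Stage 5,
#' and outpatient renal-clinic costs appear from Stage 3a.
#'
#' @return data.frame with columns `component`, `stage`, `mean`, `shape`
#'   (the gamma shape controlling between-person cost heterogeneity).
#' @export
default_cost_params <- function() {
  comps <- cost_components()
  baseline <- c(emergency = 480, hospital_nondialysis = 5700,
                medication = 1350, primary_care = 1150, pathology = 240,
                dialysis = 0, outpatient = 0)
  attributable <- rbind(
    emergency            = c(148, 255, 269, 550, 1028, 2454),
    hospital_nondialysis = c(1515, 2255, 2470, 4592, 8400, 19723),
    medication           = c(1374, 1172, 577, 831, 1121, 1780),
    primary_care         = c(315, 401, 230, 347, 463, 474),
    pathology            = c(14, 31, 47, 96, 168, 203),
    dialysis             = c(0, 0, 0, 0, 0, 36982),
    outpatient           = c(0, 0, 15, 156, 274, 942))
  colnames(attributable) <- ckd_stages()
  shape <- c(emergency = 1.5, hospital_nondialysis = 1.3, medication = 2,
             primary_care = 2.5, pathology = 2.5, dialysis = 8, outpatient = 1)
  out <- expand.grid(component = comps, stage = stage_levels(),
                     stringsAsFactors = FALSE)
  out$mean <- baseline[out$component]
  ckd <- out$stage != "None"
  out$mean[ckd] <- out$mean[ckd] +
    attributable[cbind(out$component[ckd], out$stage[ckd])]
  out$shape <- shape[out$component]
  out
}

#' Configure the synthetic linked-data generator
#'
#' Defines the study conditions the generator emulates: cohort size, analysis
#' year, true-stage prevalence, diabetes prevalence by stage (the
#' diabetes-by-stage confounding seen in real early-stage CKD cohorts), the
#' low population coverage of uACR testing, stage-dependent cost
#' distributions (gamma-shaped with a point mass at zero), mortality, loss to
#' follow-up, and the sub-dataset memberships that drive the cost-model
#' transfer (general-practice extract membership; dominant pathology
#' provider).
#'
#' @param n_persons cohort size.
#' @param analysis_year calendar year costs are computed for.
#' @param stage_prevalence named probabilities over [stage_levels()], summing
#'   to 1.
#' @param diabetes_prob_by_stage named probabilities over [stage_levels()].
#' @param uacr_testing_prob probability a person without early-stage CKD ever
#'   receives uACR testing (persons whose true stage is 1 or 2 always do, by
#'   construction of their trajectories).
#' @param component_cost_params data.frame as [default_cost_params()].
#' @param zero_cost_prob named probability of a zero-cost year per component.
#' @param death_prob probability of death during the analysis year.
#' @param lost_to_followup_prob probability a person has no records in or
#'   after the analysis year (excluded downstream).
#' @param inconsistent_interim_prob among no-CKD persons, probability of an
#'   "inconsistent interim" trajectory: two sub-60 eGFR results more than 90
#'   days apart with an interim result of 60 or more, which the staging rules
#'   must reject.
#' @param gp_data_prob probability a person belongs to the general-practice
#'   extract (medication and GP costs observed).
#' @param wd_dominant_prob probability a person uses the designated pathology
#'   provider for effectively all community pathology.
#' @param pop_multiplier local population per cohort member in each
#'   demographic stratum (>= 1).
#' @param national_multiplier national over local population ratio (>= 1).
#' @param seed integer seed; the same configuration and seed give
#'   bit-identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_persons = 10000,
                       analysis_year = 2019,
                       stage_prevalence = c(None = 0.88, "1" = 0.0082,
                                            "2" = 0.0089, "3a" = 0.0662,
                                            "3b" = 0.0256, "4" = 0.0071,
                                            "5" = 0.0040),
                       diabetes_prob_by_stage = c(None = 0.08, "1" = 0.44,
                                                  "2" = 0.49, "3a" = 0.12,
                                                  "3b" = 0.15, "4" = 0.20,
                                                  "5" = 0.15),
                       uacr_testing_prob = 0.24,
                       component_cost_params = default_cost_params(),
                       zero_cost_prob = c(emergency = 0.55,
                                          hospital_nondialysis = 0.45,
                                          medication = 0.12,
                                          primary_care = 0.08,
                                          pathology = 0.10, dialysis = 0,
                                          outpatient = 0),
                       death_prob = 0.02,
                       lost_to_followup_prob = 0.01,
                       inconsistent_interim_prob = 0.05,
                       gp_data_prob = 0.5,
                       wd_dominant_prob = 0.6,
                       pop_multiplier = 50,
                       national_multiplier = 10,
                       seed = 1L) {
  cfg <- structure(list(
    n_persons = as.integer(n_persons), analysis_year = as.integer(analysis_year),
    stage_prevalence = stage_prevalence,
    diabetes_prob_by_stage = diabetes_prob_by_stage,
    uacr_testing_prob = uacr_testing_prob,
    component_cost_params = component_cost_params,
    zero_cost_prob = zero_cost_prob, death_prob = death_prob,
    lost_to_followup_prob = lost_to_followup_prob,
    inconsistent_interim_prob = inconsistent_interim_prob,
    gp_data_prob = gp_data_prob, wd_dominant_prob = wd_dominant_prob,
    pop_multiplier = pop_multiplier, national_multiplier = national_multiplier,
    seed = as.integer(seed)), class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_persons < 1) stop("n_persons must be >= 1")
  if (!setequal(names(cfg$stage_prevalence), stage_levels())) {
    stop("stage_prevalence must be named over: ",
         paste(stage_levels(), collapse = ", "))
  }
  check_prob(cfg$stage_prevalence, "stage_prevalence")
  if (abs(sum(cfg$stage_prevalence) - 1) > 1e-8) {
    stop("stage_prevalence must sum to 1")
  }
  if (!setequal(names(cfg$diabetes_prob_by_stage), stage_levels())) {
    stop("diabetes_prob_by_stage must be named over all stage levels")
  }
  check_prob(cfg$diabetes_prob_by_stage, "diabetes_prob_by_stage")
  check_prob(c(cfg$uacr_testing_prob, cfg$death_prob,
               cfg$lost_to_followup_prob, cfg$inconsistent_interim_prob,
               cfg$gp_data_prob, cfg$wd_dominant_prob), "rate parameters")
  p <- cfg$component_cost_params
  if (!all(c("component", "stage", "mean", "shape") %in% names(p))) {
    stop("component_cost_params needs columns component, stage, mean, shape")
  }
  if (any(!is.finite(p$mean)) || any(p$mean < 0)) {
    stop("configured cost means must be non-negative and finite")
  }
  if (any(p$mean > 0 & (!is.finite(p$shape) | p$shape <= 0))) {
    stop("gamma shape must be > 0 wherever the cost mean is positive")
  }
  if (!setequal(names(cfg$zero_cost_prob), cost_components())) {
    stop("zero_cost_prob must be named over all cost components")
  }
  check_prob(cfg$zero_cost_prob, "zero_cost_prob")
  if (cfg$pop_multiplier < 1 || cfg$national_multiplier < 1) {
    stop("population multipliers must be >= 1")
  }
  cfg
}

#' Generate the unit-cost catalog for the synthetic records
#'
#' Builds a [cost_catalog()] covering every DRG, emergency end status,
#' medication and MBS item the cohort generator can emit, so catalog lookups
#' are closed over generated events. The catalog is deterministic for a given
#' configuration.
#'
#' @param config a [sim_config()].
#' @return A `cost_catalog`.
#' @export
generate_cost_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- .sim_const
  drg <- stats::setNames(c(k$drg$cost, k$dialysis_cost),
                         c(k$drg$code, k$dialysis_drg))
  cost_catalog(
    drg_unit_costs = drg, dialysis_drgs = k$dialysis_drg,
    emergency_costs = stats::setNames(k$emergency$cost, k$emergency$status),
    mbs_item_fees = c(stats::setNames(k$gp_items$fee, k$gp_items$item),
                      k$path_fees),
    collection_fee = k$collection_fee, bulk_billing_fee = k$bulk_fee,
    medication_tiers = k$med, dispensing_fee = k$dispensing,
    handling_fee = k$handling, safety_net_fee = k$safety_net,
    inflation = k$inflation,
    drg_year = 2019, emergency_year = 2023, mbs_year = 2019,
    medication_year = 2019)
}

#' Expected cost per generated utilisation event
#'
#' The generator draws event counts with intensity `mean / expected event
#' cost`, so that the priced annual cost of a component has the configured
#' mean. This helper evaluates that per-event expectation through the costing
#' functions themselves (mixture over the generator's code menus), in 2023
#' AUD.
#'
#' @param component one of [cost_components()] except `outpatient` (which is
#'   costed top-down, not event by event).
#' @param catalog the catalog from [generate_cost_catalog()].
#' @return Expected 2023 AUD per event.
#' @export
expected_event_cost <- function(component, catalog) {
  k <- .sim_const
  switch(component,
    emergency = sum(k$emergency$prob * cost_emergency(k$emergency$status, catalog)),
    hospital_nondialysis = {
      priced <- cost_admission(k$drg$code, FALSE, catalog)
      sum(k$drg$prob * priced$amount)
    },
    dialysis = cost_admission(k$dialysis_drg, TRUE, catalog)$amount,
    medication = sum(k$med_prob *
                       price_medication(names(k$med_prob), catalog)) *
      sum(k$repeats$prob * (1 + k$repeats$n)),
    primary_care = sum(k$gp_items$prob *
                         vapply(k$gp_items$item, cost_gp, numeric(1),
                                catalog = catalog)),
    pathology = sum(k$panel_prob *
                      vapply(k$path_panels, cost_pathology_collection,
                             numeric(1), catalog = catalog)),
    stop("no per-event cost for component ", component))
}

#' Generate a synthetic linked cohort
#'
#' Draws a cohort of persons with stage-conditional demographics, builds each
#' person's laboratory trajectory backward from their true stage (two
#' confirmatory results more than 90 days apart with consistent interim
#' results, placed before the analysis year so the stage holds across it, plus
#' in-year monitoring results in the same band), and draws priced utilisation
#' events whose annual cost has the configured stage-specific mean: a
#' zero-cost year with the configured probability, otherwise a gamma person
#' effect times a Poisson event count over the person's exposure. Diabetes
#' labs (paired HbA1c > 6.5% or fasting glucose > 7.0 mmol/L) are generated
#' consistently with the diabetes flag so the flag is re-derivable. A
#' configurable fraction of no-CKD persons receive inconsistent-interim
#' trajectories that the staging rules must reject, and a configurable
#' fraction are lost to follow-up (no records in or after the analysis year).
#'
#' @param config a [sim_config()].
#' @return List of class `ckd_cohort`: `persons`, `labs`, `events`, `truth`
#'   data.frames.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- .sim_const
  set.seed(config$seed)
  n <- config$n_persons
  year <- config$analysis_year
  y0 <- as.Date(sprintf("%d-01-01", year))
  y1 <- as.Date(sprintf("%d-12-31", year))
  y0n <- as.numeric(y0)
  days_in_year <- as.integer(y1 - y0) + 1L

  lv <- stage_levels()
  true_stage <- sample(lv, n, replace = TRUE, prob = config$stage_prevalence[lv])
  sex <- sample(c("male", "female"), n, replace = TRUE)
  band_idx <- pmin(length(age_bands()),
                   pmax(1, round(stats::rnorm(n, k$band_mu[true_stage], k$band_sd))))
  age_band <- age_bands()[band_idx]
  age_mid <- age_band_midpoint(age_band)
  indigenous <- stats::runif(n) < k$indig_prob[true_stage]
  remoteness <- vapply(seq_len(n), function(i) {
    sample(remoteness_levels(), 1, prob = k$remote_prob[true_stage[i], ])
  }, character(1))
  diabetes <- stats::runif(n) < config$diabetes_prob_by_stage[true_stage]
  use_fpg <- stats::runif(n) < 0.2
  ltf <- stats::runif(n) < config$lost_to_followup_prob
  died <- !ltf & stats::runif(n) < config$death_prob
  death_day <- ifelse(died, sample.int(days_in_year, n, replace = TRUE) - 1L, NA)
  inconsistent <- true_stage == "None" & !ltf &
    stats::runif(n) < config$inconsistent_interim_prob
  in_gp <- stats::runif(n) < config$gp_data_prob
  wd_dom <- stats::runif(n) < config$wd_dominant_prob
  person_id <- sprintf("P%06d", seq_len(n))

  catalog <- generate_cost_catalog(config)
  comps_bu <- c("emergency", "hospital_nondialysis", "medication",
                "primary_care", "pathology")
  e_cost <- vapply(c(comps_bu, "dialysis"), expected_event_cost, numeric(1),
                   catalog = catalog)
  pars <- config$component_cost_params
  mean_mat <- matrix(0, nrow = length(cost_components()), ncol = length(lv),
                     dimnames = list(cost_components(), lv))
  shape_vec <- stats::setNames(rep(1, length(cost_components())), cost_components())
  mean_mat[cbind(pars$component, pars$stage)] <- pars$mean
  shape_vec[pars$component] <- pars$shape
  p0 <- config$zero_cost_prob

  labs_acc <- vector("list", n)
  events_acc <- vector("list", n)

  for (i in seq_len(n)) {
    stg <- true_stage[i]
    sx <- sex[i]
    age <- age_mid[i]
    L <- list(date = numeric(0), analyte = character(0), value = numeric(0))

    if (ltf[i]) {
      old <- y0n - 730 - sample(0:200, 1)
      band <- k$egfr_band[stg, ]
      e_old <- stats::runif(1, band[1], band[2])
      L$date <- old; L$analyte <- "creatinine"
      L$value <- invert_egfr(e_old, age, sx)
      labs_acc[[i]] <- L
      next
    }

    wdays <- if (died[i]) death_day[i] + 1L else days_in_year
    band <- k$egfr_band[stg, ]
    centre <- stats::runif(1, band[1] + 1, band[2] - 1)
    egfr_val <- function(m) pmin(band[2], pmax(band[1], centre + stats::runif(m, -1, 1)))
    add_lab <- function(date, analyte, value) {
      L$date <<- c(L$date, date)
      L$analyte <<- c(L$analyte, rep_len(analyte, length(date)))
      L$value <<- c(L$value, rep_len(value, length(date)))
    }
    in_year_days <- function(m) sort(sample.int(wdays, m, replace = m > wdays)) - 1L

    thr <- if (sx == "male") 2.5 else 3.5
    t2 <- y0n - sample(10:60, 1)
    t1 <- t2 - sample(91:200, 1)

    if (stg %in% c("3a", "3b", "4", "5")) {
      conf_dates <- c(t1, if (stats::runif(1) < 0.5) round((t1 + t2) / 2), t2)
      add_lab(conf_dates, "creatinine",
              invert_egfr(egfr_val(length(conf_dates)), age, sx))
      m <- sample(1:3, 1)
      add_lab(y0n + in_year_days(m), "creatinine",
              invert_egfr(egfr_val(m), age, sx))
      if (stats::runif(1) < config$uacr_testing_prob) {
        add_lab(y0n + in_year_days(1), "uacr", stats::runif(1, 0.3, 2.0))
      }
    } else if (stg %in% c("1", "2")) {
      u_dates <- c(t1, if (stats::runif(1) < 0.5) round((t1 + t2) / 2), t2)
      add_lab(u_dates, "uacr", thr + stats::runif(length(u_dates), 0.5, 25))
      m <- sample(1:2, 1)
      add_lab(y0n + in_year_days(m), "uacr", thr + stats::runif(m, 0.5, 25))
      add_lab(t1, "creatinine", invert_egfr(egfr_val(1), age, sx))
      mc <- sample(1:2, 1)
      add_lab(y0n + in_year_days(mc), "creatinine",
              invert_egfr(egfr_val(mc), age, sx))
    } else {
      m <- sample(1:2, 1)
      add_lab(y0n + in_year_days(m), "creatinine",
              invert_egfr(egfr_val(m), age, sx))
      if (inconsistent[i]) {
        add_lab(c(t1, t1 + 45, t2), "creatinine",
                invert_egfr(c(55, 65, 55), age, sx))
      }
      if (stats::runif(1) < config$uacr_testing_prob) {
        add_lab(y0n + in_year_days(1), "uacr", stats::runif(1, 0.3, 2.0))
      }
    }

    if (diabetes[i]) {
      d1 <- y0n - sample(100:300, 1)
      d2 <- y0n + in_year_days(1)
      if (use_fpg[i]) {
        add_lab(c(d1, d2), "fpg", stats::runif(2, 7.5, 10))
      } else {
        add_lab(c(d1, d2), "hba1c", stats::runif(2, 6.7, 9.5))
      }
    } else if (stats::runif(1) < 0.6) {
      add_lab(y0n + in_year_days(1), "hba1c", stats::runif(1, 4.8, 6.4))
    }
    labs_acc[[i]] <- L

    # utilisation events: zero-inflated gamma-Poisson counts per component
    E <- list(date = numeric(0), kind = character(0), drg = character(0),
              dialysis = logical(0), end_status = character(0),
              medication = character(0), n_repeats = numeric(0),
              items = character(0), provider_id = character(0))
    frac <- wdays / 365
    add_events <- function(kind, nev, dates, drg = NA_character_,
                           dialysis = FALSE, end_status = NA_character_,
                           medication = NA_character_, n_repeats = NA_real_,
                           items = NA_character_, provider = NA_character_) {
      E$date <<- c(E$date, dates)
      E$kind <<- c(E$kind, rep(kind, nev))
      E$drg <<- c(E$drg, rep_len(drg, nev))
      E$dialysis <<- c(E$dialysis, rep_len(dialysis, nev))
      E$end_status <<- c(E$end_status, rep_len(end_status, nev))
      E$medication <<- c(E$medication, rep_len(medication, nev))
      E$n_repeats <<- c(E$n_repeats, rep_len(n_repeats, nev))
      E$items <<- c(E$items, rep_len(items, nev))
      E$provider_id <<- c(E$provider_id, rep_len(provider, nev))
    }
    n_events <- function(comp) {
      m <- mean_mat[comp, stg]
      if (m <= 0) return(0L)
      pz <- p0[comp]
      if (pz > 0 && stats::runif(1) < pz) return(0L)
      g <- stats::rgamma(1, shape = shape_vec[comp], rate = shape_vec[comp])
      stats::rpois(1, g * m / ((1 - pz) * e_cost[comp]) * frac)
    }
    ev_dates <- function(m, unique_days = FALSE) {
      y0n + sample.int(wdays, m, replace = if (unique_days) m > wdays else TRUE) - 1L
    }

    nev <- n_events("emergency")
    if (nev > 0) add_events("emergency", nev, ev_dates(nev),
                            end_status = sample(k$emergency$status, nev, TRUE,
                                                k$emergency$prob))
    nev <- n_events("hospital_nondialysis")
    if (nev > 0) add_events("admission", nev, ev_dates(nev),
                            drg = sample(k$drg$code, nev, TRUE, k$drg$prob),
                            dialysis = FALSE)
    nev <- n_events("medication")
    if (nev > 0) add_events("prescription", nev, ev_dates(nev),
                            medication = sample(names(k$med_prob), nev, TRUE,
                                                k$med_prob),
                            n_repeats = sample(k$repeats$n, nev, TRUE,
                                               k$repeats$prob))
    nev <- n_events("primary_care")
    if (nev > 0) add_events("gp_visit", nev, ev_dates(nev),
                            items = sample(k$gp_items$item, nev, TRUE,
                                           k$gp_items$prob))
    nev <- n_events("pathology")
    if (nev > 0) {
      panels <- sample(names(k$path_panels), nev, TRUE, k$panel_prob)
      prov <- if (wd_dom[i]) rep("WD", nev) else sample(c("WD", "PW"), nev, TRUE)
      add_events("pathology_collection", nev, ev_dates(nev, unique_days = TRUE),
                 items = vapply(panels, function(p) {
                   paste(k$path_panels[[p]], collapse = ";")
                 }, character(1)),
                 provider = prov)
    }
    if (stg == "5") {
      nev <- n_events("dialysis")
      if (nev > 0) add_events("admission", nev, ev_dates(nev),
                              drg = k$dialysis_drg, dialysis = TRUE)
    }
    events_acc[[i]] <- E
  }

  bind_person_lists <- function(acc, ids) {
    lens <- vapply(acc, function(x) if (is.null(x)) 0L else length(x$date),
                   integer(1))
    keep <- which(lens > 0)
    cols <- names(acc[[keep[1]]])
    out <- lapply(cols, function(cl) {
      unlist(lapply(keep, function(i) acc[[i]][[cl]]), use.names = FALSE)
    })
    names(out) <- cols
    out$person_id <- rep(ids[keep], lens[keep])
    out$date <- as.Date(out$date, origin = "1970-01-01")
    as.data.frame(out)[, c("person_id", setdiff(cols, "person_id"))]
  }

  labs <- bind_person_lists(labs_acc, person_id)
  labs$provider_id <- "PW"
  labs <- labs[order(labs$person_id, labs$date), , drop = FALSE]
  rownames(labs) <- NULL
  if (any(vapply(events_acc, function(x) !is.null(x) && length(x$date) > 0,
                 logical(1)))) {
    events <- bind_person_lists(events_acc, person_id)
    events <- events[order(events$person_id, events$date), , drop = FALSE]
    rownames(events) <- NULL
  } else {
    events <- data.frame(person_id = character(), date = as.Date(character()),
                         kind = character(), drg = character(),
                         dialysis = logical(), end_status = character(),
                         medication = character(), n_repeats = numeric(),
                         items = character(), provider_id = character())
  }

  persons <- data.frame(person_id = person_id, sex = sex, age_band = age_band,
                        age_mid = age_mid, indigenous = indigenous,
                        remoteness = remoteness, diabetes = diabetes,
                        death_date = as.Date(ifelse(died, y0n + death_day, NA),
                                             origin = "1970-01-01"),
                        in_gp_dataset = in_gp)
  truth <- data.frame(person_id = person_id, true_stage = true_stage,
                      lost_to_followup = ltf,
                      inconsistent_interim = inconsistent,
                      wd_dominant = wd_dom)
  structure(list(persons = persons, labs = labs, events = events,
                 truth = truth, config = config),
            class = "ckd_cohort")
}

#' @export
print.ckd_cohort <- function(x, ...) {
  cat(sprintf("<ckd_cohort> %d persons, %d lab results, %d utilisation events (%d)\n",
              nrow(x$persons), nrow(x$labs), nrow(x$events),
              x$config$analysis_year))
  print(table(true_stage = x$truth$true_stage)[stage_levels()])
  invisible(x)
}

#' Generate local and national population stratum tables
#'
#' Population denominators by demographic stratum (sex, indigenous status,
#' 5-year age band, remoteness): the local population is the cohort's stratum
#' count scaled by `pop_multiplier`, and the national population is the local
#' count scaled by `national_multiplier`, so every cohort stratum has a
#' population at least as large as its cohort count and the national counts
#' dominate the local ones.
#'
#' @param config a [sim_config()].
#' @param persons the `persons` table from [generate_cohort()]; when omitted
#'   the cohort is regenerated from `config` (deterministic under the seed).
#' @return List with `local` and `national` data.frames (`sex`, `indigenous`,
#'   `age_band`, `remoteness`, `population`).
#' @export
generate_population_strata <- function(config, persons = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(persons)) persons <- generate_cohort(config)$persons
  counts <- stats::aggregate(list(n = persons$person_id),
                             persons[, c("sex", "indigenous", "age_band",
                                         "remoteness")], FUN = length)
  local <- counts
  local$population <- as.integer(ceiling(counts$n * config$pop_multiplier))
  local$n <- NULL
  national <- local
  national$population <- as.integer(local$population * config$national_multiplier)
  list(local = local, national = national)
}
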