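test_that("configuration validation rejects malformed study conditions", {
  expect_error(sim_config(stage_prevalence = c(None = 0.5, "1" = 0.1, "2" = 0.1,
                                               "3a" = 0.1, "3b" = 0.1, "4" = 0.1,
                                               "5" = 0.1)), "sum to 1")
  expect_error(sim_config(death_prob = 1.5), "probabilities")
  bad <- default_cost_params()
  bad$mean[1] <- -10
  expect_error(sim_config(component_cost_params = bad), "non-negative")
  bad2 <- default_cost_params()
  bad2$shape[bad2$mean > 0][1] <- 0
  expect_error(sim_config(component_cost_params = bad2), "shape")
})

test_that("generation is bit-identical under the same seed", {
  cfg <- sim_config(n_persons = 150, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$persons, b$persons)
  expect_identical(a$labs, b$labs)
  expect_identical(a$events, b$events)
  expect_identical(a$truth, b$truth)
  expect_identical(generate_cost_catalog(cfg), generate_cost_catalog(cfg))
  s1 <- generate_population_strata(cfg, a$persons)
  s2 <- generate_population_strata(cfg, b$persons)
  expect_identical(s1, s2)
  c2 <- generate_cohort(sim_config(n_persons = 150, seed = 100))
  expect_false(identical(a$labs, c2$labs))
})

test_that("a no-CKD cohort produces no chronically-confirming trajectories", {
  prev <- c(None = 1, "1" = 0, "2" = 0, "3a" = 0, "3b" = 0, "4" = 0, "5" = 0)
  cfg <- sim_config(n_persons = 60, stage_prevalence = prev,
                    inconsistent_interim_prob = 0, seed = 21)
  coh <- generate_cohort(cfg)
  for (i in seq_len(nrow(coh$persons))) {
    p <- coh$persons[i, ]
    cre <- coh$labs[coh$labs$person_id == p$person_id &
                      coh$labs$analyte == "creatinine", ]
    eg <- data.frame(date = cre$date,
                     egfr = compute_egfr(cre$value, p$age_mid, p$sex))
    ua <- coh$labs[coh$labs$person_id == p$person_id &
                     coh$labs$analyte == "uacr", ]
    ua <- if (nrow(ua)) data.frame(date = ua$date, uacr = ua$value) else NULL
    expect_true(is.na(detect_ckd(eg, ua, p$sex)))
    # literally: no two sub-60 eGFR results more than 90 days apart
    low <- eg$date[eg$egfr < 60]
    if (length(low) >= 2) {
      expect_true(max(low) - min(low) <= 90)
    }
  }
  # inconsistent-interim trajectories carry sub-60 pairs that staging rejects
  cfg2 <- sim_config(n_persons = 120, stage_prevalence = prev,
                     inconsistent_interim_prob = 1, seed = 22)
  coh2 <- generate_cohort(cfg2)
  tease <- coh2$truth$person_id[coh2$truth$inconsistent_interim]
  expect_gt(length(tease), 0)
  for (pid in tease[1:10]) {
    p <- coh2$persons[coh2$persons$person_id == pid, ]
    cre <- coh2$labs[coh2$labs$person_id == pid &
                       coh2$labs$analyte == "creatinine", ]
    eg <- data.frame(date = cre$date,
                     egfr = compute_egfr(cre$value, p$age_mid, p$sex))
    low <- eg$date[eg$egfr < 60]
    expect_true(max(low) - min(low) > 90)      # a tempting pair exists ...
    expect_true(is.na(detect_ckd(eg, NULL, p$sex)))  # ... but is rejected
  }
})

test_that("the generated catalog is closed over every generated code", {
  cfg <- sim_config(n_persons = 250, seed = 13)
  coh <- generate_cohort(cfg)
  cat <- generate_cost_catalog(cfg)
  ev <- coh$events
  expect_true(all(ev$drg[ev$kind == "admission"] %in% names(cat$drg_unit_costs)))
  expect_true(all(ev$end_status[ev$kind == "emergency"] %in%
                    names(cat$emergency_costs)))
  expect_true(all(ev$medication[ev$kind == "prescription"] %in%
                    cat$medication_tiers$medication))
  items <- unlist(strsplit(ev$items[ev$kind %in% c("gp_visit",
                                                   "pathology_collection")],
                           ";", fixed = TRUE))
  expect_true(all(items %in% names(cat$mbs_item_fees)))
  wsum <- tapply(cat$medication_tiers$weight, cat$medication_tiers$medication, sum)
  expect_true(all(abs(wsum - 1) < 1e-12))
  # diabetes labs re-derive the simulated flag exactly (for followed persons;
  # lost-to-follow-up persons carry a single stale result by design)
  followed <- coh$persons$person_id[!coh$truth$lost_to_followup]
  flags <- vapply(followed, function(pid) {
    derive_diabetes_flag(coh$labs[coh$labs$person_id == pid, ])
  }, logical(1))
  expect_equal(unname(flags),
               coh$persons$diabetes[match(followed, coh$persons$person_id)])
  # lost-to-follow-up persons have no records in or after the analysis year
  y0 <- as.Date("2019-01-01")
  for (pid in coh$truth$person_id[coh$truth$lost_to_followup]) {
    dates <- c(coh$labs$date[coh$labs$person_id == pid],
               ev$date[ev$person_id == pid])
    expect_true(all(dates < y0))
  }
})

test_that("population strata dominate cohort counts and scale as configured", {
  cfg <- sim_config(n_persons = 300, seed = 31, pop_multiplier = 40,
                    national_multiplier = 3)
  coh <- generate_cohort(cfg)
  st <- generate_population_strata(cfg, coh$persons)
  expect_true(all(st$local$population == floor(st$local$population)))
  expect_true(all(st$local$population >= 0))
  key <- function(d) paste(d$sex, d$indigenous, d$age_band, d$remoteness)
  cohort_n <- table(key(coh$persons))
  idx <- match(names(cohort_n), key(st$local))
  expect_true(all(st$local$population[idx] >= as.integer(cohort_n)))
  expect_true(all(st$national$population == 3 * st$local$population))
})

test_that("simulated annual component costs match their configured means", {
  cfg <- sim_config(n_persons = 1500, seed = 41, death_prob = 0,
                    lost_to_followup_prob = 0)
  coh <- generate_cohort(cfg)
  cat <- generate_cost_catalog(cfg)
  none_ids <- coh$truth$person_id[coh$truth$true_stage == "None"]
  ev <- coh$events[coh$events$person_id %in% none_ids, ]
  ev_by <- split(ev, ev$person_id)
  y0 <- as.Date("2019-01-01"); y1 <- as.Date("2019-12-31")
  costs <- t(vapply(none_ids, function(pid) {
    build_ledger(pid, y0, y1, ev_by[[pid]], cat)$components
  }, setNames(numeric(7), cost_components())))
  pars <- cfg$component_cost_params
  for (comp in c("hospital_nondialysis", "medication", "primary_care")) {
    m_cfg <- pars$mean[pars$component == comp & pars$stage == "None"]
    se <- stats::sd(costs[, comp]) / sqrt(nrow(costs))
    expect_lt(abs(mean(costs[, comp]) - m_cfg), 3 * se)
  }
})
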