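d0 <- as.Date("2019-01-01")

test_that("CKD-EPI eGFR matches an independent evaluation of the closed form", {
  # direct arithmetic, written out independently of the package function
  ref <- function(scr_mgdl, age, female) {
    kappa <- if (female) 0.7 else 0.9
    alpha <- if (female) -0.329 else -0.411
    141 * min(scr_mgdl / kappa, 1)^alpha * max(scr_mgdl / kappa, 1)^(-1.209) *
      0.993^age * (if (female) 1.018 else 1)
  }
  e1 <- compute_egfr(61.9, age = 50, sex = "female")
  e2 <- compute_egfr(159, age = 70, sex = "male")
  expect_equal(e1, ref(61.9 / 88.4, 50, TRUE), tolerance = 1e-12)
  expect_equal(e2, ref(159 / 88.4, 70, FALSE), tolerance = 1e-12)
  expect_equal(e1, 101, tolerance = 0.01)  # published worked value, +/- 1
  expect_equal(e2, 37, tolerance = 0.01)

  # monotonicity: doubling creatinine strictly lowers eGFR
  grid <- expand.grid(cr = c(50, 80, 120, 200), age = c(25, 60, 85),
                      sex = c("male", "female"))
  expect_true(all(compute_egfr(grid$cr * 2, grid$age, as.character(grid$sex)) <
                    compute_egfr(grid$cr, grid$age, as.character(grid$sex))))
  expect_error(compute_egfr(-1, 50, "female"), "positive")
  expect_error(compute_egfr(80, 10, "female"), ">= 18")
})

test_that("KDIGO stage assignment follows the eGFR bands and albuminuria rule", {
  expect_equal(assign_kdigo_stage(92, TRUE), "1")
  expect_true(is.na(assign_kdigo_stage(72, FALSE)))
  expect_equal(assign_kdigo_stage(14, FALSE), "5")
  expect_equal(assign_kdigo_stage(c(95, 75, 59.9, 60, 45, 44.9, 30, 29.9, 15, 14.9),
                                  c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE,
                                    FALSE, FALSE, FALSE, FALSE)),
               c(NA, "2", "3a", "2", "3a", "3b", "3b", "4", "4", "5"))
  expect_equal(uacr_positive(c(2.5, 2.4, 3.5, 3.4), c("male", "male", "female", "female")),
               c(TRUE, FALSE, TRUE, FALSE))
})

test_that("CKD detection requires a clean window strictly over 90 days", {
  eg <- function(days, vals) data.frame(date = d0 + days, egfr = vals)
  expect_equal(detect_ckd(eg(c(0, 100), c(55, 55)), NULL, "male"), d0 + 100)
  expect_true(is.na(detect_ckd(eg(c(0, 50, 100), c(55, 65, 55)), NULL, "male")))
  expect_true(is.na(detect_ckd(eg(c(0, 60), c(55, 55)), NULL, "male")))
  # exactly 90 days is not "over 90 days"
  expect_true(is.na(detect_ckd(eg(c(0, 90), c(55, 55)), NULL, "male")))
  expect_equal(detect_ckd(eg(c(0, 91), c(55, 55)), NULL, "male"), d0 + 91)
  # uACR criterion with sex-specific thresholds
  ua <- data.frame(date = d0 + c(0, 120), uacr = c(3.0, 3.2))
  expect_equal(detect_ckd(NULL, ua, "male"), d0 + 120)
  expect_true(is.na(detect_ckd(NULL, ua, "female")))
  # earliest qualifying pair wins across criteria
  both <- detect_ckd(eg(c(0, 200), c(55, 55)), ua, "male")
  expect_equal(both, d0 + 120)
  expect_error(detect_ckd(eg(c(100, 0), c(55, 55)), NULL, "male"), "sorted")
})

test_that("follow-up windows implement the loss-to-follow-up and death rules", {
  fw <- resolve_followup("p", as.Date("2017-05-01"), 2019)
  expect_true(fw$excluded)
  fw <- resolve_followup("p", as.Date("2021-03-01"), 2019)
  expect_false(fw$excluded)
  expect_equal(fw$end_date, as.Date("2019-12-31"))
  fw <- resolve_followup("p", as.Date("2019-02-01"), 2019,
                         death_date = as.Date("2019-03-15"))
  expect_false(fw$excluded)
  expect_equal(fw$end_date, as.Date("2019-03-15"))
  # a death date is itself a mortality record
  fw <- resolve_followup("p", as.Date(character()), 2019,
                         death_date = as.Date("2019-06-01"))
  expect_false(fw$excluded)
})

test_that("diabetes evidence needs two qualifying results of either analyte", {
  lab <- function(an, v, d) data.frame(date = d0 + d, analyte = an, value = v)
  expect_true(derive_diabetes_flag(rbind(lab("hba1c", 6.8, 0), lab("hba1c", 7.0, 30))))
  expect_false(derive_diabetes_flag(lab("hba1c", 7.2, 0)))
  expect_true(derive_diabetes_flag(rbind(lab("fpg", 7.5, 0), lab("fpg", 8.1, 10))))
  expect_false(derive_diabetes_flag(rbind(lab("hba1c", 7.2, 0), lab("fpg", 8.1, 10))))
  expect_false(derive_diabetes_flag(rbind(lab("hba1c", 6.4, 0), lab("hba1c", 6.5, 30))))
})

test_that("stage histories ratchet, use the least severe pair stage, and obey Z49", {
  fw <- resolve_followup("p", d0 + 10, 2019)
  # confirmatory pair spanning 3a and 3b opens at 3a
  h <- build_stage_history(data.frame(date = d0 + c(-200, -100), egfr = c(50, 40)),
                           NULL, NULL, "male", fw, "p")
  expect_equal(h$stage[1], "3a")
  expect_equal(h$start_date[1], d0)
  expect_equal(h$end_date[nrow(h)], as.Date("2019-12-31"))
  # later improved results never lower a confirmed stage
  eg <- data.frame(date = d0 + c(-300, -150, 50, 150), egfr = c(40, 40, 65, 70))
  h <- build_stage_history(eg, NULL, NULL, "male", fw, "p")
  expect_equal(unique(h$stage), "3b")
  # dialysis code forces Stage 5 from its date; boundary day starts the new period
  eg <- data.frame(date = d0 + c(-200, -100), egfr = c(50, 52))
  h <- build_stage_history(eg, NULL, as.Date("2019-07-01"), "male", fw, "p")
  expect_equal(h$stage, c("3a", "5"))
  expect_equal(h$end_date[1], as.Date("2019-06-30"))
  expect_equal(h$start_date[2], as.Date("2019-07-01"))
  # in-year progression: new, more severe pair starts a new period on its
  # confirmation date
  eg <- data.frame(date = d0 + c(-200, -100, 60, 160), egfr = c(50, 52, 40, 42))
  h <- build_stage_history(eg, NULL, NULL, "male", fw, "p")
  expect_equal(h$stage, c("3a", "3b"))
  expect_equal(h$start_date[2], d0 + 160)
  # uACR-confirmed person staged against latest prior eGFR
  ua <- data.frame(date = d0 + c(-200, -100), uacr = c(5, 6))
  eg <- data.frame(date = d0 - 250, egfr = 95)
  h <- build_stage_history(eg, ua, NULL, "male", fw, "p")
  expect_equal(unique(h$stage), "1")
  eg$egfr <- 70
  h <- build_stage_history(eg, ua, NULL, "male", fw, "p")
  expect_equal(unique(h$stage), "2")
  # no eGFR at or before the uACR confirmation: unstageable
  h <- build_stage_history(NULL, ua, NULL, "male", fw, "p")
  expect_equal(nrow(h), 0)
  expect_true(isTRUE(attr(h, "unstageable")))
  # no confirmed CKD: empty history
  h <- build_stage_history(data.frame(date = d0 + 1, egfr = 80), NULL, NULL,
                           "male", fw, "p")
  expect_equal(nrow(h), 0)
})

test_that("interval construction agrees with the day-by-day oracle and is permutation safe", {
  cfg <- sim_config(n_persons = 60, seed = 11, inconsistent_interim_prob = 0.2,
                    lost_to_followup_prob = 0)
  coh <- generate_cohort(cfg)
  year <- cfg$analysis_year
  for (i in seq_len(nrow(coh$persons))) {
    p <- coh$persons[i, ]
    lb <- coh$labs[coh$labs$person_id == p$person_id, ]
    ev <- coh$events[coh$events$person_id == p$person_id, ]
    fw <- resolve_followup(p$person_id, c(lb$date, ev$date), year, p$death_date)
    if (fw$excluded) next
    cre <- lb[lb$analyte == "creatinine", ]
    eg <- if (nrow(cre)) data.frame(date = cre$date,
                                    egfr = compute_egfr(cre$value, p$age_mid,
                                                        p$sex)) else NULL
    ua <- lb[lb$analyte == "uacr", ]
    ua <- if (nrow(ua)) data.frame(date = ua$date, uacr = ua$value) else NULL
    dial <- ev$date[ev$kind == "admission" & !is.na(ev$dialysis) & ev$dialysis]
    h <- build_stage_history(eg, ua, dial, p$sex, fw, p$person_id)
    # ratchet invariant
    if (nrow(h) > 1) expect_true(all(diff(stage_severity(h$stage)) > 0))
    # day-by-day oracle equivalence
    oracle <- oracle_day_stage(eg, ua, dial, p$sex, fw)
    expect_identical(periods_to_days(h, fw)$stage, oracle$stage)
    # permutation safety: shuffled-then-sorted input reproduces the output
    if (!is.null(eg) && nrow(eg) > 1) {
      shuf <- eg[sample(nrow(eg)), , drop = FALSE]
      shuf <- shuf[order(shuf$date), , drop = FALSE]
      h2 <- build_stage_history(shuf, ua, dial, p$sex, fw, p$person_id)
      expect_equal(h2$stage, h$stage)
      expect_equal(h2$start_date, h$start_date)
    }
  }
})
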