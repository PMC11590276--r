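test_that("admissions are priced by DRG, inflated, and routed by dialysis status", {
  cat10 <- flat_catalog(inflation = c("2019" = 1.1, "2023" = 1))
  out <- cost_admission("A01Z", FALSE, cat10)
  expect_equal(out$component, "hospital_nondialysis")
  expect_equal(out$amount, 5500)
  # dialysis flag or dialysis DRG routes to the dialysis component
  expect_equal(cost_admission("A01Z", TRUE, cat10)$component, "dialysis")
  expect_equal(cost_admission("L61Z", FALSE, cat10)$component, "dialysis")
  expect_error(cost_admission("ZZ99", FALSE, cat10), "ZZ99")
})

test_that("emergency costs are additive over presentations by end status", {
  cat <- flat_catalog()
  expect_equal(cost_emergency("admitted", cat), 1200)
  expect_equal(sum(cost_emergency(c("admitted", "admitted"), cat)), 2400)
  expect_error(cost_emergency("transferred", cat), "transferred")
})

test_that("medication pricing is the tier-weighted average plus fees", {
  cat <- flat_catalog()
  # 0.3*31 + 0.5*7.7 + 0.2*0 + (7 + 1 + 0.5) = 21.65
  expect_equal(price_medication("MEDA", cat), 21.65)
  # single tier with weight 1: price + fees
  expect_equal(price_medication("MEDB", cat), 20 + 8.5)
  expect_error(flat_catalog(medication_tiers = data.frame(
    medication = "MEDA", tier = c("general", "concessional"),
    price = c(31, 7.7), weight = c(0.3, 0.3))), "sum to 1")
  # all-zero prices leave only the fees
  free <- flat_catalog(medication_tiers = data.frame(
    medication = "MEDZ", tier = "general", price = 0, weight = 1))
  expect_equal(price_medication("MEDZ", free), 8.5)
})

test_that("prescription costs count the original dispensing plus all repeats", {
  cat <- flat_catalog()
  one <- data.frame(medication = "MEDB", n_repeats = 5)
  expect_equal(cost_prescriptions(one, cat), 6 * 28.5)
  expect_equal(cost_prescriptions(one[0, ], cat), 0)
  two <- rbind(one, data.frame(medication = "MEDB", n_repeats = 0))
  expect_equal(cost_prescriptions(two, cat), 7 * 28.5)
  one$n_repeats <- -1
  expect_error(cost_prescriptions(one, cat), "non-negative")
})

test_that("pathology coning pays fees plus the three most expensive items", {
  cat <- flat_catalog()
  expect_equal(cost_pathology_collection(c("i50", "i40", "i30", "i20", "i10"), cat),
               50 + 40 + 30 + 10 + 5)
  expect_equal(cost_pathology_collection(c("i20", "i10"), cat), 20 + 10 + 15)
  # tie at third place: the coned sum is invariant to the tie-break
  tie <- flat_catalog(mbs_item_fees = c(a = 50, b = 30, c = 30, d = 30))
  expect_equal(cost_pathology_collection(c("a", "b", "c", "d"), tie),
               50 + 30 + 30 + 15)
  # coning never exceeds the un-coned sum plus fees
  expect_lte(cost_pathology_collection(c("i50", "i40", "i30", "i20", "i10"), cat),
             150 + 15)
  expect_error(cost_pathology_collection(character(), cat), "items")
})

test_that("GP visit costs sum the billed item fees", {
  cat <- flat_catalog()
  expect_equal(cost_gp("23", cat), 39.75)
  expect_equal(cost_gp(character(), cat), 0)
  expect_equal(cost_gp(c("23", "36"), cat), 39.75 + 76.95)
  expect_error(cost_gp("99999", cat), "99999")
})

test_that("top-down allocation conserves the total to the cent", {
  w5 <- setNames(c(0, 0, 0, 0, 0, 1), ckd_stages())
  out <- allocate_topdown(1234567.89, w5)
  expect_equal(unname(out["5"]), 1234567.89)
  uni <- allocate_topdown(600, setNames(rep(1 / 6, 6), ckd_stages()))
  expect_equal(unname(uni), rep(100, 6))
  # conservation under ragged weights (largest-remainder reconciliation)
  set.seed(5)
  for (k in 1:25) {
    w <- stats::runif(6); w <- w / sum(w)
    total <- round(stats::runif(1, 1, 1e6), 2)
    shares <- allocate_topdown(total, setNames(w, ckd_stages()))
    expect_equal(sum(shares), total, tolerance = 1e-9)
    expect_true(all(shares >= 0))
  }
  expect_error(allocate_topdown(100, c(a = 0.5, b = 0.4)), "sum to 1")
  expect_error(allocate_topdown(-1, c(a = 1)), "non-negative")
})

test_that("ledgers cover all components and are additive over windows and events", {
  cat <- flat_catalog()
  d0 <- as.Date("2019-01-01")
  ev <- data.frame(
    person_id = "p1",
    date = d0 + c(10, 40, 100, 200, 200, 300),
    kind = c("admission", "emergency", "prescription", "gp_visit",
             "pathology_collection", "admission"),
    drg = c("A01Z", NA, NA, NA, NA, "L61Z"),
    dialysis = c(FALSE, NA, NA, NA, NA, TRUE),
    end_status = c(NA, "admitted", NA, NA, NA, NA),
    medication = c(NA, NA, "MEDA", NA, NA, NA),
    n_repeats = c(NA, NA, 2, NA, NA, NA),
    items = c(NA, NA, NA, "23;36", "i50;i40", NA),
    provider_id = c(NA, NA, NA, NA, "WD", NA))
  led <- build_ledger("p1", d0, as.Date("2019-12-31"), ev, cat)
  expect_setequal(names(led$components), cost_components())
  expect_equal(unname(led$components["hospital_nondialysis"]), 5000)
  expect_equal(unname(led$components["dialysis"]), 650)
  expect_equal(unname(led$components["emergency"]), 1200)
  expect_equal(unname(led$components["medication"]), 3 * 21.65)
  expect_equal(unname(led$components["primary_care"]), 39.75 + 76.95)
  expect_equal(unname(led$components["pathology"]), 50 + 40 + 15)

  # no events: all-zero ledger
  led0 <- build_ledger("p1", d0, d0 + 1, ev[0, ], cat)
  expect_true(all(led0$components == 0))
  # additivity over a window split
  a <- build_ledger("p1", d0, d0 + 150, ev, cat)
  b <- build_ledger("p1", d0 + 151, as.Date("2019-12-31"), ev, cat)
  expect_equal(a$components + b$components, led$components)
  # additivity over event subsets
  s1 <- build_ledger("p1", d0, as.Date("2019-12-31"), ev[1:3, ], cat)
  s2 <- build_ledger("p1", d0, as.Date("2019-12-31"), ev[4:6, ], cat)
  expect_equal(s1$components + s2$components, led$components)
  # events outside the window are excluded
  mid <- build_ledger("p1", d0 + 35, d0 + 45, ev, cat)
  expect_equal(sum(mid$components), 1200)
  # one dialysis admission only: only the dialysis component is nonzero
  dial <- build_ledger("p1", d0, as.Date("2019-12-31"), ev[6, ], cat)
  expect_equal(unname(dial$components["dialysis"]), 650)
  expect_equal(sum(dial$components != 0), 1)
  # unknown codes across kinds aggregate into one error
  bad <- ev
  bad$drg[1] <- "XX01"
  bad$medication[3] <- "NOPE"
  err <- tryCatch(build_ledger("p1", d0, as.Date("2019-12-31"), bad, cat),
                  error = conditionMessage)
  expect_match(err, "XX01")
  expect_match(err, "NOPE")
})

test_that("pricing with a unit index equals pricing in 2023 dollars", {
  flat <- flat_catalog()   # all indices 1
  infl <- flat_catalog(inflation = c("2019" = 1.16, "2023" = 1))
  expect_equal(cost_admission("A01Z", FALSE, infl)$amount, 5800)
  expect_equal(cost_admission("A01Z", FALSE, flat)$amount, 5000)
  # emergency prices are already 2023-based, so the index leaves them alone
  expect_equal(cost_emergency("admitted", infl), cost_emergency("admitted", flat))
})
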