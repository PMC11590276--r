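# Independent oracles used to cross-check the package implementation.
# These are deliberately naive re-derivations, not calls into package internals.

# Brute-force day-by-day staging evaluator: for every calendar day in the
# window, recompute the most severe stage confirmed on or before that day
# from first principles (pair enumeration over the tests seen so far).
oracle_day_stage <- function(egfr, uacr, dialysis_dates, sex, window) {
  band_of <- function(e, alb) {
    if (e < 15) "5" else if (e < 30) "4" else if (e < 45) "3b"
    else if (e < 60) "3a" else if (alb && e < 90) "2" else if (alb) "1"
    else NA_character_
  }
  sev_of <- function(s) match(s, c("1", "2", "3a", "3b", "4", "5"))
  thr <- if (sex == "male") 2.5 else 3.5
  days <- seq(as.Date(window$start_date), as.Date(window$end_date), by = "day")
  out <- rep(NA_character_, length(days))
  for (di in seq_along(days)) {
    d <- days[di]
    best <- 0L
    if (!is.null(dialysis_dates) && any(as.Date(dialysis_dates) <= d)) best <- 6L
    if (!is.null(egfr)) {
      e <- egfr[egfr$date <= d, , drop = FALSE]
      ne <- nrow(e)
      if (ne >= 2) {
        for (jj in 2:ne) for (ii in 1:(jj - 1)) {
          if (e$egfr[ii] >= 60 || e$egfr[jj] >= 60) next
          if (as.numeric(e$date[jj] - e$date[ii]) <= 90) next
          inside <- e$egfr[e$date >= e$date[ii] & e$date <= e$date[jj]]
          if (any(inside >= 60)) next
          st <- min(sev_of(band_of(e$egfr[ii], FALSE)),
                    sev_of(band_of(e$egfr[jj], FALSE)))
          best <- max(best, st)
        }
      }
    }
    if (!is.null(uacr)) {
      u <- uacr[uacr$date <= d, , drop = FALSE]
      nu <- nrow(u)
      if (nu >= 2) {
        for (jj in 2:nu) for (ii in 1:(jj - 1)) {
          if (u$uacr[ii] < thr || u$uacr[jj] < thr) next
          if (as.numeric(u$date[jj] - u$date[ii]) <= 90) next
          inside <- u$uacr[u$date >= u$date[ii] & u$date <= u$date[jj]]
          if (any(inside < thr)) next
          if (is.null(egfr)) next
          pe <- egfr[egfr$date <= u$date[jj], , drop = FALSE]
          if (!nrow(pe)) next
          e_now <- pe$egfr[which.max(as.numeric(pe$date))]
          st <- sev_of(band_of(e_now, TRUE))
          if (!is.na(st)) best <- max(best, st)
        }
      }
    }
    if (best > 0) out[di] <- c("1", "2", "3a", "3b", "4", "5")[best]
  }
  data.frame(date = days, stage = out)
}

# Expand StagePeriods into one row per day for comparison with the oracle.
periods_to_days <- function(periods, window) {
  days <- seq(as.Date(window$start_date), as.Date(window$end_date), by = "day")
  out <- rep(NA_character_, length(days))
  for (q in seq_len(nrow(periods))) {
    sel <- days >= periods$start_date[q] & days <= periods$end_date[q]
    out[sel] <- periods$stage[q]
  }
  data.frame(date = days, stage = out)
}

# Exhaustive audit of greedy matching: replaying cases in processing order
# (sorted by id), no case assigned at relaxation level L may have had an
# unused control available at any stricter level, and unmatched cases must
# have had no available control at any level.
audit_matching <- function(cases, controls, pairs) {
  fields <- list(c("age_band", "sex", "indigenous", "remoteness", "diabetes"),
                 c("age_band", "sex", "indigenous", "diabetes"),
                 c("age_band", "indigenous", "diabetes"),
                 c("age_band", "diabetes"))
  lvl_names <- c("none", "remoteness", "remoteness+sex",
                 "remoteness+sex+indigenous")
  used <- character(0)
  ok <- TRUE
  for (cid in sort(as.character(cases$person_id))) {
    pr <- pairs[pairs$case_id == cid, ]
    lv <- match(pr$relaxation_level, lvl_names)  # NA for unmatched
    upto <- if (is.na(lv)) length(fields) else lv - 1
    crow <- cases[cases$person_id == cid, ]
    if (upto >= 1) {
      for (l in seq_len(upto)) {
        avail <- controls[!controls$person_id %in% used, , drop = FALSE]
        hit <- rep(TRUE, nrow(avail))
        for (f in fields[[l]]) hit <- hit & avail[[f]] == crow[[f]]
        if (any(hit)) ok <- FALSE
      }
    }
    if (!is.na(lv)) {
      # the assigned control must itself match at the recorded level
      ctl <- controls[controls$person_id == pr$control_id, ]
      if (!all(vapply(fields[[lv]], function(f) ctl[[f]] == crow[[f]],
                      logical(1)))) ok <- FALSE
      used <- c(used, pr$control_id)
    }
  }
  ok
}

# Direct gamma log-likelihood at the glm's fitted values, using the same
# deviance-based dispersion convention as the family's AIC.
gamma_loglik_direct <- function(model) {
  y <- model$y
  mu <- fitted(model)
  disp <- deviance(model) / length(y)
  sum(stats::dgamma(y, shape = 1 / disp, scale = mu * disp, log = TRUE))
}

# Minimal hand-built catalog for arithmetic tests (all prices in 2023 AUD,
# no inflation).
flat_catalog <- function(...) {
  defaults <- list(
    drg_unit_costs = c(A01Z = 5000, B02A = 1200, L61Z = 650),
    dialysis_drgs = "L61Z",
    emergency_costs = c(admitted = 1200, discharged = 600),
    mbs_item_fees = c("23" = 39.75, "36" = 76.95, i50 = 50, i40 = 40,
                      i30 = 30, i20 = 20, i10 = 10),
    collection_fee = 10, bulk_billing_fee = 5,
    medication_tiers = data.frame(
      medication = rep(c("MEDA", "MEDB"), each = 3),
      tier = rep(c("general", "concessional", "safety_net"), 2),
      price = c(31, 7.7, 0, 20, 20, 20),
      weight = c(0.3, 0.5, 0.2, 1, 0, 0)),
    dispensing_fee = 7, handling_fee = 1, safety_net_fee = 0.5,
    inflation = c("2019" = 1, "2023" = 1),
    drg_year = 2019, emergency_year = 2023, mbs_year = 2019,
    medication_year = 2019)
  over <- list(...)
  args <- defaults
  args[names(over)] <- over
  do.call(cost_catalog, args)
}

# Simulate rows from a known gamma/log-link truth over the five predictors.
simulate_glm_rows <- function(n, beta, shape = 2,
                              stages = c("None", "3a", "5"),
                              bands = c("50-54", "60-64", "70-74", "80-84"),
                              vary_indigenous = TRUE, vary_remoteness = TRUE) {
  df <- data.frame(
    stage = sample(stages, n, replace = TRUE),
    sex = sample(c("female", "male"), n, replace = TRUE),
    age_band = if (length(bands) > 1) sample(bands, n, replace = TRUE) else bands,
    indigenous = if (vary_indigenous) {
      sample(c(FALSE, TRUE), n, replace = TRUE, prob = c(0.9, 0.1))
    } else FALSE,
    remoteness = if (vary_remoteness) {
      sample(c("major_cities", "regional", "remote"), n, replace = TRUE,
             prob = c(0.7, 0.2, 0.1))
    } else "major_cities")
  fdf <- data.frame(stage = factor(df$stage, levels = stages),
                    sex = factor(df$sex, levels = c("female", "male")),
                    age_band = factor(df$age_band, levels = bands),
                    indigenous = factor(df$indigenous, levels = c(FALSE, TRUE)),
                    remoteness = factor(df$remoteness,
                                        levels = c("major_cities", "regional",
                                                   "remote")))
  multi <- names(fdf)[vapply(fdf, function(x) length(unique(x)) >= 2, logical(1))]
  mm <- stats::model.matrix(stats::reformulate(multi), fdf)
  stopifnot(ncol(mm) == length(beta))
  mu <- exp(as.numeric(mm %*% beta))
  df$cost <- stats::rgamma(n, shape = shape, rate = shape / mu)
  df
}
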