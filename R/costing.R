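#' Construct a unit-cost catalog
#'
#' Bundles the price tables needed to cost utilisation events: AR-DRG unit
#' costs (with the subset of DRGs that are dialysis episodes), emergency
#' average costs by episode end status, MBS item schedule fees (general
#' practice and pathology items) with the pathology collection and bulk
#' billing fees, PBS medication tier prices and tier weights with the
#' dispensing, handling and safety-net recording fees, and a price index
#' mapping a cost base year to 2023 dollars. Each price table carries the
#' calendar year its prices are expressed in; amounts are inflated to 2023
#' at pricing time.
#'
#' @param drg_unit_costs named numeric, AUD per AR-DRG code.
#' @param dialysis_drgs character vector of DRG codes that are dialysis
#'   episodes.
#' @param emergency_costs named numeric, AUD per episode end status.
#' @param mbs_item_fees named numeric, schedule fee per MBS item.
#' @param collection_fee,bulk_billing_fee pathology per-collection fees (AUD).
#' @param medication_tiers data.frame with columns `medication`, `tier`,
#'   `price`, `weight`; weights must sum to 1 within each medication.
#' @param dispensing_fee,handling_fee,safety_net_fee per-script fees (AUD).
#' @param inflation named numeric, multiplier from the named year to 2023
#'   dollars; must contain `"2023" = 1`.
#' @param drg_year,emergency_year,mbs_year,medication_year year the
#'   corresponding prices are expressed in.
#' @return An object of class `cost_catalog`.
#' @export
cost_catalog <- function(drg_unit_costs, dialysis_drgs = character(),
                         emergency_costs, mbs_item_fees,
                         collection_fee, bulk_billing_fee,
                         medication_tiers, dispensing_fee, handling_fee,
                         safety_net_fee, inflation = c("2023" = 1),
                         drg_year = 2019, emergency_year = 2023,
                         mbs_year = 2019, medication_year = 2019) {
  cat <- structure(list(
    drg_unit_costs = drg_unit_costs, dialysis_drgs = dialysis_drgs,
    emergency_costs = emergency_costs, mbs_item_fees = mbs_item_fees,
    collection_fee = collection_fee, bulk_billing_fee = bulk_billing_fee,
    medication_tiers = medication_tiers, dispensing_fee = dispensing_fee,
    handling_fee = handling_fee, safety_net_fee = safety_net_fee,
    inflation = inflation, drg_year = drg_year,
    emergency_year = emergency_year, mbs_year = mbs_year,
    medication_year = medication_year), class = "cost_catalog")
  validate_catalog(cat)
}

validate_catalog <- function(cat) {
  prices <- c(cat$drg_unit_costs, cat$emergency_costs, cat$mbs_item_fees,
              cat$collection_fee, cat$bulk_billing_fee,
              cat$medication_tiers$price, cat$dispensing_fee,
              cat$handling_fee, cat$safety_net_fee)
  if (any(!is.finite(prices)) || any(prices < 0)) {
    stop("catalog prices must be non-negative and finite")
  }
  wsum <- tapply(cat$medication_tiers$weight, cat$medication_tiers$medication, sum)
  if (any(abs(wsum - 1) > 1e-8)) {
    stop("medication tier weights must sum to 1 for: ",
         paste(names(wsum)[abs(wsum - 1) > 1e-8], collapse = ", "))
  }
  if (is.null(cat$inflation["2023"]) || is.na(cat$inflation["2023"]) ||
      cat$inflation["2023"] != 1) {
    stop("inflation index must map 2023 to 1")
  }
  cat
}

# Internal: multiplier from `year` prices to 2023 AUD.
inflate_to_2023 <- function(catalog, year) {
  m <- catalog$inflation[as.character(year)]
  if (is.na(m)) stop("no inflation index for year ", year)
  unname(m)
}

# Internal: lookup with an aggregated missing-price error.
lookup_prices <- function(table, codes, what) {
  miss <- setdiff(unique(codes), names(table))
  if (length(miss)) {
    stop("missing ", what, " price for code(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  unname(table[codes])
}

#' Cost a hospital admission
#'
#' Maps the admission's AR-DRG code to its unit cost, inflated to 2023
#' dollars. Dialysis admissions (dialysis-flagged, e.g. ICD Z49, or carrying
#' a dialysis DRG) are routed to the separate `dialysis` component rather
#' than `hospital_nondialysis`.
#'
#' @param drg AR-DRG code(s).
#' @param dialysis_flag logical, dialysis-coded admission (recycled).
#' @param catalog a [cost_catalog()].
#' @return data.frame with columns `component` and `amount` (2023 AUD).
#' @export
cost_admission <- function(drg, dialysis_flag = FALSE, catalog) {
  amt <- lookup_prices(catalog$drg_unit_costs, drg, "DRG") *
    inflate_to_2023(catalog, catalog$drg_year)
  dial <- rep_len(dialysis_flag, length(drg)) | drg %in% catalog$dialysis_drgs
  data.frame(component = ifelse(dial, "dialysis", "hospital_nondialysis"),
             amount = round_cents(amt))
}

#' Cost emergency presentations
#'
#' Average cost for the episode end status, inflated to 2023 dollars.
#'
#' @param end_status episode end status code(s).
#' @param catalog a [cost_catalog()].
#' @return Numeric amount(s), 2023 AUD.
#' @export
cost_emergency <- function(end_status, catalog) {
  round_cents(lookup_prices(catalog$emergency_costs, end_status, "emergency") *
                inflate_to_2023(catalog, catalog$emergency_year))
}

#' Government price per script of a medication
#'
#' Weighted average over PBS price tiers (general / concessional / safety
#' net), weighted by how often the medication is dispensed at each tier, plus
#' the dispensing, handling and safety-net recording fees, inflated to 2023
#' dollars.
#'
#' @param medication medication code(s).
#' @param catalog a [cost_catalog()].
#' @return Numeric price(s) per script, 2023 AUD.
#' @export
price_medication <- function(medication, catalog) {
  tiers <- catalog$medication_tiers
  miss <- setdiff(unique(medication), unique(tiers$medication))
  if (length(miss)) {
    stop("missing medication price for code(s): ", paste(miss, collapse = ", "))
  }
  wavg <- tapply(tiers$price * tiers$weight, tiers$medication, sum)
  fees <- catalog$dispensing_fee + catalog$handling_fee + catalog$safety_net_fee
  round_cents((unname(wavg[medication]) + fees) *
                inflate_to_2023(catalog, catalog$medication_year))
}

#' Annual prescription cost
#'
#' For each script the cost of the original dispensing plus all repeats is
#' counted: `(1 + n_repeats) * price_medication`.
#'
#' @param scripts data.frame with columns `medication` and `n_repeats`.
#' @param catalog a [cost_catalog()].
#' @return Total cost, 2023 AUD.
#' @export
cost_prescriptions <- function(scripts, catalog) {
  if (is.null(scripts) || !nrow(scripts)) return(0)
  if (any(scripts$n_repeats < 0)) stop("n_repeats must be non-negative")
  sum((1 + scripts$n_repeats) * price_medication(scripts$medication, catalog))
}

#' Cost a pathology collection under the coning rule
#'
#' A collection is paid the MBS collection fee and bulk-billing fee plus the
#' schedule fees of its three most expensive items (all items when fewer than
#' three); ties at third place are broken by item code order, which leaves
#' the sum unchanged.
#'
#' @param items character vector of MBS item codes in the collection.
#' @param catalog a [cost_catalog()].
#' @return Cost of the collection, 2023 AUD.
#' @export
cost_pathology_collection <- function(items, catalog) {
  if (!length(items)) stop("a pathology collection must contain items")
  fees <- lookup_prices(catalog$mbs_item_fees, items, "MBS item")
  ord <- order(-fees, items)
  top <- fees[ord][seq_len(min(3, length(fees)))]
  round_cents((catalog$collection_fee + catalog$bulk_billing_fee + sum(top)) *
                inflate_to_2023(catalog, catalog$mbs_year))
}

#' Cost general practice visits from billed MBS items
#'
#' @param items character vector of billed MBS item codes.
#' @param catalog a [cost_catalog()].
#' @return Total cost, 2023 AUD.
#' @export
cost_gp <- function(items, catalog) {
  if (!length(items)) return(0)
  # rounded to the cent per billed item, so totals are additive under any
  # grouping of visits or windows
  sum(round_cents(lookup_prices(catalog$mbs_item_fees, items, "MBS item") *
                    inflate_to_2023(catalog, catalog$mbs_year)))
}

#' Distribute a top-down total across CKD stages
#'
#' Splits an aggregate cost (e.g. renal outpatient clinics, home-based
#' dialysis) across stages by the supplied frequency weights. Shares are
#' reconciled to the total to the exact cent by the largest-remainder method.
#'
#' @param total total cost to distribute (AUD, >= 0).
#' @param weights named non-negative weights summing to 1.
#' @return Named numeric of stage shares summing exactly to `total`
#'   (rounded to cents).
#' @export
allocate_topdown <- function(total, weights) {
  if (length(total) != 1 || !is.finite(total) || total < 0) {
    stop("total must be a single non-negative number")
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be non-negative and sum to 1")
  }
  total_cents <- round_half_up(total * 100)
  raw <- total_cents * weights
  base <- floor(raw)
  left <- total_cents - sum(base)
  if (left > 0) {
    extra <- order(-(raw - base), seq_along(raw))[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  out <- base / 100
  names(out) <- names(weights)
  out
}

#' Build a person's component cost ledger over a window
#'
#' Prices every utilisation event dated within the window and accumulates the
#' seven cost components: admissions via AR-DRG unit costs (dialysis-coded
#' admissions routed to the dialysis component), emergency presentations by
#' end status, prescriptions with all repeats, general-practice visits by
#' billed items, and pathology collections under the coning rule (pathology
#' rows sharing a date and provider form one collection). The outpatient
#' component is zero here; it is allocated top-down at the cohort level.
#' Unknown codes across all components are aggregated into a single
#' missing-price error.
#'
#' @param person_id identifier.
#' @param window_start,window_end window Dates (inclusive).
#' @param events data.frame of utilisation events with columns `person_id`,
#'   `date`, `kind` (`admission`, `emergency`, `prescription`, `gp_visit`,
#'   `pathology_collection`) and the kind-specific payload columns `drg`,
#'   `dialysis`, `end_status`, `medication`, `n_repeats`, `items`
#'   (";"-separated codes), `provider_id`.
#' @param catalog a [cost_catalog()].
#' @return An object of class `cost_ledger`: list with `person_id`,
#'   `window_start`, `window_end` and `components`, a named numeric over
#'   [cost_components()] in 2023 AUD.
#' @export
build_ledger <- function(person_id, window_start, window_end, events, catalog) {
  comps <- stats::setNames(numeric(length(cost_components())), cost_components())
  ev <- events
  if (!is.null(ev) && nrow(ev)) {
    if ("person_id" %in% names(ev)) {
      ev <- ev[ev$person_id == person_id, , drop = FALSE]
    }
    ev <- ev[ev$date >= as.Date(window_start) & ev$date <= as.Date(window_end),
             , drop = FALSE]
  }
  if (!is.null(ev) && nrow(ev)) {
    check_event_prices(ev, catalog)
    adm <- ev[ev$kind == "admission", , drop = FALSE]
    if (nrow(adm)) {
      priced <- cost_admission(adm$drg, isTRUE_vec(adm$dialysis), catalog)
      agg <- tapply(priced$amount, priced$component, sum)
      comps[names(agg)] <- comps[names(agg)] + agg
    }
    em <- ev[ev$kind == "emergency", , drop = FALSE]
    if (nrow(em)) comps["emergency"] <- sum(cost_emergency(em$end_status, catalog))
    rx <- ev[ev$kind == "prescription", , drop = FALSE]
    if (nrow(rx)) {
      comps["medication"] <- cost_prescriptions(
        data.frame(medication = rx$medication, n_repeats = rx$n_repeats), catalog)
    }
    gp <- ev[ev$kind == "gp_visit", , drop = FALSE]
    if (nrow(gp)) {
      items <- unlist(strsplit(gp$items, ";", fixed = TRUE))
      comps["primary_care"] <- cost_gp(items, catalog)
    }
    pa <- ev[ev$kind == "pathology_collection", , drop = FALSE]
    if (nrow(pa)) {
      key <- paste(pa$date, pa$provider_id)
      coll <- tapply(pa$items, key, function(x) {
        unlist(strsplit(x, ";", fixed = TRUE))
      })
      comps["pathology"] <- sum(vapply(
        coll, cost_pathology_collection, numeric(1), catalog = catalog))
    }
  }
  structure(list(person_id = person_id, window_start = as.Date(window_start),
                 window_end = as.Date(window_end), components = comps),
            class = "cost_ledger")
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x

# Internal: pre-validate all event codes so missing prices surface as one
# aggregated error naming every unknown code.
check_event_prices <- function(ev, catalog) {
  miss <- character()
  adm <- ev[ev$kind == "admission", , drop = FALSE]
  miss <- c(miss, setdiff(unique(adm$drg), names(catalog$drg_unit_costs)))
  em <- ev[ev$kind == "emergency", , drop = FALSE]
  miss <- c(miss, setdiff(unique(em$end_status), names(catalog$emergency_costs)))
  rx <- ev[ev$kind == "prescription", , drop = FALSE]
  miss <- c(miss, setdiff(unique(rx$medication),
                          unique(catalog$medication_tiers$medication)))
  it <- ev[ev$kind %in% c("gp_visit", "pathology_collection"), , drop = FALSE]
  if (nrow(it)) {
    codes <- unique(unlist(strsplit(it$items, ";", fixed = TRUE)))
    miss <- c(miss, setdiff(codes, names(catalog$mbs_item_fees)))
  }
  miss <- miss[!is.na(miss)]
  if (length(miss)) {
    stop("missing price for code(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Extract the component vector of a ledger
#'
#' @param ledger a `cost_ledger` or named numeric over [cost_components()].
#' @return Named numeric over the seven components.
#' @export
ledger_components <- function(ledger) {
  if (inherits(ledger, "cost_ledger")) return(ledger$components)
  if (is.numeric(ledger) && !is.null(names(ledger))) {
    if (!setequal(names(ledger), cost_components())) {
      stop("ledger must cover exactly the seven cost components")
    }
    return(ledger[cost_components()])
  }
  stop("not a cost ledger")
}

#' @export
print.cost_ledger <- function(x, ...) {
  cat(sprintf("<cost_ledger> person %s, %s to %s\n", x$person_id,
              format(x$window_start), format(x$window_end)))
  print(round(x$components, 2))
  invisible(x)
}
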