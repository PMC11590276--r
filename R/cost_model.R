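#' Specify a cost regression model
#'
#' Cost components that are only observed on a sub-dataset (medication,
#' general practice, pathology) are modelled with a gamma generalised linear
#' model with a log link and transferred to the full cohort by prediction.
#' Predictors are fixed: CKD stage (seven levels including `"None"`), sex,
#' 5-year age band, indigenous status and remoteness.
#'
#' Gamma models require strictly positive responses; two zero-cost policies
#' are supported. `"epsilon_shift"` (default) replaces zero annual costs with
#' a small positive `epsilon` (0.01 AUD) before fitting, so the fitted means
#' track the full-cohort mean including zero-cost years. `"positive_only"`
#' fits on positive costs only and scales predictions by the observed
#' positive fraction within each stage.
#'
#' @param response cost component being modelled (one of [cost_components()]).
#' @param zero_handling `"epsilon_shift"` or `"positive_only"`.
#' @param epsilon positive shift applied to zero costs under
#'   `"epsilon_shift"`, in AUD.
#' @return An object of class `cost_model_spec`.
#' @export
cost_model_spec <- function(response,
                            zero_handling = c("epsilon_shift", "positive_only"),
                            epsilon = 0.01) {
  zero_handling <- match.arg(zero_handling)
  if (!response %in% cost_components()) {
    stop("response must be one of: ", paste(cost_components(), collapse = ", "))
  }
  if (zero_handling == "epsilon_shift" && (!is.finite(epsilon) || epsilon <= 0)) {
    stop("epsilon must be > 0")
  }
  structure(list(response = response, family = "gamma", link = "log",
                 predictors = c("stage", "sex", "age_band", "indigenous",
                                "remoteness"),
                 zero_handling = zero_handling, epsilon = epsilon),
            class = "cost_model_spec")
}

# Internal: coerce predictors to factors with fixed reference levels
# (stage None, female, youngest age band, non-indigenous, major cities).
prepare_predictors <- function(data) {
  lev <- list(stage = stage_levels(), sex = c("female", "male"),
              age_band = age_bands(),
              remoteness = remoteness_levels())
  for (v in names(lev)) {
    if (v %in% names(data)) {
      present <- lev[[v]][lev[[v]] %in% unique(as.character(data[[v]]))]
      data[[v]] <- factor(as.character(data[[v]]), levels = present)
    }
  }
  if ("indigenous" %in% names(data)) {
    data$indigenous <- factor(as.logical(data$indigenous),
                              levels = c(FALSE, TRUE))
  }
  data
}

#' Fit a gamma log-link cost model
#'
#' Maximum-likelihood gamma/log-link fit (iteratively reweighted least
#' squares via [stats::glm()]). Predictors with fewer than two observed
#' levels are dropped from the design (they are inestimable). Dispersion is
#' estimated by the Pearson statistic over residual degrees of freedom;
#' AIC and BIC are reported for model comparison.
#'
#' @param spec a [cost_model_spec()].
#' @param data data.frame containing the response column (annual cost, >= 0)
#'   and the predictor columns `stage`, `sex`, `age_band`, `indigenous`,
#'   `remoteness`.
#' @return An object of class `cost_model_fit` with elements `spec`, `model`
#'   (the glm), `coefficients`, `dispersion`, `aic`, `bic`, `n`, `xlevels`
#'   and, under `"positive_only"`, `positive_fraction` by stage.
#' @export
fit_cost_glm <- function(spec, data) {
  stopifnot(inherits(spec, "cost_model_spec"))
  if (!spec$response %in% names(data)) {
    stop("data lacks response column ", spec$response)
  }
  y <- data[[spec$response]]
  if (any(!is.finite(y)) || any(y < 0)) stop("costs must be finite and >= 0")
  data <- prepare_predictors(data)
  missing_pred <- setdiff(spec$predictors, names(data))
  if (length(missing_pred)) {
    stop("data lacks predictor column(s): ", paste(missing_pred, collapse = ", "))
  }

  positive_fraction <- NULL
  if (spec$zero_handling == "epsilon_shift") {
    y[y == 0] <- spec$epsilon
    fit_data <- data
  } else {
    zero_levels <- tapply(y > 0, data$stage, any)
    if (any(!zero_levels, na.rm = TRUE)) {
      stop("positive_only fit is degenerate: stage level(s) with no positive ",
           "costs: ", paste(names(zero_levels)[!zero_levels], collapse = ", "))
    }
    positive_fraction <- tapply(y > 0, data$stage, mean)
    keep <- y > 0
    fit_data <- data[keep, , drop = FALSE]
    y <- y[keep]
  }
  fit_data$.cost <- y

  used <- spec$predictors[vapply(spec$predictors, function(v) {
    length(unique(as.character(fit_data[[v]][!is.na(fit_data[[v]])]))) >= 2
  }, logical(1))]
  form <- stats::reformulate(if (length(used)) used else "1",
                             response = ".cost")
  n_terms <- 1 + sum(vapply(used, function(v) {
    length(unique(as.character(fit_data[[v]]))) - 1
  }, numeric(1)))
  if (nrow(fit_data) < 10 * n_terms) {
    stop(sprintf("too few rows (%d) for %d model terms (need >= %d)",
                 nrow(fit_data), n_terms, 10 * n_terms))
  }

  model <- stats::glm(form, family = stats::Gamma(link = "log"),
                      data = fit_data, control = list(maxit = 100))
  if (!model$converged) {
    stop(sprintf("gamma GLM did not converge in %d IRLS iterations (response %s)",
                 model$iter, spec$response))
  }
  dispersion <- sum(stats::residuals(model, type = "pearson")^2) /
    stats::df.residual(model)
  structure(list(spec = spec, model = model,
                 coefficients = stats::coef(model),
                 dispersion = dispersion,
                 aic = stats::AIC(model), bic = stats::BIC(model),
                 n = nrow(fit_data), xlevels = model$xlevels,
                 positive_fraction = positive_fraction),
            class = "cost_model_fit")
}

#' @export
print.cost_model_fit <- function(x, ...) {
  cat(sprintf("<cost_model_fit> %s ~ gamma(log), n = %d, AIC = %.1f, BIC = %.1f, dispersion = %.3f\n",
              x$spec$response, x$n, x$aic, x$bic, x$dispersion))
  invisible(x)
}

#' Rank candidate cost models by information criteria
#'
#' Models are ranked by AIC, with BIC reported alongside; when the two
#' criteria disagree on the best model the result is flagged and AIC wins.
#' All fits must be on the same number of rows (the same data).
#'
#' @param fits named list of `cost_model_fit` objects.
#' @return data.frame with one row per model ordered by AIC (ties broken by
#'   name), columns `model`, `n`, `aic`, `bic`, `rank_aic`, `rank_bic`;
#'   attribute `ic_disagreement` is `TRUE` when AIC and BIC pick different
#'   winners.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1),
                                          "cost_model_fit")))
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) > 1) {
    stop("fits must be on identical rows (differing n: ",
         paste(unique(ns), collapse = ", "), ")")
  }
  out <- data.frame(model = names(fits), n = ns,
                    aic = vapply(fits, `[[`, numeric(1), "aic"),
                    bic = vapply(fits, `[[`, numeric(1), "bic"),
                    row.names = NULL)
  out$rank_aic <- rank(out$aic, ties.method = "first")
  out$rank_bic <- rank(out$bic, ties.method = "first")
  out <- out[order(out$aic, out$model), , drop = FALSE]
  attr(out, "ic_disagreement") <-
    out$model[out$rank_aic == 1] != out$model[out$rank_bic == 1]
  out
}

#' Predict component costs for a cohort
#'
#' Applies a fitted cost model to new rows: `exp(linear predictor)`, always
#' strictly positive. Under `"positive_only"` zero handling, predictions are
#' scaled by the stage-specific observed positive fraction. Every factor
#' level in the new data must have been seen in training.
#'
#' @param fit a `cost_model_fit`.
#' @param newdata data.frame with the predictor columns.
#' @return Numeric vector of predicted annual costs (2023 AUD).
#' @export
predict_costs <- function(fit, newdata) {
  stopifnot(inherits(fit, "cost_model_fit"))
  newdata <- prepare_predictors(newdata)
  for (v in names(fit$xlevels)) {
    unseen <- setdiff(unique(as.character(newdata[[v]])), fit$xlevels[[v]])
    if (length(unseen)) {
      stop(sprintf("predictor %s has level(s) not seen in training: %s",
                   v, paste(unseen, collapse = ", ")))
    }
  }
  pred <- as.numeric(stats::predict(fit$model, newdata = newdata,
                                    type = "response"))
  if (!is.null(fit$positive_fraction)) {
    pred <- pred * as.numeric(fit$positive_fraction[as.character(newdata$stage)])
  }
  pred
}

#' Persons with near-complete pathology from one provider
#'
#' Cost models for community pathology are trained only on persons whose
#' pathology record is nearly complete: those with strictly more than
#' `threshold` of their community pathology collections from the designated
#' provider. Persons with no pathology events have an undefined share and are
#' excluded.
#'
#' @param pathology data.frame of pathology collection events with columns
#'   `person_id` and `provider_id`.
#' @param provider the designated (most complete) provider id.
#' @param threshold proportion in (0, 1]; inclusion requires share strictly
#'   greater than this.
#' @return Character vector of included person ids.
#' @export
select_complete_provider_subset <- function(pathology, provider,
                                            threshold = 0.95) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (is.null(pathology) || !nrow(pathology)) return(character())
  share <- tapply(pathology$provider_id == provider, pathology$person_id, mean)
  names(share)[share > threshold]
}
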