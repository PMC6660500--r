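#' Kaplan-Meier curve
#'
#' Product-limit estimate of event-free survival, with the median survival
#' time (NA when the curve never falls below 0.5).
#'
#' @param times Positive follow-up times.
#' @param events Logical/0-1 event indicators.
#' @return List with `time`, `surv` (step function values after each distinct
#'   time), `median` and the underlying [survival::survfit] object.
#' @export
km_curve <- function(times, events) {
  if (any(times <= 0)) stop("follow-up times must be positive")
  if (length(times) != length(events)) stop("times and events differ in length")
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  med <- unname(summary(fit)$table["median"])
  list(time = fit$time, surv = fit$surv, median = med, fit = fit)
}

endpoint_columns <- function(endpoint) {
  switch(endpoint,
         ae = c(time = "ae_time", flag = "ae_flag"),
         icd = c(time = "icd_therapy_time", flag = "icd_therapy_flag"),
         scd = c(time = "scd_time", flag = "scd_flag"),
         stop("unknown endpoint: ", endpoint))
}

#' Cox proportional-hazards fit with sequential change-in-chi-square
#'
#' Fits a (uni- or multivariable) Cox model for one of the adjudicated
#' endpoints and reports hazard ratios with 95% CIs, the model likelihood-
#' ratio chi-square, and — when `sequential = TRUE` — the change in model
#' chi-square as each covariate is added in the order given (the
#' change-chi-square of covariate k is `2 * (loglik(1..k) - loglik(1..k-1))`).
#' Proportional hazards are checked with the scaled Schoenfeld residual
#' trend test; a violation (global p < 0.05) raises `ph_violation`.
#'
#' @param cohort Patient table; adjudicated columns are added if missing.
#' @param endpoint `"ae"`, `"icd"` or `"scd"`.
#' @param covariates Character vector of covariate column names, in the order
#'   used for the sequential chi-square decomposition.
#' @param sequential Report per-covariate change-chi-square values.
#' @param min_events Minimum number of events required (default 10).
#' @return A `cox_fit_result`: data frame `terms` (term, hr, ci_lower,
#'   ci_upper, p, and change_chisq when sequential), `model_chisq`,
#'   `model_p`, `n_events`, `ph_violation`, `ph_table`, and the fitted
#'   [survival::coxph] model.
#' @export
cox_fit <- function(cohort, endpoint = c("ae", "icd", "scd"), covariates,
                    sequential = FALSE, min_events = 10L) {
  endpoint <- match.arg(endpoint)
  cols <- endpoint_columns(endpoint)
  if (!all(cols %in% names(cohort))) cohort <- adjudicate(cohort)
  missing_cov <- setdiff(covariates, names(cohort))
  if (length(missing_cov)) {
    stop("unknown covariate(s): ", paste(missing_cov, collapse = ", "))
  }
  n_events <- sum(cohort[[cols["flag"]]])
  if (n_events < min_events) {
    stop("only ", n_events, " events; need at least ", min_events)
  }
  surv_obj <- survival::Surv(cohort[[cols["time"]]],
                             as.integer(cohort[[cols["flag"]]]))
  dat <- cohort[, covariates, drop = FALSE]
  dat$.surv <- surv_obj
  form <- stats::as.formula(paste(".surv ~", paste(covariates, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(form, data = dat),
    warning = function(w) {
      if (grepl("converge|infinite|singular", conditionMessage(w))) {
        stop("Cox model did not converge (possible separation): ",
             conditionMessage(w), call. = FALSE)
      }
      suppressWarnings(survival::coxph(form, data = dat))
    })
  if (any(!is.finite(stats::coef(fit))) ||
      any(!is.finite(sqrt(diag(stats::vcov(fit)))))) {
    stop("Cox model produced non-finite estimates (possible separation)")
  }
  sm <- summary(fit)
  terms <- data.frame(term = rownames(sm$coefficients),
                      hr = sm$conf.int[, "exp(coef)"],
                      ci_lower = sm$conf.int[, "lower .95"],
                      ci_upper = sm$conf.int[, "upper .95"],
                      p = sm$coefficients[, "Pr(>|z|)"],
                      row.names = NULL)
  model_chisq <- unname(2 * (fit$loglik[2] - fit$loglik[1]))
  if (sequential) {
    ll_prev <- fit$loglik[1]  # null model log-likelihood
    change <- numeric(length(covariates))
    for (k in seq_along(covariates)) {
      fk <- stats::as.formula(paste(".surv ~",
                                    paste(covariates[seq_len(k)], collapse = " + ")))
      ll_k <- survival::coxph(fk, data = dat)$loglik[2]
      change[k] <- 2 * (ll_k - ll_prev)
      ll_prev <- ll_k
    }
    # a factor covariate can contribute several terms; report per covariate
    terms$change_chisq <- change[match(
      vapply(terms$term, function(t) {
        covariates[which.max(vapply(covariates, function(cv) {
          startsWith(t, cv) * nchar(cv)
        }, numeric(1)))]
      }, character(1)), covariates)]
  }
  zph <- tryCatch(survival::cox.zph(fit), error = function(e) NULL)
  ph_p <- if (is.null(zph)) NA_real_ else unname(zph$table["GLOBAL", "p"])
  structure(list(terms = terms, model_chisq = model_chisq,
                 model_p = stats::pchisq(model_chisq, df = length(stats::coef(fit)),
                                         lower.tail = FALSE),
                 n_events = n_events,
                 ph_violation = isTRUE(!is.na(ph_p) && ph_p < 0.05),
                 ph_table = if (is.null(zph)) NULL else zph$table,
                 fit = fit, endpoint = endpoint),
            class = "cox_fit_result")
}

#' @export
print.cox_fit_result <- function(x, ...) {
  cat(sprintf("Cox model (%s endpoint): %d events, model chi-square %.2f (p = %.3g)\n",
              x$endpoint, x$n_events, x$model_chisq, x$model_p))
  df <- x$terms
  df$hr <- sprintf("%.3f (%.3f-%.3f)", df$hr, df$ci_lower, df$ci_upper)
  print(df[, c("term", "hr", "p",
               intersect("change_chisq", names(df)))], row.names = FALSE)
  if (x$ph_violation) cat("warning: proportional-hazards assumption violated\n")
  invisible(x)
}

# Kaplan-Meier survival at a horizon within a subset.
km_surv_at <- function(times, status, horizon) {
  if (length(times) == 0L) return(NA_real_)
  fit <- survival::survfit(survival::Surv(times, status) ~ 1)
  summary(fit, times = horizon, extend = TRUE)$surv
}

#' Time-dependent ROC by the Kaplan-Meier method
#'
#' Cumulative-case / dynamic-control ROC at a follow-up horizon, with the
#' censored case/control status probabilities estimated by Kaplan-Meier:
#' for each marker cut point c,
#' sensitivity(c) = (1 - S(t | M > c)) P(M > c) / (1 - S(t)) and
#' specificity(c) = S(t | M <= c) P(M <= c) / S(t), where the conditional
#' survival curves are Kaplan-Meier estimates within the marker strata and
#' S(t) is the overall Kaplan-Meier estimate. Without censoring before the
#' horizon this reduces exactly to the empirical ROC of the marker against
#' event-by-horizon status.
#'
#' @param cohort Patient table; adjudicated columns are added if missing.
#' @param marker Column name of the (higher = higher risk) marker.
#' @param horizon_months ROC horizon in months.
#' @param endpoint `"ae"`, `"icd"` or `"scd"`.
#' @return List with `cutoffs`, `sensitivity`, `specificity`, `auc`.
#' @export
td_roc <- function(cohort, marker, horizon_months,
                   endpoint = c("ae", "icd", "scd")) {
  endpoint <- match.arg(endpoint)
  cols <- endpoint_columns(endpoint)
  if (!all(cols %in% names(cohort))) cohort <- adjudicate(cohort)
  x <- cohort[[marker]]
  if (is.null(x)) stop("unknown marker column: ", marker)
  times <- cohort[[cols["time"]]]
  status <- as.integer(cohort[[cols["flag"]]])
  if (!any(status == 1L & times <= horizon_months)) {
    stop("no events before the horizon; ROC undefined")
  }
  s_all <- km_surv_at(times, status, horizon_months)
  cuts <- sort(unique(x))
  sens <- spec <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    hi <- x > cuts[i]
    p_hi <- mean(hi)
    s_hi <- km_surv_at(times[hi], status[hi], horizon_months)
    s_lo <- km_surv_at(times[!hi], status[!hi], horizon_months)
    sens[i] <- if (s_all >= 1) 0 else (1 - s_hi) * p_hi / (1 - s_all)
    spec[i] <- if (s_all <= 0) 0 else s_lo * (1 - p_hi) / s_all
  }
  sens[is.na(sens)] <- 0
  spec[is.na(spec)] <- 1
  sens <- pmin(1, pmax(0, sens))
  spec <- pmin(1, pmax(0, spec))
  fpr <- c(1, 1 - spec, 0)
  tpr <- c(1, sens, 0)
  # sort on rounded keys: floating noise in the KM quotients must not
  # reorder staircase corners sharing an fpr value
  ord <- order(round(fpr, 9), round(tpr, 9))
  auc <- sum(diff(fpr[ord]) * (utils::head(tpr[ord], -1) + utils::tail(tpr[ord], -1)) / 2)
  list(cutoffs = cuts, sensitivity = sens, specificity = spec, auc = auc,
       horizon_months = horizon_months, marker = marker)
}
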