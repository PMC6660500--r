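#' Calibration of the synthetic heart-failure cohort
#'
#' Defaults reproduce the marginal distributions of the reference cohort of
#' 170 chronic heart-failure patients referred for ICD implantation:
#' means/SDs for the continuous covariates and imaging metrics, prevalences
#' for the binary covariates and medication classes, and the event process
#' (exponential hazard with a log-linear early-summed-score effect, a
#' bell-shaped late-H/M category multiplier peaking at intermediate values,
#' uniform censoring over the follow-up window, and the observed breakdown
#' of arrhythmic-event types).
#'
#' @param n Cohort size; default 170.
#' @param continuous Data frame (`var`, `mean`, `sd`, `lower`, `upper`)
#'   of truncated-Gaussian marginals for the continuous variables.
#' @param proportions Named vector of Bernoulli prevalences in `[0, 1]`.
#' @param correlations 3-column data frame (`a`, `b`, `rho`) of nonzero
#'   Gaussian-copula correlations; all unspecified pairs are 0.
#' @param log_hr_ess Log hazard ratio per early-summed-score point.
#' @param hm_multipliers Hazard multipliers for the low / intermediate / high
#'   late-H/M categories (bell shape: intermediate highest).
#' @param baseline_hazard Baseline event hazard per month.
#' @param event_type_probs Probabilities of the four arrhythmic-event types
#'   (sustained VT, appropriate ICD therapy, resuscitated arrest, SCD),
#'   summing to 1.
#' @param censor_window_months `c(min, max)` of the uniform censoring time.
#' @return A `cohort_calibration` list.
#' @export
cohort_calibration <- function(
    n = 170L,
    continuous = data.frame(
      var   = c("age", "bmi", "lvef", "early_hm", "late_hm",
                "wo_percent", "ess", "lss"),
      mean  = c(64.2, 1.73, 31.1, 1.62, 1.53, 30.9, 31.4, 36.2),
      sd    = c(12.6, 0.59, 9.4, 0.21, 0.23, 18.4, 11.9, 12.3),
      lower = c(18, 0.1, 5, 0.8, 0.6, -100, 0, 0),
      upper = c(100, 5, 70, 3, 3, 100, 68, 68)),
    proportions = c(
      male = 139 / 170, diabetes = 61 / 170, hypertension = 134 / 170,
      smoker = 65 / 170, dyslipidemia = 80 / 170, ischemic = 101 / 170,
      lbbb = 43 / 170, nyha_iii = 84 / 170, ace_i = 74 / 170,
      arb = 32 / 170, mra = 105 / 170, beta_blocker = 162 / 170,
      amiodarone = 38 / 170, statin = 98 / 170, diuretic = 158 / 170,
      primary_prevention = 156 / 170),
    correlations = data.frame(
      a = c("ess", "late_hm"), b = c("lss", "ess"), rho = c(0.8, -0.4)),
    log_hr_ess = log(1.028),
    hm_multipliers = c(low = 1, intermediate = 2, high = 1),
    baseline_hazard = 0.0055,
    event_type_probs = c(sustained_VT = 25, appropriate_ICD_therapy = 22,
                         resuscitated_arrest = 8, SCD = 14) / 69,
    censor_window_months = c(1, 51)) {
  cal <- structure(list(n = as.integer(n), continuous = continuous,
                        proportions = proportions, correlations = correlations,
                        log_hr_ess = log_hr_ess, hm_multipliers = hm_multipliers,
                        baseline_hazard = baseline_hazard,
                        event_type_probs = event_type_probs,
                        censor_window_months = censor_window_months),
                   class = "cohort_calibration")
  validate_calibration(cal)
  cal
}

validate_calibration <- function(cal) {
  if (any(cal$proportions < 0 | cal$proportions > 1)) {
    stop("all proportions must lie in [0, 1]")
  }
  if (any(cal$continuous$sd <= 0)) stop("all marginal sds must be positive")
  if (abs(sum(cal$event_type_probs) - 1) > 1e-8) {
    stop("event-type probabilities must sum to 1")
  }
  if (any(cal$hm_multipliers < 0) || cal$baseline_hazard < 0) {
    stop("hazard parameters must be non-negative")
  }
  if (diff(cal$censor_window_months) <= 0 || cal$censor_window_months[1] <= 0) {
    stop("censoring window must be a positive increasing interval")
  }
  invisible(cal)
}

#' The arrhythmic-event type levels
#'
#' `"none"` plus the four composite-endpoint components: sustained
#' ventricular tachycardia (> 30 s), appropriate ICD therapy
#' (anti-tachycardial pacing or defibrillation), resuscitated cardiac arrest,
#' and sudden cardiac death.
#' @export
event_type_levels <- function() {
  c("none", "sustained_VT", "appropriate_ICD_therapy",
    "resuscitated_arrest", "SCD")
}

# Correlation matrix of the Gaussian copula over the continuous variables.
copula_corr <- function(cal) {
  vars <- cal$continuous$var
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  for (i in seq_len(nrow(cal$correlations))) {
    a <- cal$correlations$a[i]; b <- cal$correlations$b[i]
    R[a, b] <- R[b, a] <- cal$correlations$rho[i]
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("correlation specification is not positive semi-definite")
  R
}

# Correlated truncated-Gaussian draws: out-of-range rows are redrawn wholesale
# (preserving the copula), so marginal means are approximately preserved
# rather than distorted by clipping.
draw_continuous <- function(n, cal) {
  spec <- cal$continuous
  R <- copula_corr(cal)
  draw <- function(m) {
    z <- MASS::mvrnorm(m, mu = rep(0, nrow(spec)), Sigma = R)
    if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
    sweep(sweep(z, 2, spec$sd, `*`), 2, spec$mean, `+`)
  }
  x <- draw(n)
  for (iter in 1:200) {
    bad <- rowSums(sweep(x, 2, spec$lower, `<`) |
                     sweep(x, 2, spec$upper, `>`)) > 0
    if (!any(bad)) break
    x[bad, ] <- draw(sum(bad))
  }
  colnames(x) <- spec$var
  as.data.frame(x)
}

#' Generate a synthetic cohort
#'
#' Draws `n` patient records from a [cohort_calibration()]: continuous
#' covariates from a Gaussian copula with the calibrated truncated marginals,
#' binary covariates as Bernoulli draws at the calibrated prevalences,
#' summed scores rounded to integers in `[0, 68]` with `dss = ess - lss`,
#' and event times from an exponential hazard
#' `baseline * exp(log_hr_ess * ess) * multiplier(late-H/M category)`
#' censored uniformly over the follow-up window. Event types are multinomial
#' over the four arrhythmic-event categories.
#'
#' @param calib A [cohort_calibration()]; defaults to the reference cohort.
#' @param n Number of records (default `calib$n`); must be at least 10.
#' @param seed Optional integer seed; the same seed yields an identical table.
#' @return A data frame of patient records, one row per patient, with columns
#'   `id`, the covariates and imaging metrics, `followup_months`,
#'   `event_type` and `event_month` (NA when censored).
#' @examples
#' coh <- make_cohort(seed = 1)
#' mean(coh$early_hm)
#' table(coh$event_type)
#' @export
make_cohort <- function(calib = cohort_calibration(), n = calib$n, seed = NULL) {
  validate_calibration(calib)
  if (n < 10L) stop("n must be at least 10 for non-degenerate statistics")
  if (!is.null(seed)) set.seed(seed)
  cont <- draw_continuous(n, calib)
  cont$ess <- pmin(68L, pmax(0L, as.integer(round(cont$ess))))
  cont$lss <- pmin(68L, pmax(0L, as.integer(round(cont$lss))))
  cont$dss <- cont$ess - cont$lss
  bins <- as.data.frame(lapply(calib$proportions, function(p) {
    stats::rbinom(n, 1L, p)
  }))
  cat_hm <- categorize_late_hm(cont$late_hm)
  hazard <- calib$baseline_hazard *
    exp(calib$log_hr_ess * cont$ess) *
    unname(calib$hm_multipliers[as.integer(cat_hm)])
  t_event <- ifelse(hazard > 0, stats::rexp(n, rate = pmax(hazard, 1e-300)), Inf)
  t_cens <- stats::runif(n, calib$censor_window_months[1],
                         calib$censor_window_months[2])
  has_event <- t_event <= t_cens  # ties: event takes precedence
  etype <- rep("none", n)
  if (any(has_event)) {
    etype[has_event] <- sample(names(calib$event_type_probs), sum(has_event),
                               replace = TRUE, prob = calib$event_type_probs)
  }
  data.frame(
    id = sprintf("P%04d", seq_len(n)),
    cont[c("age", "bmi", "lvef")],
    bins,
    cont[c("early_hm", "late_hm", "wo_percent", "ess", "lss", "dss")],
    hm_category = as.character(cat_hm),
    prevention = ifelse(bins$primary_prevention == 1L, "primary", "secondary"),
    followup_months = pmin(t_event, t_cens),
    event_type = factor(etype, levels = event_type_levels()),
    event_month = ifelse(has_event, t_event, NA_real_),
    stringsAsFactors = FALSE)
}
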