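#' Adjudicate composite and secondary endpoints
#'
#' Flags, for each patient record, the composite arrhythmic endpoint
#' (sustained VT, appropriate ICD therapy, resuscitated cardiac arrest or
#' SCD) and the secondary endpoint (appropriate ICD therapy only), with the
#' corresponding event/censoring times: the event month when the endpoint
#' occurred, otherwise the follow-up month.
#'
#' @param records Data frame with columns `event_type` (see
#'   [event_type_levels()]), `event_month`, `followup_months`.
#' @return The input with added columns `ae_flag`, `ae_time`,
#'   `icd_therapy_flag`, `icd_therapy_time`, `scd_flag`, `scd_time`.
#' @export
adjudicate <- function(records) {
  req <- c("event_type", "event_month", "followup_months")
  if (!all(req %in% names(records))) {
    stop("records must have columns: ", paste(req, collapse = ", "))
  }
  et <- as.character(records$event_type)
  if (!all(et %in% event_type_levels())) stop("unknown event type present")
  if (any(records$followup_months <= 0)) stop("follow-up must be positive")
  ae_types <- setdiff(event_type_levels(), "none")
  ae <- et %in% ae_types
  if (any(ae & is.na(records$event_month))) {
    stop("event recorded without an event month")
  }
  if (any(ae & records$event_month > records$followup_months + 1e-9)) {
    stop("event month exceeds follow-up")
  }
  records$ae_flag <- ae
  records$ae_time <- ifelse(ae, records$event_month, records$followup_months)
  icd <- et == "appropriate_ICD_therapy"
  records$icd_therapy_flag <- icd
  records$icd_therapy_time <- ifelse(icd, records$event_month,
                                     records$followup_months)
  scd <- et == "SCD"
  records$scd_flag <- scd
  records$scd_time <- ifelse(scd, records$event_month, records$followup_months)
  records
}

#' Two-group comparison with automatic test choice
#'
#' Compares one variable between two groups the way clinical baseline tables
#' are built: for a numeric variable, Welch's t-test when Shapiro-Wilk
#' accepts normality in both groups (alpha = 0.05), otherwise the
#' Mann-Whitney U test; for a categorical variable, the chi-square test
#' without continuity correction when all expected cell counts are at least
#' 5, otherwise Fisher's exact test.
#'
#' @param cohort Data frame.
#' @param variable Column name of the variable to compare.
#' @param group_flag Column name of a logical/0-1 grouping variable.
#' @return List with `test` (name used), `p`, `statistic` and per-group
#'   summaries.
#' @export
compare_groups <- function(cohort, variable, group_flag) {
  x <- cohort[[variable]]
  g <- as.logical(cohort[[group_flag]])
  if (is.null(x) || is.null(g)) stop("unknown variable or group column")
  if (min(table(g)) < 2L) stop("need at least 2 observations per group")
  if (is.numeric(x) && length(unique(x)) > 2L) {
    if (stats::sd(x) == 0) stop("variable is constant; no comparison possible")
    norm_ok <- vapply(split(x, g), function(v) {
      if (length(unique(v)) < 3L || length(v) < 3L) return(FALSE)
      stats::shapiro.test(v)$p.value >= 0.05
    }, logical(1))
    if (all(norm_ok)) {
      tt <- stats::t.test(x ~ g)
      res <- list(test = "t-test", p = tt$p.value,
                  statistic = unname(tt$statistic))
    } else {
      wt <- stats::wilcox.test(x ~ g, exact = FALSE)
      res <- list(test = "mann-whitney", p = wt$p.value,
                  statistic = unname(wt$statistic))
    }
    res$summary <- t(vapply(split(x, g), function(v) c(mean = mean(v), sd = stats::sd(v)),
                            numeric(2)))
  } else {
    tab <- table(x, g)
    if (nrow(tab) < 2L) stop("variable is constant; no comparison possible")
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (all(expected >= 5)) {
      ct <- stats::chisq.test(tab, correct = FALSE)
      res <- list(test = "chi-square", p = ct$p.value,
                  statistic = unname(ct$statistic))
    } else {
      ft <- stats::fisher.test(tab)
      res <- list(test = "fisher-exact", p = ft$p.value, statistic = NA_real_)
    }
    res$summary <- tab
  }
  res$variable <- variable
  res
}

#' Late heart-to-mediastinum ratio categories
#'
#' Assigns each late H/M value to the low (< 1.2), intermediate
#' (\[1.2, 1.6\], closed interval) or high (> 1.6) category. The three bins
#' partition the positive reals.
#'
#' @param value Positive numeric vector of late H/M ratios.
#' @param cuts Category cut points, default `c(1.2, 1.6)`.
#' @return Factor with levels `low`, `intermediate`, `high`.
#' @export
categorize_late_hm <- function(value, cuts = c(1.2, 1.6)) {
  if (anyNA(value) || any(value <= 0)) stop("late H/M must be positive")
  if (length(cuts) != 2L || diff(cuts) <= 0) stop("cuts must be increasing")
  out <- ifelse(value < cuts[1], "low",
                ifelse(value > cuts[2], "high", "intermediate"))
  factor(out, levels = c("low", "intermediate", "high"))
}

#' Combined-extremes (bell-shape) category test
#'
#' Tests the bell-shaped relation between the late H/M category and an
#' endpoint: the low and high categories are combined and compared against
#' the intermediate category in a 2 x 2 table (chi-square without continuity
#' correction when all expected counts are at least 5, otherwise Fisher's
#' exact test). A small p with a higher event rate in the intermediate
#' category is the bell-shape signature.
#'
#' @param cohort Adjudicated cohort (see [adjudicate()]).
#' @param endpoint `"ae"`, `"icd"` or `"scd"`.
#' @param hm_column Column holding the late H/M ratio.
#' @return List with the 2 x 2 `table`, `test`, `p` and the per-group event
#'   rates.
#' @export
bellshape_test <- function(cohort, endpoint = c("ae", "icd", "scd"),
                           hm_column = "late_hm") {
  endpoint <- match.arg(endpoint)
  flag_col <- c(ae = "ae_flag", icd = "icd_therapy_flag", scd = "scd_flag")[endpoint]
  if (!flag_col %in% names(cohort)) cohort <- adjudicate(cohort)
  cats <- categorize_late_hm(cohort[[hm_column]])
  grp <- factor(ifelse(cats == "intermediate", "intermediate", "extreme"),
                levels = c("extreme", "intermediate"))
  ev <- factor(ifelse(cohort[[flag_col]], "event", "no_event"),
               levels = c("event", "no_event"))
  tab <- table(grp, ev)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    ht <- stats::chisq.test(tab, correct = FALSE)
    test <- "chi-square"
  } else {
    ht <- stats::fisher.test(tab)
    test <- "fisher-exact"
  }
  rates <- tab[, "event"] / rowSums(tab)
  list(table = tab, test = test, p = ht$p.value, event_rates = rates)
}
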