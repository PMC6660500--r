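# Shared fixture builders for the test suite. All fixtures are generated in
# code; no binary data ships with the package.

# A cohort whose event-type composition matches the reference breakdown:
# 25 sustained VT, 22 appropriate ICD therapy, 8 resuscitated arrest,
# 14 SCD, 101 event-free.
fixture_endpoint_cohort <- function() {
  etypes <- c(rep("sustained_VT", 25), rep("appropriate_ICD_therapy", 22),
              rep("resuscitated_arrest", 8), rep("SCD", 14), rep("none", 101))
  n <- length(etypes)
  has_ev <- etypes != "none"
  data.frame(id = sprintf("F%03d", seq_len(n)),
             event_type = factor(etypes, levels = event_type_levels()),
             event_month = ifelse(has_ev, 12, NA_real_),
             followup_months = ifelse(has_ev, 12, 24))
}

# Independent 5-point scoring oracle: a plain lookup table over the rounded
# integer percent, written directly from the bin definition.
oracle_score_table <- function() {
  tab <- integer(101)                 # index = rounded percent + 1
  tab[0:39 + 1] <- 4L
  tab[40:49 + 1] <- 3L
  tab[50:59 + 1] <- 2L
  tab[60:69 + 1] <- 1L
  tab[70:100 + 1] <- 0L
  tab
}

# Independent concordance (Mann-Whitney) AUC oracle for a binary outcome.
oracle_auc <- function(marker, case) {
  xc <- marker[case]; xn <- marker[!case]
  cmp <- outer(xc, xn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Small uncensored survival fixture: every subject observed to the horizon.
fixture_uncensored <- function(n = 60, seed = 11) {
  set.seed(seed)
  marker <- rnorm(n)
  # higher marker -> earlier event; some subjects event-free at month 24
  ev <- runif(n) < plogis(1.2 * marker)
  emonth <- ifelse(ev, runif(n, 1, 23), NA_real_)
  data.frame(id = as.character(seq_len(n)),
             marker = marker,
             event_type = factor(ifelse(ev, "SCD", "none"),
                                 levels = event_type_levels()),
             event_month = emonth,
             followup_months = ifelse(ev, emonth, 24))
}
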