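# mibgquant

Quantification of cardiac sympathetic innervation imaging with
^123^I-*meta*-iodobenzylguanidine (mIBG), and the outcome statistics that go
with it. The package is aimed at nuclear-cardiology and clinical-research
users who need a tested, scriptable implementation of:

* **Planar metrics** — early/late heart-to-mediastinum ratio
  `H/M = H̄ / M̄` (mean counts per pixel in a polygonal heart ROI over a
  7 × 7 mediastinal square) and the background- and decay-corrected washout

  ```
  WO = 100 × [(He − Me) − (Hl − Ml)·f] / (He − Me)   %,   f = 1.21 for 3 h 45 min of 123-I decay
  ```

* **SPECT defect scoring** — mapping a short-axis volume onto the AHA
  17-segment model, per-segment uptake as % of maximum, the conventional
  5-point score (≥70 % → 0 … ≤39 % → 4), and the summed scores
  ESS, LSS, DSS = ESS − LSS.

* **Outcome statistics** — composite arrhythmic-endpoint adjudication
  (sustained VT, appropriate ICD therapy, resuscitated arrest, SCD),
  baseline-table group comparisons, Kaplan–Meier, uni-/multivariable Cox
  with sequential change-in-χ² and a proportional-hazards residual check,
  Kaplan–Meier-based time-dependent ROC, the bell-shaped late-H/M category
  analysis (low < 1.2 / intermediate 1.2–1.6 / high > 1.6, combined
  extremes vs intermediate), and ICC(2,1) inter-observer agreement with the
  clinical poor/fair/good/excellent bands.

* **Synthetic ground truth** — planar and SPECT phantoms with exact or
  Poisson counts, and a cohort generator calibrated to a reference
  heart-failure population of n = 170 (covariate marginals, a log-linear
  ESS hazard with HR 1.028 per point, a bell-shaped late-H/M category
  effect, censoring over 1–51 months), so the whole chain is testable
  without patient data.

See `vignettes/mibg-quantification.Rmd` for the models, conventions and
design decisions.

## Worked example

```r
library(mibgquant)

## phantom with known truth, Poisson counting noise
tr <- planar_truth(He = 162, Me = 100, Hl = 130, Ml = 90)
ph <- make_planar_pair(tr, noise = "on", seed = 2026)
planar_metrics(ph$early, ph$late, ph$roi)
#> planar metrics: early H/M 1.610, late H/M 1.435, washout 22.2%
#>   means/px: He 162.20  Me 100.78  Hl 130.26  Ml 90.78
```

The true early H/M is 162/100 = 1.62 and the true washout
100 × (62 − 40 × 1.21)/62 = 21.9 %; the estimates differ only by Poisson
counting error.

```r
## synthetic cohort -> endpoints -> Cox model
coh <- adjudicate(make_cohort(seed = 1))
sum(coh$ae_flag)
#> [1] 69
cox_fit(coh, endpoint = "ae", covariates = c("ess", "lvef"), sequential = TRUE)
#> Cox model (ae endpoint): 69 events, model chi-square 10.86 (p = 0.00438)
#>  term                  hr          p change_chisq
#>   ess 1.022 (1.001-1.042) 0.03787007     4.312021
#>  lvef 0.965 (0.940-0.992) 0.01051578     6.548250
```

The hazard ratio per ESS point (1.022 here) estimates the generator's truth
of 1.028; `change_chisq` is each covariate's increment to the model
likelihood-ratio χ² in the listed order.

```r
bellshape_test(coh)$p
#> [1] 0.003715757
```

The combined low/high late-H/M categories have a lower event rate (0.29)
than the intermediate category (0.51) — the bell-shaped risk pattern the
generator encodes, detected by the 2 × 2 χ² test.

A thin command-line driver wraps the same functions:

```sh
Rscript inst/cli/mibgquant.R simulate --n 170 --seed 1 --out cohort.csv
Rscript inst/cli/mibgquant.R stats --cohort cohort.csv --endpoint ae --covariates ess,lvef --sequential
Rscript inst/cli/mibgquant.R run --seed 1 --out results/
```

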