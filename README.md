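# organodx

Drug-response profiling for patient-derived organoids (PDOs), and the
downstream analyses that turn a viability screen into clinical predictions:
in vivo validation, predictive expression signatures, and candidate drugs
for resistant tumors.

Colorectal-cancer patients receive oxaliplatin-based chemotherapy (FOLFOX)
as first-line adjuvant treatment, but a large fraction do not benefit.
Organoids grown from a patient's tumor can be screened in vitro, and their
drug sensitivity compared against what happened to the patient. `organodx`
implements that workflow end to end for analysts working with such screens:

1. **Dose-response quantification.** Viability plates are fitted with the
   four-parameter logistic
   *V(d) = bottom + (top − bottom) / (1 + (d/IC50)^h)*,
   giving IC50, E~max~ (percent inhibition at the top tested dose) and a
   normalized AUC. PDOs are classified on log~10~IC50 into strong /
   moderate / minor / non-responders; strong+moderate form the
   oxaliplatin-sensitive (OS) group, minor+non the resistant (OR) group.
2. **Xenograft efficacy.** Paired control/treated tumor-volume courses are
   scored with percent tumor growth inhibition,
   *%TGI = [1 − (T~t~/T~0~)/(C~t~/C~0~)] / [1 − C~0~/C~t~] × 100*
   on arm medians, with the ≥ 50% responder rule.
3. **Signature discovery.** Counts are normalized by median-of-ratios size
   factors; differential features between OR and OS are ranked per
   leave-one-out fold, and the consensus signature is the intersection of
   every fold's top-k list. Single-feature logistic-regression predictors
   are scored by leave-one-out accuracy, and a panel of standard
   classifiers validates the signature.
4. **Connectivity scoring.** Up/down query signatures are scored against
   reference rank profiles with a signed Kolmogorov–Smirnov statistic
   scaled to ±100; perturbagens scoring ≤ −95 against both of two query
   signatures are selected as sensitization candidates.
5. **Clinical concordance.** PDO class vs patient outcome is summarized by
   confusion metrics, Fisher's exact test, and a one-sided Cochran–Armitage
   trend test across the four ordered response categories.

A synthetic-data module generates inputs with the statistical structure
each stage assumes (4PL plates, negative-binomial count matrices with
planted effects, exponential xenograft growth, bernoulli patient cohorts),
so the whole pipeline runs and is tested without any external data.

## Worked example

```r
library(organodx)

# fit a simulated noiseless plate on the standard 8-dose grid
sc  <- screen_scenario(data.frame(top = 100, bottom = 10, hill = 1.2, ic50 = 3),
                       noise_sd = 0)
fit_4pl(gen_dose_plate(sc, 1))
#> <dose_response_fit> PDO01 / oxaliplatin
#>   IC50 3 uM (log10 0.477)  Emax 88.7%  AUC 0.610
#>   top 100.0  bottom 10.0  hill 1.20

classify_response(c(0.30, 0.80, 1.10, 1.50))
#>   log10_ic50 category group
#> 1       0.30   strong    OS
#> 2       0.80 moderate    OS
#> 3       1.10    minor    OR
#> 4       1.50      non    OR

# xenograft scoring: control 100 -> 400 mm3, treated 100 -> 200 mm3
course <- tumor_course(data.frame(
  mouse_id = rep(c("C1", "T1"), each = 2),
  arm = rep(c("control", "treated"), each = 2),
  day = c(0, 21, 0, 21), volume_mm3 = c(100, 400, 100, 200)))
compute_tgi(course)
#> <tgi_result> day 21: %TGI = 66.67% (responder)

# concordance for a 17-patient cohort (7+2 OS-PDO, 3+5 OR-PDO patients)
t22 <- cohort_2x2(7, 2, 3, 5)
confusion_metrics(t22)
#> <concordance_metrics> n = 17
#>   sensitivity 70.0%  specificity 71.4%
#>   PPV 77.8%  NPV 62.5%  accuracy 70.6% (12/17)
fisher_exact(t22)
#> [1] 0.1534348
cochran_armitage(events = c(3, 2, 1, 1), n = c(4, 4, 5, 4))
#> <trend_test> Z = -1.674, one-sided (decreasing) p = 0.0471 [asymptotic]
```

The IC50 is read off at the curve's inflection; E~max~ = 88.7% means the
drug suppresses viability to 11.3% at 100 uM. In the cohort example, an OS
(sensitive) PDO call predicts clinical response with 77.8% positive
predictive value, and recurrence falls monotonically across the ordered
categories (trend p = 0.047) even though the 2×2 association alone is not
significant (Fisher p = 0.15).

An end-to-end synthetic run (42 plates, an 8 vs 8 count matrix, 8
xenograft courses, a 17-patient cohort) is one call:

```r
run_pipeline(list(output_dir = "demo_run", seed = 1))
```

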