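# modeeffects

Evaluating selection, measurement, and prediction bias in mixed-mode
cognitive assessments.

## What problem this solves

Large-scale studies increasingly administer cognitive tests in mixed modes:
supervised paper-based (PBA) or computer-based (CBA) sessions, unsupervised
web-based testing (WBA), and often a web-based *switch* offer to people who
refused a supervised appointment (WBA-switch). Before scores from these arms
can be pooled, three questions need answers:

1. **Who participates?** Mode-specific self-selection is analysed with
   participation logits and mode-interaction contrasts, and corrected with
   inverse participation-probability (propensity-score) weights
   `w = p^-1` for the assigned arms and `w = (1 - p_first)^-1 p_switch^-1`
   along the switch path.
2. **Does the test measure the same way in every arm?** Each arm is
   calibrated with a propensity-weighted one-parameter IRT model (Rasch /
   partial credit, marginal maximum likelihood with Gauss–Hermite
   quadrature). Differential test functioning compares the arms' expected
   score functions `TS(θ) = Σ_j w_j E[X_j | θ]`:

   `sDTF = ∫ (TS_ref(θ) − TS_comp(θ)) f(θ) dθ`,   `uDTF = ∫ |TS_ref − TS_comp| f dθ`,   `uDTF% = 100·uDTF / 36`,

   with confidence intervals from 100 redraws of the item parameters from
   their asymptotic covariance. Person scores are weighted maximum
   likelihood estimates (Warm), item fit is the weighted mean square
   (infit, acceptable below 1.20), and precision is the empirical
   reliability `1 − mean(SE²)/var(θ̂)`.
3. **Do the scores predict later outcomes identically?** z-standardized
   criteria are regressed on z-standardized literacy, mode dummies and
   literacy-by-mode interactions (plus effect-coded sex and teacher
   education), pooled over multiply imputed criterion data; significant
   interactions indicate mode-specific prediction bias.

Because the motivating data sources are access-restricted, the package ships
a first-class synthetic-study generator that emulates a large three-arm mode
experiment (17,473 students, arms 5371/3431/8671, participation rates
25.6/18.2/54.2% and 25.6% in the switch stage, a 29-item test scored 0–36,
mode-specific difficulty shifts, careless responding in the unsupervised
arms, and four criterion variables with mode-moderated slopes). Multiple
imputation of missing covariates and criteria uses chained equations
(regression trees for continuous, multinomial regression for categorical
columns) with Rubin pooling.

## Worked example

```r
library(modeeffects)
cfg <- sim_config(n_total = 4000,
                  mode_split = c(PBA = 1200, CBA = 800, WBA = 2000),
                  seed = 13)
res <- run_study(cfg, out_dir = "mode_run", m_imputations = 5,
                 dtf_draws = 100, log = FALSE)

res$rates
#>         mode assigned participated rate_percent
#> 1        PBA     1200          320         26.7
#> 2        CBA      800          149         18.6
#> 3        WBA     2000         1053         52.6
#> 4 WBA_switch     1531          375         24.5
```

Participation accounting per arm: of 1200 students assigned to paper-based
testing, 320 took the test (26.7%); the unsupervised web arm participates at
roughly twice that rate, and 375 of the 1531 supervised refusers accept the
web-based switch offer.

```r
res$calibration
#> Two-step mode-group calibration
#>   PBA        variance 0.76 [0.67, 0.85]
#>   CBA        variance 0.92 [0.73, 1.11]
#>   WBA        variance 0.29 [0.26, 0.33]
#>   WBA_switch variance 0.28 [0.25, 0.31]

subset(res$dtf, reference == "PBA" & comparison == "WBA",
       c(sdtf, sdtf_lower, sdtf_upper, udtf_pct))
#>  sdtf sdtf_lower sdtf_upper udtf_pct
#>  0.79       0.45       1.05     2.79
```

At equal proficiency, a student scores on average 0.79 raw-score points
(95% CI [0.45, 1.05], about 2.8% of the 36-point maximum) more in the
supervised paper arm than in the unsupervised web arm — the generator's
injected web-mode difficulty shift, recovered by the DTF analysis. The
latent-variance attenuation in the web arms reflects the injected careless
responding.

```r
res$prediction$self_concept
#> Prediction-bias regression: self_concept (n = 431, m = 5)
#>   (Intercept)             -0.24  [-0.49,  0.00]
#>   lit_z                    0.37* [ 0.21,  0.54]
#>   ...
#>   lit_z:modeWBA           -0.37* [-0.61, -0.13]
#>   ...
#>   R2 = 0.082, Delta R2 (moderation block) = 0.035
```

The literacy–self-concept association is strong where literacy was measured
on paper (0.37) and significantly weaker when it was measured in the
unsupervised web arm (interaction −0.37): a mode-specific prediction bias,
exactly as generated.

A thin command-line wrapper is installed at `exec/modeeffects`
(`modeeffects run-all --seed 1 --out run_dir`, with verbs `generate`,
`impute`, `select`, `calibrate`, `dtf`, `predict`, `report`).

See `vignettes/mode-effect-evaluation.Rmd` for the models, identification
assumptions (why group latent means are fixed at zero), calibration of the
generator defaults, and numerical choices.

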