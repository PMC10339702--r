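# hcqpbpk

Whole-body physiologically based pharmacokinetic (PBPK) modeling of
hydroxychloroquine (HCQ) linked to its primary metabolite
desethylhydroxychloroquine (DHCQ), with per-subject blood-to-plasma ratio
(B/P) variability, virtual healthy and mild-COVID-19 populations,
virtual-trial power analysis, and predicted-vs-observed model
qualification.

## The problem

HCQ pharmacokinetics are notoriously variable: the volume of distribution
spans ~25,000–94,000 L, the terminal half-life is ~30–40 days, and the
blood-to-plasma concentration ratio (B/P) ranges from 1 to 22 across
individuals because HCQ and DHCQ partition extensively into red blood
cells. Dried-blood-spot (DBS) sampling measures *blood* concentrations, so
B/P variability propagates directly into observed exposure. This package
provides a mechanistic toolkit for that setting:

- a perfusion-limited, whole-body PBPK model for HCQ with linked DHCQ
  formation through the CYP2C8/CYP3A4/CYP2D6 pathways
  (f<sub>m,CYP2C8</sub> = 0.37, f<sub>m,CYP3A4</sub> = 0.17,
  f<sub>m,CYP2D6</sub> = 0.19, f<sub>e</sub> = 0.27) and DHCQ elimination
  by renal (2.9 L/h) plus whole-organ metabolic clearance;
- mechanistic tissue-to-plasma partition coefficients (K<sub>p</sub>) for
  a diprotic base, Rodgers–Rowland style, with the acidic-phospholipid
  association calibrated from each subject's B/P and a global
  K<sub>p</sub> scalar of 2.2 (adipose and muscle overrides capture the
  extended terminal phase);
- virtual populations in which each subject draws a B/P from an empirical
  frequency table (default: levels 1–12) and log-normal CYP expression
  multipliers; the mild-COVID-19 population reduces mean CYP2C8
  expression by 60% and CYP3A4 by 30%;
- virtual-trial machinery: AUC<sub>0–672h</sub>/C<sub>max</sub> on blood
  concentrations, pooled arm summaries, the equal-variance t-test on
  pooled means/SDs, and sample-size scans;
- model qualification: AFE = 10^(mean log10(pred/obs)),
  AAFE = 10^(mean |log10(pred/obs)|), and the proportion of observations
  within the 5th–95th rank-percentile prediction band (WPI);
- a generator for sparse DBS-like observation datasets emulating the two
  clinical cohorts (94 SARS-CoV-2(−) participants with 226/197
  quantifiable HCQ/DHCQ records; 34 SARS-CoV-2(+) with 123/115), with
  self-reported-time noise, adherence thinning and 1–2000 ng/mL assay
  censoring.

The system is linear, so profiles are propagated exactly with piecewise
matrix exponentials restarted at dose events — mass balance holds to
machine precision (and is asserted at 0.1% on every run).

## Worked example

```r
library(hcqpbpk)

model <- default_model()

# expected exposure change from the mild-COVID-19 CYP reductions
expected_exposure_change(model$partition, c(cyp2c8 = 0.60, cyp3a4 = 0.30))
#> percent_removed       auc_ratio
#>        27.30000         1.37551

# default subject (B/P 7): single 310 mg i.v. infusion
s   <- virtual_subject(model = model)
sim <- simulate_profile(s, regimen_preset("iv310"), 4000)
estimate_terminal_halflife(sim, "HCQ", c(1000, 4000)) / 24
#> [1] 34.47951        # days, inside the reported 30-40 day range

kp <- predict_kp_method2(model$compounds$hcq, model$tissues, 7)
compute_vss(kp, model$physiology, 7)
#> vss_plasma  vss_blood
#>  45475.602   6496.515  # L, inside the reported 25,000-94,000 L range

# 10 virtual trials of 30/arm, healthy vs mild COVID-19, treatment regimen
des <- trial_design(30, n_trials = 10, seed = 1)
cmp <- summarize_comparison(run_trial_set(des, model = model))
cmp[, c("metric", "ratio", "p")]
#>      metric     ratio           p
#> 1   hcq_auc 1.0303753 0.824860759
#> 2  hcq_cmax 1.0145370 0.876596552
#> 3  dhcq_auc 0.6811869 0.003618000
#> 4 dhcq_cmax 0.7144579 0.004103867
```

At 300 subjects per arm the HCQ ratios sit at ~1.0 (no detectable disease
effect) while the DHCQ ratios fall to ~0.7 — DHCQ formation runs through
the reduced CYP pathways, so the metabolite shows the disease effect at
much smaller sample sizes than the parent. The synthetic cohort
generator reproduces the clinical record counts exactly:

```r
rec <- generate_dbs_dataset(cohort_spec("sars_neg"),
                            population_spec("healthy"), seed = 1)
table(rec$analyte[rec$flag == "quantifiable"])
#> DHCQ  HCQ
#>  197  226   # across 94 participants
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from the installed package: the analytic expected exposure
change implied by the CYP expression reductions; the terminal half-life
(log-linear regression over 1000–4000 h) after a single 310 mg i.v.
infusion in the default subject; and the plasma-referenced steady-state
volume of distribution of the default parameterization. Results are
written as JSON to `--out`.

A thin CLI over the same functions is in `exec/hcqpbpk`
(`simulate`, `trial`, `power`, `fit`, `evaluate`, `synth` subcommands with
`--config/--seed/--out`).

See `vignettes/methods.Rmd` for the model equations, parameter rationale,
numerical choices and limitations.
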