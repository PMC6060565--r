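# strokebbn

Discrete Bayesian belief network (BBN) pipeline for categorical
health-survey data, built around a concrete epidemiological question: which
combinations of sleep duration (short < 7 h, average 7–8 h, long ≥ 9 h) and
physical activity (intensity, per-session duration, weekly frequency) go
with a self-reported stroke prevalence below the national average
(≈ 3.07%), across age groups and sex, once the other stroke correlates are
accounted for?

It is written for biostatisticians and epidemiologists who want the whole
chain — binning, structure learning, validation, inference, profile
enumeration — as tested, scriptable R functions rather than a GUI tool.

## What it does

* **Discretization** — the survey's deterministic bins: half-hour rounding
  of sleep reports, short/average/long sleep, `<10 / 10–30 / 31–60 / >60`
  minute activity bins, `18–45 / 46–65 / 66+` age groups, plus generic
  YAML-configurable bin rules.
* **Structure learning** — naive Bayes and tree-augmented naive Bayes
  (TAN) via Chow–Liu: maximum-weight spanning tree on conditional mutual
  information `I(Xi; Xj | C)`, oriented from a deterministic root. Model
  selection by minimum description length,
  `MDL = Σ w·(−log2 P(x)) + (K/2)·log2 N`.
* **Estimation and imputation** — Laplace-smoothed CPTs; exact
  posterior-mode imputation of missing cells given each record's observed
  cells, with optional refit passes.
* **Inference** — exact posteriors by variable elimination (with a
  brute-force enumeration oracle for testing); *dynamic* observational
  queries (plain conditioning) and *fixed-probability* queries
  (covariate standardization over the baseline joint,
  `Σ_z P(z) P(C | e, z)`, enumerated or seeded Monte-Carlo) as a
  confounding control.
* **Evaluation** — association screen (mutual information in bits,
  normalized and relative MI, ordinal Pearson r, G-test `G = 2N ln2 · I`)
  and classifier validation (precision, reliability, ROC index by
  midranks, lift index).
* **Profiles** — enumeration of sleep × activity × age × sex evidence
  grids (the 36-profile study design is the default), prevalence per cell
  under either inference mode, strict flagging below a threshold, and the
  seven-column report table.
* **Synthetic survey generator** — a seeded TAN ground truth over the
  34-correlate NHIS-like schema (binary stroke target at exactly the
  configured prevalence) with MCAR missingness, so every stage is testable
  without microdata access; a `jshape_sleep` option reproduces the
  J-shaped sleep–stroke relationship qualitatively.

## Worked example

```r
library(strokebbn)

gen <- generator_config(jshape_sleep = TRUE, seed = 1)   # 35-variable survey
cfg <- pipeline_config(generator = gen, n = 100000, mc_samples = 20000,
                       seed = 2, out_dir = "run")
res <- run_pipeline(cfg)
#> generate: 100000 records, 68174 missing cells
#> split: 80000 learning / 20000 test records
#> learn: selected 'tan' by total MDL
#> impute: 54504 cells imputed; CPTs refit
#> validate: precision 97.46% reliability 97.01% ROC 92.56% lift 92.67%
#> profiles: 36 cells, 11 below 3.07%

res$selection$scores
#>   candidate model_dl data_dl total_mdl   k
#> 1        nb 1216.111 2060921   2062137 159
#> 2       tan 3678.926 1925597   1929276 481

head(res$profile_report, 3)
#>     Age  Sex             Physical activity Frequency of PA Stroke % (PA only)
#> 1 18-45 male Moderate activity (31-60 min)    5 times/week               5.86
#> 2 18-45 male Moderate activity (31-60 min)    5 times/week               5.86
#> 3 18-45 male Moderate activity (31-60 min)    5 times/week               5.86
#>   Sleep duration Stroke % (PA and sleep)
#> 1          short                    6.28
#> 2        average                    4.97
#> 3           long                   10.47
```

Reading the output: the TAN structure wins model selection (lower total
MDL — its extra 322 parameters buy a 135k-bit drop in data code length on
80,000 learning records); held-out precision/reliability/ROC/lift are the
four validation percentages; and each profile row gives the standardized
(fixed-mode) stroke prevalence for one evidence combination, with the
sleep column omitted for the "PA only" column. On this synthetic draw the
J-shape is visible in every stratum: average sleep sits below short, and
long sits above both. Artifacts (`network.json`, `scores.tsv`,
`associations.tsv`, `validation.json`, `profiles.tsv`, `pipeline_log.txt`
with every seed) land in `out_dir`.

Single queries work standalone:

```r
net <- res$net
observational_query(net, "STROKE", list(HRSLEEP = "long"),
                    mode = "fixed", mc_samples = 50000, seed = 3)
#> <bbn_obs_result> mode = fixed ( monte-carlo )
#>       no      yes
#> 0.942370 0.057630
```

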