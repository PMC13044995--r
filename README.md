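# snaftm

Estimation of **structural nested accelerated failure time models
(SNAFTM)** for the causal effect of a binary time-varying exposure on a
time-to-event outcome under time-varying confounding.

## The problem

In longitudinal observational studies a covariate such as blood pressure can
both predict future exposure (someone may quit smoking after an abnormal
reading) and be affected by past exposure, while also being a risk factor for
the outcome. Conventional survival models that simply adjust for such
time-varying confounders are biased for the joint causal effect of the
exposure process. The SNAFTM instead models the effect of each "blip" of
exposure in the interval \((t_k, t_{k+1}]\) as a multiplicative
acceleration/compression of the remaining event-free time:

```
gamma_k(y) = t_k + (y - t_k) * exp(phi_k * a_k),      phi_k = -psi_k,
```

so that transforming the observed time visit-by-visit removes the exposure
effect and recovers the counterfactual *unexposed* survival time

```
H(psi, k) = t_k + sum_{u=k..V} (min(T, t_{u+1}) - t_u) * exp(-psi_u * a_u).
```

Throughout the package **psi > 0 means exposure extends event-free time** (the
usual AFT sign convention); an exposure with reported `psi = -0.61` compresses
the event-free time by a factor `exp(-0.61) = 0.54`.

Under the sequential randomization assumption (no unmeasured time-varying
confounding), the true `psi` is the value at which `H(psi, k)` is
conditionally independent of the exposure at visit `k` given the measured
history. With right censoring, the counterfactual times are first *artificially
recensored* at the minimal potential follow-up `C(psi, k)` (the smallest
transformed administrative follow-up in the batch), giving `X = min(H, C)`,
the event indicator `Delta = 1{H < C}` and its smoothed version
`Delta* = 1 - X/C` on `[0, 1]`, which keeps the censoring mechanism
non-informative on the transformed scale and the objective usable by
gradient methods.

## Estimators

* **`gest1d` / `gest2d`** — classical grid-search g-estimation. For each
  candidate `psi` the score
  `S(psi) = sum_{i,k} G_ik(psi) * (A_ik - phat_ik)` is computed from the
  artificially censored outputs and a fitted exposure (propensity) model; the
  estimate minimizes the chi-square statistic `T(psi) = S' V^-1 S` and the
  95% confidence set is obtained by test inversion. The 2-d variant models
  `psi_ik = psi1 + psi2 * modifier_ik`.
* **`ge_score`** — a small recurrent network maps each subject's covariate
  history to individualized per-visit effects `psi_ik` (bounded output
  `psi_max * tanh`), trained by minimizing
  `sum_k [gamma1 * (|cor(r_k, X_k)| + |cor(r_k, Delta*_k)|) + gamma2 * var_i(psi_ik)]`
  against the residuals `r = A - phat` of a separately fitted, frozen
  exposure model.
* **`ge_mimic`** — the same network trained by matching the observed
  dependence statistics `cor(a_k, X_k)` and `cor(a_k, Delta*_k)` to the mean
  of their null distribution under `M` exposure copies redrawn from the
  fitted exposure mechanism (which preserves the exposure law but breaks any
  dependence on the counterfactual outcome).

A calibrated longitudinal simulator (`scenario_config()` /
`simulate_scenario()`) provides four effect scenarios — constant,
linear-in-covariate, history-dependent, and nonlinear capped — plus a null
scenario, with the generating truth attached for benchmarking
(`run_benchmark()`, `bias_summary()`).

## Worked example

```r
library(snaftm)

cfg <- scenario_config("I", "beneficial", n = 3000, seed = 11)
panel <- simulate_scenario(cfg)   # constant true effect psi* = +0.5
panel
#> SNAFTM panel: 3000 subjects, 6001 person-visit records
#> Visit schedule: t = 0, 2, 4  (K = 2 ), end of study tau = 6
#> Covariates: L, gender
#> Events: 1833 (61.1%); exposure prevalence 57.1%

fit <- snaftm(panel, method = "gest1d")
fit
#> SNAFTM fit (gest1d), 3000 subjects, 6001 person-visit records
#> psi estimate: 0.4500
#> 95% confidence interval: [0.320, 0.590]

net <- snaftm(panel, method = "ge_score", seed = 11)
net
#> SNAFTM fit (ge_score), 3000 subjects, 6001 person-visit records
#> mean individualized psi (test split): 0.4314  range [0.1467, 0.6861]
```

The grid search recovers the generating constant effect (0.45, CI covering
0.5), and the network estimator's individualized test-split predictions
center on the same value. `acceleration_factor(coef(fit))` converts the
estimate to the per-interval time-compression factor (0.64 here), and
`weibull_rate_ratio(psi, shape)` gives the event rate ratio implied by a
Weibull counterfactual survival time.

A thin command-line wrapper is installed under `exec/`:

```sh
snaftm simulate --scenario II --n 3000 --seed 7 --out data.csv --truth truth.csv
snaftm fit --data data.csv --method gest1d --grid -1,1 --step 0.01 --out fit.json
snaftm benchmark --scenario IV --methods gest1d,ge_score,ge_mimic --reps 10 --out bench/
snaftm convert --psi 0.61 --shape 2.25
```

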