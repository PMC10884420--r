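# psmcr

Cause-specific Cox proportional-hazards modelling for right-censored survival
data with two competing causes of death, plus a propensity-score rule that
reclassifies selected censored subjects as deaths before refitting.

In oncology cohorts a large share of subjects leave the study alive
("censored"), yet some of them will in reality have died — from the cancer
(cause 1, death after progression) or from unrelated causes (cause 2, direct
death). `psmcr` is aimed at biostatisticians analysing such cohorts who want
to quantify how re-labelling the highest-risk censored subjects changes the
cause-specific hazard-ratio estimates and cumulative incidence curves.

## The method

For each competing cause *k* the cause-specific hazard follows a Cox model

    h_k(t | x) = h_{k0}(t) exp(x' beta_k),

fitted by Newton–Raphson maximisation of the Breslow partial likelihood,
with the Nelson–Aalen step estimator for the cumulative baseline hazard
H\_{k0}(t). Coefficient signs (from this fit, or from a random-walk
Metropolis posterior under a flat prior) define a *minimum-hazard reference
profile* x\_min: per covariate, the sample minimum when beta\_l > 0 and the
maximum otherwise. Each censored subject r gets the score

    Delta_r = sum_v w_v (x_{v,min} - x_{v,r})^2,    w_v = 1 / s_v^2,

the weighted squared Euclidean distance from that low-risk corner. With a
threshold probability *p* (default 0.9), subjects whose empirical-CDF rank of
Delta\_r strictly exceeds *p* — the top (1 − p) fraction farthest from the
low-risk profile — are flipped from censored to dead from cause *k* (their
observed time is kept), and the model is refitted. Nonparametric
Aalen–Johansen cumulative incidence functions and a Weibull
(H(t) = lambda t^gamma) competing-risks simulator with cumulative-hazard
inversion round out the workflow, together with a Monte-Carlo harness that
reports mean, bias and MSE of every coefficient before and after the update.

## Worked example

```r
library(psmcr)

d <- simulate_crdata(n = 200, seed = 42)   # Weibull competing-risk draw
d
#> Competing-risks dataset: 200 subjects, 3 covariate(s)
#>   events: cause 1 = 84, cause 2 = 91, censored = 25
#>   administrative censoring at t = 5

fit <- psmcox(d, cause = 1, p = 0.9)       # fit -> update -> refit
fit
#> Cause-specific Cox with propensity-score censoring update
#> Propensity update towards cause 1: 3 of 25 censored subjects reclassified (p = 0.9)
#> events: 84 -> 87
#>
#> coefficients:
#>             x1     x2     x3
#> before -0.3305 0.0539 0.0361
#> after  -0.3369 0.0834 0.0739
```

The update flips the 3 censored subjects (top 10% of 25) farthest from the
minimum-hazard covariate profile to cause-1 deaths, raising the event count
from 84 to 87 and shifting the coefficients accordingly. The Monte-Carlo
study repeats this over replicated simulations:

```r
st <- run_simulation_study(n = 200, reps = 100, seed = 42)
st
#> Monte-Carlo study: 100 replicates x 200 subjects (p = 0.9, signs = mple)
#>    condition parameter   mean1   bias1   mse1   mean2   bias2   mse2
#>  without_psm     beta1 -0.4891  0.0109 0.0162 -0.5202 -0.0202 0.0175
#>  without_psm     beta2  0.0068 -0.0032 0.0136  0.4488  0.0188 0.0114
#>  without_psm     beta3  0.0143 -0.0057 0.0116  0.0289 -0.0011 0.0127
#>     with_psm     beta1 -0.4983  0.0017 0.0151 -0.5256 -0.0256 0.0168
#>     with_psm     beta2  0.0083 -0.0017 0.0210  0.4726  0.0426 0.0122
#>     with_psm     beta3  0.0176 -0.0024 0.0191  0.0388  0.0088 0.0209
```

(columns: mean/bias/MSE per cause; `without_psm` rows are the plain
cause-specific fits, `with_psm` rows the refits after the per-cause update).

A four-state illness-death workflow (LRC → FP → DP → Death with direct
LRC → Death) is available through `simulate_chemo_analog()`,
`to_long_transitions()`, `cscox_transition()`, `wide_to_crdata()`,
`psm_update_joint()` and `plot_cif_compare()`.

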