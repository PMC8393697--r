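# aircopula

Copula modelling of the duration and severity of unhealthy air-pollution
episodes.

Hourly air-quality monitoring classifies hours with an air-pollution
index (API) above 100 as *unhealthy*. A maximal run of consecutive
unhealthy hours is an **episode**, characterised by its duration *D* (run
length, hours) and severity *S* (cumulative API over the run). The two
are strongly dependent — severity accumulates over duration — and both are
heavily right-skewed with non-identical margins, so no classical bivariate
family fits. `aircopula` models the pair semi-parametrically through a
bivariate copula:

> *H(d, s) = C{F_D(d), F_S(s)} = C(u₁, u₂)*

with rank-based empirical margins and six candidate one-parameter copula
families (Clayton, Ali–Mikhail–Haq, Frank, Plackett, Gumbel–Hougaard,
Joe). The dependence parameter θ is estimated by pseudo-maximum
likelihood — maximising Σⱼ log c(û₁ⱼ, û₂ⱼ; θ) over pseudo-observations
rank/(n+1) — and the family is chosen by the leave-one-out
cross-validated copula information criterion (cvCIC, larger is better).
The selected copula feeds risk measures used in environmental planning:

* Kendall's τ implied by the fitted copula;
* conditional probability P(S ≤ s | D ≥ d′) = {u₂ − C(u₁′, u₂)}/(1 − u₁′);
* joint OR / AND return periods T′_DS = E(L)/(1 − C) and
  T_DS = E(L)/(1 − u₁ − u₂ + C);
* conditional return periods T_{D|S≥s}, T_{S|D≥d},

all in days, on the time scale of the mean event inter-arrival time E(L).

The intended users are air-quality analysts and environmental-risk
modellers; the same machinery applies to any threshold-exceedance
duration–severity pair (droughts, heat waves, extreme winds).

## Worked example

No public hourly API record is bundled, so the example generates a
synthetic 10-year series from the package's own regime-switching
generator (exceedance ≈ 2–3 %, mean episode ≈ 21 h, τ(D,S) ≈ 0.9):

```r
library(aircopula)

series <- simulate_api_series(series_gen_config(n_hours = 87600, seed = 2024))
exceedance_proportion(series)      # 0.0324 -> 3.24% unhealthy hours

events <- extract_events(series)   # threshold 100, strict exceedance
events
#> <event_catalog> 124 event(s), threshold 100, span 87600 h

catalog_stats(events)[, c("variable", "n", "mean", "median", "max", "skewness")]
#>   variable   n      mean median   max skewness
#> 1 duration 124   22.8629     16   214 3.506932
#> 2 severity 124 2999.0000   2045 27682 3.440761

el <- mean_interarrival_days(events)   # 29.57 days

sel <- select_model(events$duration_hours, events$severity)
sel
#> <copula_selection> best family by cvCIC: joe
#>            family theta_hat pseudo_loglik   cvcic tau_implied boundary
#> 1             joe    31.643       303.456 287.511     0.93924    FALSE
#> 2 gumbel_hougaard    19.577       311.027 277.960     0.94892    FALSE
#> 3           frank    75.914       293.712 269.093     0.94845    FALSE
#> 4        plackett  1339.724       295.410 264.932     0.93543    FALSE
#> 5         clayton    14.676       210.964 148.594     0.88007    FALSE
#> 6             amh     1.000        61.783  59.266     0.33333     TRUE
```

The Joe copula wins on cvCIC — its strong upper-tail dependence matches
how long episodes and extreme severities coincide — while the AMH fit
pins at its boundary (τ capped at 1/3, far below the data's ≈ 0.94) and
is flagged. Return periods over a duration × severity grid:

```r
best <- copula_spec(sel$family[1], sel$theta_hat[1])
risk_table(best, empirical_margins(events), el,
           d_list = c(24, 72, 120), s_list = c(2000, 10000, 30000))
#>   duration severity t_or_days t_and_days t_d_given_s_days t_s_given_d_days
#> 1       24     2000     58.68      94.79            188.1            303.8
#> 2       24    10000     94.79     528.12           9430.8           1692.7
#> 3       24    30000     94.79    3696.86         462107.3          11848.9
#> ...
#> 9      120    30000   1848.43    3696.86         462107.3         231053.6
```

Read row 2 as: an episode lasting ≥ 24 h *or* reaching severity ≥ 10 000
recurs about every 95 days; *both* together about every 528 days; and an
episode of ≥ 24 h recurs every ≈ 9 431 days *given* severity has reached
10 000. The OR horizon never exceeds the AND horizon, which never exceeds
either conditional horizon.

A thin command-line dispatcher over the same functions ships at
`inst/cli/aircopula` (subcommands `extract`, `margins`, `tau`, `sample`,
`fit`, `risk`, `simulate`).

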