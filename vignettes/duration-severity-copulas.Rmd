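---
title: "Duration–severity copula modelling of unhealthy air-pollution episodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duration–severity copula modelling of unhealthy air-pollution episodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aircopula)
```

## The problem and the model

Urban air-quality monitoring produces an hourly air-pollution index (API);
hours with API above 100 are classified *unhealthy*. An unhealthy
**episode** is a maximal run of consecutive unhealthy hours. Two
characteristics summarise each episode: its **duration** $D$ (the run
length in hours) and its **severity** $S$ (the cumulative API over the
run). Because severity accumulates over duration, the two are strongly and
structurally dependent; both are heavily right-skewed with long upper
tails, and their marginal distributions are not of the same family. A
bivariate copula is the natural device for such data: by Sklar's theorem
the joint law factors as

$$H(d, s) = C\{F_D(d), F_S(s)\} = C(u_1, u_2),$$

so the margins and the dependence structure can be modelled separately.

`aircopula` implements the full chain: episode extraction from an hourly
series, rank-based margins, six candidate one-parameter copula families,
semi-parametric estimation, leave-one-out model selection, and
copula-based risk measures (conditional probabilities and return periods).

## Episode extraction

`extract_events()` scans the series for maximal runs with API **strictly**
above the threshold (default 100): an hour at exactly 100 terminates a
run. Each run yields one event with $D_i \ge 1$ and
$S_i = \sum_{j \in \text{run}} \mathrm{API}_j > 100\,D_i$. Three
conventions are deliberate and configurable:

* **Missing hours.** Under the default `missing_policy = "break"` a
  missing value terminates any open run, exactly like a sub-threshold
  hour — conservative and reproducible. Under `"bridge"`, up to `bridge_k`
  consecutive missing hours *flanked by exceeding hours* are skipped
  without breaking the run; bridged hours contribute to neither $D$ nor
  $S$ (counting them in $D$ would break the $S > 100\,D$ invariant). A gap
  in the timestamp grid always breaks a run.
* **Censoring.** A run still open at the last observation is emitted with
  `censored_end = TRUE` rather than silently kept or dropped;
  `include_censored = FALSE` removes it.
* **Descriptives.** `summary_stats()` reports the adjusted Fisher–Pearson
  sample skewness and *raw* (non-excess) kurtosis, with the excess version
  alongside, so either convention can be read off directly.

The mean inter-arrival time $E(L)$ — the time scale of all return
periods — is estimated as the mean start-to-start gap between consecutive
events, the standard renewal-process reading, converted to days at the
interface (never inside formulas).

## Margins

The copula pipeline is rank-based throughout: `pseudo_observations()`
maps each variable to $\mathrm{rank}_i/(n+1)$ with average ranks for ties
(durations are integer-valued, so ties are the norm, not the exception).
The $n+1$ denominator keeps every pseudo-observation strictly inside
$(0,1)$, so copula densities evaluated at transformed data stay finite.
Parametric fits (exponential, gamma, lognormal, Weibull via maximum
likelihood) are retained **as diagnostics only**, together with a
one-sample Kolmogorov–Smirnov index; because the parameters are estimated
from the same data and no Lilliefors-type correction is applied, the KS
p-value is a descriptive index of fit, not an exact test, and the
documentation says so. The pipeline itself always uses the empirical
margins.

## The six copula families

Clayton, Ali–Mikhail–Haq (AMH), Frank, Plackett, Gumbel–Hougaard and Joe,
each with one dependence parameter $\theta$. For each family the package
provides the CDF, the density, the conditional distribution
$h(u_2 \mid u_1) = \partial C/\partial u_1$, Kendall's $\tau$, the
inverse map $\tau \mapsto \theta$, and conditional-inversion sampling.
$\tau$–$\theta$ relations: Clayton $\tau = \theta/(\theta+2)$; AMH in
closed form with the limit $\tau \to 1/3$ as $\theta \to 1$ (its maximum —
the family cannot express strong dependence, which is exactly why it is
kept as a baseline); Frank via the Debye function
$D_1(\theta) = \theta^{-1}\int_0^\theta t/(e^t - 1)\,dt$; Gumbel–Hougaard
$\tau = 1 - 1/\theta$; Joe by the convergent series
$\tau = 1 - 4\sum_{k\ge1} [k(\theta k+2)(\theta(k-1)+2)]^{-1}$, validated
against the closed partial-fraction value at $\theta = 2$ and against
quadrature; Plackett has no closed form and uses `tau_numeric()`.

### Numerical choices

* **Log-space evaluation.** All densities are computed in log space. The
  Frank family is the delicate one: its CDF, density and h-function are
  all expressed through $\log|D|$ with
  $D = e^{-\theta u_1} + e^{-\theta u_2} - e^{-\theta(u_1+u_2)} -
  e^{-\theta}$, evaluated by log-sum-exp. The naive `expm1` product form
  loses *all* precision once $\theta u$ passes about 40 — at the fitted
  dependence strengths ($\theta \approx 50$) this is not a corner case but
  the operating regime. The Joe family gets the analogous treatment for
  $T = a + b - ab$, $a = (1-u_1)^\theta$.
* **Independence guards.** $|\theta| < 10^{-6}$ (Frank, Clayton) and
  $|\theta - 1| < 10^{-6}$ (Plackett) are evaluated as the independence
  limit rather than through removable singularities.
* **$\tau$ by quadrature.** `tau_numeric()` evaluates
  $\tau = 4\iint C\,c - 1$ by tensor Gauss–Legendre quadrature under the
  substitution $u = (1-\cos \pi s)/2$, which clusters nodes quadratically
  at both corners: the tail-dependent families have densities diverging
  like $(1-u)^{-1}$ along the diagonal corner, which unmapped
  Gauss–Legendre resolves too slowly. The node count refines (up to 1024
  for strong dependence) until successive estimates agree to `tol`
  (default $10^{-4}$); non-convergence is an error, never a silent
  result.
* **Sampling.** Conditional inversion: $u_1, v$ uniform, $u_2$ solves
  $h(u_2\mid u_1) = v$ by 64 vectorised bisection steps on
  $[10^{-12}, 1-10^{-12}]$ — one deterministic code path for all six
  families rather than per-family closed-form inverses.

## Estimation and model selection

`pseudo_mle()` maximises the pseudo-log-likelihood
$\sum_j \log c(\hat u_{1j}, \hat u_{2j}; \theta)$ with a bounded 1-D
optimiser on a transformed scale — $\log\theta$ for Clayton and Plackett,
$\log(\theta - 1)$ for Gumbel–Hougaard and Joe, raw bounded $\theta$ for
Frank and AMH — so each family is an unconstrained unimodal search. An
AMH estimate within $10^{-4}$ of its boundary is *flagged* rather than
silently reported: under strong dependence the AMH maximum sits at
$\theta \to 1$, outside the open parameter space, and the flag is the
honest summary of that. For the other families a boundary-pinned optimum
raises an error.

`cvcic()` implements the exact leave-one-out cross-validated copula
information criterion: for each $i$ the parameter is re-estimated on the
remaining $n-1$ pairs and the left-out pair is evaluated through
delete-one empirical margins — the count of *remaining* values $\le u$
divided by $n$, floored at $1/n$ below the remaining minimum. (Counting
the left-out point itself would put the sample maximum at probability 1
and blow up the density there; the remaining-count reading keeps every
evaluation strictly inside the unit square.) Delete-one refits are
warm-started from the full-sample optimum via a windowed search, widened
to the full bounds whenever the optimum lands at the window edge — a pure
speed optimisation with identical optima, verified against a cold-start
brute-force implementation in the test suite. `select_model()` ranks
families by cvCIC (larger is better), breaking ties by the larger
pseudo-log-likelihood.

## Risk measures

With $C$ the selected copula, $u_1 = F_D(d)$, $u_2 = F_S(s)$ from the
empirical margins, and $E(L)$ the mean event inter-arrival time in days:

* conditional probability
  $P(S \le s \mid D \ge d') = \{u_2 - C(u_1', u_2)\}/(1 - u_1')$;
* OR return period $T'_{DS} = E(L)/\{1 - C\}$ (either variable exceeds);
* AND return period $T_{DS} = E(L)/\{1 - u_1 - u_2 + C\}$ (both exceed);
* conditional return periods
  $T_{D|S\ge s} = E(L)/[(1-u_2)\{1 - u_1 - u_2 + C\}]$ and symmetrically
  $T_{S|D\ge d}$.

The $E(L)$ factor is retained in the conditional return periods: a return
period carries time units, and dropping the factor would leave a
dimensionless quantity. Always
$T'_{DS} \le T_{DS} \le$ both conditional horizons, and all four scale
linearly in $E(L)$; these orderings are asserted over grids in the test
suite. `risk_table()` evaluates the four horizons over a
duration × severity grid through the empirical margins, which never reach
1, so every tabulated horizon is finite.

## The synthetic-data generator

No public hourly API record ships with the package, so every pipeline
stage is exercised on synthetic data built to the regime such records
exhibit:

* `simulate_api_series()` runs a two-state (healthy/unhealthy) Markov
  chain over hours. Unhealthy hours carry $100 + \text{lognormal excess}$
  (hence always $> 100$); healthy hours a sub-100 baseline. Defaults:
  `p_enter = 0.00128`, `p_stay = 0.953`, giving a stationary exceedance
  fraction $p_e/(p_e + 1 - p_s) \approx 2.6\%$ and mean run length
  $\approx 21$ h — a multi-year urban record in which unhealthy episodes
  are rare but long-tailed; extracted $(D, S)$ pairs show Kendall's
  $\tau \gtrsim 0.9$ and pronounced right skew.
* `simulate_event_pairs()` builds events directly from a copula draw:
  $D = \max(1, \lceil Q_{\text{lnorm}}(u_1)\rceil)$ and
  $S = 100D + D\,Q_{\text{lnorm}}(u_2)$, so $S > 100D$ holds by
  construction, duration ties are intentional (exercising the
  tie-handling of the rank transform), and the $(D,S)$ association is
  dominated by $D$, mimicking the near-unity dependence of real episode
  catalogs.

What the generator does **not** emulate: seasonal and diurnal structure,
haze-episode clustering in calendar time, monitor drift, or any spatial
field. Passing tests therefore demonstrate correctness of the estimators
under the stated stochastic regime, not fidelity of any particular city's
record.

## Problem sizes and what the tests check

The test suite runs at desk scale: copula property grids over
$\theta$-grids per family, brute-force cvCIC comparison at $n = 25$,
parameter recovery at $n = 1000$ over 10 seeds per (family, $\tau_0$)
pair with mean $|\tau(\hat\theta) - \tau_0| \le 0.05$, model-selection
replication at $n = 200$ over 20 seeds, and synthetic series of
$4\times10^4$–$2\times10^5$ hours. These sizes were chosen as the
smallest at which the sampling error of each check is comfortably below
its acceptance band.

## Known limitations

* One-parameter families only: no rotations (the target regime is
  strongly positive dependence), no two-parameter families
  (BB1/BB7), no vines, and no trivariate duration–severity–intensity
  extension.
* The KS diagnostic ignores parameter estimation (no bootstrap
  correction).
* No analytic standard errors for $\hat\theta$; uncertainty would require
  a bootstrap, which is out of scope.
* Plackett's $\tau$ inversion is quadrature-backed and practical for
  $\tau \in (-0.88, 1)$; stronger negative dependence is outside the
  supported range.
* `empirical_cdf()` margins are step functions: return periods between
  observed data values move in steps, and extrapolation beyond the
  largest observed event is capped at $n/(n+1)$.
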