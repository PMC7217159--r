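---
title: "Power for open-cohort longitudinal cluster randomized trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power for open-cohort longitudinal cluster randomized trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opencohortpower)
```

## The problem

Longitudinal cluster randomized trials — stepped wedge, cluster crossover,
parallel designs with repeated measurement — randomize whole clusters
(schools, wards, nursing homes) to sequences of treatment conditions over
$T$ discrete periods. Sample size calculations for these designs have
traditionally assumed one of two sampling structures: a *closed cohort*
(every participant measured in every period) or *repeated cross-sections*
(every participant measured exactly once). Many real trials sit in between:
the number of participants measured per cluster-period stays constant at
$m$, but individuals enter and leave, so each contributes a variable number
of measurements. This package computes power and sample size for that
*open cohort* middle ground, and verifies every analytic result with a
Monte Carlo simulator.

The degree of openness between periods $t$ and $s$ is summarized by the
**churn rate** $\chi(t,s)$: the expected proportion of the $m$ participants
measured in period $t$ who are not measured in period $s$. Its complement
$1-\chi(t,s)$ is the retention rate, and $n(t,s) = m(1 - \chi(t,s))$ is the
expected overlap count. $\chi = 0$ recovers the closed cohort, $\chi = 1$
repeated cross-sections.

## The outcome model and its correlation parameters

The base model for a continuous outcome is block-exchangeable: participant
$i$ in cluster $k$ at period $t$ has

$$Y_{kti} = \beta_t + \theta X_{kt} + C_k + CP_{kt} + \eta_{ki} + \epsilon_{kti},$$

with independent normal cluster effects $C_k$, cluster-period effects
$CP_{kt}$, participant effects $\eta_{ki}$ (shared across all of a
participant's measurements) and residuals $\epsilon_{kti}$. Period effects
$\beta_t$ are categorical fixed effects; the treatment indicator $X_{kt}$
comes from the design schematic. Users specify the model through four
interpretable parameters (`variance_components()`):

* `sigma2` — total variance $\sigma^2$, in squared outcome units;
* `rho` — intracluster correlation $\rho$ (two participants, same cluster
  and period), typically 0.01–0.2 in community settings, larger in small
  clusters such as classrooms;
* `pi` — cluster autocorrelation $\pi$ (two population means from the same
  cluster in different periods);
* `tau` — participant autocorrelation $\tau$ (two measurements on the same
  participant).

These map to components via $\sigma_C^2 = \sigma^2\rho\pi$,
$\sigma_{CP}^2 = \sigma^2\rho(1-\pi)$, $\sigma_\eta^2 = \sigma^2(1-\rho)\tau$,
$\sigma_\epsilon^2 = \sigma^2(1-\rho)(1-\tau)$. At the boundary $\rho = 0$
the ratio defining $\pi$ is undefined; the package treats $\pi$ as 0 there,
which leaves every component well defined.

Because cluster-period means are sufficient for $\theta$ under
within-period exchangeability, all power calculations collapse to the
$T$-vector of means per cluster, whose covariance is

$$\operatorname{var}(\bar Y_{kt}) = \sigma_C^2 + \sigma_{CP}^2 +
  \tfrac{\sigma_\eta^2 + \sigma_\epsilon^2}{m}, \qquad
  \operatorname{cov}(\bar Y_{kt}, \bar Y_{ks}) = \sigma_C^2 +
  \tfrac{\sigma_\eta^2}{m}\,(1 - \chi(t,s)).$$

Only the retained fraction of participant effects carries between periods
— this single factor is what distinguishes open from closed cohorts.

## Sampling schemes

`sampling_scheme()` supports the churn specifications a planner is likely
to have (all keep $m$ constant):

* **Core group / constant churn** (`chi`): a fixed core observed every
  period topped up with single-measurement participants; natural for
  schools or care homes.
* **Closed population** (`M`): each period an independent simple random
  sample of $m$ from a pool of $M$, so $E[\chi] = 1 - m/M$; participants
  may return after an absence.
* **Beta churn** (`alpha`, `beta` with $\alpha+\beta = m$): cluster-specific
  churn drawn once per cluster from Beta$(\alpha,\beta)$; the covariance of
  cluster-period means depends only on $E[\chi_k] = \alpha/(\alpha+\beta)$,
  so the analytic path uses the expectation.
* **Rotation, "in-for-p"** (`p`): each participant stays at most $p$
  consecutive periods and $1/p$ of the sample rotates out each period, so
  $\chi(t,s) = \min(|t-s|/p, 1)$ — churn grows with lag, and the
  constant-churn design effect does not apply.
* **Custom** tables of $\chi(t,s)$, validated by checking the implied
  covariance is positive semidefinite (an unrealizable table, e.g. full
  retention at lags 1 and 2 but none at lag 2's composition, is refused
  rather than repaired).

Any realized overlap matrix must satisfy, for all period triples,
$n(t,u) + n(u,s) \le n(t,s) + m$; `membership_matrix()` enforces this, and
every matrix `realize_membership()` produces passes it by construction
because counts are derived from an actual participant panel.

## Two routes to power

**Design-effect route** (constant churn only). With
$r = \dfrac{m\rho\pi + (1-\rho)\tau(1-\chi)}{1 + (m-1)\rho}$
— the correlation between two cluster-period means — the individually
randomized total $n_i = \frac{4\sigma^2}{\theta^{*2}}(z_{1-\alpha/2} +
z_{1-\beta})^2$ inflates to the required number of clusters
$K_L = DE(r)\,[1 + (m-1)\rho]\,n_i/m$, where $DE(r)$ is the longitudinal
design effect computed from the schematic's treatment totals
(`design_effect()`). Note that in $r$ the factor $m$ multiplies only the
cluster term $\rho\pi$: the participant term is already a per-person
quantity. `clusters_required()` reports the real-valued $K_L$, the integer
allocation $\lceil K_L/S \rceil$ per sequence, and the achieved power at
that integer allocation, so the rounding cost is visible.

**GLS route** (any scheme, either correlation model). The variance of the
generalized least squares estimator of $\theta$ from cluster-period means
with period fixed effects and known covariance $V$ is

$$\operatorname{var}(\hat\theta) = \Big[\sum_k X_k^\top V^{-1} X_k -
  \big(\textstyle\sum_k X_k\big)^\top V^{-1} \big(K V^{-1}\big)^{-1}
  V^{-1} \textstyle\sum_k X_k\Big]^{-1}.$$

Power uses the normal approximation
$\Phi(|\theta^*|/\sqrt{\operatorname{var}(\hat\theta)} - z_{1-\alpha/2})$,
ignoring the negligible opposite-tail term for consistency with the
$z$-based sample-size formula. Where both routes apply they agree to
machine precision; the test suite asserts agreement to $10^{-8}$ over a
grid of 216 configurations, and checks `gls_variance()` against a
brute-force oracle that inverts the complete $KT \times KT$ information
matrix.

## Decaying correlations

The block-exchangeable model assumes the between-period correlation is the
same at every lag. The alternative discrete-time decay model
(`decay_components()`) lets cluster-period effects decay as
$\pi_D^{|t-s|}$ and a participant's errors as $\tau_D^{|t-s|}$, giving
cluster-period-mean covariance
$\sigma_{CP,D}^2 \pi_D^{|t-s|} + \frac{\sigma_{\epsilon D}^2}{m}
\tau_D^{|t-s|} (1 - \chi(t,s))$. Under in-for-$p$ rotation the participant
term vanishes entirely beyond lag $p$.

Autocorrelations estimated under a no-decay model absorb whatever decay the
data had and must not be plugged into the decay model directly.
`adjust_autocorrelation()` performs the moment-matching conversion: the
adjusted value $x$ solves
$\sum_{t}\sum_{s} x^{|t-s|} = a\,T(T-1) + T$, whose left side regroups to
$T + 2\sum_{d=1}^{T-1}(T-d)x^d$ — continuous and strictly increasing from
$T$ to $T^2$ on $[0,1]$, so a unique root always exists. The root is found
by bisection to an absolute tolerance of $10^{-10}$; bisection was chosen
over faster iterations because monotonicity makes it unconditionally
convergent, and the solve is a one-off scalar problem. Since decay
concentrates correlation at short lags, the adjusted lag-1 value always
exceeds the flat value (e.g. at $T = 4$, a flat 0.7 becomes 0.80 and a flat
0.9 becomes 0.94). The conversion is always an explicit, separately invoked
step — it is never applied silently, because users who estimated their
parameters under a decay model should input them unchanged.

## The simulator: what it emulates and what it does not

`simulate_trial()` generates individual-level data with membership realized
from the scheme: a fixed core plus fresh singletons (core group), repeated
simple random samples (closed population), a rotating panel of $p$ entry
cohorts (in-for-$p$), or a per-cluster Beta churn draw followed by the core
construction. Under the decay model each participant's error vector is
drawn over exactly the periods they are observed in, from the
corresponding submatrix of $\sigma_{\epsilon D}^2 \tau_D^{|t-s|}$.
`empirical_power()` collapses each replicate to cluster-period means,
applies the known-variance GLS estimator and reports the rejection
fraction with its binomial standard error. Replicate $j$ reseeds
deterministically with `seed + j`, so extending a run never changes earlier
replicates.

Numerical and realization choices worth knowing:

* Non-integer expected overlaps are realized with half-up rounding,
  $n = \lfloor m(1-\chi) + 0.5 \rfloor$; the analytic path always uses the
  real-valued $\chi$, so rounding affects simulation only. Monte Carlo
  checks are run at parameter values where the rounding is exact
  ($m\chi$ integral, $m$ divisible by $p$) so that the analytic covariance
  is also the exact realized covariance.
* When $m$ is not divisible by $p$, rotation cohort sizes are
  $\lfloor m/p \rfloor$ or $\lceil m/p \rceil$, the larger sizes assigned
  deterministically to the first $m \bmod p$ rotation positions; overlap
  counts come from the realized panels, not the ideal fractions.
* Covariance factors are taken by Cholesky with an eigenvalue fallback so
  the boundary cases $\pi_D = 1$ or $\tau_D = 1$ (singular but valid) still
  simulate.
* `gls_variance()` refuses covariance matrices with condition number above
  $10^{12}$ (`singular-covariance`) instead of returning noise, and designs
  with no treatment contrast signal `singular-design`.

The simulator emulates missing-completely-at-random flow of participants
with a constant cluster-period size. It does **not** emulate informative
dropout, participants migrating between clusters, cluster-size imbalance,
binary outcomes, or treatment effect heterogeneity — so agreement between
simulation and analysis supports the formulas under their own assumptions,
not robustness to violations of them.

Default verification problem sizes are chosen to give useful Monte Carlo
resolution at interactive cost: the worked three-sequence stepped wedge
(12 clusters, $T=4$, $m=10$) with 2000–3000 replicates puts the binomial
standard error near half a percentage point, and covariance checks pool
24,000 cluster draws; all stochastic assertions use 3-standard-error bands
under fixed seeds.

## Worked example

A stepped wedge in schools: three sequences, four periods, $m = 10$
students per school-period, $\sigma^2 = 25$, $\rho = 0.33$, $\pi = 0.9$,
$\tau = 0.7$, to detect a 2-unit mean difference at two-sided
$\alpha = 0.05$.

```{r example}
d <- stepped_wedge(3, clusters_per_sequence = 4, m = 10)
vc <- variance_components(25, rho = 0.33, pi = 0.9, tau = 0.7)

# closed cohort: both routes
V0 <- cov_matrix_block_exchangeable(vc, scheme_constant_churn(0), 10, 4)
c(gls = gls_power(d, V0, theta = 2), de = design_effect_power(d, vc, 0, 2))

# how many clusters per sequence for ~89% power?
clusters_required(stepped_wedge(3, m = 10), vc, chi = 0, theta = 2,
                  target_power = 0.893)

# power across core-group proportions and rotation schemes
power_curve(d, vc, "core_group", grid = c(0, 0.5, 1), theta = 2)
power_curve(d, vc, "in_for_p", theta = 2)
```

Power rises with the core-group proportion and with $p$, because more
repeated measurement lets the GLS estimator exploit within-participant
comparisons; yet no in-for-$p$ scheme reaches closed-cohort power while
$\tau > 0$, since a fraction of participants always contributes a single
measurement. The conservative planning choice under constant churn is
$\chi = 1$ (every participant measured once) — conservative in sample
size, though not necessarily in participant burden or ethics.

```{r mc}
# Monte Carlo confirmation at reduced scale
empirical_power(d, vc, scheme_constant_churn(0), theta = 2,
                replicates = 500, seed = 1)
```

## Limitations

The design-effect route requires churn constant across period pairs and
clusters; use the GLS route otherwise. Decays are geometric in discrete
period lags — continuous-time correlation structures are out of scope, as
are incomplete designs, transition periods, multi-arm comparisons, unequal
cluster-period sizes and non-continuous outcomes. Rotation schemes with
measurement gaps can be expressed through custom churn tables for the
analytic path but have no participant-level simulation.
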