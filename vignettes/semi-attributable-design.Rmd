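---
title: "Dose escalation with semi-attributable toxicity: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose escalation with semi-attributable toxicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satox)
```

# The trial setting

satox targets dual-agent phase I dose-escalation trials in which drug A is
administered at the start of a treatment cycle and drug B at a fixed later
time $t_B$, and *only* in patients with no dose-limiting toxicity (DLT)
before $t_B$. The cycle is observed over $[0, T]$ with $0 < t_B < T$
(`cycle_timing()`; default day 4 of a 7-day cycle). The timing splits each
patient's outcome into three categories: no DLT ($Y = 0$), a DLT before
drug B that is attributable to drug A alone ($Y = 1$, drug B withheld), and
a DLT after both drugs whose source is ambiguous ($Y = 2$). We call this
mixture *semi-attributable* (SA) toxicity. The comparator analysis
("non-attributable", NA) collapses $Y$ to the binary DLT indicator and
ignores both the timing and whether drug B was actually given — the
planned combination is analysed either way.

# Dose-toxicity model

The full-cycle DLT probability at combination $(a_j, b_k)$ on a $J \times
K$ grid is a Farlie–Gumbel–Morgenstern (FGM) copula over *skeleton*
probabilities $p_j, q_k$ — prior guesses of each dose's single-agent DLT
probability:

$$\pi_T(a_j, b_k) = 1 - (1 - p_j^\alpha)(1 - q_k^\beta) +
  p_j^\alpha(1 - p_j^\alpha)\, q_k^\beta (1 - q_k^\beta)\,
  \frac{e^\gamma - 1}{e^\gamma + 1}.$$

$\alpha, \beta \ge 0$ rescale the marginals ($\alpha < 1$: drug A more
toxic than its skeleton; $\alpha > 1$: less); $\gamma$ captures
antagonistic ($\gamma < 0$), independent ($\gamma = 0$) or synergistic
($\gamma > 0$) interaction. "Drug B absent" is represented as dose index
$k = 0$ with $q \equiv 0$, so $\pi_T(a_j, 0) = p_j^\alpha$ is a grid
evaluation rather than a special case. The pre-$t_B$ probability is linked
linearly by a fraction $\lambda \in [0, 1)$:

$$\pi_{t_B}(a_j) = \lambda\, \pi_T(a_j, 0) = \lambda\, p_j^\alpha,$$

giving the trinary outcome distribution $P(Y = 0) = 1 - \pi_T$,
$P(Y = 1) = \lambda p_j^\alpha$, $P(Y = 2) = \pi_T - \lambda p_j^\alpha$
(non-negative because $\lambda < 1$ and the surface is monotone). The
linearity is a simplifying assumption, not a law: `check_conditions()`
verifies numerically, over the configured grid, the six structural
conditions any sensible specification must satisfy (zero at dose zero,
monotonicity in each drug, and every full-cycle probability dominating the
pre-$t_B$ one). Failures are reported rather than raised, because for the
FGM family with strictly increasing skeletons they indicate a
misconfigured grid, and a batch simulation should not abort on a report.
The conditions are checked numerically only; we do not attempt a symbolic
proof over all $(\alpha, \beta, \gamma)$.

# Likelihoods, priors, posterior

Each patient contributes the probability of their observed category
(`loglik_sa()`), or of their binary indicator at the planned combination
(`loglik_na()`). Any outcome with non-positive model probability (e.g.
$Y = 1$ under $\lambda = 0$) makes the log-likelihood $-\infty$; empty
data contribute 0, so the posterior is then the prior.

Default priors (`prior_spec()`): $\alpha, \beta \sim U[0, 2]$ (prior
mean and median 1, centring the model on the skeletons),
$\gamma \sim N(0, 10)$ (variance scale — vague relative to the
$\tanh(\gamma/2)$ nonlinearity, which saturates beyond $|\gamma| \approx
6$), and for the SA model

$$\lambda \sim \mathrm{Beta}\!\left(\tfrac{t_B}{T - t_B},\, 1\right)
  \text{ if } t_B \ge T - t_B, \qquad
  \mathrm{Beta}\!\left(1,\, \tfrac{T - t_B}{t_B}\right) \text{ otherwise},$$

whose mean is exactly $t_B / T$ (0.571 for 4 of 7 days; median
$0.5^{3/4} \approx 0.595$) and which is invariant to the units of time.
$\lambda$ may instead be fixed (`lambda_mode = "fixed"`, default value
$t_B/T$); we default to estimating it, which reproduces the reference
early-trial fits.

## Posterior sampling

`sample_posterior()` runs an adaptive component-wise random-walk
Metropolis sampler written in C++. Bounded parameters are sampled on
transformed scales with Jacobians — $\alpha, \beta$ by a logit of their
position within the uniform support, $\lambda$ by a logit — so proposals
never leave the support; $\gamma$ is sampled untransformed. Step sizes
adapt every 50 burn-in iterations toward a per-component acceptance rate
of 0.44 and are frozen afterwards, keeping the post-burn-in chain a valid
Markov chain. Chains start at the prior medians jittered by seed-controlled
noise (SD 0.1 on the unconstrained scale); a non-finite starting density is
re-jittered up to 100 times before erroring. All randomness flows through
R's RNG, so a single `set.seed()` reproduces every draw.

Defaults mirror the reference computational set-up: 2 chains, 500 burn-in
iterations, 4000 retained draws per chain with thinning of 2.
`mcmc_control_reduced()` (1 chain, 250 burn-in, 1000 retained) is the
batch-simulation setting. A split-chain potential-scale-reduction
statistic is computed per parameter; values above 1.1 *warn* rather than
error — in a 1000-trial batch an occasional slow-mixing fit must be
logged, not fatal. The posterior of the *surface* is summarised by
`posterior_summary()`: each retained draw is pushed through the copula,
and the per-combination posterior median $\hat\pi_T(a_j, b_k)$ and the
exceedance probability $P(\pi_T(a_1, b_1) > \Gamma)$ (strict inequality)
are taken from those transformed draws.

## The quadrature oracle

`quadrature_posterior()` recomputes the same summaries deterministically:
midpoint tensor grids over $(\alpha, \beta, \gamma)$ (default 60 points
per dimension, $\gamma$ truncated at $\pm 6$ prior SD, i.e. $\pm 19$,
where the prior mass and the $\tanh$ response are both negligible) with
posterior weights $\propto$ prior $\times$ likelihood. $\lambda$ enters
the likelihood only through $\lambda p_j^\alpha$ terms, so it is handled
on a separate one-dimensional grid with per-patient $\pi_T$ arrays cached
— the cost is $O(\text{points}^3 \times n)$, fine for the early-trial
datasets it is meant for. Posterior medians are weighted medians with
linear interpolation of the cumulative distribution (mass centred on each
grid point), which removes the half-cell bias a raw weighted median has at
symmetric posteriors. Grids coarser than 10 points per dimension are
refused. In the test suite the oracle and the Metropolis sampler must
agree on the posterior-median surface to 0.02 in sup-norm on small
datasets; during development both were additionally validated against a
3-million-draw importance sampler.

# Decision rules

All rules operate on the posterior-median surface (`tox_summary`):

* **Next combination** (`select_next()`): the candidate minimising
  $|\hat\pi_T - \Gamma|$ among the 3×3 neighbourhood of the current
  combination (including the current combination itself — staying put must
  be possible, and the reference early-trial behaviour requires it). The
  neighbourhood constraint can be disabled (`neighbourhood = FALSE`).
* **Ties**: two candidates are tied when their distances differ by at most
  `tie_tolerance` (default $10^{-6}$ — exact floating-point ties are
  measure-zero, which would make the tie rules dead code). The SA design
  picks the smallest dose of drug A (minimising the chance of a pre-$t_B$
  DLT, hence maximising the chance the patient receives both drugs), then
  the smallest dose of drug B — the secondary tie-break is our choice, the
  conservative one. The NA design randomises with weight $1/n_{jk}$, the
  inverse of the number of patients already treated at each tied
  candidate; if any tied candidate is untried ($n_{jk} = 0$, infinite
  weight) the draw is uniform over the untried candidates only — the limit
  of the inverse-count rule.
* **Early stopping** (`should_stop()`): stop when
  $P(\pi_T(a_1, b_1) > \Gamma) > \tau$, strictly; exactly $\tau$
  continues. Under the default priors this threshold also trips after two
  DLTs in the first cohort of two, whatever their timing.
* **MTD set** (`recommend_mtd()`): at the patient limit, every
  combination with at least one patient treated and
  $|\hat\pi_T - \Gamma| \le \varepsilon$ is recommended. Near-target
  combinations never experimented on are excluded; the set may be empty
  ("no MTD").

Defaults: $\Gamma = 0.25$, $\tau = 0.80$, $\varepsilon = 0.025$ (a 5%
probability window), cohorts of 2, at most 60 patients.

# The trial simulator

A `scenario()` fixes the *true* generating probabilities as tables: a
$J \times K$ full-cycle matrix and a length-$J$ pre-$t_B$ vector. Truth is
table-driven rather than parameter-driven because published scenario
tables are the ground truth of record; scenario 1 additionally carries its
generating parameters $(\alpha, \beta, \gamma) = (1, 1, 0)$ for bias/RMSE
summaries, and `scenario_from_params()` builds parameter-generated
scenarios when wanted. The 19 packaged fixtures (`packaged_scenarios()`)
transcribe six published scenarios, each at true pre-$t_B$ fractions 2/14,
8/14 and 13/14 of the full-cycle single-agent probability, plus a
sensitivity scenario whose pre-$t_B$ probabilities (0.01, 0.06, 0.12,
0.22) are *not* proportional to the marginal — the simulator never assumes
proportionality, it just consumes the vector. Printed table values are
treated as exact at two decimal places. Construction validates the same
structural conditions as the model (monotone rows and columns, pre-$t_B$
dominated everywhere).

Each patient's outcome inverts a single uniform draw against the
cut-points $(\pi_{t_B}, \pi_T)$. All of a trial's outcome uniforms are
drawn up front from the trial seed, before any sampler randomness, so the
SA and NA analyses of the same seed observe identical outcomes wherever
their dose paths agree — enabling paired comparisons. Cohort patients are
exchangeable and complete the cycle before the next decision; there is no
staggered accrual. A failed posterior fit (after the sampler's retry
limit) marks the trial invalid; invalid trials are excluded from summaries
and counted. Batch seeds derive deterministically from
(`base_seed`, trial index), making results independent of the degree of
parallelism.

## Operating characteristics

`compute_oc()` reports, over a batch: the percentage of patients treated
at combinations whose true DLT probability falls in the bins $[0, 0.2]$,
$(0.2, 0.225]$, $(0.225, 0.275]$, $(0.275, 0.3]$, $(0.3, 0.4]$,
$(0.4, 1]$; the mean and SD across trials of the per-trial DLT rate
(early-stopped trials included — their few patients count); the mean and
SD of the percentage of a trial's DLTs occurring before $t_B$, over trials
with at least one DLT (the ratio is undefined otherwise, so zero-DLT
trials are excluded rather than imputed); the distribution of MTD
recommendations over the same bins; early-stop and no-MTD counts; the
mean number of MTD recommendations per trial *that did not stop early*
(the denominator is a documented choice — stopped trials yield no
estimates, consistent with the bias/RMSE convention); and, when the
scenario carries generating parameters, the mean bias and RMSE of the
end-of-trial posterior-median estimates over non-stopped trials.

# What the generator does and does not emulate

The simulator reproduces the cohort-wise adaptive design faithfully:
model-based escalation, neighbourhood constraint, early stopping, MTD
recommendation, and the withholding of drug B after a pre-$t_B$ DLT. It
does **not** emulate staggered accrual or waiting-time pressure,
between-cycle or late-onset DLTs, toxicity misattribution or
disease-related toxicity, patient covariates, or time-to-event outcome
structure — a real trial violating these simplifications can behave
differently, and passing simulations say nothing about them.

# Numerical choices and known limitations

* The interaction factor is computed as $\tanh(\gamma/2)$, which is
  algebraically $(e^\gamma - 1)/(e^\gamma + 1)$ but does not overflow for
  $|\gamma| > 700$ — the vague normal prior does propose such values.
* Probabilities are handled in double precision throughout; at grid sizes
  up to $10 \times 10$ no log-scale storage is needed. The trinary
  probabilities sum to 1 to $10^{-12}$ by construction, and the test suite
  asserts it across the prior.
* **Weak identifiability near the prior centre.** With binary data on a
  $4 \times 4$ grid, $(\alpha, \beta, \gamma)$ trade off: the exact
  (quadrature) posterior at $n = 200$ patients still has posterior-median
  spread of roughly $\pm 0.3$ for $\alpha$ when the truth sits near the
  prior centre, and the RMSE-versus-$n$ curve is nearly flat between
  $n = 60$ and $n = 200$. The parameter-recovery test therefore uses a
  truth well away from the prior centre (1.8, 0.4, 0.5), where prior
  shrinkage at small $n$ versus posterior concentration at large $n$ makes
  the expected RMSE decrease unambiguous. This is a property of the model
  and sample sizes, not of the sampler.
* **Sensitivity of the stop rate to sampler length.** The early-stopping
  rule thresholds a Monte-Carlo estimate; a trial stops the first time the
  estimate crosses $\tau$, so shorter chains (more MC noise) inflate the
  stop rate — with the reduced batch settings by roughly 4 percentage
  points on toxic scenarios relative to full-length chains. Batch
  summaries meant for comparison across designs should use identical MCMC
  settings on both arms.
* Simulation sizes in the shipped tests and acceptance script are
  deliberately modest (50–100 trials per scenario, reduced single-chain
  fits; full-length chains only for single-fit checks): they bound the
  Monte-Carlo error at a level the published reference values can be
  compared against, while a full-scale rerun (1000 trials, 2 chains,
  every scenario and design) uses the same code paths with larger
  settings.
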