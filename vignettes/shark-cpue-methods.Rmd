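---
title: "Modelling long-term shark control program catch rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling long-term shark control program catch rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sharktrend)
```

`sharktrend` analyses multi-decade catch records from beach-protection
(shark control) programs: nets and baited drumlines deployed at coastal
beaches, with every captured shark recorded. This vignette documents the
models, the priors and numerical choices behind them, what the synthetic
data generator does and does not emulate, and the limitations a user
should know about. It states no empirical results beyond what the
package's own tests and acceptance script compute.

## Data model and cleaning

A catch record is one shark: date, region, site (beach), gear (net,
drumline, or unknown), species group, optional species, total length (cm),
sex. Effort is recorded as gear-years per site, financial year and gear.
The annual time step is the July--June *financial year* (labelled by its
starting calendar year) because catches peak in the austral summer; a
January--December bin would split each summer across two steps.

Cleaning applies three rules, all auditable through the exclusion log:

* **Length plausibility.** Records whose total length exceeds the species'
  (or, for pre-speciation records, the group's) maximum recorded total
  length are excluded, as are lengths below a minimum plausible length
  (default 30 cm). The lower cutoff targets apparent imperial-unit entries
  — a 7-foot shark recorded as "7". There is no published rule for this
  heuristic, so the threshold is configuration and every exclusion is
  logged with its reason.
* **Missing lengths** are retained for count analyses and flagged
  (`length_valid`) out of size analyses. Records of unknown sex enter
  count models but not sex-stratified size or maturity models.
* **Unknown gear.** A small fraction of early records lacks the gear type.
  They are reassigned to net or drumline in proportion to the known-gear
  catch of the same group and region (net share
  `n_net / (n_net + n_drum)`). We read the "odds ratio" allocation this
  way because it is the only interpretation that yields a well-defined
  per-record assignment probability. The default deterministic mode uses
  largest-remainder apportionment (exactly proportional totals, ties to
  net, records assigned in input order), which makes bookkeeping tests
  exact; a seeded Bernoulli mode is available when assignment noise should
  propagate.

CPUE is `catch / effort` per site, year, gear and group. Cells with effort
and no catch are observations of zero, never gaps; catch recorded where no
effort exists is an error, not data.

## The CPUE trend model

Counts are negative binomial in the mean/size parameterization,
`Var(y) = mu + mu^2 / theta`, with

```
log mu = beta0 + beta_gear * drumline + u_region + v_site + f_t + log(effort)
```

The effort offset makes predictions catch-per-unit-effort. `u` and `v` are
iid normal random intercepts for region and site nested in region. The
temporal effect `f` is an intrinsic order-2 random walk: an improper
Gaussian prior on second differences whose null space contains constant
and linear series, so it smooths like a cubic spline without penalizing
the overall level or slope of the trend. Two variants are supported and
compared by WAIC: `regional_rw` (one trajectory per region, shared
smoothing precision) and `global_rw` (one shared trajectory plus additive
region effects).

### Priors

* RW2 standard deviation: penalized-complexity (exponential) prior with
  `P(sigma > 0.1) = 0.01`. The two published prior parameters are read as
  `(u, alpha)` in this tail condition — the natural reading of a PC prior
  for a standard deviation — and model comparison is insensitive to the
  choice across `(u, alpha)` in `{0.1, 1} x {0.01, 0.05}` (exercised in
  the test suite).
* Region and site standard deviations: PC prior with
  `P(sigma > 1) = 0.1`. On the log-mean scale, a standard deviation of 1
  is already a large between-site spread, so this is weakly informative.
* Fixed effects: normal with standard deviation 100 — effectively flat,
  which also makes the trajectory-level translation moves (below) exact.
* Dispersion `theta`: log-uniform on `[e^-7, e^9]`. A proper shrinking
  prior on `log(theta)` would pull the posterior down in the
  near-Poisson regime and break the package's low-overdispersion recovery
  checks; a bounded flat prior on the log scale is the vaguest choice
  that keeps the posterior proper. One `theta` is shared by all sites
  within a fitted model; the published analysis is silent on this, and a
  shared value matches fitting each species group separately.

### Identifiability

The intrinsic RW2 is invariant to adding constants, which confounds the
trajectory's level with the intercept (global variant) or the region
effects (regional variant). We impose the standard sum-to-zero constraint
through translation moves that shift a trajectory's mean into the
corresponding level parameter, accepted under the affected priors (exact,
since the RW2 density itself is shift-invariant). We deliberately do *not*
orthogonalize the trajectory against linear time: the model contains no
linear-year fixed effect, so the linear component of `f` *is* the trend —
removing it would delete the decline the model exists to estimate.

### Sampler

Inference is adaptive Metropolis-within-Gibbs, implemented in C++ and
driven by R's RNG so that `set.seed()` makes fits bit-reproducible.
Proposal scales adapt toward 0.44 acceptance by Robbins–Monro during
warmup only; the post-warmup chain is a fixed-kernel Markov chain. Beyond
single-site updates, three families of block moves handle the posterior's
slow directions:

* **Smooth-shape moves** along a centred linear ramp and the first eight
  DCT cosine modes of the trajectory. Single-site updates mix the
  high-frequency components of `f` well but are very slow in its
  low-frequency components, which carry most of the posterior variance of
  a smooth trend; the cosine moves fix this. The linear ramp lies in the
  RW2 null space (no prior term); for curved shapes the exact
  second-difference penalty change is computed.
* **Level swaps** between confounded intercept-like parameters
  (intercept/regions, region/its sites), which leave the likelihood
  untouched and are accepted on the priors alone.
* **A curvature rescale** that moves `log(sigma_f)` jointly with the
  non-linear component of the trajectory. For this move the RW2 prior
  change cancels exactly against the transformation Jacobian, leaving the
  PC prior and the likelihood — without it, `sigma_f` mixes an order of
  magnitude more slowly because it is tightly coupled to the realized
  curvature.

The convergence contract is split R-hat below 1.05 with effective sample
sizes reported per parameter; fits that miss it warn and carry
`converged = FALSE` rather than failing silently. Default settings are 4
chains of 3000 iterations (half warmup); the package's simulation studies
use 2 chains of 2000, which the pilot diagnostics support for those data
sizes.

### Derived quantities

* **Fitted CPUE trajectories** at one unit of effort for either gear, with
  random effects at their typical (zero) level, or at a named region's
  effect.
* **Percent decline** `100 (1 − mu_last / mu_first)` per posterior draw,
  evaluated on the fitted smooth's endpoint years by default. The
  endpoint-of-smooth convention (rather than a ratio of region-averaged
  predictions) is the package default; both are available through the
  `region` argument.
* **Annual zero-catch probability**: per draw and site,
  `prod_gears (theta / (theta + mu))^theta` at the site's actual effort
  that year, averaged over a region's active sites. Both the site-level
  and region-aggregated forms are returned, since "probability of catching
  no sharks at a given site" admits either reading.
* **WAIC** from the stored pointwise log-likelihood matrix,
  `-2 (lppd − p_waic)`.

## Serial depletion

Initial catch rate is the average CPUE over the first five financial years
after a gear's installation at a beach (financial years, consistent with
the rest of the analysis; shorter windows are used and flagged when the
program span ends first). The trend model is Poisson with the window's
summed catch as response and summed effort as offset,
`log mu = beta0 + beta1 (installation_year − year0) + u_region`, fitted
with the same MCMC machinery. Window *sums* rather than means of annual
ratios keep the response an integer with a valid offset; the descriptive
mean CPUE is carried alongside for plotting. Nets and drumlines are fitted
separately by default. The headline statistic is
`100 (1 − exp(beta1 * 35))` for the 1963→1998 comparison; negative values
are increases.

A calibration caveat that the acceptance suite makes explicit: when
catches are strongly overdispersed (the generator's default `theta = 2`),
the Poisson model's posterior intervals for `beta1` are overconfident —
a real property of fitting Poisson to negative-binomial data. The
null-slope coverage study therefore generates from the generator's
Poisson limit (`dispersion = 1e6`); under overdispersion the directional
conclusion (`beta1 < 0` under real decline) is robust but interval
calibration is not, and users analysing strongly overdispersed programs
should treat the depletion model's intervals as optimistic.

## Size and maturity

Size trends are linear mixed models of total length on financial year with
gear and sex fixed effects and site-in-region random intercepts, fitted by
REML through lme4; with a single site the model reduces to ordinary least
squares. Trends are fitted on individual records, not annual means — the
random-effect structure implies as much. Reporting conventions:
`10 (first − last) / span` cm per decade, and `100 (last − first) / first`
percent change. The year-slope Wald test carries the conventional
significance stars. Singular random-effect fits are reported, not hidden.

Maturity is classified against species- and sex-specific
length-at-maturity cutoffs supplied as a CSV (species, sex, cutoff_cm,
source). Cutoffs are configuration, not constants, because published
estimates differ among studies and regions; the table shipped under
`inst/extdata/` is synthetic and illustrative, as its name says. The
boundary is inclusive: length equal to the cutoff counts as mature (a
documented convention; the data are recorded to the nearest centimetre, so
the choice moves at most a hairline of records). The trend in
`P(mature)` is a binomial mixed model on the logit scale per species and
sex (matching sex-stratified reporting), with endpoint probabilities from
the fixed effects and a delta-method confidence band. Complete separation
is detected (degenerate slope or standard error) and reported.

## The synthetic program generator

The generator exists because real program data are restricted-access. It
produces catch and effort tables with exactly the structure the analysis
assumes:

* **Schedule**: regions with staggered beach installations (defaults
  spread installations evenly from the first program year to 1998 over a
  1962--2017 span), two gears with configurable per-beach effort.
* **Latent abundance**: per region and group, either a deterministic
  exponential decline `N_t = N_0 (1 − d)^(t − t0)` or a harvest-feedback
  recursion `N_{t+1} = max(0, N_t (1 − d) − c * catch_t)`. Both are
  exposed as scenarios because the true generating mechanism of decline
  (external fishing versus the program's own removals) is not knowable
  from these data; the default is the exponential scenario.
* **Catches**: `NegBin(q_gear,group * effort * N_t, theta)` per cell — the
  same family the trend model fits. Default catchabilities are anchored at
  the published 1962 catch rates (9.5 hammerheads per net-year, 0.25 per
  drumline-year, and so on), decline rates sized to the published
  long-term declines (92%, 82%, 74%, 92% over 55 years), and `theta = 2`,
  a moderate overdispersion consistent with count data of this kind.
* **Individuals**: capture dates uniform within the financial year, total
  lengths from a truncated normal whose mean drifts linearly (default
  tiger slope −1.04 cm/yr, i.e. 10.4 cm per decade), sex Bernoulli(0.5).
  Truncated normals are drawn by rejection (exact; bounds here are wide,
  so acceptance is high) with an exact inverse-CDF fallback for means far
  outside the bounds.
* **Corruption hooks**: a configurable fraction of records (default
  0.0241, the published unknown-gear fraction) has its gear relabelled
  unknown, and optionally lengths divided by 2.54 or 30.48 to mimic
  imperial-unit entries, so the cleaning rules are exercised end to end.

A fixed seed makes the output byte-identical across runs. What the
generator does *not* emulate — and what passing tests therefore do not
establish about real data: within-year seasonality and gear lifting,
species misidentification, spatial movement between beaches
(hyperdepletion/hyperstability arise only through the harvest-feedback
scenario, not through movement), environmental covariates, and
measurement bias such as the historical bounty incentive to exaggerate
sizes. Conclusions about those features need real data or a richer
simulator.

## Problem sizes and numerical choices

The package's simulation studies use sizes chosen to exercise the full
hierarchy while remaining comfortable on a single CPU: parameter recovery
on 4 regions x 3 sites x 40 years x 2 gears (960 observations per
replicate, 50 replicates, true endpoint decline 80%, `theta = 2`); WAIC
selection on 4 regions x 2 sites x 30 years with strongly divergent
regional trends (20 replicates); depletion studies on 2-region, 10-beach
programs. Convergence-sensitive defaults (4 chains x 3000 iterations) are
deliberately larger than what those studies need. Tie-breaks and
degenerate inputs are handled explicitly: largest-remainder ties go to
net; maturity at the cutoff is mature; effort-zero/catch-zero cells are
omitted while effort-zero/catch-positive is an error; single-region or
single-site fits drop the corresponding random effect rather than leaving
it unidentified; `decline_rate` outside `[0, 1)` and installations outside
the program span are configuration errors.

## Known limitations

* The sampler is exact but not gradient-based; for much larger programs
  (hundreds of sites) HMC or INLA-style approximations would be faster.
  The Metropolis design was chosen because it is implementable and
  auditable from first principles in this codebase.
* The Poisson depletion model inherits the calibration caveat above.
* The RW2 trajectory at years with no active sites is prior-interpolated;
  endpoint declines that lean on such years widen accordingly.
* Zero-catch probabilities condition on the recorded effort; they do not
  model effort choice, which in real programs responded to catch rates.
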