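---
title: "Quantifying personality and predictability in thermoregulatory behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying personality and predictability in thermoregulatory behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`thermopred` quantifies three layers of consistent behavioural variation in
repeated assays of individually housed ectotherms: behavioural type (an
individual's mean trait level), behavioural predictability (its residual
within-individual variability, rIIV), and behavioural syndromes
(between-individual correlations across traits). This vignette is the
package's own account of the models, the generator, the numerical choices,
and their limits.

## The traits and their derivation

Thermoregulatory behaviour is summarized per individual per assay day from a
series of body temperatures logged along a thermal gradient (22 readings at
30-minute intervals in the emulated design):

* **T_sel** — the day's median body temperature, the "goal" of
  thermoregulation;
* **T_set** — the width of the central 50% of readings (upper minus lower
  quartile), a thermoregulatory-precision measure (smaller = more precise);
* **T_Vmax** — the day's maximum, a proxy for voluntary thermal tolerance.

Quartiles use linear interpolation between order statistics
(`stats::quantile` type 7). That convention is recorded in the pipeline
configuration and pinned by tests against a brute-force
sort-and-interpolate oracle, because a different quantile rule changes
T_set by up to one inter-reading gap. A series shorter than four readings
has no defined quartiles and is rejected.

Classic behavioural traits come from one-hour videotaped trials: sheltering
(seconds hidden), movement activity (grid-square transitions per minute
while outside, `transitions / seconds outside * 60`, which makes the rate
independent of sheltering time) and risk-taking (latency to emerge after a
simulated predator attack). Two conventions the source material leaves open
are fixed here:

* **Log transform.** Sheltering and risk-taking are right-skewed latencies
  and are transformed as `log(x + 1)`; the `+1` guards zero durations and is
  monotone. Activity and the thermal traits are never log-transformed.
* **Censoring.** A lizard that never emerges within the trial carries the
  trial length (3600 s) as a right-censored latency, used as-is and flagged
  in a `risk_censored` column. With 36 x 5 trials and the calibrated latency
  distribution this affects a handful of rows at most; a survival-style
  treatment of the censoring is out of scope.
* **Undefined activity.** A trial with zero seconds outside and zero
  transitions has no defined activity rate and becomes a missing value; zero
  transitions with positive time outside is a true zero rate. A record
  claiming transitions without any time outside is internally inconsistent
  and rejected. (Elsewhere a shorthand describes the full-hour-sheltering
  case as zero activity; the missing-value rule is the one implemented,
  since a rate with a zero denominator is not a zero rate.)

State covariates: head size is the first principal component of a
correlation-matrix PCA on pileus length, pileus width and maximum head width
(sign fixed so all loadings are positive; the correlation matrix because the
measures differ in scale); relative head size and body condition are
ordinary least-squares residuals of the head PC and of body weight on
snout-vent length (raw scales, no transforms); parasite intensity is the
mean of three smear-scan counts per 1000 red blood cells. Responses and
continuous covariates are z-scored (sample SD), with the transform constants
retained so fitted intercepts can be mapped back to natural units.

## The double-hierarchical model

Each trait is modelled with paired location and dispersion submodels:

$$y_{ij} \sim \mathcal N(\mu_{ij}, \sigma_{ij}), \qquad
\mu_{ij} = \beta_0 + x_{ij}^\top\beta + a_i + b_i t_j, \qquad
\log \sigma_{ij} = \gamma_0 + x_{ij}^\top\gamma + w_i,$$

where $t_j$ is the z-scored assay-day index and $(a_i, b_i, w_i)$ — the
individual's mean intercept, habituation slope and log-dispersion intercept
— are jointly trivariate normal with SDs $(\mathrm{sd}_a, \mathrm{sd}_b,
\omega)$ and a full 3x3 correlation matrix. The covariates (SVL, relative
head size, condition, parasite intensity, and parasite x size interactions)
enter both submodels; time enters the mean submodel only, in both fixed
(group-level habituation) and random (individual habituation) form. Priors:
N(0,1) on all fixed effects, half-N(0,1) on the three SDs, LKJ(1) — i.e.
uniform over positive-definite correlation matrices — on the random-effect
correlations. Covariates are grand-standardized, not group-mean-centred;
with one value per individual the distinction is immaterial for the state
covariates.

Two model variants are exposed deliberately: the full covariate set above,
and an intercept-plus-time variant (`covariates = character(0)`), because
reported repeatabilities in this literature often come from the leaner
model and the two differ through what the fixed effects absorb.

### Sampler

The posterior is explored by an adaptive scalar Metropolis-within-Gibbs
sampler (C++), built around a non-centred parameterization
$(a_i,b_i,w_i) = \mathrm{diag}(s)\,L z_i$ with $z_i \sim \mathcal N(0, I)$
and $L$ the correlation Cholesky factor — the standard remedy for the funnel
geometry at small SDs. Three ingredients matter for mixing and are tested
via prior recovery (an empty-data run must reproduce the half-normal and
LKJ prior moments exactly):

1. the mean-model fixed effects are drawn exactly from their conjugate
   conditional (a heteroscedastic-weighted normal regression);
2. interweaved, likelihood-invariant "sweep" moves translate mass between
   each intercept and its random-effect column, rescale each SD against its
   latent column, and re-draw each correlation against the latents, with
   the appropriate Jacobian terms — these are ancillary-sufficient
   interweaving moves, and they are what lets a random-walk sampler match
   the effective sample sizes a gradient-based sampler would reach;
3. step sizes adapt per scalar coordinate during warmup only
   (Robbins-Monro towards 44% acceptance), keeping the post-warmup chain a
   fixed-kernel Markov chain.

Default run lengths: `scale = "paper"` mirrors the reference analysis (4
chains x 5000 iterations, 1000 warmup, thinning 4; 4000 kept draws);
`scale = "desk"` keeps the same 4000 draws from longer, more thinned chains
(4 x 20000/5000/15), which this sampler needs to clear the convergence bar
on routine runs, at roughly 3-6 s per trait on one core. Convergence is
never assumed: every fit attaches split-chain R-hat and effective sample
sizes per parameter with the pass thresholds R-hat < 1.01 and ESS > 400,
warns loudly on failure, and the pipeline propagates failing traits as
flagged entries rather than dropping them.

Intervals are 95% highest-posterior-density intervals (shortest window over
sorted draws, exhaustive scan); a parameter is reported "different from
zero" exactly when its HPD interval excludes zero. The multivariate module
(below) uses quantile intervals instead, the convention of that model
family; both are labelled where they appear.

## Derived statistics

All derived statistics are computed per posterior draw and then summarized;
plug-in values at posterior means differ by a Jensen gap, which is why a
plug-in reader of a results table can land one or two hundredths away from
a per-draw value (e.g. plug-in CV_P 0.645 rounding to 0.65 where a per-draw
summary printed 0.64; and 0.45 vs a printed 0.46 for the thermal preference
trait). The package reports per-draw summaries and documents the gap here.

* **Adjusted repeatability** $R = \mathrm{sd}_a^2 / (\mathrm{sd}_a^2 +
  \exp(\gamma_0)^2)$: the dispersion intercept is the log residual SD of a
  population-typical individual with covariates at their means, so it is
  exponentiated and squared to become a variance. V_residual deliberately
  uses $\gamma_0$ alone, not the covariate terms.
* **Coefficient of predictability** $CV_P = \sqrt{\exp(\omega^2) - 1}$: the
  coefficient of variation of individual residual SDs implied by a
  lognormal dispersion random effect with log-scale SD $\omega$. The
  stored parameter is the SD $\omega$ (some reporting conventions label the
  same quantity with a squared symbol; numerically it must enter this
  formula as the SD).
* **Type-predictability correlation**: the posterior of the $(a_i, w_i)$
  correlation. Low rIIV means high predictability, so a negative value
  links high trait means with high predictability.
* **Per-individual rIIV** $\exp(\gamma_0 + w_i)$, the residual SD on the
  response scale at the typical covariate profile.

## The multivariate syndrome model

The six z-scored traits are stacked into $y_{ij} = \mu + u_i + e_{ij}$ with
$u_i \sim \mathrm{MVN}(0, \Sigma_B)$, $e_{ij} \sim \mathrm{MVN}(0,
\Sigma_W)$, fitted by a blocked Gibbs sampler: conjugate multivariate-normal
draws for $\mu$ and the $u_i$, inverse-Wishart draws for both covariance
matrices (identity scale, degrees of freedom = traits + 1, the minimal
proper choice that leaves prior correlations marginally uniform), and a
conditional-normal data-augmentation step for missing trait entries. Per
draw, both matrices are converted to correlations; a between-individual
interval excluding zero is the syndrome criterion. No fixed-effect
covariates enter this stage.

The assay design makes the missingness structural: thermal traits exist on
the six thermal days, behavioural traits on the five interleaved trial
days, never together. Each calendar day is one occasion row with the
unmeasured block missing, so **within**-individual correlations across the
thermal/behavioural divide are informed only indirectly through the
augmentation step and should be read with corresponding caution;
**between**-individual correlations (the syndrome level) are identified by
individual means and are robust to the interleaving. Default run length is
20,000 iterations, 5,000 burn-in, thinning 15 (about 1,000 kept draws,
matching the kept-draw count of the reference analysis's much longer run,
which remains available as `scale = "paper"`).

## The synthetic-data generator

The generator is first-class, tested code; it emulates the study design —
36 adult males, 6 thermal days x 22 readings, 5 behavioural days, the
printed covariate distributions (SVL 5.2 +/- 0.63 cm, weight 4.39 +/- 0.67
g, parasite intensity 4.75 +/- 4.34 per 1000 red blood cells at 80.6%
prevalence) — and the generative structure the models assume, with the reported
posterior means as default truth on the standardized scale.

Choices where the source design is silent, fixed once and recorded here:

* **Within-day temperature law.** Readings are normal around the day's
  T_sel target with SD = T_set target / 1.349 (so the central-50% width
  matches), truncated to the attainable gradient range [23, 60] C. A
  two-parameter law cannot also hit the reported mean daily maximum (the
  expected maximum of 22 such draws sits about 1.1 C below it), so the
  day's peak is drawn from its own T_Vmax trait model and the body readings
  are capped at it; the derived daily maximum then equals the generating
  peak exactly, which is also what makes the generator-to-derivation round
  trip a sharp test. The stated round-trip tolerance for T_sel is the
  sampling SE of a day median, `1.2533 * sigma_day / sqrt(21)`.
* **Natural-scale calibration.** The standardized models are mapped to
  natural units with location/scale pairs chosen from the reported
  descriptive statistics: T_sel 32.22/1.25 C, T_set 4.49/1.05 C, T_Vmax
  39.73/1.15 C, activity 6.84/1.8 per minute, sheltering 3.27/1.35 and
  risk-taking 4.84/0.9 on the log1p-seconds scale. The log-scale means
  carry the lognormal $-\sigma^2/2$ correction so the *arithmetic* means of
  raw seconds land on the reported 75.4 s and 195.6 s; the scales are set
  so simulated individual means span the reported ranges (e.g. T_sel means
  across 29.7-33.5 C).
* **Activity ambiguity.** The trait is the per-minute rate formula; the
  reported mean of 6.84 is treated as that rate. Taken jointly with ~75 s
  of sheltering this implies several hundred raw transitions per hour —
  the two printed statements (a rate formula and a "number of transitions"
  mean) cannot both be literal, and the rate reading is the one consistent
  with the trait definition. Transition counts are Poisson with rate
  `activity x minutes outside`, giving the derived rate its natural
  sampling noise.
* **Parasites.** Infection is Bernoulli(0.806); intensity for infected
  individuals is lognormal, moment-matched so the zero-inflated mixture
  reproduces the printed overall mean and SD (an SD near the mean implies
  right skew); the three smear scans are Poisson around the individual's
  intensity.
* **Seeds.** One master seed; per-stage streams are drawn deterministically
  from it, so identical configurations are bit-identical end to end.

What the generator does **not** emulate: time-of-day structure within the
3-h recording blocks (groups were randomized in the emulated design),
spatially explicit gradient physics, behavioural observation error beyond
the Poisson transition counts, and any covariate effect on behaviour
(default fixed-effect truths are zero apart from the time trends, matching
the reported near-null covariate results). Passing recovery tests therefore
demonstrate that the estimators are correct under the assumed generative
model at the study's size — not that real lizard data meet those
assumptions.

## Numerical conventions and degenerate inputs

* Quantile type 7 everywhere; recorded in `pipeline_config()`.
* Exactly singular random-effect correlation inputs get a 1e-8 ridge only
  for factorization; non-PSD inputs are rejected with the offending matrix
  named.
* Log-SD coordinates are hard-bounded at |log sd| <= 12 to keep proposals
  finite; non-finite likelihood evaluations reject the proposal rather than
  being clipped.
* Posterior draws with a zero diagonal variance are dropped from the
  correlation decomposition with a logged count; more than 1% rejections
  aborts the decomposition.
* Rows with missing response or covariates are dropped per response with a
  reported count; an occasion row with every trait missing is dropped from
  the multivariate stage; a trait with no repeated measures on any
  individual is rejected by name (its within-individual variance is
  unidentifiable).
* HPD intervals need at least 100 draws; fewer draws yield an error, never
  a quietly widened interval.

## Problem sizes in routine runs

Routine runs and the test suite use the desk presets: 4 x 20000/5000/15 for
the per-trait models (3-6 s per trait), 20000/5000/15 for the multivariate
model (about 15 s for six traits at the study size), parameter-recovery
checks at the study's own 36 x 6 size over 20 replicates, and
moment-recovery checks at 10^4 simulated individuals. The reference
analysis's longer settings remain one flag away (`scale = "paper"`).

## Known limitations

* Risk-taking censoring is handled by value substitution, not a censored
  likelihood.
* Within-individual cross-block correlations are weakly identified under
  the interleaved design (above); the package reports them but they carry
  little information at the study size.
* The dispersion submodel assumes lognormal individual residual SDs; CV_P
  inherits that assumption.
* Single-trait models treat traits independently; the multivariate stage
  has no location-scale structure (no per-trait dispersion random effects),
  mirroring the two-stage design of the reference analysis.
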