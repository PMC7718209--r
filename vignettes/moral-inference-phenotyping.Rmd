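---
title: "Computational phenotyping of moral inference: models, design choices, and what the synthetic cohort can show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computational phenotyping of moral inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moralinfer)
```

## The task and the inference problem

In the moral inference task an observer watches two agents repeatedly
choose between a *harmful* option (more money, more painful shocks
delivered to a third person) and a *helpful* option (less money, fewer
shocks). Each agent is characterized by a harm-aversion exchange rate
$\kappa \in [0,1]$ — how much money they require per shock — and a choice
consistency $\beta \ge 0$. With money and shock differences $\Delta m,
\Delta s$ rescaled by their task-wide maxima, the agent chooses the
harmful option with probability

$$P(\text{harmful}) = \mathrm{logistic}\big(\beta\,[(1-\kappa)\Delta m -
\kappa \Delta s]\big).$$

The rescaling makes $\kappa$ unitless and comparable across trial sets:
$\kappa = 0.5$ is indifferent exactly when the rescaled money and shock
differences are equal. The "good" agent has higher $\kappa$ (default 0.7)
than the "bad" agent (default 0.3); $\beta$ defaults to 6, which gives a
clear but noisy separation between the two agents' choices. Trial counts,
magnitudes and block structure are configuration parameters (defaults: 50
trials per agent, sequential agent blocks with independent beliefs) since
we treat them as properties of a task variant, not of the model.

Observers predict each choice before seeing it, and every third trial rate
their impression of the agent (0 = nasty to 100 = nice) and the certainty
of that impression (0 to 1). A pre-task probe records prior expectations
and prior confidence before any choice is observed.

## The dynamic-learning-rate model

The learner holds a discretized belief over $\kappa$ on a regular grid of
$G = 101$ points in $[0,1]$ (oracle tests use tiny grids). The prior is a
truncated Gaussian with mean $\mu_0$ and spread $\sigma_0$ — the minimal
two-parameter family that matches the task's pre-task probes of prior
expectation and prior confidence. After observing a choice the belief is
updated by Bayes' rule under the logistic choice likelihood, followed by a
uniform *leak* with weight $\lambda$:

$$m''(\kappa_g) = (1-\lambda)\,\frac{m(\kappa_g) L(\text{choice} \mid
\kappa_g)}{\sum_h m(\kappa_h) L(\text{choice} \mid \kappa_h)} +
\frac{\lambda}{G}.$$

The trialwise *dynamic learning rate* is the Rescorla–Wagner gain implied
by the belief-mean update,

$$\alpha_t = \frac{|\mu_{t} - \mu_{t-1}|}{|\delta_t|}, \qquad
\delta_t = \text{choice}_t - p^{\text{pred}}_t,$$

defined as 0 when $|\delta_t|$ is numerically zero. Because Bayesian
updates scale with prior imprecision, $\alpha_t$ increases strictly with
the prior spread when everything else is held fixed — the mechanism that
links belief uncertainty to updating speed, and the package's central
property (it is verified both trial-by-trial against an independent
brute-force Bayes loop and as a monotonicity sweep over $\sigma_0$).

Two comparison models update a *point estimate* $\hat\kappa$ instead of a
distribution: a single fixed rate $\hat\kappa \leftarrow
\mathrm{clip}_{[0,1]}(\hat\kappa - \alpha\,\delta_t)$, and a valenced
variant applying $\alpha_-$ after harmful and $\alpha_+$ after helpful
observations. With $\alpha_- = \alpha_+$ the valenced model reproduces the
single-rate model exactly (a nesting identity the tests exploit). We chose
point-estimate dynamics for these alternatives because they are the
minimal fixed-gain counterparts of the Bayesian learner and keep all three
models' rates on the same probability-space footing.

## Fitting, and where the information actually is

Participants' trialwise predictions are modelled as Bernoulli draws from
$q_t = (1 - 2\ell)\,p^{\text{pred}}_t + \ell$ with a lapse asymptote
$\ell = 0.02$ (fixed, not fitted; it bounds the log-likelihood when a
deterministic model disagrees with a prediction). Fits are per participant
— there is deliberately no population-level prior — by bounded multi-start
`nlminb` (bounds: means in $[0.01, 0.99]$, spreads in $[0.01, 1]$, rates
in $[0,1]$, $\beta \in [0.1, 20]$), deterministic given the seed. Model
evidence is approximated as $-\mathrm{BIC}/2$, which is cheap and
sufficient for random-effects selection.

Two fitting decisions deserve emphasis because they were forced by
measurement properties of the task, not taste:

**The agents' consistency is fixed, not fitted, in the cohort analyses.**
The agents' decision noise is a design property of the task (the
experimenter programs it), so the cohort pipeline fixes $\beta$ at the
generative value 6 and fits the prior parameters (`fit_beta = TRUE`
remains available). This also makes per-agent fits separable and fast.

**Binary predictions barely identify the prior spread; the rating streams
do.** Profiling the prediction likelihood over $\sigma_0$ at realistic
task length (50 trials per agent) moves it by well under one log-unit
across the whole admissible range: after the first few trials the
posterior is data-dominated and all spreads predict alike. Recovery of a
per-agent $\sigma_0$ from predictions alone is therefore near chance. The
task, however, *directly* probes the belief trajectory: impressions read
out the belief mean (scaled to 0–100) and certainties read out
$1 - \sigma/0.5$ (0.5 being the largest possible SD on $[0,1]$), with the
pre-task probe reading out the prior itself. `fit_participant(...,
use_ratings = TRUE)` augments the prediction likelihood with Gaussian
terms for these streams (noise SD 0.05 on the unit scale, matching the
generator). The recovery study in the test suite (50 participants, 50
trials per agent) holds the truth-vs-fit correlation for both prior
parameters above 0.7 with the rating likelihood; prediction-only fits
fall well short of that bar for the prior spread. Model *selection*
remains prediction-only — the point-estimate
models carry no belief spread, so a rating likelihood would be undefined
for them and the comparison unfair.

A related choice: with two agents and one shared prior, the two opposing
evidence streams pin down the prior jointly; the `shared_mean` scheme (one
$\mu_0$, per-agent $\sigma_0$) extends this to the cohort analyses, and
`per_agent` frees both parameters when ratings make them identifiable.

## The leak parameter

The leak keeps uncertainty bounded away from zero over long runs, which
sustains nonzero learning rates and certainty dynamics late in the task.
Its magnitude trades off memory for adaptability: at $\lambda = 0.1$ the
prior's influence decays within roughly ten trials, which erases exactly
the prior-driven group differences the cohort profiles encode. The
package therefore defaults the *cohort* leak to $\lambda = 0.02$, which
retains prior-driven asymmetries across a 50-trial session while still
preventing belief collapse; recovery studies that probe pure Bayesian
identifiability run at $\lambda = 0$. All three values are a single
argument away.

## The synthetic cohort: what it emulates and what it does not

No participant data are distributed with the task, so the package
generates cohorts with the structure the analysis assumes: three groups
(untreated borderline personality disorder, $n = 20$; screened controls,
$n = 106$; patients treated in a democratic therapeutic community,
$n = 23$), matched task variants (each patient's trial-and-choice sequence
is shared by five matched controls), pre-task probes, every-third-trial
ratings, a screening score for controls (generated below the exclusion
threshold of 6, i.e. the generator emulates the *post-screen* sample; the
`msi_screen` operation applies the threshold to raw tables), a symptom
severity score for the patient groups (means 41.4 and 26.9, SDs 8.8 and
9.4), and a medication flag (9/20 and 11/23).

The group profiles encode the phenotype generatively, with magnitudes
chosen once to give the qualitative pattern at moderate effect size
(population values are unpublished): controls hold more uncertain beliefs
about the bad agent than the good one ($\sigma_0$: 0.30 vs 0.15); the
untreated patient profile reverses that asymmetry (0.18 vs 0.22) and is
pessimistic in its prior mean (0.40 vs 0.50); the treated profile matches
the untreated one except that bad-agent uncertainty is restored (0.28),
leaving prior pessimism in place. Between-participant SDs are 0.05 on both
parameters; predictions are sampled from the learner's own probabilities
(probability matching) so that likelihoods remain informative.

What the generator does **not** emulate: questionnaire item responses
(only scalar scores), dropout or missing ratings, reaction times,
within-session motivation drift, or any dependence of the leak, lapse or
consistency on group. Passing the end-to-end checks therefore shows that
the pipeline detects the encoded phenotype when the generating model is
the fitted model — a software and identifiability guarantee, not evidence
about real patients.

## The statistical layer

Group analyses mirror standard practice for this design: learning rates
are standardized across the full analysis sample (preserving between-group
differences), certainty is reverse-scored to uncertainty, and each measure
is regressed on agent, group, their interaction and trial number by
iteratively reweighted least squares with Tukey bisquare weights (tuning
constant 4.685, scale from the median absolute deviation — the standard
95%-efficiency configuration, via `MASS::rlm`). Dummy coding uses a
configurable reference group; the phenotype report fits both the
untreated-patient and the control reference so that each headline contrast
is read off directly. Observations enter as repeated trialwise rows with a
trial covariate by default; per-participant aggregation is a flag, and it
is the configuration used for type-I calibration, because repeated
within-participant rows are correlated by construction and the trialwise
variant is anticonservative for between-participant effects. Rank-sum
tests (pre-task expectation comparisons) use midranks, an exact null
distribution for small tie-free samples and a tie- and
continuity-corrected normal approximation otherwise, reporting the z
statistic alongside. Pearson's chi-square (no continuity correction)
compares best-model proportions across groups. p-values are uncorrected,
matching the convention for this analysis style. Degenerate cases are
defined, not crashed: zero residual scale returns the least-squares fit
with unit weights, fully tied rank-sum samples return $z = 0, p = 1$, and
an empty best-model class makes the proportion test undefined (reported as
absent).

Random-effects model selection follows the variational Dirichlet scheme:
responsibilities proportional to $\exp(\text{log evidence} +
\psi(\alpha_k) - \psi(\sum \alpha))$, $\alpha = \alpha_0 + \sum_n g_{nk}$,
iterated to $10^{-6}$ with $\alpha_0 = 1$; exceedance probabilities come
from $10^6$ Monte Carlo Dirichlet draws. Best-model ties break toward the
dynamic model, then lexicographically, so tallies are deterministic.

## Problem sizes and numerical choices

The shipped validation suite uses: grids $G \le 5$ with $T \le 10$ against
the brute-force oracle (tolerance $10^{-12}$); $10^4$ randomized updates
for normalization ($10^{-10}$); 50 participants at 100 predictions each
for parameter recovery; 30 participants and two seeds for model recovery;
the full 149-participant cohort on three seeds for the end-to-end
phenotype checks; and 200 reduced cohorts (three groups of 12, 20 trials
per agent, grid 51) for null calibration of the interaction test. These
sizes were chosen to exercise every stage at full fidelity where it is
cheap and at reduced-but-representative scale where it is not.

Numerical details worth knowing: prior densities are evaluated in log
space and shifted by their maximum before exponentiation, so very tight
priors far from grid points do not underflow; the logistic likelihood is
strictly positive, so the posterior cannot vanish on the whole grid;
learning rates are defined as 0 when $|\delta| < 10^{-12}$; optimizer
restarts draw uniformly within bounds from a participant-specific seed,
making every fit bit-reproducible.

## Known limitations

Per-participant, per-agent prior spreads are not identifiable from
predictions alone at realistic task lengths — any analysis of this design
that claims otherwise should be treated with suspicion — hence the rating
likelihood described above. The $-\mathrm{BIC}/2$ evidence approximation
ignores posterior curvature differences between models of equal parameter
count. The robust regressions treat trialwise rows as independent; the
aggregation flag exists precisely because that assumption fails
within participants. And the synthetic phenotype is a sign-level target:
the generative magnitudes are calibration constants, so coefficient sizes
from synthetic cohorts should never be compared numerically to empirical
ones.

## A minimal session

```{r example, eval = FALSE}
library(moralinfer)

cfg <- default_config()
cfg$seed <- 7
cohort <- simulate_cohort(seed = cfg$seed)
fits <- fit_cohort(cohort, models = "dynamic", config = cfg)
res <- pipeline_analyze(cohort, fits, cfg, out_dir = "results")
print(res$report)
```
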