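---
title: "How initial expectations shadow learning asymmetry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How initial expectations shadow learning asymmetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(qshadow)
```

# The model

`qshadow` is built around the asymmetric Q-learning model of two-armed
bandit choice. Each option carries a value $Q$; after the chosen option's
outcome $r_t$ is observed, only that option's value is updated:

$$
Q_{t+1} = \begin{cases}
Q_t + \alpha_P\,(r_t - Q_t) & \text{if } r_t - Q_t \ge 0\\[2pt]
Q_t + \alpha_N\,(r_t - Q_t) & \text{otherwise,}
\end{cases}
$$

and choices follow a softmax on the value difference,
$p(\text{left}) = 1/(1 + e^{-\beta (Q_L - Q_R)})$. The tie case
$r_t - Q_t = 0$ takes the positive branch (the update is zero either way,
but the convention matters for exact-equality tests).

**Outcome coding.** Outcomes are coded on a unit scale: +10 points
$\to$ +1, nothing $\to$ 0, −10 points $\to$ −1. This is the only coding
under which the initial-expectation bounds ("between the worst and the best
outcome": $[0,1]$ in gain, $[-1,0]$ in loss, $[-1,1]$ in mixed) and the
signs of the mean-outcome fixed values (+0.5 gain, −0.5 loss, 0 mixed) are
mutually consistent, and it is the coding the package uses throughout. In
the loss condition the *reinforced* event — the one occurring with the
scheduled probability — is the −10 outcome, so a "75%" loss option is a bad
option.

**Initial expectation.** Every option starts at $Q_0$, one value per
subject per condition, shared by both options. In the stable mini-block
task both options re-initialize to $Q_0$ at each mini-block start, because
each mini-block introduces novel cues; in the single-block random-walk task
$Q_0$ applies once at trial 1. Within a condition the same $Q_0$ is shared
across mini-blocks: the mini-blocks differ only in cue identity, so a
common prior expectation is the parsimonious reading, and it is what the
fitting layer estimates.

**Variants.** Four variants cross asymmetric vs symmetric learning rates
with free vs fixed $Q_0$: A-VI (the full model), A-FI ($Q_0$ pinned at the
condition's mean outcome), S-VI ($\alpha_P=\alpha_N$, free $Q_0$) and S-FI.
Two primed variants (A-FI′, S-FI′) pin $Q_0 = 0$ in every condition.

# Parameters, bounds and transforms

| parameter | meaning | bounds | transform |
|---|---|---|---|
| $Q_0$ | initial expectation (outcome units) | condition's outcome range | $\theta_{min} + \Phi(\theta')(\theta_{max}-\theta_{min})$ |
| $\alpha_P$ | learning rate, positive PEs | $[0,1]$ | $\Phi(\alpha_P')$ |
| $\alpha_N$ | learning rate, negative PEs | $[0,1]$ | $\Phi(\alpha_P' + \delta)$ |
| $\beta$ | softmax inverse temperature | $[0,20]$ | $20\,\Phi(\beta')$ |

$\Phi$ is the standard normal CDF. The negative rate is parameterized
through the unbounded offset $\delta$ added to $\alpha_P'$, so the group
mean of $\delta$ ($\mu_\delta$) directly measures the learning asymmetry:
$\mu_\delta > 0$ means $\alpha_N > \alpha_P$ (pessimistic learning). This
offset is distinct from the prediction error $\delta_t$.

Each subject's unbounded parameters are drawn from group-level normal
distributions, $\theta'_i \sim N(\mu_{\theta'}, \sigma_{\theta'})$, with
priors $\mu_{\theta'} \sim N(0, 2)$ and
$\sigma_{\theta'} \sim \text{half-Cauchy}(0, 5)$. The "2" in the
hyper-mean prior is read as a standard deviation (the usual convention for
this notation in the cognitive-modeling literature); it is configurable via
`fit_config(mu_prior_sd =)` should a variance reading be preferred. All
conditions are fitted separately. $\beta$ is pooled hierarchically in every
variant.

# Posterior sampling

`sample_posterior()` draws from the joint posterior with an adaptive
Metropolis-within-Gibbs scheme implemented in compiled code:

- componentwise Gaussian random-walk proposals on each subject's unbounded
  parameters, with the subject's likelihood cached between component
  updates;
- an anti-correlated pair proposal on $(\alpha_P', \delta)$ — shifting one
  up and the other down leaves $\alpha_N$ nearly unchanged, the soft
  direction of the asymmetric likelihood;
- conjugate Gibbs updates for the hyper means;
- log-scale Metropolis updates for the hyper standard deviations;
- two *group moves* per parameter: a joint translation of the hyper mean
  together with every subject's value, and a joint rescaling of the hyper
  sd together with every subject's offset from the mean. These interweaved
  moves are what break the funnel that otherwise traps centered
  hierarchical samplers when the group heterogeneity is small (exactly the
  situation of the recovery grid, whose simulated subjects share
  parameters).

All proposal scales adapt toward 44% acceptance during warmup only
(Robbins–Monro with gain $t^{-0.6}$), so the retained draws come from a
fixed-kernel, valid Markov chain. Chains run sequentially from
`fit_config()$seed`, making every fit bit-reproducible.

Three profiles set the chain geometry: `"paper"` (4 chains × 4000 warmup ×
6000 kept = 24,000 retained draws per parameter, the package default),
`"reduced"` (4 × 1000/1500) and `"test"` (2 × 1000/1000), the profile used
by the test suite and the acceptance script. Convergence is monitored by
split-$\hat R$ (warning threshold 1.05 by default) and a
Geyer-initial-positive-sequence effective sample size.

**Validation strategy.** The sampler is checked three ways: (1) the target
density it samples is exposed as `joint_log_density()` and verified
term-by-term against an independent computation; (2) the identical
hierarchy with a Gaussian data term — where the subject level integrates
out analytically — is sampled and compared against two-dimensional
numerical quadrature for the hyper-mean posterior mean and sd and the
subject-level shrinkage means; (3) self-recovery on simulated Q-learning
data. Point estimates are 10% trimmed means, dropping
$\lfloor 0.1 n \rfloor$ draws from each tail (the rounding rule is the one
ambiguity in the definition; floor was chosen and is tested).

# Model comparison

DIC is computed per fit as $\bar D + p_D$ with
$p_D = \bar D - D(\hat\theta)$, where $\bar D$ averages the total deviance
over retained draws and $D(\hat\theta)$ plugs in each subject's
trimmed-mean natural-scale parameters. The decomposition is additive over
subjects, and the subject-level evidence proxy feeding the group-level
model selection is $-\mathrm{DIC}_i / 2$. How a hierarchical DIC should be
converted into subject-wise evidence is genuinely under-determined; this
proxy is one defensible choice and is isolated behind the evidence-matrix
contract of `group_bms()`, so it can be swapped without touching the
selection machinery.

`group_bms()` implements random-effects Bayesian model selection: a
variational Dirichlet posterior over model frequencies, exceedance
probabilities by Monte-Carlo Dirichlet draws (default $10^6$), the Bayes
omnibus risk (BOR) from the free-energy comparison against the
equal-frequency null (whose evidence is exact), and
$\mathrm{PXP} = \mathrm{EP}\,(1-\mathrm{BOR}) + \mathrm{BOR}/K$.

# Task schedules and the synthetic-data generator

The generator is the package's stand-in for raw behavioral data, and its
defaults are the study conditions themselves:

- **Stable task:** four mini-blocks with probability pairs 40/60, 25/75,
  25/25 and 75/75 (%), 32 trials each, block order randomly permuted per
  subject.
- **Random-walk task:** 100 trials per condition; each option's
  reinforcement probability starts from Uniform(0.25, 0.75) and moves
  ±0.05 equiprobably and independently each trial, reflecting off the
  boundaries as $p' = 2b - p$ (a value exactly on a boundary is legal and
  unreflected).
- **Recovery grid:** $Q_0 \in \{0, 0.25, 0.5, 0.75, 1\}$ crossed with
  seven rate pairs $(\alpha_P,\alpha_N) \in \{(0.1,0.7), (0.2,0.6),
  (0.3,0.5), (0.4,0.4), (0.5,0.3), (0.6,0.2), (0.7,0.1)\}$, 30 datasets
  per cell × 30 subjects = 1050 datasets, $\beta = 10$ for all agents
  (a sensitivity rerun at $\beta = 5$ is a one-argument change in
  `recovery_grid_design()`). Loss-condition grids mirror the $Q_0$ levels
  onto $[-1, 0]$. All agents in a dataset share the cell's parameters;
  each simulated subject receives an independently drawn schedule, as each
  participant would in the experiments.

Outcomes are realized lazily — only the chosen option's outcome is drawn,
at choice time (partial feedback). Every dataset records its derived seed,
so any single dataset is reproducible in isolation.

What the generator does *not* emulate: response times and deadlines,
left/right screen counterbalancing, practice blocks, monetary conversion,
and — more substantively — any behavioral structure outside the fitted
model family (choice perseveration kernels, attention lapses, drifting
learning rates). Passing recovery tests therefore show that the estimation
machinery is faithful to the model, not that the model is faithful to human
learners.

# The recovery and shadowing analyses

`fit_grid()` fits A-VI and A-FI to every grid dataset (the recovery study
fits only these two, with A-FI's $Q_0$ pinned at the condition's mean
outcome). `bias_curves()` reports estimate-minus-truth of the group-level
learning rates by true $Q_0$; `pooled_mu_delta()` concatenates the
$\mu_\delta$ draws of a cell's datasets and classifies the recovered
asymmetry direction by the pooled posterior median's sign, with a null cell
($\alpha_P = \alpha_N$) counted as correctly recovered iff the central 95%
interval covers zero. The figure-shading of the original analyses implies
but never states a numeric rule; the median-sign/95%-coverage rule is the
package's own, and it is symmetric in the two error directions.

The expected phenomenology, which the acceptance checks verify at reduced
scale: A-VI recovers all cells; A-FI overestimates $\alpha_P$ and
underestimates $\alpha_N$ when the true $Q_0$ is below the assumed value,
flips both signs above it, and is approximately unbiased at it — so a
truly symmetric learner is classified optimistic when $Q_0 < 0.5$ (gain),
with the pooled $\mu_\delta$ mass almost entirely on one side.

# Problem sizes and numerical choices

The test suite and `scripts/acceptance.R` run every analysis at reduced
scale, chosen so the full pipeline is exercised end to end on a single
CPU: 5 datasets × 30 subjects per shadowing cell (three $Q_0$ levels: 0,
0.5, 1, the fixed value and both extremes), the test sampler profile, and
$2\times10^5$ Dirichlet draws for EP estimates. The full 1050-dataset grid
is generated (and counted, and timed) but not fitted by default;
`run_recover()` with `paper_grid_design()` and the `"paper"` profile runs
the complete study.

Numerical details worth recording:

- the softmax log-probability is computed via a stable `log1p(exp(·))`
  branch, exact over the whole $\beta \in [0,20]$ range;
- the probit transform uses the R math library's `pnorm`, accurate far
  beyond the $[-8, 8]$ range the hierarchy visits;
- equal-probability blocks have no defined "correct" choice and are
  reported as `NA` in correct-choice-rate curves; they are summarized by
  the preferred response rate instead;
- the stay-probability check is a fixed-effects logistic regression fitted
  by an in-package IRLS (a mixed-effects version is out of scope by
  design); perfect separation is flagged rather than silently returning a
  divergent coefficient;
- Pearson correlations and paired t statistics are computed from closed
  formulas in-package, so the reported inferential quantities have no
  black-box dependencies, and are cross-checked against `cor.test()` /
  `t.test()` in the tests.

# Design choices on open questions

- **Model-recovery task.** The model-comparison acceptance check simulates
  the stable mini-block task. $Q_0$ re-applies at each of four block
  starts there (and the equal-probability blocks make spontaneous
  preference $Q_0$-driven), so per-subject evidence for a free $Q_0$ is
  strong. In the 100-trial random-walk task $Q_0$ enters once and its
  per-subject evidence is weak; A-VI still attains the lowest DIC, but the
  protected exceedance probability is shrunk toward uniform by a high BOR.
  This discriminability gap is itself informative: single-block designs
  are a poor instrument for detecting individualized initial expectations.
- **Per-condition fitting.** Mini-blocks of a condition are fitted jointly
  with a shared $\beta$ and per-block value resets; conditions are never
  pooled.
- **Sampler choice.** Any correct MCMC scheme is acceptable for this
  posterior; the package uses its own adaptive Metropolis-within-Gibbs
  (validated as described above) rather than depending on an external
  gradient-based engine.

# Known limitations

- The MH sampler needs the group moves to mix across the hierarchy; for
  much larger subject counts (hundreds) a gradient-based sampler would
  scale better.
- The subject-evidence proxy inherits DIC's known optimism about effective
  parameters; rankings are robust in practice but absolute PXP values
  should be read with the proxy in mind.
- Trimmed means are robust but not invariant: on the natural scale they
  are computed from transformed draws, so they are not the transform of
  the raw-scale trimmed mean. The package consistently summarizes on the
  natural scale.
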