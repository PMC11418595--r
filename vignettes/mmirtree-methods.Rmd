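---
title: "Mixture multidimensional IRTrees: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture multidimensional IRTrees: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The response model

`mmirtree` models 5-point rating responses as the outcome of up to three
sequential binary decisions. For person $p$ and item $j$ the observed
category $Y_{pj}\in\{1,\dots,5\}$ is decomposed into pseudo-items: a
*disagreement* node $Y^*_{p0j}$ (categories 1–2 vs 3–5), a *neutrality*
node $Y^*_{p1j}$ (category 3 vs 4–5, reached only after non-disagreement)
and an *extremity* node $Y^*_{p2j}$ (extreme vs moderate, reached on both
the disagreement and the agreement branch). Nodes not traversed by a
response are missing by design and contribute nothing to the likelihood.
The first two nodes form a sequential model for the ordinal judgment
disagree / neutral / agree, so the middle category is part of the ordinal
response process rather than a detached "non-response" option.

Each node follows a 2PL Bernoulli model on the logit scale (a probit link
is available as an option). With substantive trait $\theta_p$, extreme
response style (ERS) trait $\eta^{ers}_p$ and midpoint response style
(MRS) trait $\eta^{mrs}_p$:

$$
\begin{aligned}
P(Y^*_{p0j}=1) &= g^{-1}\!\left(-\alpha^{\theta}_j \theta_p
  - \alpha^{mrs}_j \eta^{mrs}_p - \beta_{0j}\right)\\
P(Y^*_{p1j}=1) &= g^{-1}\!\left(-\alpha^{\theta}_j \theta_p
  + \alpha^{mrs}_j \eta^{mrs}_p - \beta_{1j}\right)\\
P(Y^*_{p2j}=1) &= g^{-1}\!\left(\pm\,\omega\,\alpha^{\theta}_j \theta_p
  + \alpha^{ers}_j \eta^{ers}_p - \beta_{2j}\right),
\end{aligned}
$$

where the sign of the substantive term at the extremity node is negative
on the disagreement branch and positive on the agreement branch, and the
proportionality constant $\omega$ scales the substantive trait's effect on
extremity relative to its effect at the first two nodes. One $\beta_{2j}$
and one $\alpha^{ers}_j$ are shared between the two extremity branches.
The probability of an observed category is the product of the node
probabilities along its tree path, so the five category probabilities sum
to one by construction. A notational point worth making explicit: each
node is a Bernoulli variable with $P(Y^*{=}1)$ given by the logistic and
$P(Y^*{=}0)$ its complement — this is the only reading under which the
category probabilities normalise.

### The four-class mixture

The mixture model assumes four latent classes of respondents that share
the tree and the substantive-trait parameters but differ in *which*
response styles affect their responses: "ERS only" (class 1), "MRS only"
(class 2), "2RS" (both, class 3) and "0RS" (neither, class 4). A style
that is not part of a class's strategy has its loadings fixed to exactly
zero for every item in that class. Free response-style loadings and all
node difficulties are class-specific; $\alpha^{\theta}_j$ and $\omega$
are class-invariant so the same substantive trait is measured in every
class and trait estimates are comparable across classes. Traits are
multivariate normal with zero means and unit variances (the
identification constraint) and a class-invariant correlation matrix.
Conditional on a person's class indicator $z_p$, exactly one component
model is active; class proportions $\pi$ carry a uniform Dirichlet prior
and memberships a categorical($\pi$) prior, so empty classes are driven
towards staying empty.

Because the components are distinguished by structural zero patterns
rather than exchangeable labels, classical label switching cannot occur.
A subtler degeneracy replaces it, discussed below.

## Estimation

All models are estimated by Gibbs sampling implemented in C++:

* every logistic Bernoulli node is augmented with a Pólya-Gamma latent
  variable, giving exact conjugate updates — truncated-normal for
  loadings (prior $N(0,2)$ truncated to positive values), normal for
  difficulties (prior $N(0,2)$), trivariate normal for the person traits;
* $\omega$ has a conjugate normal conditional truncated to its uniform
  prior support $(0,2)$, so no tuning is needed;
* trait correlations carry the elementwise $U(-1,1)$ prior subject to
  positive definiteness and are updated by elementwise random-walk
  Metropolis (proposal SD 0.06, eight sweeps per iteration; non-PD
  proposals have prior mass zero and are rejected);
* memberships are drawn from their categorical conditionals and $\pi$
  from its Dirichlet conditional; when a class is empty its parameters
  are automatically redrawn from their priors, the standard mixture
  behaviour.

"$N(0,2)$" is read as variance 2; this and all other prior constants are
arguments of `prior_spec()`. Item parameters are updated *before* the
membership draw within an iteration, so a fresh chain adapts its class
parameters to the current partition before reassigning anyone. Linear
predictors are clipped at $\pm 35$ and probabilities floored at
$10^{-300}$ in logs. Each chain derives its own seed from the user seed;
given a seed, a fit is exactly reproducible.

The per-iteration deviance is $-2\log$ of the mixture likelihood
evaluated at the sampled parameters and memberships (the conditional
deviance a general-purpose Gibbs engine would report). DIC is
$\bar D + p_V$ with $p_V$ half the sample variance ($n-1$ denominator)
of the deviance draws. Convergence is monitored with the Gelman–Rubin
statistic on all stored scalar parameters (threshold 1.05 by default,
flagged but not fatal).

## Mode degeneracy and how fits are initialised

The mixture posterior contains near-degenerate minor modes in which the
*contents* of two classes are exchanged. The "2RS" class nests every
other class (its two loading vectors can shrink to zero), and "ERS only"
and "MRS only" each nest "0RS", so e.g. a population of pure-ERS
respondents can sit in the 2RS class with all MRS loadings near zero at
essentially no cost in likelihood — in fact the ~$J$ spurious loadings
absorb sampling noise and typically *lower* the conditional deviance by a
few dozen units, while genuine misplacement (a block of respondents whose
active style is unmodelled in its class) raises it far more. Ordinary
Gibbs moves update one membership at a time and cannot exchange whole
class contents, so a chain that forms the wrong arrangement keeps it.

`fit_irtree()` therefore prepares mixture fits in two steps before the
long chains run:

1. **Exploration.** Several short chains (default 4 × 400 iterations)
   start from random partitions with memberships free from the first
   iteration; the end state with the smallest mean deviance is kept.
   Random starts sort respondents well in most runs because, early on,
   the positively-truncated loading priors keep all style loadings away
   from zero, so a respondent's data genuinely prefer the class whose
   masks match their behaviour.
2. **Pairwise swap repair.** All six pairwise class-label swaps of the
   current partition are tried. Each candidate partition is scored by a
   fresh fit — neutral item starting values, profile-based trait starting
   values, memberships held fixed throughout — so that every arrangement
   is judged from the same unbiased context; re-adapting the evolved
   sampler state instead is unreliable, because trait scores and
   correlations that have absorbed a misplaced block's style are
   metastable and mask the gain of the corrected arrangement. Within a
   round, the baseline and all candidates share RNG seeds, cancelling
   most of the deviance drift out of the comparisons, and each score is
   the smaller of two independently seeded runs (an evaluation run can
   fail to form a newly activated loading-by-latent pair and settle above
   the arrangement's mode; such failures only ever bias the score
   upward). A swap is accepted when it
   clearly improves the fit, or when it is nearly deviance-neutral and
   moves content into the structurally simpler class. The margins
   encode the prior-volume (Occam) penalty that the conditional
   deviance cannot see, and they scale with the number of respondents
   whose class complexity changes: a spurious style in an occupied
   class lowers the conditional deviance by roughly 0.4 per member at
   20 items (its loadings and, more importantly, its person-side latent
   scores absorb overdispersion), while leaving a genuinely used style
   unmodelled costs roughly 1.2 per member. The acceptance threshold of
   $15 + 0.8\,|\Delta c|$ deviance units (with $\Delta c$ the
   person-weighted complexity change, and a flat 25-unit improvement
   required for complexity-neutral swaps) sits between those two rates,
   so deviance-neutral superset arrangements are dismantled while
   genuinely needed placements survive.

3. **Refinement cycles.** Swap repair needs clean blocks — a handful of
   respondents individually stuck in a wrong class shifts the fixed-z
   comparisons by tens of deviance units — while membership refinement
   needs the right arrangement. The two therefore alternate: up to two
   repair rounds, then a free-membership refinement pass, for up to
   three cycles, stopping once a cycle accepts no swap and refinement
   moves (almost) nobody.

All long chains are then warm-started from the repaired state. Starting
chains from a common point makes the between-chain diagnostic slightly
optimistic about mode coverage, but overdispersed starts are exactly what
the degeneracy defeats; the diagnostic retains its role for all
continuous parameters. Initialisation affects only which mode the chains
sample around, not the stationary distribution — `init = "heuristic"`
(a median split on middle-category share and on extreme share among
non-middle responses) and `init = "random"` are available and agree with
the default on well-identified data, but the profile heuristic is near
chance level on data generated under this design, because class-specific
difficulties, not raw response shares, carry most of the class signal.

## The synthetic-data generator

`generate_condition()` reproduces the generating design of the recovery
study: traits drawn from a trivariate normal with unit variances and
correlations $\mathrm{cor}(\theta,\eta^{ers})=.20$,
$\mathrm{cor}(\theta,\eta^{mrs})=0$,
$\mathrm{cor}(\eta^{ers},\eta^{mrs})=-.40$ (the correlation matrix is an
argument); $\alpha^{\theta}_j \sim U(0.75, 1.75)$, $\omega = 0.50$ fixed,
$\alpha^{ers}_j \sim U(0.75, 1.25)$ and $\alpha^{mrs}_j \sim U(0.50,
0.75)$ in the classes where the style is active, all difficulties
$U(-2,2)$ independently per class; memberships assigned in deterministic
contiguous blocks of sizes $\mathrm{round}(n\pi_c)$ (remainder to the
last class); responses drawn from the implied 5-category distributions.
Nine registered conditions cover equal proportions, four 70%-dominated
mixtures and four non-mixture populations; defaults are 2000 persons, 20
items, 10 replications. Item parameters, traits and memberships are
drawn once per condition and responses re-drawn per replication
(`redraw_persons = TRUE` regenerates traits as well). All stage seeds
derive deterministically from the master seed.

What the generator does *not* emulate: real questionnaires have
content-driven item clustering, acquiescence, person misfit and missing
data; passing recovery tests on these synthetic conditions shows the
estimator works under the stated population model, not that empirical
data follow it.

## Problem sizes used in the packaged checks

The full-scale study (9 conditions × 10 replications of 2000 × 20, 10
chains × 3000 iterations for the mixture model) is reproducible via
`study_config()` defaults, but takes hours per replication. The packaged
tests and the acceptance script run the same pipeline at desk scale —
one dataset per scenario with 450–500 persons, 20 items and 2 chains of
1200–1500 iterations — which keeps each mixture fit (including mode
exploration and repair) within a few minutes.
At this scale, posterior uncertainty is roughly twice that of the
full-scale study: 10%-proportion classes hold only ~50 respondents, so
per-class hit rates a few points below the full-scale values (0.93–0.96
for 10% classes, 0.96–0.98 for 25%, >0.99 for 70%, 99.9% for non-mixture
populations) are expected and the packaged bounds allow for it.
Loading-recovery correlations are computed across all loading blocks
jointly, since each block's generating range (width 0.5–1.0) is narrow
relative to desk-scale posterior spread.

## Known limitations

* Only 5-point scales and this tree are implemented; other category
  counts or tree shapes (e.g. a detached-midpoint tree) are out of scope.
* The probability functions accept `link = "probit"`, but the sampler is
  logit-only: Pólya-Gamma augmentation is specific to the logistic link,
  and the logistic model is the tested path throughout.
* In non-mixture populations the mixture fit correctly empties three
  classes; the emptied classes' parameters are then prior draws whose
  chains need not agree, so the Gelman–Rubin flag can trigger on
  parameters that carry no information. Inspect `tidy(fit)` before
  discarding such a fit.
* Deviance (and hence DIC) is conditional on the sampled latent traits
  and memberships; a marginal alternative over $z$ is not provided.
* The swap-repair margins were set from the observed deviance geometry
  at $J = 20$ items and scale with class occupancy, but extremely small
  classes (a handful of respondents) may still park in a flexible class.
* Missing responses are excluded listwise on input; missingness
  mechanisms are not modelled.
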