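---
title: "Modelling aquatic-adaptation transitions and body-mass trends in mammals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling aquatic-adaptation transitions and body-mass trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquaevol)
```

# The scientific questions

`aquaevol` addresses two linked macroevolutionary questions about mammals
(and, by extension, any clade with graded ecological transitions):

1. **Are aquatic adaptations irreversible?** Species are scored on an
   ordered four-level scale — `A0` (no morphological aquatic adaptation),
   `A1` (aquatic adaptations but fully mobile on land, e.g. water shrews,
   platypus), `A2` (limited terrestrial locomotion: pinnipeds, sea otter),
   `A3` (fully aquatic: cetaceans, sirenians). If losses of terrestrial
   competence obey a Dollo-like threshold, backward transition rates above
   that threshold should be zero.
2. **Do lineages gain relative body mass as they become more aquatic?**
   Water's high thermal conductivity penalizes small endotherms, so a
   Bergmann-like positive trend in (log) body mass is expected in
   water-adapted lineages.

# Discrete-state models

## Structures

Seven continuous-time Markov (Mk) structures on the ordered state space
`A0 < A1 < A2 < A3` are provided by `build_structure()`:

| name | free rates k | constraint |
|------|---|------------|
| ER | 1 | one rate shared by all 12 transitions |
| SYM | 6 | `q_ij = q_ji` |
| ORD | 6 | only adjacent states exchange |
| IR_32 | 5 | ORD with `A3 -> A2` forbidden |
| IR_2132 | 4 | ORD with `A3 -> A2`, `A2 -> A1` forbidden |
| IR_102132 | 3 | ORD, all backward moves forbidden |
| ARD | 12 | all rates free |

The irreversibility ladder (`IR_*`) operationalizes Dollo's Law at three
candidate thresholds. ER is defined over all 12 cells, not
adjacency-restricted; this is the natural reading of "all equal rates" and
is recorded here as a design decision since the structures are otherwise
only constrained by their verbal descriptions.

## Likelihood and root treatment

`pruning_loglik()` computes the Felsenstein pruning likelihood with the
FitzJohn–Maddison root treatment: root weights are taken proportional to
the root conditional likelihoods, `pi_i = L_i / sum_j L_j`, and the total
likelihood is `sum_i pi_i L_i`. This "maddfitz" rule lets the data choose
the root state rather than imposing a uniform or stationary prior.
Transition matrices `exp(Qt)` are computed from the eigendecomposition of
`Q` when it reconstructs `Q` to within `1e-9` (relative, infinity norm),
otherwise by scaling-and-squaring; the matrices involved are 4x4 (or 3x3
for diet), so both paths are exact to machine precision in practice.

`fit_mk()` maximizes the likelihood over log-rates (L-BFGS-B, rates
bounded to `[1e-9, 1e3]` per Myr) from one heuristic start
(rate = 1 / tree height) plus random log-normal perturbations (default 5
starts). The log scale and multiple starts matter because likelihood
surfaces flatten near irreversibility boundaries, where some rates run to
zero. Model scores use AICc with `n` = number of tips; `n` is not uniquely
defined for phylogenetic data and the tip count is the convention of the
comparative-methods tools this package follows. Akaike weights
(`akaike_weights()`) and the weight-averaged rate matrix
(`model_average_Q()`) summarize model uncertainty; across a tree sample
the package averages per-tree weights rather than re-weighting mean AICc,
which keeps the cross-tree summary internally consistent.

## Stochastic mapping

`sample_map()` draws full character histories conditional on the tip data:
node states by backward filtering / forward sampling, then
endpoint-conditioned branch paths by **uniformization**. Uniformization is
chosen over rejection sampling deliberately: under near-irreversible `Q`
many endpoint pairs have tiny forward probability and rejection becomes
pathological, while uniformization samples the number of (virtual) jumps
from its exact conditional distribution. Transition counts
(`count_transitions()`, `summarize_transitions()`) are summarized as
medians with central 95% intervals pooled across maps; clade-wise
empirical rates divide the mean within-clade count by the clade's total
branch length. A branch belongs to the clade of its child node, so a
clade is its crown plus its stem branch — the stem treatment is not
dictated by the estimators themselves and is fixed here once, used
consistently for both empirical rates and rate partitions.

# The D-test of correlated evolution

Diet is reduced to three categories by the animal (vertebrate +
invertebrate) fraction of the diet: below 20% herbivore, 20–80% inclusive
omnivore, above 80% carnivore. `dtest()` then measures the association
between two discrete characters as

`d_ij = a_ij - m_i(X) m_j(Y)`

where `a_ij` is the fraction of total tree time jointly spent in state
pair `(i, j)` (computed by overlaying stochastic maps branch by branch)
and `m_i` are marginal time fractions from the same maps; `d` is averaged
over map pairs. Significance comes from posterior predictive simulation:
both traits are re-simulated independently under their own fitted rate
matrices (root states drawn from each trait's FitzJohn–Maddison root
weights), each null pair is scored identically, and the cellwise p-value
is the upper tail `P(d_null >= d_obs)` — p near 0 flags positive
association, p near 1 negative association. Resimulating *both* traits
keeps the null symmetric in the two characters.

A calibration note: when the observed statistic is averaged over many
maps it has smaller sampling variance than a single unconditioned null
draw, which makes the p-values mildly conservative. The package's
calibration test therefore scores single-map statistics, for which the
observed and null draws are exchangeable by construction and the p-value
is exactly uniform under independence; with the default `n_maps = 100`
the test errs on the conservative side, never anti-conservative.

# Trend Brownian motion with hierarchical priors

## Model

Log10 body mass (grams) evolves along each branch `b` (child `c`, parent
`p`) as

`x_c ~ Normal(x_p + mu_state(b) * t_b,  sigma2_clade(b) * t_b)`

with `t_b` in Myr. Branch states come from `assign_branch_states()` — the
modal marginal ancestral state of the child node (tips keep their observed
state) — and branch clades from the rate partition (for the empirical
mammal analysis, 21 clades plus a background partition covering the root
region, i.e. 22 rate partitions). Three trend parameters `mu_A1, mu_A2,
mu_A3` (trait units per Myr) are shared across all branches in the
corresponding state; terrestrial branches are fixed at `mu_A0 = 0`, which
anchors the model and makes aquatic trends interpretable as deviations
from the terrestrial baseline. Within-branch state changes are not
modelled; each branch carries a single state, consistent with the
per-branch assignment.

Body mass is treated on the log10 scale. The trait scale's base is needed
to express a trend as a relative change: `percent_change_per_myr()`
computes `(base^mu - 1) * 100`. Both the transform of the posterior mean
and the posterior mean of the transform are reported by the pipeline,
since the two differ for skewed posteriors.

## Priors

* trends: `mu_s ~ Normal(0, sigma_trend^2)`, putting the highest prior
  density on "no trend";
* `sigma_trend`: fixed at 0.1 or, with `hyperprior = TRUE`, free under an
  exponential hyperprior with rate 10 (prior mean 0.1, matching the fixed
  default — the hyperprior's rate is a package choice, stated here, since
  only the family is fixed by the model's description);
* clade rates: `sigma2_c ~ Exp(lambda)` with `lambda ~ Exp(1)` sampled by
  MCMC;
* root value: diffuse normal, mean = tip average, sd = 10 x tip standard
  deviation (a weakly informative default; the root value is otherwise
  unidentified from a single draw of the process).

## Sampler

`mcmc_run()` alternates (i) Gibbs draws of every ancestral value from its
conditional normal (the model is jointly Gaussian given rates and trends),
(ii) Metropolis–Hastings updates of each `sigma2_c` on the log scale,
(iii) conjugate Gibbs draws of each trend from its conditional normal,
(iv) an MH update of `sigma_trend` (log scale) and a conjugate Gamma draw
of `lambda`. Proposal scales adapt toward ~30% acceptance during burn-in
only, so the post-burn-in chain is a fixed Markov kernel. Defaults are
500 000 iterations / 20% burn-in / thin 100 for empirical-scale trees and
~30 000–50 000 / 20% / 10 for the 300-tip validation trees; at validation
scale one chain takes on the order of seconds. The sampler's correctness
is pinned by three closed-form checks in the test suite: the single-branch
conjugate posterior of a trend, the exact Gaussian posterior of ancestral
values on a three-tip tree, and prior-only runs recovering
`Normal(0, 0.1)` trend marginals.

# The synthetic-data generator

The generator is the package's stand-in for the empirical mammal data and
defines the validation conditions:

* `simulate_tree()`: pure-birth trees rescaled to root age 100 Myr —
  roughly the crown age of mammals.
* `default_sim_Q()`: an `IR_2132`-structure matrix with rates
  `(A0->A1, A1->A0, A1->A2, A2->A3) = (6e-4, 8e-3, 6e-3, 2e-2)` per Myr,
  calibrated so a lineage starting terrestrial is aquatic with probability
  ~4% after 100 Myr (mix approximately 95.7 / 3.1 / 0.6 / 0.5% across
  A0–A3), emulating the real composition of 5635 mammals of which 3.3%
  are water-adapted.
* `partition_clades()`: deterministic monophyletic partition (default 8
  clades on simulated trees; the empirical analysis uses 21 + background).
* clade rates: log-uniform on `[0.01, 0.5]` (trait variance per Myr), a
  broad, scale-balanced stand-in for the posterior rate spread of the
  empirical analysis, which is not shipped with the package.
* three scenarios (`build_scenario()`): (1) all trends zero; (2)
  `mu_A1..A3 ~ U(-0.1, 0.1)` independently, terrestrial branches neutral;
  (3) as (2) plus an independent `U(-0.1, 0.1)` trend for the terrestrial
  branches of each clade.

Simulated traits use the same per-branch state assignment that the
analysis model sees (the child-node state of the true history), so
scenario analyses test trend identifiability, not state-inference error;
that matches how the validation study is designed, where the simulation
reuses the partition and mapping of the empirical analysis. What the
generator does **not** emulate: extinction (trees are pure-birth),
taxon-sampling bias, state-dependent diversification, measurement error
in body mass, and within-branch state changes. Passing validation
therefore demonstrates that the estimator recovers its own generative
model at realistic sizes — not that the real mammal data satisfy these
assumptions.

## Outcome classification

`classify_outcome()` scores each 95% credible interval against the truth:
with zero truth, an interval containing 0 is a *true negative*, otherwise
an over/underestimate by sign; with nonzero truth, an interval covering
the true value is a *true positive*. "True positive" is defined by
coverage (not by excluding zero with the right sign), matching the
accuracy-and-coverage reading of the validation table; the
significance-based alternative can be computed from the same records
(`lo95`/`hi95` columns) if wanted.

## Validation results recomputed here

`scripts/acceptance.R` re-runs the reduced-scale study from scratch:
20 scenario-1 and 20 scenario-2 replicates on 300-tip trees, each analysed
with and without the hyperprior (30 000 iterations, 20% burn-in, thin 10).
The reduced scale keeps a full dual-scenario, dual-prior study in the
order of a minute while leaving each state group with enough replicates
(20) for stable proportions. The quantities reported are the false
positive rate (any aquatic CI excluding zero under neutral truth, with
hyperprior), the per-group true-negative rates under both priors, and the
scenario-2 coverage of the true trends. The test suite asserts the same
quantities at the thresholds of the published validation table (false
positives <= 5%, true negatives >= 91% / >= 97% without/with hyperprior,
true positives >= 84%).

# Numerical choices and degenerate inputs

* Rates in `fit_mk` are bounded to `[1e-9, 1e3]` per Myr; a monomorphic
  dataset drives rates to the lower bound with log-likelihood -> 0.
* `transition_probs` clamps entries to `[0, 1]` and renormalizes rows,
  guarding eigen round-off near absorbing states.
* Pruning rescales partial likelihoods per node (log-scale accumulator),
  so 5000-tip trees do not underflow.
* Uniformization truncates the jump-count distribution when the posterior
  tail is exhausted (cap 5000 jumps); unreachable endpoint pairs raise an
  error naming the condition rather than looping.
* Zero-length branches contribute likelihood only through exact equality
  of endpoint values (`-Inf` otherwise); ties in AICc model choice go to
  the model with fewer parameters.
* All pipeline randomness flows through `derive_seed()` (stable string
  hash combined with the master seed), so every stage is reproducible and
  independently re-runnable.

# Known limitations

* Hidden-rate (HMM) extensions, covarion models and polymorphic tip
  states are out of scope; tip states must be complete.
* The trend model ignores within-branch state changes; branches are
  labelled by their child node's modal state.
* Fossil tips, tip dating, OU/multi-optimum models and reversible-jump
  exploration of partition schemes are not implemented.
* The D-test's default map-averaged statistic is mildly conservative (see
  above); this is inherent to posterior predictive checks of this form.
* On a sample of trees the package assumes a shared taxon set across
  trees.
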