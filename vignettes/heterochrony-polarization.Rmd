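---
title: "Polarizing heterochrony on chronograms: models, priors, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polarizing heterochrony on chronograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heterochron)
```

## The scientific problem

Heterochrony — evolutionary change in the timing of developmental events —
can only be polarized against an estimate of the ancestral condition. In
plethodontid salamanders the question is concrete: were the long larval
periods of some lineages ancestral (so that most descendants are
*accelerations*), or derived (*decelerations*)? And when a clade evolved
larval-form paedomorphosis, did it do so by advancing maturation
(*progenesis*) or by delaying metamorphosis with maturation unchanged
(*neoteny*)?

`heterochron` answers these questions on a posterior sample of
time-calibrated trees with four linked analyses:

1. **Ordered multistate reconstruction** of life-history mode
   (direct development < biphasic < paedomorphic) and of binned
   developmental ages, under an Mk model whose generator carries
   *structural zeros*: only numerically adjacent categories exchange, so
   ancestors evolve through the ordering without skipping.
2. **Node fossilization**: a focal node (addressed as the MRCA of a taxon
   set) is fixed to each alternative state in turn; the harmonic-mean log
   marginal likelihood (hm) of each constrained run enters a Log Bayes
   factor table, `LBf = 2 (hm_best - hm_alt)`.
3. **Brownian-motion continuous reconstruction** of ages in months, with
   exact Gaussian node conditionals and 95% highest-posterior-density
   intervals.
4. **Heterochrony polarization**: each tip age is called *accelerated*
   (below the ancestral 95% HPD), *decelerated* (above it), or
   *stasis/undetected* (inside it); and a two-pronged rule tests
   progenesis against neoteny across the branch carrying the
   life-history transition.

## The ordered Mk model

For `K` ordered states the generator `Q` has `Q[i,j] = 0` whenever
`|i - j| > 1`; these are structural zeros that no constructor argument can
perturb. The one-rate model shares a single rate across all `2(K-1)`
allowed directed transitions; the multi-rate model frees each of them.
Note the distinction between `Q` and the branch transition matrix
`P = exp(Q t)`: `P` connects non-adjacent categories at `t > 0` through
multi-step paths, as it must.

Likelihoods use Felsenstein pruning with per-node scaling (stable on
100-tip trees); missing tips contribute all-ones partials, which is how
paedomorphic taxa — coded as missing metamorphic age — stay in the tree
without informing the metamorphic analysis. Root state frequencies default
to uniform (a symmetric prior across the ordering); stationary frequencies
of the fitted chain are available as an alternative.

Age categories are half-open 12-month bins, `[12(k-1), 12k)`, the last bin
unbounded: 16 months is category 2 and exact multiples of 12 move up a
category, so 36 months is category 4 of the four-state metamorphic space.
Metamorphic age uses 4 bins; male and female maturation use 6.

Model choice between one-rate and multi-rate is by AIC on maximum-
likelihood refits (`fit_ml()`, multi-start L-BFGS-B on the log-rate scale,
rates bounded in (0, 100] to match the Bayesian prior support). Because
the source analyses do not state how model scores were aggregated across
a tree posterior, `fit_ml()` scores a single summary tree by default; any
tree of the posterior can be selected, and users can average AIC over a
subsample if they prefer. dAIC below 3 is negligible, 3 or more moderately
strong, 10 or more very strong — the same scale used for Log Bayes
factors.

## MCMC design

`run_multistate_mcmc()` targets the joint posterior of transition rates
(uniform(0, 100) priors), the chronogram (uniform prior over the supplied
posterior sample, mixed by uniform swap proposals accepted on the
likelihood ratio; proposal probability 0.25 per generation), and the
states of focal nodes. Rate proposals are sliding windows on the log scale
(symmetric in log space; the uniform-on-rate prior contributes the
Jacobian), reflected at the upper prior bound. Proposal windows are tuned
only during burnin — every 500 generations, toward a 20–40% acceptance
window — and frozen afterwards so the post-burnin chain exactly preserves
its target. Realized acceptance outside the window after burnin raises a
warning with the observed rate.

Defaults mirror a full-scale analysis: 5 million generations, sampling
every 1,000, the first 1 million discarded, hence 4,000 retained samples.
All tests and the bundled pipeline profile run reduced chains (10–300
thousand generations); chain length trades Monte-Carlo error against time
and does not change the target distribution.

Focal nodes are located in *every* tree by the MRCA of their taxon set.
When the taxa are not monophyletic in some trees the MRCA subsumes extra
taxa; the fraction of trees in which the clade is exactly monophyletic is
recorded on the trace. At each retained sample the focal node's state is
drawn from its exact conditional marginal given the current rates and
tree (computed by constrained pruning sweeps), so reported "prob." values
are posterior state probabilities integrated over rates and trees.

Fossilization restricts the node's partial-likelihood vector to the fixed
state in every evaluation, leaving the root prior unchanged. The
harmonic-mean marginal-likelihood estimator is computed in log space via
log-sum-exp. Its instability is well documented; it is retained because
it is the convention behind published fossilization tables, and
`stepping_stone_log_marginal()` (power posteriors with Beta-spaced rungs)
is provided as a more stable cross-check that is *not* part of the
published procedure.

## Brownian-motion reconstruction

Ages are analyzed in raw months (as reported in the field); a `log_scale`
flag is available. The BM likelihood is evaluated by phylogenetic
independent contrasts — mathematically identical to the dense
multivariate-normal density, in linear time — after pruning taxa with
missing values; the stem between the original root and the pruned
subtree's MRCA is retained as extra root variance so the root mean keeps
its meaning. `sigma2` takes a uniform(0, 100) prior; the root mean takes a
flat prior implemented as uniform(-1e6, 1e6).

`ancestral_conditional()` exposes the exact Gaussian conditionals behind
the node draws. Its default marginalizes the root under the flat prior
(so the root's conditional mean is the GLS phylogenetic mean, and constant
tip values give every node that constant); `root_prior = "fixed"` is the
conditional used inside the sampler given its current root-mean value.
Node HPDs from `run_bm_mcmc()` therefore integrate over rate, root and
tree uncertainty, and are wider than any fixed-parameter conditional.

## The polarity and progenesis/neoteny rules

`classify_tip()` partitions the age axis: strictly above the ancestral
95% HPD is *decelerated*, strictly below is *accelerated*, and anything
inside — including ages exactly on an endpoint, conservatively — is
*stasis*. The report labels this category "stasis/undetected": a tip
inside the interval may have shifted by less than the method can resolve.

The progenesis test needs a numeric criterion for a "significant
reduction" in maturation across the transition branch, which the source
procedure does not state. Two prongs are evaluated and reported
separately so users can apply their own standard:

* **categorical**: the child node's best-fit maturation category is
  younger than the parent's, *and* the parent's best category is rejected
  at the child with `LBf >= 3` (the same moderately-strong threshold used
  everywhere else);
* **continuous**: the 95% HPDs of parent and child are disjoint with the
  child younger.

Either prong gives *progenesis*; otherwise, if the life-history
transition to paedomorphosis occurred on the branch (per
`localize_transition()`, which flags branches where the modal state
changes), the verdict is *neoteny*; otherwise *ambiguous*.

Which node serves as the "parent" maturation reference is a genuine
design choice. The transition branch's immediate parent is the literal
reading, but under Brownian smoothing its estimate is dominated by its
own — mostly paedomorphic — descendants, so a maturation shift in the
paedomorphic clade drags the reference along and leaves almost no
contrast. The recommended (and default pipeline) reference is therefore
the rootward focal node whose estimate is not dominated by the shifted
clade — in the bundled analyses, the biphasic clade's ancestor. Both
nodes' estimates are attached to the verdict's evidence table. Requiring
disjoint HPDs, and an LBf of 3 against the parent's category, makes both
prongs deliberately conservative: one-category drifts with overlapping
intervals stay "neoteny", which is the appropriate null when the somatic
transition is established and maturation shows no clear advance.

## The synthetic-data generator

`make_study_dataset()` emulates the empirical design so every stage is
testable offline: a Yule chronogram (Gillespie simulation, sampled at the
moment the (n+1)-th lineage would arise, then rescaled) with 63 taxa and
root depth 73 time units — echoing the calibration scale of the empirical
chronograms so simulated rates are numerically comparable; a biphasic
clade of about 26 taxa containing a paedomorphic subclade of about 8;
direct developers at 2 months metamorphic age (hatching); paedomorphs
with missing metamorphic age; and Brownian ages. Life-history states are
assigned *structurally* (by clade membership) rather than simulated, so
the transition branch is known exactly — the right ground truth for
testing localization and the verdict. Discrete-trait evolution is
simulated separately (`simulate_mk()`, Gillespie along branches with a
full jump log) for rate-recovery and model-selection tests.

Default Brownian parameters are anchored to the scale of the published
node estimates: metamorphic age root 8 months with `sigma2 = 2`
months^2 per time unit (root-depth spread ~12 months, ancestral HPD
half-widths ~9 months), maturation root 30 months with `sigma2 = 1.5`
(tip spread ~10.5 months around the root, matching the empirical range
of minimum maturation ages and node-to-node differences of a few
months). Ages are clamped below at 0.5 months — Brownian motion on a raw
scale can go negative; the clamp is a generator convenience, not part of
any model.

Pseudo-posteriors (`jitter_tree_posterior()`) perturb internal node ages
with lognormal noise and restore monotonicity, keeping exact ultrametry
and the topology: they emulate branch-length uncertainty only. Features
of real posteriors that the generator deliberately does **not** emulate:
topological uncertainty, non-clock rate variation, correlated male/female
maturation, plasticity-driven within-species variance, and measurement
error in literature-derived minimum ages (tip ages are treated as exact
throughout). Passing tests therefore validate the estimators and the
pipeline plumbing under the stated generative model, not robustness to
those real-data complications.

## Numerical choices

* Branch transition probabilities inside the sampler: reversible
  birth-death generators are symmetrized by their detailed-balance
  weights and eigendecomposed once per likelihood call. For short
  branches (`q t <= 2`) a uniformization series is used instead because
  its non-negative terms give entrywise *relative* accuracy for the tiny
  multi-step probabilities; when the detailed-balance weights are
  ill-conditioned (stationary-frequency ratios beyond 1e4) a
  scaling-and-squaring Padé exponential takes over. The public
  `transition_probabilities()` uses a general matrix exponential.
* Pruning accumulates per-node scaling factors in log space; likelihoods
  stay finite whenever any state assignment has positive probability.
* HPD intervals are the shortest contiguous window of the sorted samples
  containing `ceiling(0.95 n)` of them; tied windows resolve to the
  lowest lower bound.
* Zero-length branches are legal (identity transition); negative branch
  lengths are a hard error. Polytomies are resolved deterministically
  (left-to-right) into zero-length branches at read time. Ultrametricity
  violations beyond a relative tolerance (default 1e-6 of root depth) are
  flagged, not fatal, because empirical posterior samples routinely carry
  rounding-induced spread.
* Degenerate Brownian cases: `sigma2 = 0` with non-constant values gives
  `-Inf`; a zero-variance contrast with a non-zero difference marks the
  likelihood degenerate.

## Problem sizes used by the test and acceptance suites

Unit tests run chains of 4–50 thousand generations on 4–64-taxon trees;
the calibration suites use 20 replicate one-rate chains of 200,000
generations on 64-tip, depth-73 trees (rate 0.05), 10 Brownian
replicates at `sigma2 = 2`, 50 root-coverage replicates on 24-tip trees,
and 10 + 10 verdict-recovery replicates with a -12-month planted
maturation shift. These sizes are the package's reduced profile of the
full-scale defaults (which remain available through `mcmc_config()`).

## Known limitations

* The harmonic-mean estimator has infinite variance in many models; LBf
  tables from short chains are noisy, and the stepping-stone cross-check
  is recommended whenever a decision sits near a threshold.
* MRCA addressing across a posterior subsumes extra taxa in trees where
  the named clade is not monophyletic; the monophyly fraction is reported
  but no attempt is made to match "the same" node topologically.
* Brownian motion smooths jumps: a discrete shift planted on one branch
  is partly absorbed by neighboring node estimates (shrinkage), which is
  why the progenesis test is conservative by construction.
* No Ornstein-Uhlenbeck, rate-shift, covarion, or stable-distribution
  models; no divergence-time estimation — chronograms are consumed as
  given.
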