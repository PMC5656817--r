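---
title: "Methods: state-dependent diversification and range-size analyses for cave lineages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state-dependent diversification and range-size analyses for cave lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speleodiv)
```

# The question

Obligate cave life ("troglobitism") has long been viewed as an evolutionary
dead-end: once a lineage commits to the subterranean habitat, it is expected
to have a tiny geographic range, to rarely or never transition back to the
surface, and to suffer elevated extinction relative to speciation.
`speleodiv` implements the comparative machinery needed to test each of
those predictions on a time-calibrated phylogeny with per-species habitat
assignments and range sizes, and ships seeded generators that produce all of
those inputs synthetically with known ground truth, so every estimator in
the package can be checked for calibration and parameter recovery.

Throughout, trees are `ape` `phylo` objects with branch lengths in Myr, and
rates are in events/lineage/Myr.

# Habitat coding

Species occupy one or more of four habitat classes: lentic (still) water,
lotic (flowing) water, caves, and burrows.  Two codings are derived:

* **Binary, per focal class** (`binaryCoding`): a species is 0 when its
  habitat set is *exactly* the focal class (the specialist) and 1 otherwise.
  For the `generalist` focal class, species with two or more habitats are 0.
  Primary (obligate) burrowers carry the habitat set `{burrow}` by
  definition; secondary burrowers have `burrow` plus a surface class and are
  therefore never burrow specialists.
* **Three-state** (`geoCoding`): obligate cave-dwellers are `A`, species
  never using caves are `B`, and troglophiles (cave plus surface) are `AB`.
  The two codings agree by construction: `A` equals binary cave-0.

Range sizes arrive as per-polygon areas in m² (GIS extraction is upstream of
this package); `totalRangeKm2` sums polygons, converts to km² and stores the
log10 value.  Class summaries (`medianRangeByClass`) use medians on the km²
scale with the midpoint convention for even counts — the original data
description does not fix a convention, so linear interpolation is this
package's documented choice.

# State-dependent diversification models

## Likelihood engine

All three models are computed with one pruning core (C++, adaptive
Dormand–Prince 5(4) with absolute and relative tolerance $10^{-8}$,
integrating branch-wise from the tips to the root).  For the anagenetic
$k$-state family (BiSSE, HiSSE) the per-branch equations are

$$\frac{dE_i}{dt} = \mu_i - (\lambda_i + \mu_i + \textstyle\sum_j q_{ij}) E_i
  + \lambda_i E_i^2 + \textstyle\sum_j q_{ij} E_j$$
$$\frac{dD_i}{dt} = -(\lambda_i + \mu_i + \textstyle\sum_j q_{ij}) D_i
  + \textstyle\sum_j q_{ij} D_j + 2 \lambda_i E_i D_i$$

with the node merge $D_i \leftarrow \lambda_i D_i^{(L)} D_i^{(R)}$.  GeoSSE
adds the widespread state `AB` with within-region speciation $s_A, s_B$,
between-region speciation $s_{AB}$, region loss $x_A, x_B$ and range
expansion $d_A, d_B$, and its cladogenetic node merge symmetrizes over which
daughter inherits the full range.  Incomplete sampling enters through
per-state sampling fractions $\rho$: a tip in state $s$ initializes
$D_s = \rho_s$ and every state starts at $E_i(0) = 1 - \rho_i$.

Numerical choices:

* $D$ is renormalized to sum 1 after every branch with the log of the
  normalizer accumulated, so long trees cannot underflow silently; a
  non-positive or non-finite $D$ sum is reported as $-\infty$, never as a
  silent zero.
* Root treatment defaults to weights proportional to the root $D$ values
  ("observed" weighting), with flat weights, user-supplied weights, a fixed
  root state and optional survival conditioning available.  The default
  mirrors the most common practice for these models; because the choice is
  not dictated by the data, all alternatives are exposed.
* Each branch is allowed a generous but finite number of integrator steps;
  a branch that exhausts it (which only happens at rates far outside the
  plausible regime, where the system is extremely stiff) is reported as
  $-\infty$ rather than computed at an arbitrary cost.  For the same
  reason, maximum-likelihood searches are bounded to rates below
  $e^{3} \approx 20$ events/lineage/Myr.
* The engine rejects non-bifurcating trees and trees whose root-to-tip
  depths differ by more than `1e-6` × height by default (penalized-likelihood
  chronograms carry rounding noise at about that scale).  Zero-length
  terminal branches are legal but logged.

The engine is validated in the test suite against independent oracles that
share none of its code: a fixed-step RK4 pruning implementation in plain R,
the closed-form constant-rate birth–death likelihood, the exact
factorization of a state-independent BiSSE likelihood into (birth–death) ×
(two-state Markov character), and a generic cladogenetic ("ClaSSE-style")
pruning implementation into which GeoSSE embeds.

## The irreversibility constraint

In the GeoSSE habitat reading, `A` is the cave-endemic state, so the rate at
which a cave-endemic lineage gains surface habitat — the dispersal/range
expansion parameter $d_A$ — is the flux *out of* the exclusively-cave state.
The "irreversible" model therefore fixes $d_A = 0$ **and** the root to the
surface state (`constrain(model, fix = c(dA = 0), root.state = "B")`).
Which single GeoSSE parameter represents "transition out of caves" is a
modeling judgement (a cave lineage leaves the cave-only state by range
expansion, not by a single anagenetic switch); the constraint surface is
generic, so any other mask can be requested.

## Hidden-state (HiSSE) model set

`hisseModelSet()` defines six models over the binary cave/surface character:
a BiSSE-equivalent (no hidden states), two character-independent models
(CID-2 with two hidden diversification regimes, CID-4 with four), a full
model with a hidden regime under both observed states, and two one-sided
models with a hidden regime only under the cave or only under the surface
state.  Five of these roles follow the standard hidden-state model-selection
battery; the set is completed to six with the BiSSE-equivalent, which also
serves as the reduction check (`hisseLoglik` with that spec equals
`bisseLoglik` exactly).  In all specs, observed-state transitions `q01`,
`q10` are shared across hidden regimes, hidden-regime switches occur at one
rate `alpha`, and dual transitions are structurally zero.  Models are
compared by AIC weights from multi-start derivative-free maximum-likelihood
fits (`fitMLSse`, Nelder–Mead on log-rates from random exponential starts);
the test suite requires every fit to reach at least the best MCMC draw's
likelihood on the same data.

# Bayesian inference

`sliceSample` implements the univariate slice sampler (stepping-out and
shrinkage), one full sweep over the free parameters per generation, with
independent exponential priors of mean 0.5 on every rate — a broad prior on
the events/lineage/Myr scale of this system.  Parameters are sampled on the
natural scale with the slice bracket truncated at zero, so the prior is
exact rather than transformed.  Slice widths start at the prior mean and
adapt toward the local slice scale during burn-in only (the sampler that
produces retained draws is fixed-width), which keeps likelihood evaluations
near five per parameter per sweep.  Defaults follow the analysis this
package reproduces: 5000 generations and 10% burn-in for SSE chains.

Derived machinery: posterior hypothesis probabilities are draw fractions
(`posteriorProbability`); credible intervals are shortest-window HPD
intervals with ties to the lowest start (`hpdInterval`); effective sample
sizes use the initial-positive-sequence autocorrelation rule (`essChain`);
marginal likelihoods for the reversible-vs-irreversible comparison are
harmonic means of per-draw likelihoods computed in log space
(`bayesFactorHarmonic`).  The harmonic-mean estimator is known to be
high-variance, so the function also reports bootstrap standard errors of
each log marginal likelihood; comparisons should carry that uncertainty.

# The threshold model

`thresholdMcmc` estimates the correlation $r$ between the unobserved
liability of a binary habitat trait and a continuous trait (log10 range
size), with the pair evolving by correlated Brownian motion on the tree:
trait covariance $R = [[1, r\sigma], [r\sigma, \sigma^2]]$ (liability
variance fixed at 1 for identifiability) and tip covariance $R \otimes C$
with $C$ the tree's shared-path-length matrix; ancestral liabilities are
integrated out analytically through $C$.  State 0 corresponds to negative
liability, matching the coding in which the specialist is 0; under this
orientation a range-size deficit in specialists (low liability with low
trait values) appears as *positive* $r$.  Analyses that orient the liability
with the specialist on the positive side report the mirrored sign for the
same biology, so only signs relative to the stated orientation are
comparable across implementations.

The sampler alternates (a) Gibbs updates of tip liabilities from their
truncated-normal full conditionals (C++ inner loop; every retained draw is
asserted to sign-match its tip's state), (b) a joint Gibbs update of the two
root means from their generalized-least-squares conditional, and (c)
Metropolis updates of $r$ (uniform(−1, 1) prior) and $\log\sigma$ (flat
prior), with proposal scales adapted during burn-in only.  The reference
analyses ran 30 million generations sampling every 3000 with 25% burn-in;
that budget is a compute choice, not a model feature, so the default here is
a few thousand full sweeps with 25% burn-in, and convergence is gated on
ESS($r$) > 200 as in the original protocol.  Internally the chain runs in a
canonical orientation (first tip in state 1) and is mirrored back, which
makes the 0↔1 relabeling symmetry exact draw-by-draw.  Significance follows
the sign convention of the 95% HPD interval of $r$: `significant-` when the
interval lies below 0, `significant+` above, otherwise not significant —
the threshold model's power supports sign conclusions, not magnitudes.

# Posterior-predictive adequacy

`simulateSseForward` is a Gillespie (exact event-time) simulator of lineage
birth, death, state change and, for GeoSSE, cladogenetic range inheritance.
With the default taxa-stop rule the process halts at the instant the extant
count first reaches the target, so the final sister pair is separated by
zero time; fixed-age stopping is available and is what the analytic
birth–death checks use (single-lineage extinction probability
$\mu(e^{(\lambda-\mu)t}-1)/(\lambda e^{(\lambda-\mu)t}-\mu)$, pure-birth
mean $e^{\lambda t}$).  `simulateConditioned` keeps tip-state prevalence
fixed by rejection of forward simulations — the same target distribution as
a true backward-in-time sampler at these problem sizes, with the acceptance
rate reported so a parameter/count mismatch is visible rather than hidden.

Two statistics compare simulated to observed data:

* **Tip-state counts** (`tipCountTest`): expected counts are the mean
  simulated counts rescaled to the observed total; the statistic is
  $\sum (O-E)^2/E$ with `#states − 1` degrees of freedom and p from the
  $\chi^2$ distribution.  Simulations are pooled into one expected vector
  (the alternative — one test per simulation — is not what the original
  protocol describes).
* **Phylogenetic signal** (`sscd`): the sum of sister-clade differences,
  computed tips-to-root with nodal values the mean of the two daughters.
  `sscdComparison` applies a Welch two-sample t-test ("t-test" alone does
  not fix a variance assumption; Welch is the safer reading) plus the
  fraction of observed values inside the simulated 50% and 95% bands
  (type-7 empirical quantiles).

# Synthetic data and the conditions used by the tests

The generators define the study conditions for all calibration and recovery
tests:

* SSE scenarios (`genSseScenario`): crayfish-scale rates — speciation
  0.2–0.3, extinction 0.05–0.1, transitions 0.01–0.1 per lineage per Myr —
  at 100–300 tips, the scale of the cave-bearing subtree in the motivating
  system.
* Threshold scenarios (`genThresholdScenario`): Yule backbone (birth 0.15,
  grown past the final speciation so the tip covariance is non-singular),
  bivariate Brownian (liability, log10 range) with the generating $r$, and
  the binary state as the liability's sign.
* Range tables (`genRangeTable`): habitat classes drawn with probabilities
  approximating a temperate freshwater-crayfish mix (lotic-dominated,
  ~8% cave, ~22% generalist), log10 range = 4.3 + class effect + N(0, 0.5),
  cave effect −0.8 (about an order of magnitude smaller ranges).

Each generator writes a JSON manifest from which its files regenerate
byte-identically (hash-checked in the tests).

Problem sizes in the test suite are chosen to keep the default run in
minutes while leaving the conclusions unchanged: threshold calibration uses
50 null datasets at 100 tips and 20 sign-recovery datasets at 200 tips with
2500-sweep chains; GeoSSE ratio recovery uses 20 datasets at 300 tips with
600-generation chains; the BiSSE rate-ranking check uses 10 datasets at 150
tips with 400-generation chains; the adequacy self-calibration uses 50
replicates of 100 tips with 60 predictive simulations each.  The
end-to-end pipeline smoke tests run the full stage graph on 40–60-tip data
with short chains.

What the generators deliberately do **not** emulate: phylogenetic error
(the empirical workflow propagates uncertainty over 1000 bootstrap trees;
the generators produce true trees), spatial structure in range polygons,
and taxonomic incompleteness beyond per-state binomial thinning.  Passing
tests therefore demonstrate correctness and calibration of the estimators
under their own model, not robustness to the many ways real data violate
these models.

# Known limitations

* **The tip-count χ² is anticonservative for slowly mixing characters.**
  Tip states produced by an SSE process are phylogenetically correlated, so
  the variance of a tip-state count exceeds the multinomial variance the
  χ² reference distribution assumes.  In self-calibration experiments
  (data and battery both at the true parameters) the joint tip-count +
  SSCD pass rate at p > 0.05 is far below nominal when transitions are
  rare (about 0.2 at q = 0.01, 0.6 at q = 0.1 per Myr) and approaches
  nominal only when the character mixes fast (about 0.9 at q = 0.5).  The
  test is implemented as specified because it is the protocol being
  reproduced; treat small tip-count p-values under strong phylogenetic
  signal with caution, and lean on the SSCD comparison, which is calibrated
  in the same experiments.
* The harmonic-mean marginal likelihood is high-variance; the reported
  bootstrap SE should accompany any Bayes-factor statement.
* Subspecies collapsing keeps the alphabetically first tip per binomial —
  a reproducible convention, not a biological choice.
* MCMC pooling across bootstrap trees (when a tree set is supplied) treats
  per-tree posteriors as exchangeable; per-tree summaries are available by
  running the chain per tree.
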