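---
title: "Bayesian rating prediction by averaging over stochastic block models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian rating prediction by averaging over stochastic block models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbmrec)
```

## The model

We observe a bipartite network of users and items whose links are labeled
with one of $K$ rating classes; only a subset $O$ of the user–item pairs
carries an observed rating $r_{ui}$. The inferential question is the
probability that an *unobserved* pair takes class $r$, given everything
observed.

`sbmrec` answers it with stochastic block models (SBMs): users and items
are simultaneously partitioned into groups, and the probability of each
rating class depends only on the pair of groups,
$p(r_{ui} = r) = q_r(\sigma_u, \tau_i)$ with $\sum_r q_r = 1$ per block.
Instead of fitting one partition, the package treats every pair of
user/item partitions $(P_U, P_I)$ as a candidate model and averages their
predictions, weighted by how well each explains the observations. With a
flat prior over models, the per-block probability parameters integrate out
in closed form (each block contributes a Dirichlet–multinomial term), and
the posterior predictive becomes

$$
p(r_{ui} = r \mid R^O) \;=\; \frac{1}{Z} \sum_{P_U, P_I}
  \frac{n^r_{\sigma_u \tau_i} + 1}{n_{\sigma_u \tau_i} + K}\,
  \exp\!\big(-H(P_U, P_I)\big),
$$

where $n^r_{\alpha\beta}$ counts the $r$-ratings between user group
$\alpha$ and item group $\beta$, $n_{\alpha\beta} = \sum_r
n^r_{\alpha\beta}$, and

$$
H(P_U, P_I) = \sum_{\alpha\beta}\Big[\ln\Gamma(n_{\alpha\beta} + K)
  - \sum_r \ln\Gamma(n^r_{\alpha\beta} + 1) - \ln\Gamma(K)\Big].
$$

Lower $H$ means more explanatory power; empty blocks contribute exactly
zero. The fraction inside the sum is the Laplace rule of succession — the
posterior predictive of a flat-prior multinomial — so even a block with
little data makes a calibrated, shrunk prediction. Classes are treated as
categorical throughout the model; ordinality enters only through the
`mean`/`median` prediction rules and MAE.

Two properties are worth stressing because the test suite leans on them:

* the model-complexity trade-off is automatic. Splitting a homogeneous
  block always raises $H$ (the marginalization penalizes parameters that
  the data do not support), so no extra over-fitting penalty is needed;
* with no data at all, $H \equiv 0$ and the posterior over partitions is
  uniform — a sharp, testable null.

## Sampling the partition ensemble

The double sum over partitions is a sum over Bell-number-many terms and is
exact only for tiny instances; `exhaustive_posterior()` implements it (via
restricted-growth-string enumeration) precisely to serve as the oracle in
tests. At scale, `run_ensemble()` uses Metropolis sampling: a move picks a
node uniformly among all users and items and proposes a uniformly random
group label on its side, accepted with probability
$\min(1, e^{-\Delta H'})$.

The sampler works with *labeled* groups (each side has as many potential
labels as nodes), which over-counts an unlabeled partition with $g$
non-empty groups by the number of injective label assignments,
$N!/(N-g)!$. The corrected Hamiltonian
$H' = H + \ln N_U!/(N_U - g_U)! + \ln N_I!/(N_I - g_I)!$ cancels this bias
exactly; the package verifies the cancellation by checking that empty-data
sampling is uniform over the 15 unlabeled partitions of 4 nodes
(chi-square goodness of fit). This correction is not a prior against many
groups — it only undoes a bookkeeping artifact of the move set.

Moves are evaluated incrementally: a single-node move touches only the
blocks incident to its old and new groups, so one attempt costs
$O(\deg(\text{node}) + g K)$ rather than a full recount. `move_delta()`
exposes the same computation in R, and both paths are tested against full
recomputation of $H'$.

Because the partition landscape is multimodal and single-node moves merge
groups only through unlikely intermediate states, the package follows the
short-parallel-chains strategy: several independent chains are started in
different regions (`init_groups = "random-g"` draws a group count
uniformly and assigns nodes uniformly), and their samples are pooled. Each
sample already carries the Boltzmann weight, so the pooled unweighted
average is the estimator.

### Defaults and numerical choices

* `n_chains = 10`, `sweeps_per_chain = 500` (a sweep is one attempted move
  per node), `burn_in = 20%` of sweeps, sampling interval targeting
  ~100 samples per chain. Chain-level sweep counts were chosen so the
  desk-scale checks below converge; for harder posteriors (e.g. the
  planted-recovery analysis) we use 2,000 sweeps per chain, which is where
  the within-group co-classification stabilizes.
* all randomness flows through R's RNG; per-chain sub-seeds are drawn once
  from the master seed, so runs are exactly reproducible and chains are
  independent.
* log-domain arithmetic via `lgamma` throughout (counts reach $10^5$;
  factorials are never formed). Inside the compiled sampler the
  `lgamma` values are table-lookups precomputed up to $|O| + K$.
* the sampler re-synchronizes its incrementally tracked $H$ against an
  exact recomputation at every recorded sample (on instances small enough
  to afford it), so stored $H$ values match recomputation to $10^{-8}$.
* MAP ties break toward the lowest class; discretized real-valued
  predictions round half-way cases toward the lower class and clip to
  $[1, K]$.

## The synthetic generator

`generate_ratings()` emulates dichotomous like/dislike data with planted
structure. Each item gets an intrinsic quality $Q_i \sim U(0,1)$; users
and items get planted groups (5 × 5 by default, assigned uniformly); each
block pair gets an a-priori preference $\pi_{\alpha\beta}$, by default
$U(0,1)$ and overridable via `pi_matrix` (the analyses that need
well-separated groups use a deterministic 0.05/0.95 pattern). A pair is
rated "like" with probability

$$p(u, i) = (1 - \lambda)\, Q_i + \lambda\, \pi_{\sigma_u \tau_i},$$

so $\lambda$ interpolates from quality-only ($\lambda = 0$, where the
per-item mean is the optimal predictor) to preference-only
($\lambda = 1$, where only the block structure is informative). The
default study conditions are 100 users × 100 items, 4,000 observed
ratings and 1,000 held-out test pairs, sampled distinctly and uniformly.

Since the truth is known, `optimal_accuracy()` reports the ceiling
$\mathbb{E}[\max(p, 1-p)]$ that no algorithm can beat in expectation.

One property of these conditions deserves a note. At $\lambda = 1$ the
item mean no longer sees the item's quality, but it still aggregates the
five user groups' preferences for that item's group: the item's marginal
like-rate is a mean of five $U(0,1)$ draws, which deviates from $1/2$ by
$\approx 0.10$ on average. The naive recommender therefore settles around
accuracy 0.60 at $\lambda = 1$, not at the coin-flip 0.5: it is
*uninformative about item quality*, not literally at chance. The benchmark
records this as the measured naive curve rather than forcing it to 0.5.

What the generator deliberately does not emulate about real rating data:
heavy-tailed degree distributions (every pair is equally likely to be
observed), more than two rating classes, ordinal structure, and
rating-dependent missingness. Passing the synthetic benchmark therefore
shows correct inference under the planted model, not performance on real
data; the MovieLens readers and `benchmark_real()` exist for the latter.

## Baselines

Three standard collaborative-filtering baselines are implemented behind
the same query interface, to reproduce the comparison protocol:

* `naive_predict()` — the per-item mean rating (global mean for unseen
  items);
* `svd_fit()`/`svd_predict()` — Funk-style matrix factorization
  $\hat r = \mu + b_u + b_i + p_u \cdot q_i$, trained by per-observation
  SGD on the regularized squared error. Defaults $f = 40$, rate 0.002,
  regularization 0.02, 100 epochs — conventional Funk-SVD settings, all
  configurable. Raw predictions are real-valued and may leave the rating
  range; only the discretized path clips;
* `item_sim_fit()`/`itemitem_predict()` — item–item kNN with adjusted
  cosine similarity (user means subtracted; denominators restricted to
  co-rating users; pairs with no co-rater get similarity 0). Default
  $k = 30$; negative-similarity neighbors are excluded and an empty
  neighborhood falls back to the naive prediction — standard practice
  where the protocol is silent.

## Interpretability analytics

`coclassification()` turns the sampled ensemble into the probability that
two nodes share a group; `consensus_partition()` summarizes it by
average-linkage clustering of $1 - $ co-classification;
`attribute_vs_coclass()` relates co-grouping frequency to node metadata
(same-category fraction for categorical attributes, mean absolute
difference for numeric ones) in 10 equal-width bins by default, flagging
bins with fewer than 20 pairs; `genre_overlap()` is the Jaccard index of
genre sets (undefined — an error — for empty sets, and the metadata
reader flags zero-genre items for exclusion).

## Desk-scale checks and problem sizes

The test suite validates the whole chain at sizes where exact answers
exist: the Hamiltonian against hand-evaluated simplex integrals and an
`lgamma`-free factorial reference; the sampler against exhaustive
enumeration on 4 × 3 nodes (75 partition pairs, maximum posterior error
≤ 0.02); the correction against the uniform null on Bell(4) = 15
partitions with over $10^5$ samples; the scaled benchmark (100 × 100
nodes, 5 replicates) against the optimal curve at $\lambda \in \{0, 1\}$;
and planted-group recovery (adjusted Rand index of the consensus
partition against the planted one) under well-separated preferences.
These sizes keep the full suite under a couple of minutes on one CPU
while leaving each check statistically sharp.

## Known limitations

* Metropolis sampling over partitions is expensive; ~$10^3$ nodes and
  $10^5$ ratings are practical, an order of magnitude more is not. The
  move set is single-node reassignment only; multi-chain pooling, not
  merge/split moves, is the mitigation.
* The model ignores metadata at inference time (by design — the
  correlation analyses are diagnostics, not features).
* Degree-corrected and mixed-membership block models, non-flat model
  priors, and belief-propagation approximations are out of scope.
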