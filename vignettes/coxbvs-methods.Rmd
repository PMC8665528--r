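---
title: "Methods: subgroup Cox models with graph-structured selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subgroup Cox models with graph-structured selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
model, every tunable parameter, the sampler and its numerical choices,
what the bundled data generators emulate, and what the passing test
suite does and does not establish.

## Model

The data are $S$ pre-defined patient subgroups. Subgroup $s$ contributes
a covariate matrix $X_s \in \mathbb{R}^{n_s \times p}$ (continuous
molecular measurements on a shared gene panel) and right-censored
survival outcomes $(\tilde t_{s,m}, \delta_{s,m})$. Both are treated as
random: the joint likelihood factorizes into a survival part and an
expression part.

**Survival part.** Each subgroup has its own Cox model with a
grouped-data likelihood. The time axis is partitioned at the subgroup's
unique observed event times, with one extra boundary just beyond the
last observed time ($c_J = \max \tilde t \cdot (1 + 10^{-6})$), so every
observation falls in exactly one interval $(c_{g-1}, c_g]$ and tied
event times share one failure set — ties are the reason for using the
grouped likelihood at all. The baseline-hazard increments
$h_{s,g} = H_0(c_{s,g}) - H_0(c_{s,g-1})$ carry independent
$\mathcal{G}(a_0 (H^*(c_{s,g}) - H^*(c_{s,g-1})),\, a_0)$ priors from a
gamma process centred on a Weibull guess $H^*(t) = \eta_s t^{\kappa_s}$,
whose parameters are estimated by maximum likelihood from the training
survival data of the subgroup without covariates
(`survival::survreg`). Degenerate inputs fail loudly: a subgroup without
events has no defined partition; a Weibull fit needs at least two
events.

**Expression part.** Rows of $X_s$ are modelled as
$N_p(0, \Omega_{ss}^{-1})$. Precision matrices carry the continuous
spike-and-slab (SSSL) prior: off-diagonals $N(0, \nu_1^2)$ when the
corresponding edge indicator $g_{ss,ij} = 1$ and $N(0, \nu_0^2)$
otherwise, diagonals $\mathrm{Exp}(\lambda/2)$, restricted to the
positive-definite cone. Edge indicators are Bernoulli($\pi_G$) a
priori. The graph-dependent normalizing constant is never evaluated; it
cancels inside the block Gibbs construction.

**Selection part.** Coefficients follow the spike-and-slab mixture
$\beta_{s,i} \mid \gamma_{s,i} \sim (1-\gamma) N(0, \tau^2) + \gamma
N(0, c^2\tau^2)$. The $pS$ indicators carry a Markov random field prior
$p(\gamma \mid G) \propto \exp(a\,\mathbf{1}'\gamma + b\,\gamma' G
\gamma)$ over the joint adjacency matrix whose diagonal blocks are the
within-subgroup gene–gene graphs and whose off-diagonal blocks are
diagonal (same-gene links only: different genes in different subgroups
are unconnected by construction). The quadratic form runs over the full
symmetric adjacency, so an edge with both endpoints selected contributes
twice — consistent with the factor $2b$ in the conditional
$p(\gamma_{s,i} \mid \cdot) = \mathrm{expit}\{a + 2b_1 \sum_{j \ne i}
\gamma_{s,j} g_{ss,ij} + 2b_2 \sum_{r \ne s} \gamma_{r,i}
g_{rs,ii}\}$. Because $a$ and $b$ are fixed, the intractable MRF
normalizing constant cancels in every Gibbs ratio. The `sub_struct`
variant drops the between-subgroup term ($b_2$-part empty); `subgroup`
and `pooled` replace the MRF prior by independent
Bernoulli($\pi_\gamma$) indicators (the pooled model first merges all
subgroups into one).

## Hyperparameters

All constants live in `coxbvs_hyper()`:

| parameter | default | meaning |
|---|---|---|
| `a0` | 2 | weight of the Weibull guess in the gamma process |
| `tau` | 0.0375 | spike sd; spike coefficients are effectively zero |
| `c` | 20 | slab inflation; slab sd $c\tau = 0.75$, central 95% interval $\pm 1.47$ — a hazard-ratio range of roughly $e^{\pm 1.47}$, wide enough for realistic log-hazard effects of standardized expression |
| `a` | −4 | MRF sparsity; empty-graph prior inclusion $\mathrm{expit}(-4) \approx 0.018$ |
| `b1`, `b2` | 1, 1 | MRF edge rewards within / between subgroups |
| `nu0`, `nu1` | 0.1, 10 | SSSL spike/slab sds for precision entries |
| `lambda` | 1 | rate of the exponential prior on precision diagonals |
| `pi_G` | $\min(2/(p-1), 0.5)$ | prior edge probability, about two edges per node; clamped so tiny-$p$ instances stay valid |
| `pi_gamma` | 0.02 | Bernoulli inclusion probability of the baseline models, matching the MRF's empty-graph level |

`preset = "protein"` switches to the calibration used for
protein-panel plasmode designs: $\nu_0 = 0.6$, $\nu_1 = 360$,
$a = -1.75$, $b_1 = b_2 = 0.5$, $\pi_\gamma = 0.2$.

Covariates are standardized before fitting — per subgroup for the joint
and subgroup models, pooled for the pooled model — and the training
means and sds (sample sd, denominator $n-1$) are stored in the fit and
re-applied to test data, which therefore is *not* re-centred on its own
scale.

## Sampler

Each iteration performs, in a fixed deterministic order driven by a
single seeded RNG stream (so chains are bit-reproducible):

1. **Precision matrices**: one column-block Gibbs sweep per subgroup.
   For column $j$, the off-diagonal block is drawn from
   $N(-C s_{12}, C)$ with
   $C = ((s_{jj} + \lambda)\Omega_{11}^{-1} + \mathrm{diag}(1/v_{12}))^{-1}$,
   $v_{12}$ the edge-specific prior variances, and the shifted diagonal
   from $\mathcal{G}(n/2 + 1, (s_{jj}+\lambda)/2)$; positive definiteness
   is preserved exactly. At $p = 1$ this reduces to the conjugate gamma
   posterior, which the tests verify by a Kolmogorov–Smirnov check.
2. **Edge indicators**: all within-subgroup edges in one vectorized
   Bernoulli draw from
   $p(g=1 \mid \cdot) \propto \pi_G N(\omega_{ij} \mid 0, \nu_1^2)
   e^{2 b_1 \gamma_i \gamma_j}$ versus
   $(1-\pi_G) N(\omega_{ij} \mid 0, \nu_0^2)$; between-subgroup edges
   from $\mathrm{expit}\{\mathrm{logit}(\pi_G) + 2 b_2 \gamma_{r,i}
   \gamma_{s,i}\}$ (no precision entry exists across subgroups). Both
   conditionals are validated against brute-force normalization in the
   tests.
3. **Selection indicators** (`select_sweeps` passes, default 3): for
   each $(s,i)$, first a Gibbs draw of $\gamma_{s,i}$ given
   $\beta_{s,i}$ (MRF conditional odds times the slab/spike density
   ratio), then a joint add/delete move proposing
   $(1-\gamma,\ \beta^* \sim$ the matching prior component$)$. The
   proposal density cancels the spike/slab prior, so the acceptance
   ratio is just the grouped-likelihood ratio times the conditional MRF
   prior odds. This move is what lets a coefficient cross between spike
   and slab without a random-walk excursion through the spike tail,
   where the two regimes barely overlap ($\tau \ll c\tau$); without it,
   chains of practical length stay trapped in the empty model. Repeating
   the (valid) kernel a fixed number of times changes nothing about the
   invariant distribution, only the exploration speed.
4. **Coefficients**: per-coefficient symmetric normal random-walk
   Metropolis steps; the acceptance ratio multiplies the
   grouped-likelihood ratio by the spike-and-slab prior ratio at the
   current indicator. Proposal scales are kept separately for the spike
   and slab states (the two conditional posteriors differ by an order of
   magnitude in width) and adapted every 100 burn-in iterations —
   multiplied by 1.1 when the windowed acceptance exceeds 0.44 and by
   0.9 below 0.23, only in windows with at least 20 attempts in that
   state — then frozen at the end of burn-in to preserve ergodicity.
5. **Baseline increments**: the gamma distribution
   $\mathcal{G}(a_0 \Delta H^* + d_g,\ a_0 + \sum_{k \in R_g - D_g}
   e^{\beta' x_k})$ approximates the full conditional (it linearizes the
   failure-set factors $1 - e^{-h u}$). The package uses it as an
   independence Metropolis–Hastings *proposal* with the exact
   correction, whose log-ratio reduces to the difference of
   $\sum_{l \in D_g} \log(1 - e^{-h u_l}) - d_g \log h$ between proposed
   and current values. Intervals without failures accept always (there
   the gamma *is* the exact conditional). The correction matters: used
   as a plain Gibbs draw, the approximation visibly shifts the
   stationary distribution on coarse partitions, which the quadrature
   oracle test in `test-mcmc.R` would detect. With the correction the
   chain's stationary inclusion probability matches brute-force
   enumeration (with $\beta$ and $h$ integrated by quadrature) within
   one Monte Carlo standard error.

Starting values are the empty model: zero graph, identity precisions,
all indicators zero, $\beta \sim U[-0.02, 0.02]$,
$h \sim \mathcal{G}(1,1)$. Default chain length is 20 000 with 10 000
burn-in; the test suite runs 2 000/1 000 at $p = 20$, $n = 100$ (about
45 s on one core), a size at which the joint model's qualitative
selection behaviour is already stable on a favourable replicate.

Numerical choices: likelihood failure-set terms are evaluated as
`log1p(-exp(-x))`; the final catch-all interval has a vanishing prior
increment ($\Delta H^*$ over a width of $10^{-6} t_{\max}$), so its
draws may underflow to zero — harmless because that interval never
contains failures. A non-finite joint log-likelihood aborts the chain
with the iteration number.

## Posterior summaries and prediction

`summary()` reports selection probabilities, marginal and conditional
(on inclusion) means and sds, and the mean model size $m^*$. Selection
rules: top-$m^*$ (with $m^*$ rounded half-to-even, ties broken by gene
order) and the median probability model (strictly greater than 0.5).
For Bayesian model averaging a "model" is a distinct indicator
configuration visited after burn-in, ranked by the maximum joint
log-likelihood attained over its iterations; coefficients average over
all iterations of the top 100 models. Ranking by individual iterations
instead is available via `rank_by = "iteration"` — the choice between
the two readings of "top models" is genuinely open, so both are
implemented and the distinct-configuration reading is the default.

Prediction uses the plug-in proportional-hazards form
$\hat S(t \mid x) = \exp(-\hat H_0(t) e^{\hat\beta' x})$ with the
posterior-mean increments accumulated over the fitted partition and
linear interpolation inside the current interval. The Brier score uses
inverse-probability-of-censoring weights with the reverse Kaplan–Meier
estimator $\hat C(t)$, by default estimated on the training data of the
same subgroup (`cens_on = "test"` switches to the test outcomes; which
the original analyses used is not documented, so the choice is
exposed). The integrated Brier score is the trapezoid over the
evaluation grid — unique test event times up to $t^*$, defaulting to
the 90th percentile of observed test times — normalized by $t^*$, with
constant extension of the curve to the ends of $[0, t^*]$ so that a
constant curve integrates to itself.

## Synthetic data

`simulate_subgroup_data()` generates the package's two-subgroup study
design: shared multivariate-normal expression with unit variances and
partial correlations of magnitude 0.5 inside the three 3-gene blocks of
prognostic genes (1–3, 4–6, 7–9); effect vectors
$\beta_1 = (1,1,1,-1,-1,-1,0,\dots)$ and
$\beta_2 = (0,0,0,-1,-1,-1,1,1,1,0,\dots)$, so genes 1–3 and 7–9 are
subgroup-specific and genes 4–6 shared; Weibull survival via the
inverse-transform $T = (-\log U / (\eta e^{x\beta}))^{1/\kappa}$ with
per-subgroup parameters obtained by exact two-point inversion of
$S(t) = e^{-\eta t^\kappa}$ through printed Kaplan–Meier survival
probabilities of two cancer cohorts — (57%, 42%) at 3 and 5 years for
subgroup 1 and (75%, 62%) for subgroup 2; which cohort maps to which
subgroup is a package choice. Censoring times are drawn from the same
Weibull *without* the covariate term (non-informative censoring),
giving approximately 50% censoring on standardized covariates; an
option includes the covariate term, which makes the event/censoring
race exactly symmetric.

A note on the block construction: a 3-block with equicorrelated partial
correlations of exactly +0.5 requires precision off-diagonals of −0.5,
which is singular ($1.5 I - 0.5 J$ has eigenvalue 0). The generator
therefore sets the standardized precision off-diagonals to +0.5 — valid
and positive definite, with partial correlations of −0.5, matching the
intended magnitude — and rejects the singular request with an
explanatory error.

`make_plasmode()` implements the plasmode design: a real (or the
bundled synthetic, clearly-labelled `synthetic_protein_matrix()`)
covariate matrix keeps its empirical correlation structure, rows are
split into two equal subgroups at random, and survival is simulated
from chosen effects — by default the 20-column protein-panel pattern in
which phospho-site groups of one protein share an effect, including a
pair of opposite-sign effects across subgroups.

What the generators do **not** emulate: measurement error and batch
effects, non-normal marginals of real expression data, informative
censoring, covariate-dependent censoring distributions, time-varying
effects, and competing risks. Passing tests therefore demonstrate
correctness of the algorithms under the generating model, and the
qualitative power comparison between the joint and baseline models on
such data — not performance guarantees on real cohorts.

## Scope of the test evidence

The suite validates every conditional against an independent oracle
(enumeration, quadrature, conjugate closed forms, hand computation),
checks bit-reproducibility, prior calibration identities, the
simulation design's censoring rate and survival calibration, and the
desk-scale selection ordering (every truly prognostic gene above every
noise gene for the joint model; the pooled model failing at least one
subgroup-specific gene) on a fixed replicate. Replicates differ: in
some data draws a prognostic gene's realized effect is too weak to beat
the noise floor at any chain length, which is why multi-replicate
averaging is the right design for quantitative power studies and why
the packaged check fixes one replicate and seed.

## Limitations

Pure-R single-chain sampler: practical up to a few hundred covariates;
thousands of genes need screening first. No hyperpriors on the MRF
parameters $(a, b)$ — fixed values chosen once, as sensitivity to them
is real and a wrong $b$ can materially change selection. Subgroups must
be known and disjoint; discovering latent subgroups is out of scope, as
are time-varying covariates, left truncation, competing risks, and
concordance-type evaluation metrics.
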