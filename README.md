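# coxbvs

Bayesian Cox proportional-hazards models for **pre-defined patient
subgroups** (cohorts, data sets, centres) with spike-and-slab variable
selection linked across subgroups by a jointly inferred graph.

## The problem

Molecular risk models are usually built either per cohort (losing power
when cohorts are small) or on the pooled data (biasing estimates when
cohorts are heterogeneous). `coxbvs` fits a **separate Cox model per
subgroup** while **borrowing strength across subgroups** through the
selection prior, so that genes which are conditionally dependent within
a subgroup, or simultaneously prognostic in several subgroups, reinforce
each other's selection. It is aimed at settings with continuous
molecular covariates (gene or protein expression), right-censored
survival, and small-to-moderate samples per cohort (p comparable to or
exceeding n).

## The model

For subgroup *s* with covariates X_s and survival data D_s:

* **Likelihood.** The grouped-data Cox likelihood over a partition
  0 = c_0 < ... < c_J of follow-up time,

  L(D_s | β_s, h_s) ∝ ∏_g exp(−h_g Σ_{k∈R_g−D_g} e^{β_s'x_k})
  ∏_{l∈D_g} (1 − e^{−h_g e^{β_s'x_l}}),

  with risk sets R_g, failure sets D_g (ties are handled naturally) and
  baseline-hazard increments h_g under a gamma-process prior
  h_g ~ Gamma(a₀·ΔH*, a₀) centred on a Weibull guess H*(t) = η t^κ
  fitted to the training survival data. The covariates are modelled as
  N(0, Ω_ss⁻¹), giving the Gaussian-graphical part of the likelihood.
* **Selection prior.** Each coefficient has a spike-and-slab mixture
  β_{s,i} | γ_{s,i} ~ (1−γ) N(0, τ²) + γ N(0, c²τ²) with τ = 0.0375,
  c = 20 (slab sd 0.75). The pS inclusion indicators carry a **Markov
  random field prior** p(γ | G) ∝ exp(a·1'γ + b·γ'Gγ) over a joint graph
  G with gene–gene edges within each subgroup and same-gene edges
  between subgroups (a = −4, b = 1 by default; prior inclusion
  probability expit(−4) ≈ 0.018 under an empty graph).
* **Graph prior.** Precision matrices follow the continuous
  spike-and-slab (SSSL) prior with edge indicators
  (ν₀ = 0.1, ν₁ = 10, λ = 1, π_G = 2/(p−1)), sampled by the
  positive-definiteness-preserving column-block Gibbs sampler.
* **Posterior.** A Gibbs/Metropolis sampler updates Ω, G, γ, β, h in
  turn. Summaries include posterior selection probabilities, the median
  probability model (prob > 0.5), mean-model-size selection, Bayesian
  model averaging over the top visited models, and IPCW (integrated)
  Brier scores on held-out data.

Model variants: `coxbvs_sl` (the joint model), `sub_struct` (no
between-subgroup edges), `subgroup` (independent Bernoulli prior per
subgroup), `pooled` (single model on the merged data) — the latter two
are the classical baselines.

## Worked example

Simulate the package's two-subgroup study design (p = 20 genes, n = 100
per subgroup; genes 1–3 prognostic only in subgroup 1, genes 7–9 only in
subgroup 2, genes 4–6 shared; correlated in 3-gene blocks), fit the
joint model, and evaluate it:

```r
library(coxbvs)
sim <- simulate_subgroup_data(p = 20, n = 100, seed = 7)
fit <- coxbvs(sim$train, model = "coxbvs_sl",
              control = coxbvs_control(n_iter = 2000, burn_in = 1000, seed = 1))
print(fit)
#> Bayesian Cox variable-selection model (coxbvs_sl)
#>   subgroups: 1, 2  genes: 20
#>   iterations: 2000 (burn-in 1000 ), seed 1
#>   mean MH acceptance rate: 0.364
#>   mean model size: 6.18, 4.88

print(summary(fit), top = 4)
#> Subgroup 1 (top 4 by selection probability):
#>    gene prob cond_mean
#> 1 gene1    1     1.113
#> 2 gene3    1     0.962
#> 3 gene4    1    -1.010
#> 4 gene5    1    -0.975
#> Subgroup 2 (top 4 by selection probability):
#>    gene  prob cond_mean
#> 1 gene6 0.813    -0.907
#> 2 gene7 0.807     0.946
#> 3 gene4 0.803    -0.853
#> 4 gene5 0.803    -0.721

pe <- prediction_error(fit, sim$test)   # IPCW Brier / IBS per subgroup
#> IBS subgroup 1: 0.146   IBS subgroup 2: 0.138

head(edge_probabilities(fit)[order(-edge_probabilities(fit)$probability), ], 4)
#>  subgroup_pair gene_i gene_j probability
#>            1-1  gene4  gene5       1.000
#>            1-1  gene4  gene6       1.000
#>            1-1  gene5  gene6       1.000
#>            1-1  gene8  gene9       0.999
```

The mean model size (~6 in subgroup 1) matches the number of truly
prognostic genes; the conditional posterior means recover the simulated
effects (±1); and the inferred within-subgroup graph picks out the
correlated prognostic blocks. True-gene selection probabilities exceed
every noise gene's probability, while the pooled baseline misses the
subgroup-specific effects — the motivating contrast for the joint model.

Data can also be read from CSV/TSV (`load_multi_subgroup`), split by
subgroup and event status (`stratified_split`), and driven from a shell
via `inst/scripts/coxbvs-cli.R` (subcommands `simulate`, `fit`,
`summarize`, `evaluate`).

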