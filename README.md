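# aceindex

Composite neighborhood-adversity indexes for adverse childhood experience
(ACE) research: build them four ways, compare them, and carry the winner into
multilevel outcome models.

## The scientific problem

Childhood adversity clusters geographically. Researchers summarizing a
neighborhood's risk environment face a mixture problem: dozens of correlated
census-tract variables (poverty, violent crime, housing vacancy, greenspace,
...) must be collapsed into a single per-person index that best explains high
ACE exposure (4+ ACEs vs 0–3). `aceindex` implements and compares four index
construction strategies on the same data:

1. **Threshold-based PCA** — iterative principal-components variable
   reduction: starting from 2 components, grow the component count until every
   component has at least 4 high-loading variables (|loading| ≥ 0.15 with a
   ≥ 0.10 margin over every other component), dropping variables that load
   highly nowhere, and restarting after each drop.
2. **First principal component** — the classic single-axis deprivation index.
3. **Supervised PCA** — the leading direction of the outcome-covariance
   kernel, so the axis is chosen *for* its association with the outcome.
4. **Bayesian index regression** — a weighted-quantile-sum logistic model,
   `logit(p) = β0 + β1 Σ_j w_j q_ij`, where `q_ij` are decile scores and the
   weights `w` live on the probability simplex under a Dirichlet(1,…,1)
   prior, fitted by an adaptive Metropolis-within-Gibbs sampler with Geweke
   convergence diagnostics.

Candidate indexes are compared by AIC from per-index logistic regressions
(differences ≥ 3 treated as meaningful; a multi-component method is
collectively worse if *any* of its components is meaningfully worse). The
selected index then enters a suite of random-intercept (census tract) linear
models of BMI, with variance-inflation-factor collinearity checks and an
ACE-coefficient attenuation summary.

Because individual-level ACE survey data are typically restricted, the
package ships a synthetic-data generator with a latent-factor correlation
structure, known true weights, a calibrated outcome prevalence, and nested
tract/participant BMI structure — so every method can be validated against
ground truth.

## Worked example

Simulate a study (200 tracts, 1,500 participants, 25 neighborhood variables,
a deliberately strong index effect of OR = 2.5 per weighted decile so the
demo is legible) and run the whole pipeline:

```r
library(aceindex)

cfg <- run_config(
  simulate = sim_config(n_tracts = 200, n_participants = 1500,
                        beta1 = log(2.5), seed = 7),
  mcmc = mcmc_settings(n_iter = 4000, n_burnin = 2000, n_adapt = 500,
                       seed = 7))
res <- run_pipeline(cfg)

res$comparison
#> Index method comparison (lower AIC is better)
#>      method component     aic delta_aic meaningfully_worse
#>   threshold       PC1 1942.79   +135.23               TRUE
#>   threshold       PC2 1939.92   +132.35               TRUE
#>    first_pc     index 1943.52   +135.96               TRUE
#>  supervised     index 1843.05    +35.48               TRUE
#>       bayes     index 1807.56     +0.00              FALSE
#> Collectively meaningfully worse (delta AIC >= 3 ): threshold, first_pc, supervised
#> Selected method: bayes

res$bayes_fit$summary
#> Posterior summary (medians, 95% CrI)
#>   param median  lower upper geweke_z
#>   beta0  -5.36 -6.324 -4.28  -0.4366
#>   beta1   1.04  0.806  1.24   0.4503
#>  sigma1   9.23  0.700 92.55  -0.0088
#> Odds ratio exp(beta1): 2.827 (2.239, 3.471) *
#> Geweke convergence: NOT converged
#> Median weights range: 0.0112 - 0.1209

res$suite$models$model3
#> Random-intercept linear model: 1500 obs in 200 clusters
#>         term estimate    se  lower upper     z        p
#>  (Intercept)   27.279 1.430 24.476 30.08 19.07 4.31e-81
#>        index    0.499 0.338 -0.163  1.16  1.48 1.40e-01
#>         ace4    1.104 0.356  0.406  1.80  3.10 1.95e-03
#> Cluster variance: 1.8487  Residual variance: 38.2197
```

The posterior odds-ratio interval (2.24, 3.47) covers the generating value
2.5, and the Bayesian index wins the AIC comparison by a wide margin on data
generated from its own model class. The `NOT converged` flag is honest
single-chain Geweke screening across all 28 parameters at this short
schedule — lengthen the chain (`mcmc_settings()`) for production use.

Set `output_dir` in `run_config()` to write every intermediate artifact
(oriented-variable summary, index definitions as JSON, MCMC chains, posterior
summary, comparison table, model suite, and a manifest with the seed and a
config hash).

Real data enter through `read_tables(tract_file, participant_file, specs)`:
comma-separated tables validated for ranges, unique tract ids, and
referential integrity, with a `variable_spec()` per neighborhood variable
declaring its scale (`percent`/`rate`) and direction (inverse-direction
variables such as greenspace are re-oriented with `max(x) − x`).

## Documentation

See the vignette source in `vignettes/` for the full methodology: the
generative model behind the simulator, every algorithmic parameter, the
decile tie convention, sampler design (log-scale random-walk updates on
unnormalized Gamma weights, batch adaptation toward 44% acceptance), and
known limitations.

## License

MIT.
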