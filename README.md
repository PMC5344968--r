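# seedshadow

Inverse estimation of seed dispersal kernels from seed-trap counts in
mapped stands, plus the downstream demographic stages needed to turn a
lost fruit–frugivore mutualism into a number: the predicted decline in
seedling recruitment when the frugivores are gone.

The package is written for ecologists comparing seed dispersal and
recruitment between forests with and without their frugivore
community — the motivating system is an island whose forest birds were
extirpated by an invasive predator, compared with neighbouring islands
where the birds persist — but every component is generic: mapped
conspecific trees, seed traps, germination trials, and near/far
survival experiments.

## The model

A parent tree's **seed shadow** is its seed output (proportional to
basal area *b*, with lognormal site-level fecundity β_s) times an
isotropic 2D dispersal kernel *f(r)*. The expected count in trap *j*
with area *A* is

    mu_j = A * sum_i beta_s * b_i * f(r_ij)

with a negative-binomial likelihood whose variance is the quadratic
polynomial `Var = mu(1+k1) + k2*mu^2`. Two kernel families are
supported with fixed shapes: the power-exponential
`f(r) = p/(2*pi*a^2*Gamma(2/p)) * exp(-(r/a)^p)` at p = 0.5, and the
2Dt `f(r) = p/(pi*a^2) * (1 + r^2/a^2)^-(p+1)` at p = 1. The scale *a*
(metres) is estimated in a hierarchical Bayesian framework (seeded
blocked Metropolis-within-Gibbs; Gelman–Rubin diagnostics), and six
candidate models — two families × three hypotheses about island-level
scales (shared / bird-free island distinct / all distinct) — are
compared by DIC.

Binomial GLM/GLMM stages (AICc selection, profile-likelihood CIs)
model germination by fruit handling, the probability a trapped seed
was bird-ingested as a function of distance to the nearest adult, and
distance-dependent (Janzen–Connell) seedling survival. Everything
composes into overall seed-to-seedling survival

    phi = integral g(r) * [ p(I|r) p(G|I=1,r) + (1-p(I|r)) p(G|I=0,r) ]
                      * p(S1|r) * p(S2|r) dr

evaluated under frugivore-present and frugivore-absent scenarios; the
ratio `phi_absent / phi_present` (and the decline `1 - ratio`) is the
headline metric, with Monte-Carlo propagation of the kernel posterior
and the stage-coefficient sampling distributions.

A synthetic-data generator reproduces the study designs (13
wedge-shaped 17-trap arrays = 221 traps; three-treatment nursery
trials; 1,120 outplanted seedlings; 900 seeds sown per distance
category) with known ground truth, including an oracle value of the
survival ratio obtained by forward-simulating a million seeds.

## Worked example

```r
library(seedshadow)

# simulate a study with known truth
world <- simulate_world(world_config(species = "Premna", seed = 42))
#> synthetic Premna study: 221 traps, 104 trees, 371 germination trials
#>   true seed-to-seedling survival ratio (no birds : birds): 0.241

# hierarchical Bayesian kernel fit: does the bird-free island differ?
fit <- fit_dispersal(world$stand, family = "t2d",
                     hypothesis = "guam_vs_rest", seed = 1,
                     n_chains = 3, n_retain = 500, burn_in = 2000, thin = 2)
fit
#> hierarchical dispersal-kernel fit: t2d kernel, guam_vs_rest scales
#>   3 chains x 500 draws (burn-in 2000, thin 2)
#>   a[Guam]: posterior mean 0.384 m (95% CrI 0.288-0.513)
#>   a[birds]: posterior mean 3.49 m (95% CrI 3.13-3.94)
#>   max R-hat 1.039 (converged)

# germination by fruit handling (log-odds vs whole fruit)
fit_germination_glm(world$germination)
#> binomial stage fit [germination]: best model 'treatment' (n = 371)
#>       (Intercept) treatmentdepulped treatmentingested
#>           -1.6405            0.6903            1.6939

# recruitment decline with full uncertainty propagation
stages <- list(
  germination = fit_germination_glm(world$germination),
  ingestion = fit_ingestion_distance(world$stand),
  survival = fit_seedling_survival(world$survival),
  field_germination = fit_field_germination(world$seed_addition, "germination"),
  field_survival = fit_field_germination(world$seed_addition, "survival"))
res <- propagate_uncertainty(fit, stages, n_draws = 1000, seed = 2)
res
#> seed-to-seedling recruitment metric (1000 draws, t2d kernel)
#>   phi (birds present): mean 0.08881; phi (birds absent): mean 0.02184
#>   recruitment decline 1 - phi_absent/phi_present: 75.5% (95% CI 66.0-84.0%)
```

Reading the output: the posterior scales say seeds travel an order of
magnitude farther where birds are present (mean dispersal distance
`pi*a/2` ≈ 0.60 m vs 5.5 m for the 2Dt); bird-ingested seeds germinate
at 1.69 log-odds above whole fruit (≈ 3× the probability); and
composing dispersal, ingestion, germination and the two survival
stages predicts that losing the birds cuts recruitment by about 75%
(the generator's known truth, 1 − 0.241 = 75.9%, sits inside the
interval).

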