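# memtraj

Bayesian nonparametric phenotyping of longitudinal declarative-memory
trajectories.

Longitudinal cognition studies usually summarize each test with one
population-average rate of change, which can mask subgroups whose memory
declines much faster (or not at all). `memtraj` is for epidemiologists and
biostatisticians who want to *discover* such subgroups from repeated
neuropsychological testing — here, the four declarative-memory measures of
the Hopkins Verbal Learning Test–Revised on a scaled-score metric
(reference mean 10, SD 3) — and then ask which baseline and cumulative
exposures predict membership. It was designed around semiannual
observational cohorts of women with and without HIV, analyzed within
serostatus-by-race strata.

## The model

Subject *i*'s outcome *g* at visit *k* follows a linear trajectory in
decades since her first test, `u_ik = (age_ik − age_i1)/10`:

    y_igk = α_ig + β_ig u_ik + ε_igk,          ε_igk ~ N(0, σ_g²)
    θ_i   = (α_i·, β_i·) = μ_{z_i} + Λ η_i + d_i,
    η_i ~ N(0, I_q),  d_i ~ N(0, diag(ψ)),
    z_i ~ CRP(a),  μ_c ~ N(m0, s0² I),  a ~ Gamma(1, 1)

A latent factor model (Λ, q = 2) absorbs the correlation among the 2G
coefficients; the Dirichlet-process prior on the coefficient means μ
induces a data-driven clustering on intercepts *and* slopes jointly. A
blocked Gibbs sampler (RcppArmadillo) runs 20,000 sweeps by default
(10,000 burned); draws are summarized by the posterior similarity matrix
and the partition maximizing the posterior expected adjusted Rand index
(PEAR) over average-linkage dendrogram cuts. Clusters with fewer than 15
members are set aside as outliers. Retained clusters are characterized by
mixed-effects rates of change per decade (lme4, Wald 95% CI), compared by
likelihood-ratio tests, contrasted against the motor domain, and related
to covariates with multinomial logistic membership models.

## Worked example

Simulate a cohort in the emulated study's regime (four latent clusters
with baseline scaled scores near 12.8/10.5/8.5/6.4 and per-decade slopes
−0.85…−0.24, ~2.1-year visit gaps, 1% item missingness), impute, cluster,
and characterize:

```r
library(memtraj)
cfg <- sim_config(n_subjects = 300, seed = 42,
                  loading_scale = 0.4, slope_loading_scale = 0.15)
g <- generate_cohort(cfg)
cohort <- impute_missing_items(g$cohort)
fit <- cluster_trajectories(cohort, mcmc = mcmc_control(4000, 2000, seed = 1))
fit$partition
#> Trajectory partition (maxpear): 4 cluster(s), sizes 129/93/34/33; 11 excluded; PEAR = 0.9674
```

Four phenotypes emerge; 11 subjects fall in no distinct cluster and are
excluded. Per-cluster total-learning summaries (baseline level at first
test and change per decade of age):

```r
fit_cluster_trajectories(cohort, fit$partition, "total_learning")
#>   cluster n_subjects baseline_mean baseline_sd  slope ci_lower ci_upper
#> 1       1        129         10.23        1.34 -0.591  -1.0282   -0.154
#> 2       2         93          8.49        1.38 -0.894  -1.3622   -0.425
#> 3       3         34          6.19        1.47  0.144  -0.5764    0.865
#> 4       4         33         12.28        1.42  0.791   0.0564    1.526

lrt_rate_difference(cohort, fit$partition, "total_learning")
#> 	Likelihood-ratio test for cluster x time interaction
#> data:  total_learning
#> chi-squared = 15.999, df = 3, p-value = 0.001135
```

The partition recovers the generating clusters with adjusted Rand index
0.988, and the LRT confirms the clusters differ in their rates of change.
`cross_domain_contrast()` reruns the same test on the timed motor
outcomes to check whether memory phenotypes track another domain, and
`membership_model()` / `multivariable_membership()` relate membership to
covariates such as education or cumulative depression exposure (built
with `cumulative_exposures()`: exposed at 10 of 30 pre-testing visits
gives 0.33).

A thin command-line runner lives at `inst/scripts/memtraj.R`
(`simulate`, `cluster`, `run-all` subcommands over CSV/YAML artifacts);
`run_stratified()` executes the whole pipeline independently within
strata and writes per-stratum artifacts plus a JSON manifest.

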