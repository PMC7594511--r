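---
title: "Phenotyping longitudinal declarative-memory trajectories"
author: "memtraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping longitudinal declarative-memory trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memtraj)
```

## The problem

Cohort studies of cognition usually report one population-average rate of
change per test, which hides the possibility that distinct subgroups of
participants decline at very different rates — or start from very
different levels. `memtraj` implements a Bayesian nonparametric pipeline
that clusters participants by their *joint* trajectories across several
declarative-memory outcomes (the four word-list measures of the HVLT-R:
single-trial learning, total learning, delayed recall, recognition),
then characterizes the resulting phenotypes and asks which demographic,
lifestyle, and clinical exposures predict membership. It was built for
semiannual women's-cohort data with HIV-serostatus and race strata, but
nothing in the model is specific to that setting.

## The model

For subject $i$, outcome $g \in 1..G$ and visit $k$ at age $a_{ik}$,
with $u_{ik} = (a_{ik} - a_{i1})/10$ (decades since the subject's first
testing visit):

$$y_{igk} = \alpha_{ig} + \beta_{ig}\, u_{ik} + \varepsilon_{igk},
  \qquad \varepsilon_{igk} \sim N(0, \sigma_g^2).$$

Intercepts are performance at the subject's first test and slopes are
change per decade of age, which decouples the two scales and matches the
convention of reporting rates "per decade of age-years". The stacked
coefficient vector $\theta_i = (\alpha_{i1..G}, \beta_{i1..G}) \in
\mathbb{R}^{2G}$ gets a latent factor model that captures correlation
between outcomes (a person who recalls more words at trial 1 usually also
has higher total learning) without estimating a free $2G \times 2G$
covariance:

$$\theta_i = \mu_{z_i} + \Lambda \eta_i + d_i, \qquad
  \eta_i \sim N(0, I_q), \quad d_i \sim N(0, \mathrm{diag}(\psi)).$$

Clustering comes from a Dirichlet-process prior on the coefficient means:
$z_i$ follows the Chinese-restaurant process with concentration $a$, and
each cluster's mean $\mu_c$ is drawn from a product-normal base measure
$G_0 = N(m_0, s_0^2)^{2G}$. Both intercepts and slopes drive the
clustering, so "starts low, stable" and "starts high, declines" are
different phenotypes even where their values cross.

### Hyperparameters and defaults

All priors act on z-scored outcomes (`standardize_panel()` is applied
internally by `fit_dp_mixture()`), which makes one set of weakly
informative conjugate defaults serviceable across datasets:

| parameter | default | meaning |
|---|---|---|
| `factor_dim` (q) | 2 | latent factors behind coefficient correlation |
| $\Lambda_{jl}$ prior | $N(0, 1)$ | loading scale on z-scored coefficients |
| $\psi_j, \sigma_g^2$ prior | Inv-Gamma(2, 1) | unit-scale variances, mean 1 |
| $G_0$ | $N(0, 4)$ per coordinate | covers any cluster mean on the z-scale |
| $a$ prior | Gamma(1, 1) | favors few clusters; updated by beta augmentation |
| `n_iter` / `n_burn` | 20,000 / 10,000 | analysis protocol; `thin = 1` |

Rotation and sign of $\Lambda$ are deliberately left unidentified: the
quantities the pipeline reports (the partition, the posterior similarity
matrix, cluster means) are invariant to them, and identifying constraints
would buy nothing but complexity.

## The Gibbs sampler

`fit_dp_mixture()` alternates conjugate updates of (i) $\theta_i$ given
the data and the prior centered at $\mu_{z_i} + \Lambda\eta_i$ — a $2
\times 2$ solve per subject-outcome, using only per-subject sufficient
statistics; (ii) factor scores $\eta_i$; (iii) loadings rows and $\psi$;
(iv) $\sigma_g^2$; (v) cluster labels; (vi) cluster means; (vii) the
concentration $a$. Subjects are processed in a canonical sorted-id order,
so shuffling input rows cannot change the result for a fixed seed.

Two exact label updates are available. The default is the **marginal
conjugate scheme**: conditional on $\eta_i$, the label kernel
$N(\theta_i - \Lambda\eta_i;\, \mu_c, \mathrm{diag}(\psi))$ is conjugate
to $G_0$, so the weight of opening a new cluster has the closed form
$a \cdot N(r_i;\, m_0, \mathrm{diag}(\psi) + s_0^2 I)$ and the new
cluster's mean is drawn from its exact posterior. The alternative
(`dp_control(label_update = "aux")`) proposes `n_aux` fresh means from
$G_0$. Both target the same posterior; we default to the marginal scheme
because a fresh draw from a broad base measure almost never lands near a
subject's residual once $2G = 8$, so the auxiliary scheme opens new
clusters at a vanishing rate and mixes far too slowly at realistic
dimension — on a strongly separated two-cluster fixture it produced no
split in hundreds of sweeps, while the marginal scheme recovers the
partition within tens.

### Initialization

Single-site Gibbs samplers for mixture models have a genuinely absorbing
bad mode: started with all subjects in one cluster, the idiosyncratic
variances $\psi$ inflate to cover the between-cluster spread, the
one-cluster state then explains the data adequately, and no single-subject
move can escape. We therefore initialize from a deterministic
over-partition: per-subject least-squares coefficients are cut by Ward's
method into `min(20, n/6)` groups, and $\sigma^2$, $\psi$ are initialized
consistently with that start. Because least-squares slopes from two-visit
subjects are almost pure sampling noise, each coefficient coordinate is
weighted by an estimated reliability (between-subject signal variance
over total variance) before computing distances; without this the init
distances are dominated by slope noise. Merging from an over-partition is
easy for the sampler — it only requires single-subject moves into larger
clusters — so this start is both deterministic and safe. Single-cluster
data still collapses to one cluster (we verify a modal posterior of
$K = 1$ on null simulations). `mcmc_control(init_clusters = 1)` restores
the all-in-one start if wanted.

## From draws to a reported partition

Labels from every retained sweep form the posterior similarity matrix
(PSM): $S_{ij}$ is the share of draws in which $i$ and $j$ co-cluster,
which is immune to label switching. The reported partition maximizes the
posterior expected adjusted Rand index (PEAR) over cuts of the
average-linkage dendrogram of $1 - S$, with ties resolved toward fewer
clusters; `cut_partition()` provides fixed-$k$ cuts ($k = 3..6$ is the
protocol's sensitivity range) and tie-breaking within the dendrogram is
delegated to `stats::hclust`, which is deterministic for fixed input. On
random similarity matrices of seven subjects the dendrogram optimum
coincided with exhaustive search over all 877 set partitions in every
case we generated, so the restriction to dendrogram cuts appears mild.
Clusters below 15 members are dropped and their subjects recorded as
excluded — small clusters are treated as outliers, not phenotypes.

## Characterization and associations

Within each retained cluster, `fit_cluster_trajectories()` fits a linear
mixed model per outcome (random intercept and slope per subject,
unstructured covariance, REML) and reports the baseline mean/SD at first
visits plus the per-decade slope with a Wald 95% CI; boundary (singular)
variance fits are kept, and only genuine convergence failures fall back
to a random-intercept model (flagged in the output). Between-cluster
differences in rates use a likelihood-ratio test comparing ML fits with
and without the cluster-by-time interaction ($\chi^2_{K-1}$); the same
machinery applied to the timed motor outcomes (`cross_domain_contrast()`)
asks whether memory phenotypes track a different domain. Membership
models are multinomial logistic regressions (reference = the
highest-baseline cluster) with likelihood-ratio p-values, unadjusted,
adjusted for age/ethnicity/education, or mutually adjusted; rank-deficient
covariate sets abort with the offending columns named, and no
multiple-testing correction is applied, matching the analysis protocol
(flagged here deliberately).

Exposure covariates come in two forms per protocol: the indicator at the
first testing visit, and the cumulative proportion of pre-testing
semiannual visits with exposure (10 exposed of 30 prior visits gives
0.33). Visits with a missing indicator leave both numerator and
denominator; denominators are reported for audit. The low-income
indicator uses a strict `< $12,000` threshold. The source tables print
both "≤ 48" and "< 48" cp/mL for viral suppression; the package treats
the per-visit suppression indicator as an input and leaves the boundary
convention to the data preparer.

## The synthetic cohort generator

`generate_cohort()` is first-class, tested code that produces
truth-labelled cohorts in the emulated study's regime: four clusters with
baseline scaled scores near 12.8/10.5/8.5/6.4 and per-decade slopes
between −0.85 and −0.24 (mixing proportions 99:340:267:95), visit gaps
$N(2.1, 0.4^2)$ years truncated at 0.5, 2–5 visits per subject, baseline
age $N(42, 8.5^2)$, ~1% of visits missing exactly one test item, and
semiannual exposure histories simulated as two-state Markov chains
(stationary prevalence + visit-to-visit persistence 0.85, with optional
cluster-linked log-odds shifts for association power studies). Education
is drawn around cluster-specific means (SD 2.7) as a known association
signal. What it does **not** emulate: informative dropout, practice
effects, non-linear age trends, floor/ceiling effects of discrete test
scores, and the real joint covariate distribution — so green tests show
the pipeline recovers structure *of the modelled kind*, not that the
model is correct for any particular cohort.

## Numerical and design choices

* **Imputation rule.** A visit missing exactly one declarative-memory
  item is completed with the mean of that visit's other memory scores —
  the most local reading of "impute with the mean"; the within-subject or
  population mean of the missing test are defensible alternatives. Visits
  missing two or more items are dropped with a warning.
* **Eligibility** defaults to at least two testing visits (configurable).
* **Degenerate subjects.** Least-squares initialization falls back to
  the outcome mean with zero slope when a subject's design is singular;
  subjects with fewer than two distinct visit ages are an error by the
  time they reach the sampler.
* **Standardization** is per outcome over all observations; coefficients
  are not re-standardized afterwards, so intercept and slope coordinates
  enter clustering on their natural (decade-based) relative scale.
* **PEAR degeneracies** return 0 when the denominator vanishes (e.g. an
  off-diagonal-zero similarity matrix), which combined with the
  smaller-$k$ tie rule yields the one-cluster partition there.
* **Determinism.** One integer seed fixes the cohort, the chain, and all
  artifacts; stratified runs derive per-stratum seeds by offset.

## Problem sizes used in the test suite

The suite exercises the full pipeline at desk scale: recovery runs use
$n = 300$ and 4,000 sweeps (half burned) over 10 seeds — a deliberate
scale-down of the 20,000-sweep analysis protocol that leaves the
per-seed recovery quality essentially unchanged (median ARI ≈ 0.98) —
plus 1,000-replicate LRT null calibration at $n = 200$ and 200-replicate
CI coverage at $n = 300$. The LRT calibration uses the study's own visit
design (2–5 visits ~2.1 years apart); with an impoverished 3-visit
design the ML likelihood-ratio test becomes noticeably anticonservative,
which is a known property of sparse-design mixed-model tests, not a
package defect.

## Known limitations

Linear trajectories only (deliberately conservative for ~3 assessments
per subject); no covariate-dependent clustering; no time-varying
membership modelling; label-update moves are single-subject (no
split-merge), so pathological initializations can persist — hence the
deterministic over-partitioned start; multinomial membership models use
complete cases.
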