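test_that("two separated clusters are recovered exactly (n = 120, G = 4)", {
  g <- generate_cohort(two_cluster_config(seed = 7))
  fit <- cluster_trajectories(g$cohort,
                              mcmc = mcmc_control(1000, 500, seed = 1))
  truth <- g$truth$clusters[names(fit$partition$labels)]
  expect_equal(ari(fit$partition$labels, truth), 1)
  expect_equal(fit$partition$k, 2)
})

test_that("single-cluster data yields a modal posterior of one cluster", {
  cfg <- sim_config(n_subjects = 100, cluster_props = 1,
                    cluster_intercepts = matrix(10, 1, 4),
                    cluster_slopes = matrix(-0.5, 1, 4),
                    loading_scale = 0.5, slope_loading_scale = 0.2,
                    item_missing_rate = 0, seed = 3)
  g <- generate_cohort(cfg)
  fit <- fit_dp_mixture(g$cohort, mcmc = mcmc_control(4000, 2000, seed = 2))
  expect_gte(mean(fit$n_clusters == 1), 0.5)
})

test_that("fixed seed gives identical draws; permuted input gives the same PSM", {
  g <- generate_cohort(two_cluster_config(n = 30, seed = 15))
  m <- mcmc_control(400, 200, seed = 5)
  f1 <- fit_dp_mixture(g$cohort, mcmc = m)
  f2 <- fit_dp_mixture(g$cohort, mcmc = m)
  expect_identical(f1$labels, f2$labels)

  # shuffle cohort rows: canonical subject ordering makes the fit invariant
  perm <- sample(nrow(g$cohort))
  f3 <- fit_dp_mixture(g$cohort[perm, ], mcmc = m)
  expect_identical(f1$labels, f3$labels)
  expect_equal(posterior_similarity(f1), posterior_similarity(f3))
})

test_that("sampler errors on underdetermined or non-finite input", {
  coh <- data.frame(subject_id = c("a", "a", "b"),
                    age_years = c(40, 42, 40),
                    outcome = "y", value = c(1, 2, 3))
  expect_error(fit_dp_mixture(coh, outcomes = "y"), "fewer than 2 visits")
  coh2 <- data.frame(subject_id = rep(c("a", "b"), each = 2),
                     age_years = rep(c(40, 42), 2),
                     outcome = "y", value = c(1, NA, 3, 4))
  expect_error(fit_dp_mixture(coh2, outcomes = "y"), "non-finite")
})

test_that("factor-free sampler matches the conjugate closed form at fixed labels", {
  set.seed(42)
  n <- 24
  lab <- rep(1:2, each = n / 2)
  psi <- c(0.4, 0.2); s2 <- 0.25; m0 <- 0; s02 <- 4
  mu_true <- rbind(c(-1, -0.3), c(1.5, 0.5))
  ids <- sprintf("S%02d", 1:n)
  rows <- lapply(1:n, function(i) {
    k <- 4
    ages <- 40 + c(0, cumsum(runif(k - 1, 1.5, 2.5)))
    u <- (ages - ages[1]) / 10
    th <- mu_true[lab[i], ] + rnorm(2, 0, sqrt(psi))
    data.frame(subject_id = ids[i], age_years = ages, outcome = "y",
               value = th[1] + th[2] * u + rnorm(k, 0, sqrt(s2)))
  })
  coh <- do.call(rbind, rows)

  # oracle: exact Gaussian posterior of the cluster means by GLS, with the
  # subject coefficients integrated out of the likelihood
  posterior_mu <- function(cl) {
    P <- diag(2) / s02
    b <- rep(m0 / s02, 2)
    for (i in which(lab == cl)) {
      d <- coh[coh$subject_id == ids[i], ]
      u <- (d$age_years - d$age_years[1]) / 10
      X <- cbind(1, u)
      Vi <- solve(X %*% diag(psi) %*% t(X) + s2 * diag(length(u)))
      P <- P + t(X) %*% Vi %*% X
      b <- b + t(X) %*% Vi %*% d$value
    }
    drop(solve(P, b))
  }
  oracle <- rbind(posterior_mu(1), posterior_mu(2))

  ctrl <- dp_control(fix_loadings = TRUE, fixed_labels = lab,
                     fixed_sigma2 = s2, fixed_psi = psi,
                     base_mean = m0, base_var = s02)
  fit <- fit_dp_mixture(coh, outcomes = "y", control = ctrl,
                        mcmc = mcmc_control(6000, 1000, seed = 9),
                        standardize = FALSE)
  idx <- match(fit$subject_ids, ids)
  est <- rbind(colMeans(fit$coef_mean[lab[idx] == 1, ]),
               colMeans(fit$coef_mean[lab[idx] == 2, ]))
  expect_equal(unname(est), unname(oracle), tolerance = 0.05)
})

test_that("the auxiliary-component label update also recovers separated clusters", {
  g <- generate_cohort(two_cluster_config(n = 60, gap = 8, seed = 23))
  fit <- cluster_trajectories(
    g$cohort, control = dp_control(label_update = "aux"),
    mcmc = mcmc_control(2500, 1500, init_clusters = 10, seed = 4),
    min_size = 10)
  truth <- g$truth$clusters[names(fit$partition$labels)]
  expect_gte(ari(fit$partition$labels, truth), 0.9)
})
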