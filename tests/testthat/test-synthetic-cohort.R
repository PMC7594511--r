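test_that("generated cohorts honour the count contract and reproducibility", {
  cfg <- sim_config(n_subjects = 100, seed = 7)
  g <- generate_cohort(cfg)
  expect_equal(length(unique(g$cohort$subject_id)), 100)
  visits <- tapply(g$cohort$age_years, g$cohort$subject_id,
                   function(a) length(unique(a)))
  expect_true(all(visits >= 2))
  expect_true(all(tapply(g$cohort$age_years, g$cohort$subject_id,
                         function(a) all(diff(sort(unique(a))) > 0))))
  expect_length(g$truth$clusters, 100)
  expect_equal(dim(g$truth$theta), c(100, 8))

  g2 <- generate_cohort(cfg)
  expect_identical(g, g2)
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(cluster_props = c(0.6, 0.6)), "sum to 1")
  expect_error(sim_config(item_missing_rate = 1), "item_missing_rate")
  expect_error(sim_config(n_visits_range = c(1, 3)), "n_visits_range")
  expect_error(sim_config(residual_sd = 0), "standard deviations")
  expect_error(
    sim_config(cluster_intercepts = matrix(10, 2, 4)),
    "cluster_intercepts")
})

test_that("inter-visit gaps match the configured 2.1 (0.4) year schedule", {
  g <- generate_cohort(sim_config(n_subjects = 1000, n_visits_range = c(3, 5),
                                  item_missing_rate = 0, seed = 21))
  gaps <- unlist(tapply(g$cohort$age_years, g$cohort$subject_id,
                        function(a) diff(sort(unique(a)))))
  expect_lt(abs(mean(gaps) - 2.1), 0.1)
  expect_lt(abs(sd(gaps) - 0.4), 0.1)
})

test_that("baseline means and missingness match their generating values", {
  cfg <- sim_config(n_subjects = 1500, item_missing_rate = 0.05, seed = 5)
  g <- generate_cohort(cfg)
  coh <- g$cohort
  base_age <- tapply(coh$age_years, coh$subject_id, min)
  base <- coh[coh$age_years == base_age[coh$subject_id], ]

  expected <- drop(cfg$cluster_props %*% cfg$cluster_intercepts)
  for (j in seq_along(memory_outcomes())) {
    o <- memory_outcomes()[j]
    expect_lt(abs(mean(base$value[base$outcome == o], na.rm = TRUE) -
                    expected[j]), 0.25)
  }

  # missingness: fraction of visits with a deleted item, never more than
  # one per visit
  key <- paste(coh$subject_id, coh$age_years)
  n_miss <- tapply(is.na(coh$value), key, sum)
  expect_true(all(n_miss <= 1))
  p_hat <- mean(n_miss == 1)
  se <- sqrt(0.05 * 0.95 / length(n_miss))
  expect_lt(abs(p_hat - 0.05), 4 * se)
})

test_that("exposure chains hit degenerate and stationary regimes", {
  cfg <- sim_config(n_subjects = 5, seed = 3,
                    exposure_specs = list(exposure_spec("always", 1, 1)))
  g <- generate_cohort(cfg)
  h <- generate_exposure_history(cfg, g$truth)
  expect_true(all(h$indicator == 1))
  cum <- cumulative_exposures(h)
  expect_true(all(cum$always_cum == 1.0))

  # stationarity: prevalence 0.3, persistence 0.5 over many visits
  cfg2 <- sim_config(n_subjects = 400, seed = 11,
                     n_prior_visits_range = c(25, 25),
                     exposure_specs = list(exposure_spec("x", 0.3, 0.5)))
  g2 <- generate_cohort(cfg2)
  h2 <- generate_exposure_history(cfg2, g2$truth)
  expect_gt(sum(!h2$is_testing), 9999)
  expect_lt(abs(mean(h2$indicator[!h2$is_testing]) - 0.3), 0.02)

  expect_error(generate_exposure_history(cfg2, g2$truth, exposures = "nope"),
               "unknown exposure")
})

test_that("cluster-linked exposures shift prevalence by cluster", {
  spec <- exposure_spec("risk", 0.3, 0.7, cluster_logor = c(0, log(3)))
  cfg <- two_cluster_config(n = 500, seed = 13)
  cfg$exposure_specs <- list(risk = spec)
  g <- generate_cohort(cfg)
  h <- generate_exposure_history(cfg, g$truth)
  pre <- h[!h$is_testing, ]
  rate <- tapply(pre$indicator, g$truth$clusters[pre$subject_id], mean)
  p2 <- plogis(qlogis(0.3) + log(3))
  expect_lt(abs(rate[["1"]] - 0.3), 0.04)
  expect_lt(abs(rate[["2"]] - p2), 0.04)
})
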