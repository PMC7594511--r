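test_that("noise-free common-slope data is interpolated exactly", {
  ages <- lapply(1:12, function(i) 40 + i / 3 + c(0, 2, 4, 6))
  coh <- linear_cohort(intercepts = rnorm(12, 10),
                       slopes = rep(-0.7, 12), ages_list = ages)
  p <- manual_partition(setNames(rep(1L, 12), unique(coh$subject_id)))
  tab <- suppressWarnings(
    fit_cluster_trajectories(coh, p, "y", min_fit_size = 2))
  expect_equal(tab$slope, -0.7, tolerance = 1e-6)
  expect_equal(tab$n_subjects, 12)
})

test_that("slope estimates are unbiased near zero and affine-equivariant", {
  set.seed(31)
  n <- 500
  ids <- sprintf("P%03d", 1:n)
  rows <- lapply(1:n, function(i) {
    ages <- 40 + rnorm(1, 0, 5) + c(0, cumsum(runif(4, 1.8, 2.4)))
    u <- (ages - ages[1]) / 10
    a <- rnorm(1, 10, 2); b <- rnorm(1, 0, 0.4)
    data.frame(subject_id = ids[i], age_years = ages, outcome = "y",
               value = a + b * u + rnorm(5, 0, 0.8))
  })
  coh <- do.call(rbind, rows)
  p <- manual_partition(setNames(rep(1L, n), ids))
  tab <- fit_cluster_trajectories(coh, p, "y")
  expect_lt(abs(tab$slope), 0.1)

  coh2 <- coh
  coh2$value <- 2 * coh2$value + 5
  tab2 <- fit_cluster_trajectories(coh2, p, "y")
  expect_equal(tab2$slope, 2 * tab$slope, tolerance = 1e-6)
  expect_equal(tab2$baseline_mean, 2 * tab$baseline_mean + 5,
               tolerance = 1e-10)
})

test_that("rate-difference LRT detects a slope gap and requires 2 clusters", {
  set.seed(17)
  n <- 200
  ids <- sprintf("P%03d", 1:n)
  cl <- rep(1:2, each = n / 2)
  rows <- lapply(1:n, function(i) {
    ages <- 40 + c(0, cumsum(runif(3, 1.8, 2.4)))
    u <- (ages - ages[1]) / 10
    b <- c(-0.2, -1.2)[cl[i]] + rnorm(1, 0, 0.3)
    a <- rnorm(1, 10, 1.5)
    data.frame(subject_id = ids[i], age_years = ages, outcome = "y",
               value = a + b * u + rnorm(4, 0, 1))
  })
  coh <- do.call(rbind, rows)
  p <- manual_partition(setNames(cl, ids))
  ht <- lrt_rate_difference(coh, p, "y")
  expect_lt(ht$p.value, 0.001)
  expect_equal(unname(ht$parameter), 1)
  expect_gte(unname(ht$statistic), 0)

  p1 <- manual_partition(setNames(rep(1L, n), ids))
  expect_error(lrt_rate_difference(coh, p1, "y"), "nothing to compare")
})

test_that("cross-domain contrast follows the memory partition", {
  g <- generate_cohort(two_cluster_config(n = 150, seed = 19))
  # memory-linked motor change: reuse the true clusters with a slope gap
  coh_dep <- simulate_motor_outcomes(
    g$cohort, g$truth,
    intercepts = rbind(c(10, 10), c(10, 10)),
    slopes = rbind(c(-0.1, -0.1), c(-1.3, -1.3)),
    subject_sd = c(1, 0.3), seed = 2)
  # motor change independent of clusters: one common row
  coh_ind <- simulate_motor_outcomes(
    g$cohort, g$truth,
    intercepts = matrix(10, 1, 2), slopes = matrix(-0.5, 1, 2),
    subject_sd = c(1, 0.3), seed = 3)
  p <- manual_partition(g$truth$clusters)

  dep <- cross_domain_contrast(coh_dep, p)
  expect_true(all(dep$p.value < 0.05))
  ind <- cross_domain_contrast(coh_ind, p)
  expect_true(all(ind$p.value > 0.001))  # no systematic signal

  expect_error(cross_domain_contrast(g$cohort, p), "absent from cohort")
  p1 <- manual_partition(setNames(rep(1L, length(g$truth$clusters)),
                                  names(g$truth$clusters)))
  expect_error(cross_domain_contrast(coh_dep, p1), "nothing to compare")
})

test_that("summary table combines baselines, slopes and LRT p-values", {
  g <- generate_cohort(two_cluster_config(n = 100, seed = 29))
  p <- manual_partition(g$truth$clusters)
  tab <- trajectory_summary_table(g$cohort, p,
                                  outcomes = c("total_learning",
                                               "recognition"))
  expect_equal(nrow(tab), 4)  # 2 clusters x 2 outcomes
  expect_true(all(tab$estimated))
  expect_true(all(tab$ci_lower <= tab$slope & tab$slope <= tab$ci_upper))
  expect_true(all(tab$lrt_p > 0 & tab$lrt_p <= 1))
  # cluster 1 sits ~6 scaled-score units above cluster 2 at baseline
  b <- tapply(tab$baseline_mean, tab$cluster, mean)
  expect_gt(abs(b[["1"]] - b[["2"]]), 4)
})
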