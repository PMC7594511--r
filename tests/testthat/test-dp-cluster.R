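test_that("posterior similarity counts co-clustering fractions", {
  draws <- rbind(c(1, 1, 2), c(1, 1, 2))
  S <- posterior_similarity(draws)
  expect_equal(S[1, 2], 1)
  expect_equal(S[1, 3], 0)

  draws2 <- rbind(c(1, 1), c(1, 2))
  expect_equal(posterior_similarity(draws2)[1, 2], 0.5)

  set.seed(2)
  r <- noisy_draws(c(1, 1, 2, 2, 3), n_draws = 25)
  S3 <- posterior_similarity(r)
  expect_equal(S3, t(S3))
  expect_equal(diag(S3), rep(1, 5), ignore_attr = TRUE)
  expect_true(all(S3 >= 0 & S3 <= 1))
  # invariant to relabeling cluster indices within draws
  perm <- c(9, 7, 8)
  r_relab <- t(apply(r, 1, function(z) perm[z]))
  expect_equal(posterior_similarity(r_relab), S3)

  expect_error(posterior_similarity(matrix(integer(0), 0, 3)), "no retained")
})

test_that("pear_score reproduces hand-evaluated values", {
  S <- block_psm(c(1, 1, 2, 2))
  expect_equal(pear_score(c(1, 1, 2, 2), S), 1)
  expect_equal(pear_score(1:4, S), 0)
  # candidate {1,3},{2,4}: sum I S = 0, sum I = 2, sum S = 2, B = 6
  expect_equal(pear_score(c(1, 2, 1, 2), S), -0.5)
  expect_error(pear_score(c(1, 2), S), "n x n")
  # PEAR never exceeds 1 on random instances
  set.seed(5)
  for (r in 1:20) {
    Sr <- posterior_similarity(noisy_draws(sample(1:3, 6, TRUE), 15))
    cand <- sample(1:3, 6, TRUE)
    expect_lte(pear_score(cand, Sr), 1 + 1e-12)
  }
})

test_that("maxpear recovers block structure and resolves ties downward", {
  S <- block_psm(c(1, 1, 1, 2, 2))
  p <- maxpear_partition(S, k_max = 4)
  expect_equal(p$k, 2)
  expect_equal(unname(p$labels[1:3]), rep(p$labels[[1]], 3))
  expect_equal(p$pear, 1)

  # off-diagonal zero similarity: PEAR = 0 at every cut, tie rule gives k = 1
  S0 <- diag(6)
  dimnames(S0) <- list(paste0("i", 1:6), paste0("i", 1:6))
  p0 <- maxpear_partition(S0, k_max = 5)
  expect_equal(p0$k, 1)
  expect_equal(p0$pear, 0)

  expect_error(maxpear_partition(S, k_max = 5), "k_max")
  bad <- S; bad[1, 2] <- 2
  expect_error(maxpear_partition(bad, k_max = 2), "not a valid similarity")
})

test_that("maxpear agrees with exhaustive search over all partitions (n = 7)", {
  ap <- all_set_partitions(7)
  expect_length(ap, 877)  # Bell number B7
  set.seed(14)
  for (r in 1:10) {
    draws <- noisy_draws(sample(1:3, 7, replace = TRUE), 30)
    S <- posterior_similarity(draws)
    dimnames(S) <- list(paste0("i", 1:7), paste0("i", 1:7))
    best_full <- max(vapply(ap, pear_score, 0, S = S))
    mp <- maxpear_partition(S, k_max = 6)
    expect_equal(mp$pear, best_full, tolerance = 1e-9)
  }
})

test_that("fixed-k cuts behave at the extremes and on blocks", {
  S <- block_psm(c(1, 1, 2, 2, 3, 3))
  expect_equal(cut_partition(S, 1)$k, 1)
  expect_equal(cut_partition(S, 6)$k, 6)
  p3 <- cut_partition(S, 3)
  expect_equal(p3$k, 3)
  expect_equal(ari(p3$labels, c(1, 1, 2, 2, 3, 3)), 1)
  expect_error(cut_partition(S, 0), "between 1 and n")
  expect_error(cut_partition(S, 7), "between 1 and n")
})

test_that("small-cluster filter excludes and compacts", {
  p <- manual_partition(setNames(rep(1:2, c(20, 14)), sprintf("s%02d", 1:34)))
  f <- filter_small_clusters(p, min_size = 15)
  expect_equal(f$k, 1)
  expect_length(f$excluded, 14)
  expect_equal(sum(f$sizes), 20)

  p15 <- manual_partition(setNames(rep(1, 15), sprintf("s%02d", 1:15)))
  expect_equal(filter_small_clusters(p15, 15)$k, 1)  # boundary retained

  p3 <- manual_partition(setNames(rep(1:3, c(100, 50, 3)),
                                  sprintf("s%03d", 1:153)))
  f3 <- filter_small_clusters(p3, 15)
  expect_equal(sum(f3$sizes), 150)
  expect_length(f3$excluded, 3)
  expect_equal(sort(unique(f3$labels)), 1:2)
})

test_that("panel standardization is exact and invertible", {
  set.seed(8)
  coh <- data.frame(subject_id = rep("s", 40), age_years = 1:40,
                    outcome = rep(c("a", "b"), 20),
                    value = c(rnorm(20, 5, 2), rnorm(20, -3, 0.5)))
  st <- standardize_panel(coh)
  for (o in c("a", "b")) {
    expect_equal(mean(st$value[st$outcome == o]), 0, tolerance = 1e-12)
    expect_equal(sd(st$value[st$outcome == o]), 1, tolerance = 1e-12)
  }
  # idempotence: re-standardizing changes nothing
  expect_equal(standardize_panel(st)$value, st$value, tolerance = 1e-12)
  back <- unstandardize_panel(st)
  expect_equal(back$value, coh$value, tolerance = 1e-12)

  coh$value <- 1
  expect_error(standardize_panel(coh), "zero variance")
})
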