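make_assoc_fixture <- function(n = 400, edu_gap = 2, seed = 61) {
  set.seed(seed)
  ids <- sprintf("A%03d", seq_len(n))
  cl <- sample(1:4, n, replace = TRUE)
  covs <- data.frame(
    subject_id = ids,
    age = rnorm(n, 42, 8),
    ethnicity = rbinom(n, 1, 0.05),
    education = rnorm(n, 13 - edu_gap * (cl - 1) / 3, 2.7),
    noise = rnorm(n),
    stringsAsFactors = FALSE)
  list(partition = manual_partition(setNames(cl, ids)), covariates = covs)
}

test_that("membership model flags a real education gradient and not noise", {
  fx <- make_assoc_fixture()
  row <- membership_model(fx$partition, fx$covariates, "education",
                          adjusters = c("age", "ethnicity"))
  expect_lt(row$p_adjusted, 0.01)
  expect_lt(row$p_unadjusted, 0.01)
  expect_equal(row$df, 3)

  null_row <- membership_model(fx$partition, fx$covariates, "noise",
                               adjusters = c("age", "ethnicity"))
  expect_gt(null_row$p_unadjusted, 0.001)
})

test_that("membership model p-values are calibrated under the null", {
  set.seed(71)
  n <- 150
  ids <- sprintf("B%03d", seq_len(n))
  cl <- sample(1:3, n, replace = TRUE)
  p <- manual_partition(setNames(cl, ids))
  pvals <- replicate(300, {
    covs <- data.frame(subject_id = ids, x = rnorm(n))
    membership_model(p, covs, "x", adjusters = character())$p_unadjusted
  })
  rej <- mean(pvals < 0.05)
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.09)
})

test_that("membership model enforces its preconditions", {
  fx <- make_assoc_fixture(n = 100)
  fx$covariates$const <- 1
  expect_error(membership_model(fx$partition, fx$covariates, "const"),
               "constant")
  p1 <- manual_partition(setNames(rep(1L, 100), fx$covariates$subject_id))
  expect_error(membership_model(p1, fx$covariates, "education"),
               ">= 2 retained clusters")
})

test_that("results are invariant to cluster label permutation", {
  fx <- make_assoc_fixture(n = 250, seed = 81)
  row1 <- membership_model(fx$partition, fx$covariates, "education",
                           adjusters = "age", reference = 1)
  perm <- c(3L, 1L, 4L, 2L)
  relab <- manual_partition(setNames(perm[fx$partition$labels],
                                     names(fx$partition$labels)))
  # same reference group under the permutation
  row2 <- membership_model(relab, fx$covariates, "education",
                           adjusters = "age", reference = perm[1])
  expect_equal(row1$p_adjusted, row2$p_adjusted, tolerance = 1e-6)
  expect_equal(row1$p_unadjusted, row2$p_unadjusted, tolerance = 1e-6)
})

test_that("multivariable model isolates the associated covariate", {
  fx <- make_assoc_fixture(n = 600, edu_gap = 2.5, seed = 91)
  for (j in 1:5) fx$covariates[[paste0("null", j)]] <- rnorm(600)
  vars <- c("education", "age", "ethnicity", paste0("null", 1:5))
  mv <- multivariable_membership(fx$partition, fx$covariates, vars)
  expect_equal(nrow(mv), length(vars))
  expect_equal(mv$covariate[which.min(mv$p_multivariable)], "education")
  expect_lt(mv$p_multivariable[mv$covariate == "education"], 0.01)
})

test_that("rank deficiency and empty sets are reported, not silently fit", {
  fx <- make_assoc_fixture(n = 200)
  fx$covariates$edu_copy <- fx$covariates$education * 2 + 1
  err <- tryCatch(
    multivariable_membership(fx$partition, fx$covariates,
                             c("education", "edu_copy", "age")),
    error = conditionMessage)
  expect_match(err, "rank-deficient")
  expect_match(err, "education")
  expect_match(err, "edu_copy")

  expect_error(multivariable_membership(fx$partition, fx$covariates,
                                        character(0)), "empty covariate set")
  # overfit guard
  expect_error(
    multivariable_membership(fx$partition, fx$covariates[1:40, ],
                             c("education", "age", "noise")),
    "complete cases")
})

test_that("association table stacks unadjusted and multivariable columns", {
  fx <- make_assoc_fixture(n = 500, seed = 101)
  tab <- association_table(fx$partition, fx$covariates,
                           covariate_set = c("education", "noise"),
                           adjusters = c("age", "ethnicity"))
  expect_equal(tab$covariate, c("education", "noise"))
  expect_true(all(c("p_unadjusted", "p_adjusted", "p_multivariable")
                  %in% names(tab)))
  expect_lt(tab$p_multivariable[1], 0.05)
})
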