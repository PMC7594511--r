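# Shared fixtures and independent oracles for the test suite.

# small two-cluster simulation config with well-separated intercepts
two_cluster_config <- function(n = 120, gap = 6, residual_sd = 1,
                               item_missing_rate = 0, seed = 7) {
  base <- 10 + gap / 2
  sim_config(
    n_subjects = n,
    cluster_props = c(0.5, 0.5),
    cluster_intercepts = rbind(rep(base, 4), rep(base - gap, 4)),
    cluster_slopes = rbind(rep(-0.4, 4), rep(-0.8, 4)),
    loading_scale = 0.5, slope_loading_scale = 0.2,
    theta_noise_sd = 0.3, residual_sd = residual_sd,
    item_missing_rate = item_missing_rate, seed = seed)
}

# hand-built long cohort with exact linear trajectories
linear_cohort <- function(intercepts, slopes, ages_list, outcome = "y") {
  rows <- lapply(seq_along(intercepts), function(i) {
    ages <- ages_list[[i]]
    u <- (ages - ages[1]) / 10
    data.frame(subject_id = sprintf("P%03d", i), age_years = ages,
               outcome = outcome, value = intercepts[i] + slopes[i] * u,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# partition object with prescribed labels (bypasses clustering)
manual_partition <- function(labels, ids = names(labels)) {
  stopifnot(!is.null(ids))
  memtraj:::new_partition(labels, ids, method = "manual")
}

# enumerate all set partitions of n items (restricted growth strings);
# independent search oracle for maxpear
all_set_partitions <- function(n) {
  out <- list()
  rec <- function(rgs, mx) {
    if (length(rgs) == n) {
      out[[length(out) + 1L]] <<- rgs
      return()
    }
    for (v in seq_len(mx + 1L)) rec(c(rgs, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

# block-perfect similarity matrix for a given label vector
block_psm <- function(labels) {
  S <- outer(labels, labels, function(a, b) as.numeric(a == b))
  dimnames(S) <- list(paste0("i", seq_along(labels)),
                      paste0("i", seq_along(labels)))
  S
}

# noisy posterior-style label draws around a true partition
noisy_draws <- function(true_p, n_draws = 40, noise = NULL) {
  t(replicate(n_draws, {
    z <- true_p
    p <- noise %||% runif(1, 0.1, 0.5)
    flip <- runif(length(z)) < p
    if (any(flip))
      z[flip] <- sample(seq_len(max(true_p) + 1L), sum(flip), replace = TRUE)
    z
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# simple exposure history builder: one subject, one exposure
history_of <- function(pre, testing = NA, name = "smokes", id = "S1") {
  n_pre <- length(pre)
  data.frame(
    subject_id = id,
    visit_index = seq_len(n_pre + !is.null(testing)),
    is_testing = c(rep(FALSE, n_pre), if (!is.null(testing)) TRUE),
    exposure_name = name,
    indicator = c(pre, if (!is.null(testing)) testing),
    stringsAsFactors = FALSE)
}
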