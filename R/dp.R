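#' Z-score a long cohort panel per outcome
#'
#' Standardizes each outcome across all observations so shared hyperpriors
#' on the coefficient model are well conditioned; the back-transform is
#' stored in attribute `"standardization"`.
#'
#' @param cohort Long cohort data frame.
#' @return The cohort with standardized `value` and a `"standardization"`
#'   attribute (data frame `outcome`, `mean`, `sd`).
#' @export
standardize_panel <- function(cohort) {
  outs <- unique(cohort$outcome)
  st <- do.call(rbind, lapply(outs, function(o) {
    x <- cohort$value[cohort$outcome == o]
    s <- sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop("outcome '", o, "' has zero variance; cannot standardize")
    data.frame(outcome = o, mean = mean(x, na.rm = TRUE), sd = s,
               stringsAsFactors = FALSE)
  }))
  idx <- match(cohort$outcome, st$outcome)
  cohort$value <- (cohort$value - st$mean[idx]) / st$sd[idx]
  attr(cohort, "standardization") <- st
  cohort
}

#' Undo [standardize_panel()]
#' @param cohort A standardized cohort carrying the `"standardization"`
#'   attribute (or pass `record` explicitly).
#' @param record Optional standardization record.
#' @return The cohort on the original scale.
#' @export
unstandardize_panel <- function(cohort, record = attr(cohort, "standardization")) {
  stopifnot(!is.null(record))
  idx <- match(cohort$outcome, record$outcome)
  cohort$value <- cohort$value * record$sd[idx] + record$mean[idx]
  attr(cohort, "standardization") <- NULL
  cohort
}

#' Hyperparameters of the trajectory clustering model
#'
#' Weakly informative conjugate choices on the standardized scale:
#' `q = 2` latent factors with standard-normal loadings, inverse-gamma(2, 1)
#' residual and idiosyncratic variances, a `N(0, 4)` product base measure
#' for cluster means, and a Gamma(1, 1) prior on the Dirichlet-process
#' concentration updated by the usual beta augmentation.
#'
#' @param factor_dim Latent factor dimension `q` (>= 1).
#' @param base_mean,base_var Base-measure mean and variance per coordinate.
#' @param sigma_shape,sigma_rate Inverse-gamma prior on observation
#'   variances.
#' @param psi_shape,psi_rate Inverse-gamma prior on coefficient
#'   idiosyncratic variances.
#' @param alpha_shape,alpha_rate Gamma prior on the DP concentration.
#' @param label_update `"conjugate"` (default) for the marginal conjugate
#'   label update — the new-cluster weight integrates the cluster mean
#'   over the base measure, which seeds clusters efficiently in high
#'   coefficient dimension — or `"aux"` for the auxiliary-component
#'   update drawing `n_aux` fresh candidate means from the base measure.
#'   Both are exact; they differ only in mixing speed.
#' @param fix_loadings If `TRUE`, loadings are pinned to zero (factor-free
#'   limit used for sampler validation).
#' @param fixed_labels Optional integer vector of 1-based labels pinning
#'   cluster memberships (validation mode; disables label and
#'   concentration updates).
#' @param fixed_sigma2,fixed_psi Optional fixed variance vectors
#'   (validation mode).
#' @param fixed_alpha Optional fixed concentration (> 0).
#' @return An object of class `memtraj_dp_control`.
#' @export
dp_control <- function(factor_dim = 2,
                       base_mean = 0, base_var = 4,
                       sigma_shape = 2, sigma_rate = 1,
                       psi_shape = 2, psi_rate = 1,
                       alpha_shape = 1, alpha_rate = 1,
                       label_update = c("conjugate", "aux"),
                       fix_loadings = FALSE,
                       fixed_labels = NULL,
                       fixed_sigma2 = NULL,
                       fixed_psi = NULL,
                       fixed_alpha = NULL) {
  stopifnot(factor_dim >= 1, base_var > 0, sigma_shape > 0, sigma_rate > 0,
            psi_shape > 0, psi_rate > 0, alpha_shape > 0, alpha_rate > 0)
  label_update <- match.arg(label_update)
  structure(list(factor_dim = as.integer(factor_dim),
                 base_mean = base_mean, base_var = base_var,
                 sigma_shape = sigma_shape, sigma_rate = sigma_rate,
                 psi_shape = psi_shape, psi_rate = psi_rate,
                 alpha_shape = alpha_shape, alpha_rate = alpha_rate,
                 label_update = label_update,
                 fix_loadings = isTRUE(fix_loadings),
                 fixed_labels = fixed_labels,
                 fixed_sigma2 = fixed_sigma2,
                 fixed_psi = fixed_psi,
                 fixed_alpha = fixed_alpha %||% -1),
            class = "memtraj_dp_control")
}

#' MCMC settings
#'
#' Defaults follow the analysis protocol: 20,000 iterations with the first
#' 10,000 discarded and every retained sweep recorded (`thin = 1`). Label
#' updates use `n_aux = 3` auxiliary components.
#'
#' @param n_iter Total Gibbs sweeps.
#' @param n_burn Burn-in sweeps discarded.
#' @param thin Recording stride over post-burn sweeps.
#' @param n_aux Auxiliary components in the label update (>= 1).
#' @param init_clusters Number of clusters in the deterministic
#'   initial partition (Ward cut of per-subject least-squares
#'   coefficients). `NULL` picks `min(20, max(1, n %/% 6))`; an
#'   over-partitioned start lets within-cluster variances initialize near
#'   their well-separated mode, from which merges are easy. `1` starts
#'   all subjects in one cluster.
#' @param seed Optional integer seed applied before sampling.
#' @return An object of class `memtraj_mcmc_control`.
#' @export
mcmc_control <- function(n_iter = 20000, n_burn = 10000, thin = 1,
                         n_aux = 3, init_clusters = NULL, seed = NULL) {
  stopifnot(n_burn < n_iter, thin >= 1, n_aux >= 1)
  structure(list(n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
                 thin = as.integer(thin), n_aux = as.integer(n_aux),
                 init_clusters = if (is.null(init_clusters)) NULL else
                   as.integer(init_clusters),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "memtraj_mcmc_control")
}

# per-subject OLS coefficients (mean + zero slope fallback), used for the
# deterministic initial partition
ols_coefficients <- function(ps) {
  n <- nrow(ps$sxx)
  G <- ps$G
  theta <- matrix(0, n, 2 * G)
  for (i in seq_len(n)) {
    ni <- ps$sxx[i, 1]; su <- ps$sxx[i, 2]; su2 <- ps$sxx[i, 3]
    det <- ni * su2 - su * su
    for (g in seq_len(G)) {
      sy <- ps$sxy[i, 2 * g - 1]; suy <- ps$sxy[i, 2 * g]
      if (det > 1e-10) {
        theta[i, g] <- (su2 * sy - su * suy) / det
        theta[i, G + g] <- (ni * suy - su * sy) / det
      } else {
        theta[i, g] <- sy / ni
      }
    }
  }
  theta
}

# Ward cut of per-subject OLS coefficients, with each coordinate weighted
# by its estimated reliability (between-subject signal variance over total
# variance): slope coordinates of short series are nearly pure sampling
# noise and would otherwise dominate the distances.
initial_partition <- function(ps, k0 = NULL) {
  n <- nrow(ps$sxx)
  if (is.null(k0)) k0 <- min(20L, max(1L, n %/% 6L))
  if (k0 <= 1 || n < 3) return(rep(1L, n))
  theta <- ols_coefficients(ps)
  G <- ps$G

  # pooled residual variance per outcome from subjects with > 2 visits
  sig2 <- vapply(seq_len(G), function(g) {
    a <- theta[, g]; b <- theta[, G + g]
    ssr <- ps$syy[, g] - 2 * (a * ps$sxy[, 2 * g - 1] + b * ps$sxy[, 2 * g]) +
      a^2 * ps$sxx[, 1] + 2 * a * b * ps$sxx[, 2] + b^2 * ps$sxx[, 3]
    df <- pmax(ps$sxx[, 1] - 2, 0)
    if (sum(df) > 0) max(sum(pmax(ssr, 0)) / sum(df), 1e-8) else 1
  }, 0)

  dets <- pmax(ps$sxx[, 1] * ps$sxx[, 3] - ps$sxx[, 2]^2, 1e-10)
  weights <- numeric(2 * G)
  z <- theta
  for (j in seq_len(2 * G)) {
    g <- if (j <= G) j else j - G
    se2 <- if (j <= G) sig2[g] * ps$sxx[, 3] / dets else
      sig2[g] * ps$sxx[, 1] / dets
    v_tot <- stats::var(theta[, j])
    noise <- mean(pmin(se2, v_tot))
    rel <- if (v_tot > 0) max(v_tot - noise, 0) / v_tot else 0
    weights[j] <- rel
    z[, j] <- if (v_tot > 0) theta[, j] / sqrt(v_tot) * rel else 0
  }
  if (all(weights == 0)) z <- scale(theta)
  hc <- hclust(stats::dist(z), method = "ward.D2")
  as.integer(cutree(hc, k = min(k0, n)))
}

# per-subject sufficient statistics on the centered-age/10 time scale
build_panel_stats <- function(cohort, outcomes) {
  cohort <- cohort[cohort$outcome %in% outcomes, ]
  if (any(!is.finite(cohort$value)))
    stop("non-finite outcome values; impute or drop before fitting")
  ids <- unique(cohort$subject_id)
  ids <- ids[canonical_subject_order(ids)]
  G <- length(outcomes)
  n <- length(ids)
  sxx <- matrix(0, n, 3)
  sxy <- matrix(0, n, 2 * G)
  syy <- matrix(0, n, G)
  split_idx <- split(seq_len(nrow(cohort)), cohort$subject_id)
  for (i in seq_len(n)) {
    sub <- cohort[split_idx[[ids[i]]], ]
    ages <- sort(unique(sub$age_years))
    if (length(ages) < 2)
      stop("subject '", ids[i], "' has fewer than 2 visits")
    u <- (ages - ages[1]) / 10
    sxx[i, ] <- c(length(u), sum(u), sum(u * u))
    for (g in seq_len(G)) {
      y <- sub$value[sub$outcome == outcomes[g]][order(sub$age_years[sub$outcome == outcomes[g]])]
      if (length(y) != length(u))
        stop("subject '", ids[i], "' lacks outcome '", outcomes[g],
             "' at some visits")
      sxy[i, 2 * g - 1] <- sum(y)
      sxy[i, 2 * g] <- sum(u * y)
      syy[i, g] <- sum(y * y)
    }
  }
  list(ids = ids, G = G, sxx = sxx, sxy = sxy, syy = syy)
}

#' Fit the Dirichlet-process mixture of multivariate linear trajectories
#'
#' Runs the Gibbs sampler alternating conjugate updates of per-subject
#' coefficients, factor scores, loadings and idiosyncratic variances,
#' observation variances, cluster labels (auxiliary-component
#' Dirichlet-process update), cluster means, and the concentration
#' parameter. Subjects are processed in a canonical (sorted-id) order, so
#' results do not depend on input row order.
#'
#' @param cohort Long cohort data frame; every subject needs at least two
#'   visits with complete values on `outcomes`.
#' @param outcomes Outcomes modelled jointly (default the four
#'   declarative-memory measures).
#' @param control A [dp_control()] object.
#' @param mcmc A [mcmc_control()] object.
#' @param standardize Z-score outcomes internally before fitting
#'   (recommended; the hyperpriors assume unit-scale data).
#' @return An object of class `memtraj_draws`: list with `labels`
#'   (retained-draws x subjects integer matrix), `n_clusters` per draw,
#'   `subject_ids`, `coef_mean` (posterior mean cluster-mean coefficient
#'   per subject, standardized scale), `alpha` and `sigma2` traces, and
#'   the `outcomes`/`control`/`mcmc` used.
#' @export
fit_dp_mixture <- function(cohort, outcomes = memory_outcomes(),
                           control = dp_control(), mcmc = mcmc_control(),
                           standardize = TRUE) {
  stopifnot(inherits(control, "memtraj_dp_control"),
            inherits(mcmc, "memtraj_mcmc_control"))
  if (standardize) cohort <- standardize_panel(cohort[cohort$outcome %in% outcomes, ])
  ps <- build_panel_stats(cohort, outcomes)
  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)
  fl <- control$fixed_labels
  if (!is.null(fl)) {
    if (length(fl) != length(ps$ids)) stop("fixed_labels length mismatch")
    fl <- as.integer(fl)
  }
  init <- initial_partition(ps, mcmc$init_clusters)
  res <- dp_gibbs_cpp(
    ps$sxx, ps$sxy, ps$syy, ps$G, control$factor_dim,
    control$base_mean, control$base_var,
    control$sigma_shape, control$sigma_rate,
    control$psi_shape, control$psi_rate,
    control$alpha_shape, control$alpha_rate,
    mcmc$n_iter, mcmc$n_burn, mcmc$thin, mcmc$n_aux,
    identical(control$label_update, "aux"),
    init,
    control$fix_loadings,
    if (is.null(fl)) integer(0) else fl,
    if (is.null(control$fixed_sigma2)) numeric(0) else control$fixed_sigma2,
    if (is.null(control$fixed_psi)) numeric(0) else control$fixed_psi,
    control$fixed_alpha, TRUE)
  structure(list(labels = res$labels, n_clusters = as.integer(res$n_clusters),
                 subject_ids = ps$ids, coef_mean = res$coef_mean,
                 alpha = res$alpha, sigma2 = res$sigma2,
                 outcomes = outcomes, control = control, mcmc = mcmc),
            class = "memtraj_draws")
}

#' Posterior similarity matrix
#'
#' `S[i, j]` is the fraction of retained draws in which subjects `i` and
#' `j` share a cluster; symmetric with unit diagonal, invariant to label
#' switching within draws.
#'
#' @param draws A `memtraj_draws` object or a draws-by-subjects integer
#'   label matrix.
#' @return An `n x n` similarity matrix with subject ids as dimnames.
#' @export
posterior_similarity <- function(draws) {
  labs <- if (inherits(draws, "memtraj_draws")) draws$labels else as.matrix(draws)
  if (is.null(labs) || nrow(labs) < 1) stop("no retained draws")
  S <- psm_cpp(labs)
  ids <- if (inherits(draws, "memtraj_draws")) draws$subject_ids else colnames(labs)
  if (!is.null(ids)) dimnames(S) <- list(ids, ids)
  S
}

#' Posterior expected adjusted Rand index of a candidate partition
#'
#' Scores candidate labels against a posterior similarity matrix:
#' with pair indicators `I_ij` and `B = n(n-1)/2`,
#' `PEAR = (sum I S - sum I * sum S / B) /
#'         ((sum I + sum S)/2 - sum I * sum S / B)`
#' over pairs `i < j`; defined as 0 when the denominator vanishes.
#'
#' @param labels Candidate cluster labels (length `n`).
#' @param S Posterior similarity matrix (`n x n`).
#' @return A scalar, at most 1.
#' @export
pear_score <- function(labels, S) {
  n <- length(labels)
  if (!is.matrix(S) || nrow(S) != n || ncol(S) != n)
    stop("S must be an n x n matrix matching labels")
  up <- upper.tri(S)
  Iij <- outer(labels, labels, `==`)[up]
  Sij <- S[up]
  B <- n * (n - 1) / 2
  sI <- sum(Iij)
  sS <- sum(Sij)
  expected <- sI * sS / B
  den <- (sI + sS) / 2 - expected
  if (abs(den) < 1e-12) return(0)
  (sum(Sij[Iij]) - expected) / den
}

# renumber labels 1..K by decreasing cluster size (ties: first appearance
# in canonical order), keeping determinism and permutation invariance
compact_labels <- function(labels) {
  tab <- table(labels)
  ord <- names(tab)[order(-as.integer(tab), names(tab), method = "radix")]
  as.integer(factor(as.character(labels), levels = ord))
}

new_partition <- function(labels, ids, pear = NA_real_, excluded = character(),
                          method = "maxpear") {
  labels <- setNames(compact_labels(labels), ids)
  structure(list(labels = labels,
                 sizes = as.integer(table(labels)),
                 excluded = excluded,
                 k = length(unique(labels)),
                 pear = pear, method = method),
            class = "memtraj_partition")
}

#' @export
print.memtraj_partition <- function(x, ...) {
  cat("Trajectory partition (", x$method, "): ", x$k, " cluster(s), sizes ",
      paste(x$sizes, collapse = "/"), sep = "")
  if (length(x$excluded)) cat("; ", length(x$excluded), " excluded", sep = "")
  if (is.finite(x$pear)) cat("; PEAR = ", signif(x$pear, 4), sep = "")
  cat("\n")
  invisible(x)
}

# average-linkage dendrogram on dissimilarity 1 - S
psm_dendrogram <- function(S) {
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8)) ||
      any(S < -1e-8) || any(S > 1 + 1e-8) ||
      any(abs(diag(S) - 1) > 1e-8))
    stop("S is not a valid similarity matrix")
  hclust(as.dist(1 - S), method = "average")
}

#' Partition maximizing the posterior expected adjusted Rand index
#'
#' Builds an average-linkage dendrogram on `1 - S`, evaluates
#' [pear_score()] at each cut `k = 1..k_max`, and returns the best cut
#' (ties resolved toward fewer clusters).
#'
#' @param S Posterior similarity matrix.
#' @param k_max Largest number of clusters examined (default 10).
#' @return A `memtraj_partition`; attribute `"pear_by_k"` holds the PEAR
#'   value at every examined cut.
#' @export
maxpear_partition <- function(S, k_max = 10) {
  n <- nrow(S)
  stopifnot(k_max >= 1, k_max < n)
  hc <- psm_dendrogram(S)
  cuts <- cutree(hc, k = seq_len(k_max))
  pear <- unname(apply(cuts, 2, pear_score, S = S))
  best <- which.max(pear)  # first max: ties go to smaller k
  p <- new_partition(cuts[, best], rownames(S) %||% as.character(seq_len(n)),
                     pear = pear[best], method = "maxpear")
  attr(p, "pear_by_k") <- data.frame(k = seq_len(k_max), pear = pear)
  p
}

#' Cut the similarity dendrogram at a fixed number of clusters
#'
#' Sensitivity-analysis companion to [maxpear_partition()]: average-linkage
#' cut at exactly `k` groups (the protocol inspected `k` from 3 to 6).
#'
#' @param S Posterior similarity matrix.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return A `memtraj_partition`.
#' @export
cut_partition <- function(S, k) {
  n <- nrow(S)
  if (k < 1 || k > n) stop("k must be between 1 and n")
  hc <- psm_dendrogram(S)
  labs <- cutree(hc, k = k)
  new_partition(labs, rownames(S) %||% as.character(seq_len(n)),
                pear = pear_score(labs, S), method = paste0("cut_k", k))
}

#' Drop clusters smaller than a minimum size
#'
#' Subjects in clusters below `min_size` (protocol: 15) are moved to the
#' excluded list — mirroring participants "not falling into a distinct
#' cluster" — and remaining labels are compacted.
#'
#' @param partition A `memtraj_partition`.
#' @param min_size Minimum retained cluster size.
#' @return The filtered `memtraj_partition`.
#' @export
filter_small_clusters <- function(partition, min_size = 15) {
  stopifnot(inherits(partition, "memtraj_partition"))
  sizes <- table(partition$labels)
  small <- as.integer(names(sizes)[sizes < min_size])
  if (!length(small)) return(partition)
  drop <- partition$labels %in% small
  excluded <- c(partition$excluded, names(partition$labels)[drop])
  kept <- partition$labels[!drop]
  if (!length(kept)) {
    message("all clusters below min_size; empty partition")
    out <- structure(list(labels = setNames(integer(0), character(0)),
                          sizes = integer(0), excluded = excluded, k = 0L,
                          pear = partition$pear, method = partition$method),
                     class = "memtraj_partition")
    return(out)
  }
  out <- new_partition(kept, names(kept), pear = partition$pear,
                       excluded = excluded, method = partition$method)
  out
}

#' End-to-end trajectory clustering
#'
#' Convenience wrapper: fit the Dirichlet-process mixture, compute the
#' posterior similarity matrix, select the PEAR-optimal partition, and
#' apply the small-cluster filter.
#'
#' @inheritParams fit_dp_mixture
#' @param k_max Largest cut examined by [maxpear_partition()].
#' @param min_size Small-cluster filter threshold ([filter_small_clusters()]).
#' @return List with `draws`, `psm`, `partition` (filtered),
#'   `partition_unfiltered`, and `pear_by_k`.
#' @export
cluster_trajectories <- function(cohort, outcomes = memory_outcomes(),
                                 control = dp_control(),
                                 mcmc = mcmc_control(),
                                 k_max = 10, min_size = 15) {
  draws <- fit_dp_mixture(cohort, outcomes, control, mcmc)
  S <- posterior_similarity(draws)
  part0 <- maxpear_partition(S, k_max = min(k_max, nrow(S) - 1L))
  part <- filter_small_clusters(part0, min_size = min_size)
  list(draws = draws, psm = S, partition = part,
       partition_unfiltered = part0,
       pear_by_k = attr(part0, "pear_by_k"))
}
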