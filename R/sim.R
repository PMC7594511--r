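#' Simulation configuration for a synthetic longitudinal cohort
#'
#' Defines the generating truth for a cohort of women followed with
#' approximately biennial cognitive testing on `G` scaled-score outcomes.
#' Each subject is assigned a latent cluster; her stacked trajectory
#' coefficients (intercepts in scaled-score units, slopes in scaled-score
#' units per decade of age) are the cluster mean plus a low-rank factor
#' contribution plus independent noise. Defaults emulate the seropositive
#' Black/African American stratum of a large observational cohort: four
#' clusters with baseline scaled scores near 13/10.5/8.5/6.5 and
#' per-decade slopes between -0.85 and -0.24, visits about 2.1 (SD 0.4)
#' years apart, 2-5 visits per subject, and ~1% of visits missing one
#' test item.
#'
#' @param n_subjects Number of subjects.
#' @param n_outcomes Number of outcomes `G` modelled jointly (default 4).
#' @param cluster_props Mixture proportions over latent clusters (summing
#'   to 1; default proportional to observed cluster sizes 99/340/267/95).
#' @param cluster_intercepts `clusters x G` matrix of baseline means
#'   (scaled-score units).
#' @param cluster_slopes `clusters x G` matrix of slopes (scaled-score
#'   units per decade of age).
#' @param factor_dim Latent factor dimension `q` of the coefficient model.
#' @param loading_scale SD of factor loadings on intercept coordinates.
#' @param slope_loading_scale SD of factor loadings on slope coordinates
#'   (smaller, matching the per-decade scale).
#' @param theta_noise_sd Idiosyncratic SD of each coefficient coordinate
#'   around its cluster-plus-factor mean (scalar or length `2*G`).
#' @param residual_sd Observation noise SD per outcome (scalar or length
#'   `G`), scaled-score units.
#' @param visit_interval_mean,visit_interval_sd Gaussian inter-visit gap
#'   in years (truncated below at 0.5).
#' @param n_visits_range Integer range of testing visits per subject
#'   (uniform; minimum 2).
#' @param baseline_age_mean,baseline_age_sd Age at first testing visit.
#' @param item_missing_rate Probability that a visit is missing exactly
#'   one of the `G` test items (in `[0, 1)`).
#' @param exposure_specs List of [exposure_spec()] objects describing the
#'   binary semiannual exposure processes.
#' @param n_prior_visits_range Integer range of semiannual study visits
#'   preceding the first testing visit.
#' @param education_means Per-cluster mean years of education (baseline
#'   covariate simulation).
#' @param education_sd SD of years of education within cluster.
#' @param hispanic_prev Prevalence of Hispanic ethnicity (cluster-free).
#' @param seed Integer seed; fixed seed gives a bit-identical cohort.
#'
#' @return An object of class `memtraj_sim_config`.
#' @seealso [generate_cohort()], [generate_exposure_history()]
#' @export
sim_config <- function(n_subjects = 800,
                       n_outcomes = 4,
                       cluster_props = c(99, 340, 267, 95) / 801,
                       cluster_intercepts = default_cluster_intercepts(),
                       cluster_slopes = default_cluster_slopes(),
                       factor_dim = 2,
                       loading_scale = 1.2,
                       slope_loading_scale = 0.4,
                       theta_noise_sd = 0.3,
                       residual_sd = 1.0,
                       visit_interval_mean = 2.1,
                       visit_interval_sd = 0.4,
                       n_visits_range = c(2, 5),
                       baseline_age_mean = 42,
                       baseline_age_sd = 8.5,
                       item_missing_rate = 0.01,
                       exposure_specs = default_exposure_specs(),
                       n_prior_visits_range = c(4, 28),
                       education_means = c(14.4, 12.8, 11.7, 11.1),
                       education_sd = 2.7,
                       hispanic_prev = 0.03,
                       seed = NULL) {
  cluster_intercepts <- as.matrix(cluster_intercepts)
  cluster_slopes <- as.matrix(cluster_slopes)
  n_clusters <- length(cluster_props)
  G <- n_outcomes

  stopifnot(n_subjects >= 1, G >= 1)
  if (abs(sum(cluster_props) - 1) > 1e-8)
    stop("cluster_props must sum to 1")
  if (any(cluster_props < 0))
    stop("cluster_props must be non-negative")
  if (!all(dim(cluster_intercepts) == c(n_clusters, G)))
    stop("cluster_intercepts must be a ", n_clusters, " x ", G, " matrix")
  if (!all(dim(cluster_slopes) == c(n_clusters, G)))
    stop("cluster_slopes must be a ", n_clusters, " x ", G, " matrix")
  residual_sd <- rep_len(residual_sd, G)
  theta_noise_sd <- rep_len(theta_noise_sd, 2 * G)
  if (any(residual_sd <= 0) || any(theta_noise_sd <= 0) ||
      visit_interval_sd <= 0 || baseline_age_sd <= 0 || education_sd <= 0)
    stop("all standard deviations must be > 0")
  n_visits_range <- as.integer(n_visits_range)
  if (length(n_visits_range) != 2 || n_visits_range[1] < 2 ||
      n_visits_range[2] < n_visits_range[1])
    stop("n_visits_range must be an increasing integer pair with minimum >= 2")
  if (item_missing_rate < 0 || item_missing_rate >= 1)
    stop("item_missing_rate must be in [0, 1)")
  if (factor_dim < 1) stop("factor_dim must be >= 1")
  n_prior_visits_range <- as.integer(n_prior_visits_range)
  if (length(n_prior_visits_range) != 2 || n_prior_visits_range[1] < 1 ||
      n_prior_visits_range[2] < n_prior_visits_range[1])
    stop("n_prior_visits_range must be an increasing integer pair >= 1")
  education_means <- rep_len(education_means, n_clusters)

  structure(list(
    n_subjects = as.integer(n_subjects),
    n_outcomes = as.integer(G),
    n_clusters = as.integer(n_clusters),
    cluster_props = cluster_props,
    cluster_intercepts = cluster_intercepts,
    cluster_slopes = cluster_slopes,
    factor_dim = as.integer(factor_dim),
    loading_scale = loading_scale,
    slope_loading_scale = slope_loading_scale,
    theta_noise_sd = theta_noise_sd,
    residual_sd = residual_sd,
    visit_interval_mean = visit_interval_mean,
    visit_interval_sd = visit_interval_sd,
    n_visits_range = n_visits_range,
    baseline_age_mean = baseline_age_mean,
    baseline_age_sd = baseline_age_sd,
    item_missing_rate = item_missing_rate,
    exposure_specs = exposure_specs,
    n_prior_visits_range = n_prior_visits_range,
    education_means = education_means,
    education_sd = education_sd,
    hispanic_prev = hispanic_prev,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "memtraj_sim_config")
}

#' Default cluster baseline means (scaled-score units)
#'
#' Four clusters ordered high to very-low baseline performance, one column
#' per declarative-memory outcome (single-trial learning, total learning,
#' delayed recall, recognition).
#' @return A 4 x 4 numeric matrix.
#' @export
default_cluster_intercepts <- function() {
  m <- rbind(
    c(12.8, 12.8, 13.0, 11.9),
    c(10.7, 10.5, 10.7, 10.6),
    c(8.7,  8.4,  8.5,  8.6),
    c(6.8,  6.4,  6.4,  6.3))
  dimnames(m) <- list(NULL, memory_outcomes())
  m
}

#' Default cluster slopes (scaled-score units per decade of age)
#' @return A 4 x 4 numeric matrix matching [default_cluster_intercepts()].
#' @export
default_cluster_slopes <- function() {
  m <- rbind(
    c(-0.58, -0.40, -0.47, -0.29),
    c(-0.61, -0.70, -0.67, -0.58),
    c(-0.74, -0.84, -0.78, -0.85),
    c(-0.24, -0.35, -0.43, -0.37))
  dimnames(m) <- list(NULL, memory_outcomes())
  m
}

#' Specification of a binary semiannual exposure process
#'
#' Exposure indicators evolve over semiannual study visits as a two-state
#' Markov chain parameterized by a stationary prevalence and a visit-to-visit
#' persistence `P(exposed at t | exposed at t-1)`. The entry probability
#' from the unexposed state is chosen so the stated prevalence is the
#' stationary marginal. `cluster_logor` optionally shifts the log-odds of
#' the prevalence per latent cluster, creating cluster-linked exposures
#' for association power studies.
#'
#' @param name Exposure name (e.g. `"smokes"`).
#' @param prevalence Stationary marginal probability of exposure.
#' @param persistence `P(1 -> 1)` across consecutive visits.
#' @param cluster_logor Optional numeric vector of per-cluster log odds
#'   ratios added to `qlogis(prevalence)`.
#' @return An object of class `memtraj_exposure_spec`.
#' @export
exposure_spec <- function(name, prevalence, persistence = 0.85,
                          cluster_logor = NULL) {
  stopifnot(is.character(name), length(name) == 1,
            prevalence >= 0, prevalence <= 1,
            persistence >= 0, persistence <= 1)
  structure(list(name = name, prevalence = prevalence,
                 persistence = persistence, cluster_logor = cluster_logor),
            class = "memtraj_exposure_spec")
}

#' Default exposure processes
#'
#' Eleven binary exposures with stationary prevalences near the cumulative
#' exposure levels observed in the emulated cohort (income below $12,000,
#' employment, depression, smoking, heavy drinking, marijuana,
#' crack/cocaine, heroin, CD4 below 200, viral suppression, viral load
#' above 10,000 cp/mL).
#' @return A named list of [exposure_spec()] objects.
#' @export
default_exposure_specs <- function() {
  prev <- c(low_income = 0.50, employed = 0.36, depressed = 0.36,
            smokes = 0.46, heavy_drinker = 0.07, marijuana_use = 0.17,
            crack_cocaine_use = 0.10, heroin_use = 0.03,
            cd4_under_200 = 0.11, vl_suppressed = 0.13, vl_over_10k = 0.21)
  specs <- lapply(names(prev), function(nm) exposure_spec(nm, prev[[nm]]))
  names(specs) <- names(prev)
  specs
}

#' Generate a synthetic longitudinal cohort with known cluster structure
#'
#' Draws cluster memberships, per-subject trajectory coefficients
#' `theta_i = mu_c + Lambda eta_i + noise`, irregular visit schedules, and
#' scaled-score observations `y = alpha + beta * (age - age_1)/10 + e`,
#' then deletes at most one test item per visit at the configured rate.
#'
#' @param config A [sim_config()] object.
#' @return A list with components:
#'   \describe{
#'     \item{cohort}{Long-format data frame: `subject_id`, `age_years`,
#'       `outcome`, `value` (`NA` for deleted items).}
#'     \item{truth}{List with `clusters` (named integer vector of true
#'       labels), `theta` (`n x 2G` matrix of true coefficients, intercepts
#'       first), and `loadings` (the realized `2G x q` loading matrix).}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "memtraj_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_subjects
  G <- config$n_outcomes
  d <- 2L * G
  q <- config$factor_dim
  outcomes <- if (G == 4) memory_outcomes() else paste0("outcome", seq_len(G))

  ids <- sprintf("S%05d", seq_len(n))
  clusters <- sample.int(config$n_clusters, n, replace = TRUE,
                         prob = config$cluster_props)
  names(clusters) <- ids

  # loadings: larger on intercept coordinates than on per-decade slopes
  load_sd <- rep(c(config$loading_scale, config$slope_loading_scale), each = G)
  Lambda <- matrix(rnorm(d * q), d, q) * load_sd
  eta <- matrix(rnorm(n * q), n, q)
  mu <- cbind(config$cluster_intercepts, config$cluster_slopes)  # clusters x 2G
  theta <- mu[clusters, , drop = FALSE] + eta %*% t(Lambda) +
    matrix(rnorm(n * d), n, d) %*% diag(config$theta_noise_sd, d)
  rownames(theta) <- ids
  colnames(theta) <- c(paste0("intercept_", outcomes), paste0("slope_", outcomes))

  n_visits <- sample_range(config$n_visits_range, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    k <- n_visits[i]
    gaps <- pmax(0.5, rnorm(k - 1, config$visit_interval_mean,
                            config$visit_interval_sd))
    ages <- rnorm(1, config$baseline_age_mean, config$baseline_age_sd) +
      c(0, cumsum(gaps))
    u <- (ages - ages[1]) / 10
    vals <- outer(u, theta[i, G + seq_len(G)]) +
      matrix(theta[i, seq_len(G)], k, G, byrow = TRUE) +
      matrix(rnorm(k * G), k, G) %*% diag(config$residual_sd, G)
    # at most one item deleted per visit
    if (config$item_missing_rate > 0 && G > 1) {
      hit <- runif(k) < config$item_missing_rate
      if (any(hit)) {
        which_item <- sample.int(G, sum(hit), replace = TRUE)
        vals[cbind(which(hit), which_item)] <- NA_real_
      }
    }
    rows[[i]] <- data.frame(
      subject_id = ids[i],
      age_years = rep(ages, G),
      outcome = rep(outcomes, each = k),
      value = as.vector(vals),
      stringsAsFactors = FALSE)
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL

  list(cohort = cohort,
       truth = list(clusters = clusters, theta = theta, loadings = Lambda))
}

#' Generate semiannual exposure histories for a simulated cohort
#'
#' For each subject, simulates an ordered run of pre-testing semiannual
#' visits (count uniform over `n_prior_visits_range`) followed by the first
#' testing visit, each carrying binary indicators per exposure from the
#' configured two-state Markov chains. When a spec carries `cluster_logor`,
#' the chain's stationary prevalence is shifted on the log-odds scale by
#' the subject's true cluster.
#'
#' @param config A [sim_config()] object.
#' @param truth The `truth` component returned by [generate_cohort()].
#' @param exposures Optional character vector naming a subset of
#'   `config$exposure_specs`; unknown names are an error.
#' @param seed Seed for this stage (default `config$seed + 1` when the
#'   config has a seed, so cohort and history are jointly reproducible).
#' @return Long-format data frame: `subject_id`, `visit_index`,
#'   `is_testing` (`TRUE` on the first testing visit), `exposure_name`,
#'   `indicator` (0/1).
#' @export
generate_exposure_history <- function(config, truth, exposures = NULL,
                                      seed = NULL) {
  stopifnot(inherits(config, "memtraj_sim_config"))
  specs <- config$exposure_specs
  if (!is.null(exposures)) {
    unknown <- setdiff(exposures, vapply(specs, `[[`, "", "name"))
    if (length(unknown))
      stop("unknown exposure name(s): ", paste(unknown, collapse = ", "))
    specs <- specs[vapply(specs, `[[`, "", "name") %in% exposures]
  }
  if (is.null(seed) && !is.null(config$seed)) seed <- config$seed + 1L
  if (!is.null(seed)) set.seed(seed)

  ids <- names(truth$clusters)
  n <- length(ids)
  m_prior <- sample_range(config$n_prior_visits_range, n)

  out <- vector("list", length(specs))
  for (s in seq_along(specs)) {
    sp <- specs[[s]]
    p <- rep(sp$prevalence, n)
    if (!is.null(sp$cluster_logor)) {
      lo <- rep_len(sp$cluster_logor, config$n_clusters)
      p <- plogis(qlogis(pmin(pmax(sp$prevalence, 1e-8), 1 - 1e-8)) +
                    lo[truth$clusters])
    }
    chains <- vector("list", n)
    for (i in seq_len(n)) {
      m <- m_prior[i] + 1L  # prior visits plus the testing visit
      x <- markov_chain(m, p[i], sp$persistence)
      chains[[i]] <- data.frame(
        subject_id = ids[i],
        visit_index = seq_len(m),
        is_testing = c(rep(FALSE, m - 1L), TRUE),
        exposure_name = sp$name,
        indicator = x,
        stringsAsFactors = FALSE)
    }
    out[[s]] <- do.call(rbind, chains)
  }
  hist <- do.call(rbind, out)
  rownames(hist) <- NULL
  hist
}

# uniform integer draw over an inclusive range (degenerate range safe)
sample_range <- function(range, n) {
  vals <- seq(range[1], range[2])
  if (length(vals) == 1L) rep(vals, n) else sample(vals, n, replace = TRUE)
}

# two-state chain with stationary marginal prevalence p and
# P(1 -> 1) = persistence
markov_chain <- function(m, p, persistence) {
  if (p >= 1) return(rep(1L, m))
  if (p <= 0) return(rep(0L, m))
  if (persistence >= 1) return(rep(as.integer(runif(1) < p), m))
  p01 <- min(1, p * (1 - persistence) / (1 - p))
  x <- integer(m)
  x[1] <- as.integer(runif(1) < p)
  if (m > 1) {
    u <- runif(m - 1)
    for (t in 2:m)
      x[t] <- as.integer(u[t - 1] < if (x[t - 1] == 1L) persistence else p01)
  }
  x
}

#' Simulate baseline covariates for the membership models
#'
#' Convenience companion to [generate_cohort()]: returns per-subject age
#' at first testing visit (read off the cohort), years of education drawn
#' around cluster-specific means, and a Hispanic-ethnicity indicator
#' independent of cluster. Used to exercise the association stage with a
#' known signal (education) and known nulls.
#'
#' @param config A [sim_config()] object.
#' @param truth The `truth` component of [generate_cohort()].
#' @param cohort The cohort data frame from [generate_cohort()].
#' @param seed Seed (default `config$seed + 2` when the config has one).
#' @return Data frame: `subject_id`, `age`, `education`, `ethnicity`.
#' @export
simulate_baseline_covariates <- function(config, truth, cohort, seed = NULL) {
  if (is.null(seed) && !is.null(config$seed)) seed <- config$seed + 2L
  if (!is.null(seed)) set.seed(seed)
  base_age <- tapply(cohort$age_years, cohort$subject_id, min)
  ids <- names(truth$clusters)
  data.frame(
    subject_id = ids,
    age = as.numeric(base_age[ids]),
    education = rnorm(length(ids),
                      config$education_means[truth$clusters],
                      config$education_sd),
    ethnicity = rbinom(length(ids), 1, config$hispanic_prev),
    stringsAsFactors = FALSE)
}

#' Add a contrast-domain (motor) outcome to a simulated cohort
#'
#' Appends timed-test outcomes on the same visit schedule. `slopes` may be
#' a `clusters x length(outcomes)` matrix (cluster-linked change, for
#' dependence simulations) or a single row (common change, independent of
#' the memory clusters).
#'
#' @param cohort Cohort data frame from [generate_cohort()].
#' @param truth Matching `truth` component.
#' @param intercepts,slopes Generating values on the scaled-score scale
#'   (matrix rows recycled over clusters).
#' @param residual_sd Observation noise SD.
#' @param outcomes Names for the added outcomes.
#' @param subject_sd SD of per-subject random intercept and slope.
#' @param seed Optional seed.
#' @return The cohort with added rows.
#' @export
simulate_motor_outcomes <- function(cohort, truth,
                                    intercepts = matrix(10, 1, 2),
                                    slopes = matrix(-0.5, 1, 2),
                                    residual_sd = 1,
                                    outcomes = motor_outcomes(),
                                    subject_sd = c(1.5, 0.4),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  intercepts <- as.matrix(intercepts)
  slopes <- as.matrix(slopes)
  n_out <- length(outcomes)
  stopifnot(ncol(intercepts) == n_out, ncol(slopes) == n_out)
  ids <- names(truth$clusters)
  visits <- unique(cohort[, c("subject_id", "age_years")])
  visits <- visits[order(visits$subject_id, visits$age_years), ]
  base_age <- tapply(visits$age_years, visits$subject_id, min)

  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    cl <- truth$clusters[[id]]
    ri <- 1L + (cl - 1L) %% nrow(intercepts)
    rs <- 1L + (cl - 1L) %% nrow(slopes)
    ages <- visits$age_years[visits$subject_id == id]
    u <- (ages - base_age[[id]]) / 10
    a_i <- intercepts[ri, ] + rnorm(n_out, 0, subject_sd[1])
    b_i <- slopes[rs, ] + rnorm(n_out, 0, subject_sd[2])
    vals <- outer(u, b_i) + matrix(a_i, length(u), n_out, byrow = TRUE) +
      matrix(rnorm(length(u) * n_out, 0, residual_sd), length(u), n_out)
    rows[[i]] <- data.frame(
      subject_id = id,
      age_years = rep(ages, n_out),
      outcome = rep(outcomes, each = length(u)),
      value = as.vector(vals),
      stringsAsFactors = FALSE)
  }
  new_rows <- do.call(rbind, rows)
  extra <- setdiff(names(cohort), names(new_rows))
  for (col in extra) new_rows[[col]] <- NA
  out <- rbind(cohort, new_rows[, names(cohort), drop = FALSE])
  rownames(out) <- NULL
  out
}
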