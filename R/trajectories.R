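# Per-cluster rate-of-change characterization and between-cluster
# likelihood-ratio tests, using lme4 mixed models with subject-level
# random intercepts and slopes on the decades-since-baseline scale.

cluster_long_data <- function(cohort, partition, outcome) {
  labs <- partition$labels
  sub <- cohort[cohort$outcome == outcome &
                  cohort$subject_id %in% names(labs), ]
  if (!nrow(sub)) stop("no data for outcome '", outcome, "'")
  base_age <- tapply(sub$age_years, sub$subject_id, min)
  sub$decade <- (sub$age_years - base_age[sub$subject_id]) / 10
  sub$cluster <- factor(labs[sub$subject_id])
  sub
}

fit_growth_model <- function(data, reml = TRUE, formula_rhs = "decade") {
  f_full <- as.formula(paste("value ~", formula_rhs,
                             "+ (decade | subject_id)"))
  f_int <- as.formula(paste("value ~", formula_rhs, "+ (1 | subject_id)"))
  # boundary (singular) fits are legitimate REML/ML optima and are kept;
  # only genuine convergence failures trigger the random-intercept fallback
  quiet_lmer <- function(f) suppressMessages(withCallingHandlers(
    lme4::lmer(f, data = data, REML = reml),
    warning = function(w) {
      if (grepl("converge|gradient|Hessian", conditionMessage(w),
                ignore.case = TRUE))
        invokeRestart("muffleWarning")
    }))
  fit <- tryCatch(quiet_lmer(f_full), error = function(e) NULL)
  model <- "intercept_slope"
  conv_fail <- is.null(fit) ||
    length(fit@optinfo$conv$lme4$messages %||% character(0)) > 0
  if (conv_fail) {
    fit <- quiet_lmer(f_int)
    model <- "intercept_only"
  }
  list(fit = fit, model = model)
}

#' Per-cluster baseline levels and rates of change
#'
#' For each retained cluster, fits a linear mixed model of the outcome on
#' decades since each subject's first testing visit, with random intercept
#' and random slope per subject (REML; falls back to random intercept only
#' on convergence failure). Baseline mean/SD are computed at first visits.
#'
#' @param cohort Long cohort (scaled scores).
#' @param partition A `memtraj_partition` of retained subjects.
#' @param outcome Outcome name to characterize.
#' @param conf_level Wald confidence level for the slope.
#' @param min_fit_size Minimum subjects per cluster to attempt a fit.
#' @return Data frame with one row per cluster: `cluster`, `outcome`,
#'   `n_subjects`, `baseline_mean`, `baseline_sd`, `slope` (per decade),
#'   `slope_se`, `ci_lower`, `ci_upper`, `model`, `estimated`.
#' @export
fit_cluster_trajectories <- function(cohort, partition, outcome,
                                     conf_level = 0.95, min_fit_size = 2) {
  dat <- cluster_long_data(cohort, partition, outcome)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  rows <- lapply(sort(unique(as.integer(as.character(dat$cluster)))), function(cl) {
    d <- dat[dat$cluster == cl, ]
    firsts <- d[d$decade == 0, ]
    out <- data.frame(cluster = cl, outcome = outcome,
                      n_subjects = length(unique(d$subject_id)),
                      baseline_mean = mean(firsts$value),
                      baseline_sd = sd(firsts$value),
                      slope = NA_real_, slope_se = NA_real_,
                      ci_lower = NA_real_, ci_upper = NA_real_,
                      model = NA_character_, estimated = FALSE,
                      stringsAsFactors = FALSE)
    if (out$n_subjects < min_fit_size) return(out)
    gm <- fit_growth_model(d, reml = TRUE)
    b <- lme4::fixef(gm$fit)[["decade"]]
    se <- sqrt(vcov(gm$fit)["decade", "decade"])
    out$slope <- b
    out$slope_se <- se
    out$ci_lower <- b - zq * se
    out$ci_upper <- b + zq * se
    out$model <- gm$model
    out$estimated <- TRUE
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Likelihood-ratio test for between-cluster differences in rate of change
#'
#' Compares maximum-likelihood fits of a pooled mixed model with cluster
#' main effects plus a cluster-by-time interaction against the model with
#' cluster main effects and a common slope; the statistic is referred to a
#' chi-square with `K - 1` degrees of freedom.
#'
#' @inheritParams fit_cluster_trajectories
#' @return An object of class `htest` with `statistic`, `parameter` (df),
#'   and `p.value`.
#' @export
lrt_rate_difference <- function(cohort, partition, outcome) {
  dat <- cluster_long_data(cohort, partition, outcome)
  K <- nlevels(droplevels(dat$cluster))
  if (K < 2) stop("nothing to compare: fewer than 2 retained clusters")
  dat$cluster <- droplevels(dat$cluster)
  full <- fit_growth_model(dat, reml = FALSE,
                           formula_rhs = "cluster * decade")
  red <- fit_growth_model(dat, reml = FALSE,
                          formula_rhs = "cluster + decade")
  # nested comparison requires a common random-effects structure
  if (full$model != red$model) {
    refit <- function(rhs) lme4::lmer(
      as.formula(paste("value ~", rhs, "+ (1 | subject_id)")),
      data = dat, REML = FALSE)
    full <- list(fit = refit("cluster * decade"), model = "intercept_only")
    red <- list(fit = refit("cluster + decade"), model = "intercept_only")
  }
  stat <- max(0, 2 * (as.numeric(logLik(full$fit)) -
                        as.numeric(logLik(red$fit))))
  df <- K - 1
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(statistic = c(`chi-squared` = stat),
                 parameter = c(df = df),
                 p.value = p,
                 method = "Likelihood-ratio test for cluster x time interaction",
                 data.name = outcome,
                 alternative = "rates of change differ between clusters"),
            class = "htest")
}

#' Cross-domain contrast of memory-derived clusters
#'
#' Reapplies [lrt_rate_difference()] on a different cognitive domain
#' (default: timed motor outcomes) using the memory-derived partition, to
#' check whether memory phenotypes track change in the other domain.
#'
#' @inheritParams fit_cluster_trajectories
#' @param domain_outcomes Outcome names of the contrast domain.
#' @return Data frame: `outcome`, `statistic`, `df`, `p.value`.
#' @export
cross_domain_contrast <- function(cohort, partition,
                                  domain_outcomes = motor_outcomes()) {
  missing_out <- setdiff(domain_outcomes, unique(cohort$outcome))
  if (length(missing_out))
    stop("domain outcome(s) absent from cohort: ",
         paste(missing_out, collapse = ", "))
  rows <- lapply(domain_outcomes, function(o) {
    ht <- lrt_rate_difference(cohort, partition, o)
    data.frame(outcome = o, statistic = unname(ht$statistic),
               df = unname(ht$parameter), p.value = ht$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Table-style summary of cluster trajectories
#'
#' Combines [fit_cluster_trajectories()] across outcomes with per-outcome
#' [lrt_rate_difference()] p-values, in the layout of the study's
#' characteristics tables (baseline M (SD); slope (95% CI); LRT p).
#'
#' @inheritParams fit_cluster_trajectories
#' @param outcomes Outcomes to summarize.
#' @return Data frame with per-(cluster, outcome) rows and an `lrt_p`
#'   column repeated within outcome (NA when only one cluster).
#' @export
trajectory_summary_table <- function(cohort, partition,
                                     outcomes = memory_outcomes()) {
  rows <- lapply(outcomes, function(o) {
    tab <- fit_cluster_trajectories(cohort, partition, o)
    tab$lrt_p <- if (partition$k >= 2)
      lrt_rate_difference(cohort, partition, o)$p.value else NA_real_
    tab
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Plot within-cluster mean trajectories
#'
#' Draws, for each outcome, the linear fit of within-cluster averages of
#' scaled scores against age.
#'
#' @inheritParams trajectory_summary_table
#' @param col Colors per cluster.
#' @return Invisibly, the per-cluster linear fits.
#' @export
plot_cluster_trajectories <- function(cohort, partition,
                                      outcomes = memory_outcomes(),
                                      col = NULL) {
  k <- partition$k
  if (is.null(col)) col <- grDevices::hcl.colors(max(k, 2), "Dark 2")
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(outcomes)))
  on.exit(graphics::par(old))
  fits <- list()
  for (o in outcomes) {
    dat <- cluster_long_data(cohort, partition, o)
    graphics::plot(range(dat$age_years), range(dat$value, na.rm = TRUE),
                   type = "n", xlab = "Age (years)",
                   ylab = "Scaled score", main = o)
    for (cl in seq_len(k)) {
      d <- dat[dat$cluster == cl, ]
      if (nrow(d) < 2) next
      fit <- lm(value ~ age_years, data = d)
      xr <- range(d$age_years)
      graphics::lines(xr, stats::predict(fit, data.frame(age_years = xr)),
                      col = col[cl], lwd = 2)
      fits[[paste(o, cl, sep = ".")]] <- fit
    }
  }
  invisible(fits)
}
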