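# Models of cluster membership: multinomial logistic regression with
# likelihood-ratio p-values, unadjusted, covariate-adjusted, and mutually
# adjusted (multivariable). A binomial each-cluster-versus-reference mode
# is available where a multi-category model is not wanted.

merge_membership_data <- function(partition, covariates, reference = NULL) {
  stopifnot(inherits(partition, "memtraj_partition"))
  if (partition$k < 2) stop("need >= 2 retained clusters")
  lab <- data.frame(subject_id = names(partition$labels),
                    .cluster = partition$labels,
                    stringsAsFactors = FALSE)
  dat <- merge(lab, covariates, by = "subject_id")
  dat$.cluster <- factor(dat$.cluster)
  if (!is.null(reference)) {
    reference <- as.character(reference)
    if (!reference %in% levels(dat$.cluster))
      stop("reference cluster '", reference, "' not among retained clusters")
    dat$.cluster <- stats::relevel(dat$.cluster, ref = reference)
  }
  dat
}

#' Reference cluster: best baseline performance
#'
#' Returns the retained cluster with the highest mean scaled score at
#' first visits on the given outcome, used as the reference category of
#' the membership models (decline is framed relative to high performers).
#'
#' @param cohort Long cohort.
#' @param partition Retained partition.
#' @param outcome Outcome defining "performance" (default total learning).
#' @return Integer cluster label.
#' @export
reference_cluster <- function(cohort, partition, outcome = "total_learning") {
  tab <- fit_cluster_trajectories(cohort, partition, outcome,
                                  min_fit_size = Inf)
  tab$cluster[which.max(tab$baseline_mean)]
}

fit_multinom <- function(formula, data) {
  fit <- nnet::multinom(formula, data = data, trace = FALSE, maxit = 500)
  fit
}

multinom_lrt <- function(full, reduced, df) {
  stat <- max(0, reduced$deviance - full$deviance)
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p.value = p)
}

#' Association of a covariate with cluster membership
#'
#' Fits multinomial logistic models of retained-cluster membership on the
#' target covariate, with and without adjusters (default: age, ethnicity,
#' years of education), on the same complete-case subject set; p-values
#' come from likelihood-ratio comparisons dropping the target.
#'
#' @param partition Retained `memtraj_partition`.
#' @param covariates Data frame keyed by `subject_id`.
#' @param target Name of the covariate tested.
#' @param adjusters Covariates adjusted for (may be `character(0)`).
#' @param reference Reference cluster label (see [reference_cluster()]).
#' @return One-row data frame: `covariate`, `n`, `df`,
#'   `p_unadjusted`, `p_adjusted`, `directions` (signs of the target
#'   coefficient for each non-reference cluster, collapsed to a string),
#'   `note` (diagnostics such as possible separation).
#' @export
membership_model <- function(partition, covariates, target,
                             adjusters = c("age", "ethnicity", "education"),
                             reference = NULL) {
  stopifnot(target %in% names(covariates))
  adjusters <- intersect(adjusters, names(covariates))
  dat <- merge_membership_data(partition, covariates, reference)
  use <- c(".cluster", target, adjusters)
  dat <- dat[complete.cases(dat[, use, drop = FALSE]), use, drop = FALSE]
  if (length(unique(dat[[target]])) < 2)
    stop("covariate '", target, "' is constant on the analysis set")
  K <- nlevels(droplevels(dat$.cluster))
  if (K < 2) stop("need >= 2 retained clusters on the analysis set")
  dat$.cluster <- droplevels(dat$.cluster)

  q_target <- ncol(model.matrix(as.formula(paste("~", target)), dat)) - 1L
  df <- (K - 1L) * q_target

  null_fit <- fit_multinom(.cluster ~ 1, dat)
  target_fit <- fit_multinom(as.formula(paste(".cluster ~", target)), dat)
  unadj <- multinom_lrt(target_fit, null_fit, df)

  if (length(adjusters)) {
    adj_red <- fit_multinom(
      as.formula(paste(".cluster ~", paste(adjusters, collapse = " + "))), dat)
    adj_full <- fit_multinom(
      as.formula(paste(".cluster ~", target, "+",
                       paste(adjusters, collapse = " + "))), dat)
    adj <- multinom_lrt(adj_full, adj_red, df)
  } else {
    adj_full <- target_fit
    adj <- unadj
  }

  cf <- coef(adj_full)
  if (K == 2) cf <- matrix(cf, nrow = 1, dimnames = list(
    levels(dat$.cluster)[2], names(cf)))
  target_cols <- grep(paste0("^", target), colnames(cf))
  dirs <- paste(rownames(cf),
                ifelse(rowMeans(cf[, target_cols, drop = FALSE]) >= 0,
                       "+", "-"),
                sep = ":", collapse = " ")
  note <- if (any(abs(cf[, target_cols]) > 15))
    "possible separation: |coef| > 15" else ""

  data.frame(covariate = target, n = nrow(dat), df = df,
             p_unadjusted = unadj$p.value, p_adjusted = adj$p.value,
             directions = dirs, note = note, stringsAsFactors = FALSE)
}

#' Mutually adjusted (multivariable) membership model
#'
#' Fits one multinomial model containing all covariates simultaneously on
#' the complete-case subject set, and reports a likelihood-ratio p-value
#' for each covariate by dropping it in turn. Errors on rank-deficient
#' design matrices, naming the offending covariate columns, and guards
#' against overfitting (complete cases must be at least
#' `guard_ratio` times the parameter count unless `guard = FALSE`).
#'
#' @inheritParams membership_model
#' @param covariate_set Names of the covariates entering jointly.
#' @param guard,guard_ratio Overfit guard (default: `n >= 10 p`).
#' @return Data frame with one row per covariate: `covariate`, `n`, `df`,
#'   `p_multivariable`.
#' @export
multivariable_membership <- function(partition, covariates, covariate_set,
                                     adjusters = character(),
                                     reference = NULL,
                                     guard = TRUE, guard_ratio = 10) {
  if (!length(covariate_set)) stop("empty covariate set")
  stopifnot(all(covariate_set %in% names(covariates)))
  covariate_set <- union(covariate_set, intersect(adjusters, names(covariates)))
  dat <- merge_membership_data(partition, covariates, reference)
  use <- c(".cluster", covariate_set)
  dat <- dat[complete.cases(dat[, use, drop = FALSE]), use, drop = FALSE]
  K <- nlevels(droplevels(dat$.cluster))
  if (K < 2) stop("need >= 2 retained clusters on the analysis set")
  dat$.cluster <- droplevels(dat$.cluster)

  mm <- model.matrix(as.formula(
    paste("~", paste(covariate_set, collapse = " + "))), dat)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    involved <- unique(unlist(lapply(aliased, function(a) {
      covariate_set[vapply(covariate_set, function(v)
        grepl(v, a, fixed = TRUE), TRUE)]
    })))
    # a column aliased with another names both sides of the collinearity
    partners <- covariate_set[vapply(covariate_set, function(v) {
      col <- grep(paste0("^", v), colnames(mm))
      length(col) > 0 && any(vapply(aliased, function(a) {
        acol <- match(a, colnames(mm))
        cc <- suppressWarnings(stats::cor(mm[, acol], mm[, col[1]]))
        is.finite(cc) && abs(cc) > 0.999
      }, TRUE))
    }, TRUE)]
    stop("rank-deficient covariate set; aliased: ",
         paste(union(involved, partners), collapse = ", "))
  }
  n_par <- (K - 1L) * ncol(mm)
  if (guard && nrow(dat) < guard_ratio * n_par)
    stop("only ", nrow(dat), " complete cases for ", n_par,
         " parameters; need >= ", guard_ratio * n_par,
         " (set guard = FALSE to override)")

  full <- fit_multinom(as.formula(
    paste(".cluster ~", paste(covariate_set, collapse = " + "))), dat)
  rows <- lapply(covariate_set, function(v) {
    rest <- setdiff(covariate_set, v)
    rhs <- if (length(rest)) paste(rest, collapse = " + ") else "1"
    red <- fit_multinom(as.formula(paste(".cluster ~", rhs)), dat)
    q_v <- ncol(model.matrix(as.formula(paste("~", v)), dat)) - 1L
    lrt <- multinom_lrt(full, red, (K - 1L) * q_v)
    data.frame(covariate = v, n = nrow(dat), df = lrt$df,
               p_multivariable = lrt$p.value, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Covariate-by-covariate association table
#'
#' Runs [membership_model()] for each covariate and merges in the mutually
#' adjusted p-values from [multivariable_membership()], giving the layout
#' of the study's characteristics tables (unadjusted / multivariable
#' adjusted columns).
#'
#' @inheritParams multivariable_membership
#' @param multivariable Also fit the mutually adjusted model.
#' @return Data frame, one row per covariate.
#' @export
association_table <- function(partition, covariates, covariate_set,
                              adjusters = c("age", "ethnicity", "education"),
                              reference = NULL, multivariable = TRUE) {
  uni <- do.call(rbind, lapply(covariate_set, function(v)
    membership_model(partition, covariates, v,
                     adjusters = setdiff(adjusters, v),
                     reference = reference)))
  if (multivariable) {
    mv <- tryCatch(
      multivariable_membership(partition, covariates, covariate_set,
                               adjusters = adjusters, reference = reference),
      error = function(e) {
        warning("multivariable model skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(mv))
      uni <- merge(uni, mv[, c("covariate", "p_multivariable")],
                   by = "covariate", sort = FALSE)
  }
  uni
}
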