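# Baseline and cumulative exposure covariates from semiannual visit
# histories. The history table is long-format: subject_id, visit_index,
# is_testing (TRUE on the first neuropsychological testing visit),
# exposure_name, indicator (0/1/NA). All non-testing rows precede the
# testing visit in time.

check_history <- function(history) {
  need <- c("subject_id", "visit_index", "exposure_name", "indicator")
  if (!all(need %in% names(history)))
    stop("history must have columns: ", paste(need, collapse = ", "))
  if (!"is_testing" %in% names(history)) history$is_testing <- FALSE
  bad <- !(history$indicator %in% c(0, 1) | is.na(history$indicator))
  if (any(bad)) stop("indicator values must be 0, 1 or NA")
  history
}

#' Baseline exposure indicators
#'
#' Extracts, per subject and exposure, the indicator value at the first
#' neuropsychological testing visit. Missing indicators propagate as `NA`.
#'
#' @param history Exposure history table (see [generate_exposure_history()]
#'   for the layout); must contain testing-visit rows (`is_testing`).
#' @return Wide data frame: `subject_id` plus one `<exposure>_baseline`
#'   column per exposure.
#' @export
baseline_exposures <- function(history) {
  history <- check_history(history)
  tv <- history[history$is_testing, ]
  if (!nrow(tv)) stop("no testing visit found in history")
  # first testing visit per subject x exposure
  tv <- tv[order(tv$subject_id, tv$exposure_name, tv$visit_index), ]
  first <- !duplicated(tv[, c("subject_id", "exposure_name")])
  tv <- tv[first, ]
  wide <- reshape_exposures(tv, value_col = "indicator",
                            suffix = "_baseline")
  wide
}

#' Cumulative exposure proportions
#'
#' For each subject and exposure, the proportion of pre-testing visits
#' with a positive indicator among visits with a non-missing indicator
#' (e.g. exposed at 10 of 30 prior visits gives 0.33). Subjects with zero
#' usable pre-testing visits get `NA`. Denominators are returned for
#' audit.
#'
#' @param history Exposure history table.
#' @return Wide data frame: `subject_id`, one `<exposure>_cum` proportion
#'   column and one `<exposure>_nvisits` denominator column per exposure.
#' @export
cumulative_exposures <- function(history) {
  history <- check_history(history)
  pre <- history[!history$is_testing, ]
  if (!nrow(pre)) stop("no pre-testing visits in history")
  obs <- pre[!is.na(pre$indicator), ]
  if (nrow(obs)) {
    agg <- aggregate(indicator ~ subject_id + exposure_name, data = obs,
                     FUN = function(x) c(p = mean(x), n = length(x)))
    agg$p <- agg$indicator[, "p"]
    agg$n <- agg$indicator[, "n"]
    agg$indicator <- NULL
  } else {
    agg <- data.frame(subject_id = character(), exposure_name = character(),
                      p = numeric(), n = integer(), stringsAsFactors = FALSE)
  }
  # subjects x exposures with no non-missing visits drop out of aggregate;
  # restore them as NA with denominator 0
  full <- expand.grid(subject_id = unique(pre$subject_id),
                      exposure_name = unique(pre$exposure_name),
                      stringsAsFactors = FALSE)
  agg <- merge(full, agg, by = c("subject_id", "exposure_name"),
               all.x = TRUE)
  agg$n[is.na(agg$n)] <- 0L
  prop <- reshape_exposures(agg, value_col = "p", suffix = "_cum")
  denom <- reshape_exposures(agg, value_col = "n", suffix = "_nvisits")
  merge(prop, denom, by = "subject_id")
}

reshape_exposures <- function(long, value_col, suffix) {
  wide <- stats::reshape(
    long[, c("subject_id", "exposure_name", value_col)],
    idvar = "subject_id", timevar = "exposure_name", direction = "wide")
  names(wide) <- sub(paste0("^", value_col, "\\."), "", names(wide))
  exposure_cols <- setdiff(names(wide), "subject_id")
  names(wide)[match(exposure_cols, names(wide))] <-
    paste0(exposure_cols, suffix)
  rownames(wide) <- NULL
  wide[order(wide$subject_id, method = "radix"), , drop = FALSE]
}

#' Low-income indicator from annual household income
#'
#' Strict threshold: income below $12,000 per year codes 1.
#'
#' @param income Annual household income in dollars.
#' @return Integer 0/1 vector (`NA` propagated).
#' @export
flag_low_income <- function(income) {
  as.integer(income < 12000)
}

#' Assemble the per-subject covariate table
#'
#' Merges baseline and cumulative exposure covariates with any additional
#' per-subject baseline covariates (age, education, ...).
#'
#' @param history Exposure history table.
#' @param baseline_covariates Optional data frame keyed by `subject_id`.
#' @return Wide covariate data frame keyed by `subject_id`.
#' @export
build_covariate_table <- function(history, baseline_covariates = NULL) {
  out <- merge(baseline_exposures(history), cumulative_exposures(history),
               by = "subject_id")
  if (!is.null(baseline_covariates))
    out <- merge(baseline_covariates, out, by = "subject_id")
  out[order(out$subject_id, method = "radix"), , drop = FALSE]
}
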