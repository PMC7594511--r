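#' Fit a linear scaled-score transform against a reference sample
#'
#' Computes, per outcome, the reference mean and SD (denominator `n - 1`)
#' from a normative sample — in the emulated study, the seronegative
#' women — defining the affine map
#' `scaled = 10 + 3 * sign * (raw - ref_mean) / ref_sd`.
#' Timed outcomes (where larger raw values mean worse performance) take
#' `sign = -1` so that higher scaled scores always mean better performance.
#'
#' @param reference_raw Named list of numeric vectors of raw scores, one
#'   per outcome, or a long data frame with columns `outcome` and `value`.
#' @param sign Named numeric vector of +1/-1 per outcome, or a single
#'   value recycled; defaults to +1 with -1 for outcomes named in
#'   [motor_outcomes()].
#' @param target_mean,target_sd Scaled-score center and spread
#'   (defaults 10 and 3).
#' @return An object of class `memtraj_scaling`: a data frame with columns
#'   `outcome`, `reference_mean`, `reference_sd`, `sign`, `target_mean`,
#'   `target_sd`.
#' @export
fit_linear_scaling <- function(reference_raw, sign = NULL,
                               target_mean = 10, target_sd = 3) {
  if (is.data.frame(reference_raw)) {
    stopifnot(all(c("outcome", "value") %in% names(reference_raw)))
    reference_raw <- split(reference_raw$value, reference_raw$outcome)
  }
  stopifnot(is.list(reference_raw), length(reference_raw) > 0,
            !is.null(names(reference_raw)), target_sd > 0)
  outs <- names(reference_raw)
  if (is.null(sign)) {
    sign <- setNames(ifelse(outs %in% motor_outcomes(), -1, 1), outs)
  } else if (length(sign) == 1) {
    sign <- setNames(rep(sign, length(outs)), outs)
  }
  if (!all(outs %in% names(sign)))
    stop("sign must cover every outcome")

  rows <- lapply(outs, function(o) {
    x <- reference_raw[[o]]
    x <- x[is.finite(x)]
    if (length(x) < 2) stop("reference for '", o, "' needs >= 2 values")
    s <- sd(x)
    if (s == 0) stop("reference for '", o, "' has zero variance")
    data.frame(outcome = o, reference_mean = mean(x), reference_sd = s,
               sign = unname(sign[o]), target_mean = target_mean,
               target_sd = target_sd, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("memtraj_scaling", "data.frame"))
}

#' Apply a fitted scaled-score transform to a raw long-format table
#'
#' Elementwise affine transform; row order and shape are preserved and
#' `NA` values pass through untouched.
#'
#' @param raw Long data frame with columns `subject_id`, `age_years`,
#'   `outcome`, `value` holding raw scores.
#' @param params A [fit_linear_scaling()] object covering every outcome
#'   present in `raw`.
#' @return `raw` with `value` replaced by scaled scores.
#' @export
apply_scaling <- function(raw, params) {
  stopifnot(inherits(params, "memtraj_scaling"),
            all(c("outcome", "value") %in% names(raw)))
  missing_out <- setdiff(unique(raw$outcome), params$outcome)
  if (length(missing_out))
    stop("no scaling parameters for outcome(s): ",
         paste(missing_out, collapse = ", "))
  idx <- match(raw$outcome, params$outcome)
  raw$value <- params$target_mean[idx] + params$target_sd[idx] *
    params$sign[idx] * (raw$value - params$reference_mean[idx]) /
    params$reference_sd[idx]
  raw
}

#' Invert a scaled-score transform
#'
#' @param scaled Long data frame of scaled scores (as from
#'   [apply_scaling()]).
#' @param params The [fit_linear_scaling()] object used to scale.
#' @return The table with `value` back on the raw scale.
#' @export
invert_scaling <- function(scaled, params) {
  stopifnot(inherits(params, "memtraj_scaling"))
  idx <- match(scaled$outcome, params$outcome)
  scaled$value <- params$reference_mean[idx] +
    params$reference_sd[idx] * (scaled$value - params$target_mean[idx]) /
    (params$target_sd[idx] * params$sign[idx])
  scaled
}

#' Single imputation of missing test items
#'
#' Applies the study's imputation rule visit by visit: when a subject-visit
#' is missing exactly one of the declarative-memory items, the missing
#' value is replaced by the mean of that visit's observed
#' declarative-memory scaled scores. Visits missing two or more items are
#' dropped (all their memory rows removed) with a warning; outcomes outside
#' `outcomes` (e.g. motor tests) are never imputed or dropped.
#'
#' @param cohort Long cohort data frame (`subject_id`, `age_years`,
#'   `outcome`, `value`), scaled scores, `NA` marking missing items.
#' @param outcomes The declarative-memory outcome set subject to the rule.
#' @return The completed cohort; imputed rows are flagged in a logical
#'   `imputed` attribute-free column `imputed`, and the dropped visits are
#'   recorded in attribute `"dropped_visits"` (data frame of `subject_id`,
#'   `age_years`, `n_missing`).
#' @export
impute_missing_items <- function(cohort, outcomes = memory_outcomes()) {
  mem <- cohort$outcome %in% outcomes
  cohort$imputed <- FALSE
  key <- interaction(cohort$subject_id, cohort$age_years, drop = TRUE)
  dropped <- list()
  for (k in levels(key)) {
    rows <- which(key == k & mem)
    if (!length(rows)) next
    miss <- rows[is.na(cohort$value[rows])]
    if (length(miss) == 0) next
    if (length(miss) == 1) {
      obs <- cohort$value[setdiff(rows, miss)]
      cohort$value[miss] <- mean(obs)
      cohort$imputed[miss] <- TRUE
    } else {
      dropped[[length(dropped) + 1L]] <- data.frame(
        subject_id = cohort$subject_id[rows[1]],
        age_years = cohort$age_years[rows[1]],
        n_missing = length(miss), stringsAsFactors = FALSE)
      cohort <- cohort[-rows, ]
      key <- key[-rows]
      mem <- mem[-rows]
    }
  }
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(subject_id = character(), age_years = numeric(),
               n_missing = integer(), stringsAsFactors = FALSE)
  if (nrow(dropped))
    warning(nrow(dropped), " visit(s) missing >= 2 memory items dropped")
  attr(cohort, "dropped_visits") <- dropped
  rownames(cohort) <- NULL
  cohort
}
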