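# Plain-CSV readers/writers for the pipeline's tabular artifacts.

#' Read / write a long-format cohort
#'
#' Columns: `subject_id`, `age_years`, `outcome`, `value`.
#' @param path File path.
#' @param cohort Cohort data frame.
#' @return `read_cohort()` returns the data frame; writers return the path
#'   invisibly.
#' @export
read_cohort <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age_years", "outcome", "value")
  if (!all(need %in% names(x)))
    stop("cohort file must have columns: ", paste(need, collapse = ", "))
  x$subject_id <- as.character(x$subject_id)
  x
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort[, c("subject_id", "age_years", "outcome", "value")],
            path, row.names = FALSE)
  invisible(path)
}

#' Read / write an exposure history
#'
#' Columns: `subject_id`, `visit_index`, `is_testing`, `exposure_name`,
#' `indicator`.
#' @param path File path.
#' @param history History data frame.
#' @export
read_exposure_history <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  x$subject_id <- as.character(x$subject_id)
  if ("is_testing" %in% names(x)) x$is_testing <- as.logical(x$is_testing)
  check_history(x)
}

#' @rdname read_exposure_history
#' @export
write_exposure_history <- function(history, path) {
  write.csv(history, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a partition
#'
#' CSV with `subject_id`, `cluster` (`NA` for excluded subjects), and
#' `excluded` flag.
#' @param partition A `memtraj_partition`.
#' @param path File path.
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(
    subject_id = c(names(partition$labels), partition$excluded),
    cluster = c(partition$labels,
                rep(NA_integer_, length(partition$excluded))),
    excluded = c(rep(FALSE, length(partition$labels)),
                 rep(TRUE, length(partition$excluded))),
    stringsAsFactors = FALSE)
  df <- df[order(df$subject_id, method = "radix"), ]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  kept <- df[!df$excluded, ]
  p <- new_partition(kept$cluster, as.character(kept$subject_id),
                     excluded = as.character(df$subject_id[df$excluded]),
                     method = "file")
  p
}

#' Write a similarity matrix as CSV
#' @param S Matrix with subject-id dimnames.
#' @param path File path.
#' @export
write_similarity <- function(S, path) {
  write.csv(data.frame(subject_id = rownames(S), S, check.names = FALSE),
            path, row.names = FALSE)
  invisible(path)
}

#' Serialize / load scaled-score parameters as JSON
#' @param params A [fit_linear_scaling()] object.
#' @param path File path.
#' @export
write_scaling <- function(params, path) {
  jsonlite::write_json(as.data.frame(unclass(params)), path,
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_scaling
#' @export
read_scaling <- function(path) {
  df <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  structure(df, class = c("memtraj_scaling", "data.frame"))
}
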