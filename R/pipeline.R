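# End-to-end orchestration: eligibility -> imputation -> clustering ->
# small-cluster filter -> per-cluster characterization -> membership
# associations, run independently within strata (e.g. serostatus x race),
# with a JSON run manifest for reproducibility.

#' Apply the visit-count eligibility rule
#'
#' Removes subjects with fewer than `min_assessments` testing visits
#' (protocol: at least two complete neuropsychological batteries) and logs
#' exclusions.
#'
#' @param cohort Long cohort.
#' @param min_assessments Minimum testing visits (>= 2 by default).
#' @return The filtered cohort; attribute `"exclusions"` is a data frame
#'   of `subject_id`, `n_visits`, `reason`.
#' @export
apply_eligibility <- function(cohort, min_assessments = 2) {
  stopifnot(min_assessments >= 1)
  visits <- tapply(cohort$age_years, cohort$subject_id,
                   function(a) length(unique(a)))
  drop_ids <- names(visits)[visits < min_assessments]
  out <- cohort[!cohort$subject_id %in% drop_ids, ]
  if (!nrow(out)) stop("no eligible subjects remain")
  log <- data.frame(subject_id = drop_ids,
                    n_visits = as.integer(visits[drop_ids]),
                    reason = rep(sprintf("fewer than %d assessments",
                                         min_assessments),
                                 length(drop_ids)),
                    stringsAsFactors = FALSE)
  attr(out, "exclusions") <- log
  rownames(out) <- NULL
  out
}

#' Run the full analysis within one stratum
#'
#' @param cohort Long cohort (scaled scores; may contain `NA` items and
#'   contrast-domain outcomes).
#' @param covariates Optional covariate table keyed by `subject_id` for
#'   the association stage.
#' @param outcomes Memory outcomes modelled jointly.
#' @param contrast_outcomes Contrast-domain outcomes present in the cohort
#'   (skipped when absent).
#' @param control,mcmc Model and sampler settings.
#' @param min_assessments Eligibility threshold.
#' @param k_max,min_size Partition-selection settings.
#' @param covariate_set Covariates tested for membership association.
#' @param adjusters Adjustment covariates of the membership models.
#' @return List: `partition`, `psm`, `draws`, `pear_by_k`,
#'   `trajectory_table`, `contrast_table`, `association`, `exclusions`,
#'   `counts`.
#' @export
run_pipeline <- function(cohort, covariates = NULL,
                         outcomes = memory_outcomes(),
                         contrast_outcomes = intersect(motor_outcomes(),
                                                       unique(cohort$outcome)),
                         control = dp_control(), mcmc = mcmc_control(),
                         min_assessments = 2, k_max = 10, min_size = 15,
                         covariate_set = NULL,
                         adjusters = c("age", "ethnicity", "education")) {
  n_input <- length(unique(cohort$subject_id))
  cohort <- apply_eligibility(cohort, min_assessments)
  elig_log <- attr(cohort, "exclusions")
  cohort <- impute_missing_items(cohort, outcomes = outcomes)

  cl <- cluster_trajectories(cohort, outcomes = outcomes, control = control,
                             mcmc = mcmc, k_max = k_max, min_size = min_size)
  part <- cl$partition

  traj <- if (part$k >= 1)
    trajectory_summary_table(cohort, part, outcomes) else NULL
  contrast <- if (part$k >= 2 && length(contrast_outcomes))
    cross_domain_contrast(cohort, part, contrast_outcomes) else NULL

  assoc <- NULL
  if (!is.null(covariates) && part$k >= 2) {
    if (is.null(covariate_set))
      covariate_set <- setdiff(names(covariates), "subject_id")
    ref <- reference_cluster(cohort, part, outcomes[2])
    assoc <- tryCatch(
      association_table(part, covariates, covariate_set,
                        adjusters = adjusters, reference = ref),
      error = function(e) {
        warning("association stage failed: ", conditionMessage(e))
        NULL
      })
  }

  list(partition = part, psm = cl$psm, draws = cl$draws,
       pear_by_k = cl$pear_by_k,
       trajectory_table = traj, contrast_table = contrast,
       association = assoc,
       exclusions = elig_log,
       counts = list(input = n_input,
                     eligible = n_input - nrow(elig_log),
                     retained = length(part$labels),
                     excluded_small_cluster = length(part$excluded)))
}

#' Run the pipeline independently within strata
#'
#' Splits subjects by stratum (e.g. serostatus by race), runs
#' [run_pipeline()] in each stratum of sufficient size, optionally writes
#' per-stratum artifacts (partition, PSM, PEAR-by-k, trajectory and
#' association tables as CSV) and a global JSON manifest, and returns all
#' results. Strata below `min_stratum_size` are skipped with a warning.
#'
#' @param cohort Long cohort covering all strata.
#' @param strata Data frame `subject_id`, `stratum` (one row per subject).
#' @param covariates Optional covariate table.
#' @param out_dir Optional output directory for artifacts.
#' @param seed Integer seed; stratum `s` (in sorted order) runs with seed
#'   `seed + s - 1` so reruns are deterministic.
#' @param min_stratum_size Minimum subjects to attempt a stratum.
#' @param ... Passed to [run_pipeline()].
#' @return List with `results` (per stratum) and `manifest`.
#' @export
run_stratified <- function(cohort, strata, covariates = NULL,
                           out_dir = NULL, seed = 1,
                           min_stratum_size = 30, ...) {
  stopifnot(all(c("subject_id", "stratum") %in% names(strata)))
  if (anyDuplicated(strata$subject_id))
    stop("strata must assign each subject exactly once")
  missing_ids <- setdiff(unique(cohort$subject_id), strata$subject_id)
  if (length(missing_ids))
    stop(length(missing_ids), " subject(s) lack a stratum assignment")
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  strat_levels <- sort(unique(as.character(strata$stratum)), method = "radix")
  dots <- list(...)
  results <- list()
  for (s in seq_along(strat_levels)) {
    sname <- strat_levels[s]
    ids <- strata$subject_id[strata$stratum == sname]
    sub <- cohort[cohort$subject_id %in% ids, ]
    if (length(unique(sub$subject_id)) < min_stratum_size) {
      warning("stratum '", sname, "' below minimum size; skipped")
      next
    }
    mcmc <- dots$mcmc %||% mcmc_control()
    mcmc$seed <- as.integer(seed + s - 1)
    args <- c(list(cohort = sub,
                   covariates = if (is.null(covariates)) NULL else
                     covariates[covariates$subject_id %in% ids, ],
                   mcmc = mcmc),
              dots[setdiff(names(dots), "mcmc")])
    res <- do.call(run_pipeline, args)
    results[[sname]] <- res
    if (!is.null(out_dir)) {
      sdir <- file.path(out_dir, gsub("[^A-Za-z0-9_.-]", "_", sname))
      dir.create(sdir, showWarnings = FALSE)
      write_partition(res$partition, file.path(sdir, "partition.csv"))
      write_similarity(res$psm, file.path(sdir, "psm.csv"))
      write.csv(res$pear_by_k, file.path(sdir, "pear_by_k.csv"),
                row.names = FALSE)
      if (!is.null(res$trajectory_table))
        write.csv(res$trajectory_table,
                  file.path(sdir, "trajectory_summary.csv"),
                  row.names = FALSE)
      if (!is.null(res$association))
        write.csv(res$association, file.path(sdir, "associations.csv"),
                  row.names = FALSE)
    }
  }

  manifest <- list(
    package = "memtraj",
    version = as.character(utils::packageVersion("memtraj")),
    created = format(Sys.time(), tz = "UTC"),
    seed = seed,
    strata = lapply(results, function(r) r$counts),
    mcmc = {
      m <- dots$mcmc %||% mcmc_control()
      list(n_iter = m$n_iter, n_burn = m$n_burn, thin = m$thin,
           n_aux = m$n_aux)
    })
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(results = results, manifest = manifest)
}

#' Read a run configuration from YAML or JSON
#'
#' Thin loader for the command-line runner: returns the file's contents as
#' a named list with defaults filled in for missing MCMC fields.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$mcmc <- do.call(mcmc_control, as.list(cfg$mcmc %||% list()))
  cfg
}
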