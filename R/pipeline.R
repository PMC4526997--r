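# End-to-end orchestration: simulate -> features -> associations -> models.
# These functions back the command-line interface (inst/cli/mobmood.R) and
# give tests a single deterministic entry point.

#' Apply the data-sufficiency filter to a feature table
#'
#' Location-derived features of participants whose location coverage is not
#' above 50% are set to `NA`, and likewise usage features for participants
#' without usage coverage, mirroring a study design in which the two sensor
#' streams are analyzed on independently eligible subsets.
#'
#' @param features Feature table from [extract_features_cohort()].
#' @param coverage Data frame of [assess_coverage()] rows, one per
#'   participant.
#' @return The feature table with ineligible entries blanked.
#' @export
apply_coverage_filter <- function(features, coverage) {
  m <- match(features$participant_id, coverage$participant_id)
  loc_cols <- c("location_variance", "entropy", "normalized_entropy",
                "home_stay", "circadian_movement", "transition_time",
                "total_distance", "n_clusters")
  use_cols <- c("usage_frequency", "usage_duration")
  bad_loc <- !coverage$eligible_location[m]
  bad_use <- !coverage$eligible_usage[m]
  features[bad_loc, loc_cols] <- NA_real_
  features[bad_use, use_cols] <- NA_real_
  features
}

#' Coverage report for a list of participant records
#'
#' @param records List of [participant_record()]s.
#' @param study_start,study_end Epoch-second bounds of the study period.
#' @param bin_s Nominal sampling period (s).
#' @return Data frame of one [assess_coverage()] row per participant.
#' @export
assess_coverage_cohort <- function(records, study_start, study_end,
                                   bin_s = 300) {
  do.call(rbind, lapply(records, assess_coverage, study_start = study_start,
                        study_end = study_end, bin_s = bin_s))
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Simulates a cohort, writes its raw logs, reads them back (so the analysis
#' consumes exactly what the file formats carry), applies the coverage
#' filter, extracts features, computes the association table, and evaluates
#' the requested feature sets with the bootstrapped leave-one-participant-out
#' protocol. All outputs are plain CSVs under `out_dir`; a fixed seed makes
#' the run byte-for-byte reproducible.
#'
#' @param out_dir Output directory.
#' @param seed Master seed (overrides `spec$seed`).
#' @param spec [cohort_spec()].
#' @param link [severity_link()].
#' @param baseline [behavior_params()].
#' @param cfg [preprocess_config()].
#' @param feature_sets Feature sets for [evaluate_feature_sets()].
#' @param B Bootstrap resamples per feature set.
#' @param low_coverage_frac Passed to [generate_cohort()].
#' @return Invisibly, a list with `features`, `associations`, `evaluation`.
#' @export
run_pipeline <- function(out_dir, seed = 1L, spec = cohort_spec(),
                         link = severity_link(score_range = c(0L, 10L)),
                         baseline = behavior_params(),
                         cfg = preprocess_config(),
                         feature_sets = list("normalized_entropy",
                                             c("usage_frequency", "usage_duration")),
                         B = 25, low_coverage_frac = 0) {
  spec$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(spec, link, baseline, low_coverage_frac)
  data_dir <- file.path(out_dir, "data")
  write_cohort(cohort, data_dir)
  records <- read_cohort(data_dir)

  horizon <- spec$days * 86400
  coverage <- assess_coverage_cohort(records, 0, horizon,
                                     bin_s = spec$sampling_period_s)
  utils::write.csv(coverage, file.path(out_dir, "coverage.csv"),
                   row.names = FALSE, quote = FALSE)

  features <- extract_features_cohort(records, cfg, seed = seed)
  features <- apply_coverage_filter(features, coverage)
  write_feature_table(features, file.path(out_dir, "features.csv"))

  assoc <- associate_features(features)
  utils::write.csv(assoc, file.path(out_dir, "associations.csv"),
                   row.names = FALSE, quote = FALSE, na = "NA")

  evaluation <- evaluate_feature_sets(features, feature_sets, B = B,
                                      seed = seed)
  utils::write.csv(evaluation, file.path(out_dir, "evaluation.csv"),
                   row.names = FALSE, quote = FALSE, na = "NA")
  invisible(list(features = features, associations = assoc,
                 evaluation = evaluation, coverage = coverage))
}
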