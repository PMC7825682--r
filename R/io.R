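# Patient CSV I/O and pipeline configuration.

#' Read patient records from CSV
#'
#' Expects the canonical header (`id, gender, age, systolic_bp,
#' diastolic_bp, hbp_flag, bmi, neck_circumference, ess, ahi_before,
#' ahi_after, osa_label`); optional columns may be missing or empty, unknown
#' columns are ignored. Records violating the domain invariants are dropped
#' with their row numbers messaged.
#'
#' @param path CSV file path.
#' @return Validated patient records (see [validate_patients()]).
#' @export
read_patients <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "gender", "age", "bmi", "neck_circumference", "ess",
                "ahi_before")
  if (!all(required %in% names(raw)))
    stop("malformed header; missing columns: ",
         paste(setdiff(required, names(raw)), collapse = ", "))
  for (col in setdiff(patient_columns, names(raw))) raw[[col]] <- NA
  raw <- raw[patient_columns]
  raw$id <- as.character(raw$id)
  raw$hbp_flag <- as.logical(raw$hbp_flag)
  raw$osa_label <- as.logical(raw$osa_label)
  for (col in c("age", "systolic_bp", "diastolic_bp", "bmi",
                "neck_circumference", "ess", "ahi_before", "ahi_after"))
    raw[[col]] <- as.numeric(raw[[col]])
  out <- validate_patients(raw)
  rej <- attr(out, "rejected")
  if (nrow(rej) > 0)
    message("read_patients: skipped rows ",
            paste(rej$row, collapse = ", "))
  out
}

#' Write patient records to CSV
#'
#' @param records Patient records.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_patients <- function(records, path) {
  for (col in setdiff(patient_columns, names(records))) records[[col]] <- NA
  utils::write.csv(records[patient_columns], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Pipeline configuration
#'
#' All tunable parameters of the analysis in one object: discretization
#' cutoffs, the compatibility threshold, community-detection options, the
#' response-class and representativeness thresholds, the ROC candidate
#' cutoffs, and the synthetic cohort settings. Round-trips through YAML.
#'
#' @param seed Master seed for simulation and detection.
#' @param compatibility_threshold Minimum shared classes for an edge (1-6).
#' @param weighted Weight-aware modularity (default TRUE).
#' @param best_threshold Improvement percentage separating best from good.
#' @param representative_threshold Prevalence for a representative class.
#' @param roc_cutoffs Candidate NC cutoffs for the ROC table.
#' @param nc_eval_cutoffs NC cutoffs evaluated against the response classes.
#' @param rules [discretization_rules()].
#' @param d1,d2,d3 Cohort specifications.
#' @param response [response_model_spec()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            compatibility_threshold = 4L,
                            weighted = TRUE,
                            best_threshold = 85,
                            representative_threshold = 0.70,
                            roc_cutoffs = 39:46,
                            nc_eval_cutoffs = 39:43,
                            rules = discretization_rules(),
                            d1 = d1_cohort_spec(),
                            d2 = d2_cohort_spec(),
                            d3 = d3_cohort_spec(),
                            response = response_model_spec()) {
  stopifnot(compatibility_threshold >= 1, compatibility_threshold <= 6,
            best_threshold >= 0, best_threshold <= 100,
            representative_threshold > 0, representative_threshold <= 1)
  structure(list(seed = as.integer(seed),
                 compatibility_threshold = as.integer(compatibility_threshold),
                 weighted = weighted, best_threshold = best_threshold,
                 representative_threshold = representative_threshold,
                 roc_cutoffs = roc_cutoffs,
                 nc_eval_cutoffs = nc_eval_cutoffs,
                 rules = rules, d1 = d1, d2 = d2, d3 = d3,
                 response = response),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `write_config()` the path invisibly; `read_config()` the
#'   reconstructed `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  yaml::write_yaml(strip(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  null_ok <- function(x) if (is.null(x)) NULL else x
  spec_of <- function(s) do.call(cohort_spec, s[setdiff(names(s), character(0))])
  pipeline_config(
    seed = raw$seed,
    compatibility_threshold = raw$compatibility_threshold,
    weighted = raw$weighted,
    best_threshold = raw$best_threshold,
    representative_threshold = raw$representative_threshold,
    roc_cutoffs = raw$roc_cutoffs,
    nc_eval_cutoffs = raw$nc_eval_cutoffs,
    rules = do.call(discretization_rules,
                    raw$rules[setdiff(names(raw$rules), character(0))]),
    d1 = spec_of(raw$d1), d2 = spec_of(raw$d2), d3 = spec_of(raw$d3),
    response = do.call(response_model_spec, raw$response))
}
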