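#' @keywords internal
"_PACKAGE"

#' Ordered AHI severity levels
#'
#' Severity of obstructive sleep apnea graded from the apnea-hypopnea index
#' (AHI, events per hour of sleep): `norm` (< 5), `mild` (5 to < 15),
#' `mod` (15 to < 30), `sev` (>= 30).
#'
#' @format Character vector of the four levels in increasing severity order.
#' @export
severity_levels <- c("norm", "mild", "mod", "sev")

#' Classify AHI into OSA severity classes
#'
#' Maps apnea-hypopnea index values to the standard four severity classes:
#' normal/low risk below 5 events/h, mild from 5 to below 15, moderate from
#' 15 to below 30, severe at 30 and above.
#'
#' @param ahi Numeric vector of AHI values (events/h), all non-negative.
#' @return Ordered factor with levels `norm < mild < mod < sev`.
#' @examples
#' classify_ahi_severity(c(0, 4.9, 5, 14.9, 15, 29.9, 30, 80))
#' @export
classify_ahi_severity <- function(ahi) {
  if (!is.numeric(ahi)) stop("`ahi` must be numeric")
  if (anyNA(ahi)) stop("`ahi` contains missing values")
  if (any(ahi < 0)) stop("`ahi` must be non-negative")
  cls <- cut(ahi, breaks = c(-Inf, 5, 15, 30, Inf),
             labels = severity_levels, right = FALSE)
  factor(cls, levels = severity_levels, ordered = TRUE)
}

#' Discretization rules for the six risk-compatibility parameters
#'
#' Cutoffs used to map raw clinical measurements to the six parameter
#' classes driving the compatibility network. Defaults follow standard sleep
#' laboratory practice: hypertension if systolic > 140 mmHg or
#' diastolic > 90 mmHg; obesity if BMI > 30 kg/m^2 (strict); thick neck if
#' neck circumference >= 43 cm (men) / >= 40 cm (women); sleepiness if
#' Epworth score >= 11; age groups (-Inf,20], (20,40], (40,60], (60,Inf)
#' coded 0..3. Age boundaries are half-open and configurable because ages
#' exactly on a boundary are otherwise ambiguous.
#'
#' @param systolic_hbp Systolic cutoff (mmHg), hypertensive if strictly above.
#' @param diastolic_hbp Diastolic cutoff (mmHg), hypertensive if strictly above.
#' @param bmi_obese BMI cutoff (kg/m^2), obese if strictly above.
#' @param nc_thick_male,nc_thick_female Neck circumference cutoffs (cm),
#'   thick neck if greater than or equal.
#' @param ess_sleepy Epworth score cutoff, sleepy if greater than or equal.
#' @param age_breaks Increasing numeric vector of age-group boundaries (years);
#'   group g contains ages in (breaks[g], breaks[g+1]], groups coded from 0.
#' @return A list of class `discretization_rules`.
#' @export
discretization_rules <- function(systolic_hbp = 140, diastolic_hbp = 90,
                                 bmi_obese = 30,
                                 nc_thick_male = 43, nc_thick_female = 40,
                                 ess_sleepy = 11,
                                 age_breaks = c(20, 40, 60)) {
  stopifnot(is.numeric(age_breaks), !is.unsorted(age_breaks, strictly = TRUE))
  structure(list(systolic_hbp = systolic_hbp, diastolic_hbp = diastolic_hbp,
                 bmi_obese = bmi_obese, nc_thick_male = nc_thick_male,
                 nc_thick_female = nc_thick_female, ess_sleepy = ess_sleepy,
                 age_breaks = age_breaks),
            class = "discretization_rules")
}

# Column roster of the patient-record data.frame dialect. BP columns may be
# all-NA when hbp_flag is supplied instead.
patient_columns <- c("id", "gender", "age", "systolic_bp", "diastolic_bp",
                     "hbp_flag", "bmi", "neck_circumference", "ess",
                     "ahi_before", "ahi_after", "osa_label")

#' Validate patient records
#'
#' Checks each record against the domain invariants: gender in
#' {male, female}; age >= 0; BMI > 0; neck circumference > 0; Epworth score
#' an integer in [0, 24]; AHI values >= 0; and blood-pressure information
#' present either as both systolic and diastolic values or as an `hbp_flag`.
#' Invalid records are dropped, with reasons attached.
#'
#' @param records Data frame in the patient-record dialect
#'   (see [read_patients()]).
#' @param quiet Suppress the rejection message.
#' @return The valid subset, with a `rejected` attribute holding a data frame
#'   of row numbers and reasons for the dropped records.
#' @export
validate_patients <- function(records, quiet = FALSE) {
  records <- as.data.frame(records)
  missing_cols <- setdiff(c("id", "gender", "age", "bmi", "neck_circumference",
                            "ess", "ahi_before"), names(records))
  if (length(missing_cols) > 0)
    stop("patient records missing required columns: ",
         paste(missing_cols, collapse = ", "))
  for (col in setdiff(patient_columns, names(records))) records[[col]] <- NA
  records <- records[patient_columns]
  if (anyDuplicated(records$id)) stop("duplicate patient ids")

  reasons <- character(nrow(records))
  flag <- function(bad, why) {
    bad <- which(bad)
    reasons[bad] <<- ifelse(reasons[bad] == "", why,
                            paste(reasons[bad], why, sep = "; "))
  }
  flag(!(records$gender %in% c("male", "female")), "gender not male/female")
  flag(is.na(records$age) | records$age < 0, "invalid age")
  flag(is.na(records$bmi) | records$bmi <= 0, "bmi not positive")
  flag(is.na(records$neck_circumference) | records$neck_circumference <= 0,
       "neck circumference not positive")
  flag(is.na(records$ess) | records$ess < 0 | records$ess > 24 |
         records$ess != round(records$ess), "ess outside 0..24")
  flag(is.na(records$ahi_before) | records$ahi_before < 0,
       "invalid ahi_before")
  flag(!is.na(records$ahi_after) & records$ahi_after < 0, "negative ahi_after")
  flag(is.na(records$hbp_flag) &
         (is.na(records$systolic_bp) | is.na(records$diastolic_bp)),
       "no blood pressure information")

  bad <- reasons != ""
  rejected <- data.frame(row = which(bad), id = records$id[bad],
                         reason = reasons[bad], stringsAsFactors = FALSE)
  if (!quiet && nrow(rejected) > 0)
    message("validate_patients: rejected ", nrow(rejected), " of ",
            nrow(records), " records")
  out <- records[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Discretize patient records into six-parameter class profiles
#'
#' Converts raw measurements to the six classes used for risk compatibility:
#' gender (M/F), age group (0-3), hypertension, obesity, thick neck and
#' sleepiness. An explicit `hbp_flag` overrides raw blood-pressure values.
#' Thin neck is the complement of thick neck, so only the latter is stored.
#'
#' @param records Validated patient records (see [validate_patients()]).
#' @param rules Cutoff configuration from [discretization_rules()].
#' @return Data frame of class profiles: `id`, `gender_class` ("M"/"F"),
#'   `age_group` (integer 0..length(age_breaks)), and logicals `hbp`,
#'   `obese`, `thick_neck`, `sleepiness`.
#' @examples
#' rec <- data.frame(id = "p1", gender = "male", age = 55, systolic_bp = 150,
#'                   diastolic_bp = 85, bmi = 32, neck_circumference = 43,
#'                   ess = 12, ahi_before = 45)
#' discretize_patients(rec)
#' @export
discretize_patients <- function(records, rules = discretization_rules()) {
  stopifnot(inherits(rules, "discretization_rules"))
  records <- validate_patients(records, quiet = TRUE)
  if (nrow(attr(records, "rejected")) > 0)
    stop("invalid patient records: ",
         paste(attr(records, "rejected")$reason, collapse = "; "))
  hbp <- ifelse(!is.na(records$hbp_flag), records$hbp_flag,
                records$systolic_bp > rules$systolic_hbp |
                  records$diastolic_bp > rules$diastolic_hbp)
  male <- records$gender == "male"
  nc_cut <- ifelse(male, rules$nc_thick_male, rules$nc_thick_female)
  # (lo, hi] closure: a boundary age stays in the lower group
  age_group <- findInterval(records$age, rules$age_breaks, left.open = TRUE)
  data.frame(id = as.character(records$id),
             gender_class = ifelse(male, "M", "F"),
             age_group = as.integer(age_group),
             hbp = as.logical(hbp),
             obese = records$bmi > rules$bmi_obese,
             thick_neck = records$neck_circumference >= nc_cut,
             sleepiness = records$ess >= rules$ess_sleepy,
             stringsAsFactors = FALSE)
}

profile_columns <- c("gender_class", "age_group", "hbp", "obese",
                     "thick_neck", "sleepiness")

# Internal: class profiles as a character matrix (one column per class slot)
# so pairwise slot comparisons vectorize.
profile_matrix <- function(profiles) {
  stopifnot(all(c("id", profile_columns) %in% names(profiles)))
  m <- vapply(profile_columns, function(cl) as.character(profiles[[cl]]),
              character(nrow(profiles)))
  if (nrow(profiles) == 1L) m <- matrix(m, nrow = 1,
                                        dimnames = list(NULL, profile_columns))
  rownames(m) <- profiles$id
  m
}

#' Summarize a cohort in the style of a baseline-characteristics table
#'
#' Means and standard deviations for the continuous measurements plus counts
#' and percentages for the derived binary classes (obesity, thick neck,
#' sleepiness, severe OSA before/after CPAP).
#'
#' @param records Patient records.
#' @param rules Discretization rules for the derived classes.
#' @return A data frame with one row per parameter: `parameter`, `value`,
#'   where counts are reported as `n` and percentages rounded to 2 decimals.
#' @export
cohort_summary <- function(records, rules = discretization_rules()) {
  records <- validate_patients(records, quiet = TRUE)
  prof <- discretize_patients(records, rules)
  n <- nrow(records)
  pct <- function(k) round(100 * k / n, 2)
  msd <- function(x) sprintf("%.2f+/-%.2f", mean(x), stats::sd(x))
  sev_before <- sum(records$ahi_before >= 30)
  has_after <- !is.na(records$ahi_after)
  rows <- list(
    c("n", as.character(n)),
    c("male n (%)", sprintf("%d (%.2f%%)", sum(prof$gender_class == "M"),
                            pct(sum(prof$gender_class == "M")))),
    c("age (years)", msd(records$age)),
    c("bmi (kg/m2)", msd(records$bmi)),
    c("obesity n (%)", sprintf("%d (%.2f%%)", sum(prof$obese),
                               pct(sum(prof$obese)))),
    c("neck circumference (cm)", msd(records$neck_circumference)),
    c("thick neck n (%)", sprintf("%d (%.2f%%)", sum(prof$thick_neck),
                                  pct(sum(prof$thick_neck)))),
    c("ess (0-24)", msd(records$ess)),
    c("sleepiness n (%)", sprintf("%d (%.2f%%)", sum(prof$sleepiness),
                                  pct(sum(prof$sleepiness)))),
    c("ahi before cpap", msd(records$ahi_before)),
    c("severe before cpap n (%)", sprintf("%d (%.2f%%)", sev_before,
                                          pct(sev_before))))
  if (any(has_after)) {
    sev_after <- sum(records$ahi_after[has_after] >= 30)
    rows <- c(rows, list(
      c("ahi after cpap", msd(records$ahi_after[has_after])),
      c("severe after cpap n (%)", sprintf("%d (%.2f%%)", sev_after,
                                           pct(sev_after)))))
  }
  data.frame(parameter = vapply(rows, `[`, "", 1),
             value = vapply(rows, `[`, "", 2), stringsAsFactors = FALSE)
}

#' Prevalence as a percentage
#'
#' @param k Count of patients in the class.
#' @param n Cohort size.
#' @param digits Decimal places (default 2, table convention).
#' @return `100 * k / n` rounded to `digits`.
#' @export
prevalence_percent <- function(k, n, digits = 2) {
  stopifnot(n > 0, k >= 0, k <= n)
  round(100 * k / n, digits)
}
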