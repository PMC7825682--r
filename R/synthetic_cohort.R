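# Synthetic cohorts emulating the marginal structure of the three study
# groups: a CPAP-titration cohort (D1-like), an OSA-diagnosed male screening
# cohort (D2-like) and a non-OSA male control cohort (D3-like).

# Quantile of a normal(mean, sd) truncated to [lo, hi], evaluated at u in
# (0,1). Monotone in u, so rank-based dependence injected on u survives.
qtruncnorm <- function(u, mean, sd, lo = 0, hi = Inf) {
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(p_lo + u * (p_hi - p_lo), mean, sd)
}

# AHI marginal: a fraction `sev_fraction` of the mass sits in the severe band
# [30, Inf) of the zero-truncated normal, the rest in [0, 30). Keeps both a
# printed mean/SD and a printed severe prevalence representable at once.
qahi <- function(u, mean, sd, sev_fraction = NULL) {
  if (is.null(sev_fraction)) return(qtruncnorm(u, mean, sd, 0, Inf))
  p_non <- 1 - sev_fraction
  ifelse(u < p_non,
         qtruncnorm(u / p_non, mean, sd, 0, 30),
         qtruncnorm((u - p_non) / pmax(sev_fraction, 1e-12), mean, sd, 30, Inf))
}

#' Specification of a synthetic cohort
#'
#' Marginal means/SDs for the continuous measurements, the male fraction,
#' the hypertension prevalence, the severe-OSA fraction of the AHI marginal,
#' and a target Spearman rank correlation between neck circumference and AHI
#' (injected through a Gaussian copula).
#'
#' @param n Cohort size (> 0).
#' @param male_fraction Fraction of male patients, in \[0, 1\].
#' @param age_mean,age_sd,bmi_mean,bmi_sd,nc_mean,nc_sd,ess_mean,ess_sd,ahi_mean,ahi_sd
#'   Marginal parameters; all quantities drawn from normals truncated at 0
#'   (Epworth additionally rounded and clipped to \[0, 24\]).
#' @param sev_fraction Fraction of the cohort with AHI >= 30 (NULL for a plain
#'   truncated normal AHI marginal).
#' @param p_hbp Hypertension prevalence (emitted as `hbp_flag`).
#' @param nc_ahi_rank_corr Target Spearman correlation between neck
#'   circumference and AHI before treatment (NULL for independence).
#' @param osa_label Diagnosis label attached to every record (logical or NA).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n, male_fraction, age_mean, age_sd, bmi_mean, bmi_sd,
                        nc_mean, nc_sd, ess_mean, ess_sd, ahi_mean, ahi_sd,
                        sev_fraction = NULL, p_hbp = 0.5,
                        nc_ahi_rank_corr = NULL, osa_label = NA) {
  stopifnot(n > 0, n == round(n),
            male_fraction >= 0, male_fraction <= 1,
            age_sd > 0, bmi_sd > 0, nc_sd > 0, ess_sd > 0, ahi_sd > 0,
            p_hbp >= 0, p_hbp <= 1)
  if (!is.null(sev_fraction))
    stopifnot(sev_fraction >= 0, sev_fraction <= 1)
  if (!is.null(nc_ahi_rank_corr))
    stopifnot(abs(nc_ahi_rank_corr) < 1)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Default cohort specifications for the three study groups
#'
#' `d1_cohort_spec()`: 145 patients under one-night CPAP titration (77.24%
#' male, NC 43.12+/-5.06 cm, AHI before 52.28+/-23.58 with 97.93% severe).
#' `d2_cohort_spec()`: 836 OSA-diagnosed males (NC 44.91+/-4.45,
#' AHI 41.68+/-24.07, 93.06% severe, NC-AHI Spearman 0.35).
#' `d3_cohort_spec()`: 65 non-OSA male controls (NC 40.67+/-5.77,
#' AHI 6.01+/-2.42).
#'
#' @param n Cohort size override.
#' @return A [cohort_spec()].
#' @export
d1_cohort_spec <- function(n = 145) {
  cohort_spec(n = n, male_fraction = 112 / 145,
              age_mean = 52.79, age_sd = 12.32,
              bmi_mean = 33.17, bmi_sd = 6.64,
              nc_mean = 43.12, nc_sd = 5.06,
              ess_mean = 11.81, ess_sd = 4.98,
              ahi_mean = 52.28, ahi_sd = 23.58,
              sev_fraction = 142 / 145, p_hbp = 0.68,
              nc_ahi_rank_corr = 0.35, osa_label = TRUE)
}

#' @rdname d1_cohort_spec
#' @export
d2_cohort_spec <- function(n = 836) {
  cohort_spec(n = n, male_fraction = 1,
              age_mean = 51.75, age_sd = 12.47,
              bmi_mean = 33.13, bmi_sd = 6.37,
              nc_mean = 44.91, nc_sd = 4.45,
              ess_mean = 10.01, ess_sd = 5.07,
              ahi_mean = 41.68, ahi_sd = 24.07,
              sev_fraction = 778 / 836, p_hbp = 0.61,
              nc_ahi_rank_corr = 0.35, osa_label = TRUE)
}

#' @rdname d1_cohort_spec
#' @export
d3_cohort_spec <- function(n = 65) {
  cohort_spec(n = n, male_fraction = 1,
              age_mean = 43.63, age_sd = 18.66,
              bmi_mean = 27.81, bmi_sd = 6.37,
              nc_mean = 40.67, nc_sd = 5.77,
              ess_mean = 6.73, ess_sd = 5.06,
              ahi_mean = 6.01, ahi_sd = 2.42,
              sev_fraction = NULL, p_hbp = 0.31,
              nc_ahi_rank_corr = NULL, osa_label = FALSE)
}

#' Response model for one-night CPAP treatment
#'
#' Generative assumption connecting neck thickness to CPAP response: a
#' patient severe before CPAP becomes normal or mild after one night with
#' probability `p_improve_thick_neck` if thick-necked, else
#' `p_improve_thin_neck`. Defaults sit at the midpoints of the 87-89%
#' (best class) and 68-77% (good class) improvement ranges the analysis is
#' designed to recover.
#'
#' @param p_improve_thick_neck,p_improve_thin_neck Improvement probabilities
#'   in \[0, 1\].
#' @return A list of class `response_model_spec`.
#' @export
response_model_spec <- function(p_improve_thick_neck = 0.88,
                                p_improve_thin_neck = 0.72) {
  stopifnot(p_improve_thick_neck >= 0, p_improve_thick_neck <= 1,
            p_improve_thin_neck >= 0, p_improve_thin_neck <= 1)
  structure(list(p_improve_thick_neck = p_improve_thick_neck,
                 p_improve_thin_neck = p_improve_thin_neck),
            class = "response_model_spec")
}

# Internal: draw one cohort of patient records from a cohort_spec. Assumes
# the RNG state has been seeded by the caller.
draw_cohort <- function(spec, id_prefix = "P") {
  n <- spec$n
  gender <- ifelse(stats::runif(n) < spec$male_fraction, "male", "female")
  age <- qtruncnorm(stats::runif(n), spec$age_mean, spec$age_sd)
  bmi <- qtruncnorm(stats::runif(n), spec$bmi_mean, spec$bmi_sd)
  ess <- pmin(round(qtruncnorm(stats::runif(n), spec$ess_mean, spec$ess_sd)),
              24)
  # NC and AHI share a Gaussian copula; the Spearman target rho maps to the
  # copula correlation via r = 2 * sin(pi * rho / 6).
  if (!is.null(spec$nc_ahi_rank_corr)) {
    r <- 2 * sin(pi * spec$nc_ahi_rank_corr / 6)
    z1 <- stats::rnorm(n)
    z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
    u_nc <- stats::pnorm(z1); u_ahi <- stats::pnorm(z2)
  } else {
    u_nc <- stats::runif(n); u_ahi <- stats::runif(n)
  }
  nc <- qtruncnorm(u_nc, spec$nc_mean, spec$nc_sd)
  ahi <- qahi(u_ahi, spec$ahi_mean, spec$ahi_sd, spec$sev_fraction)
  data.frame(id = sprintf("%s%04d", id_prefix, seq_len(n)),
             gender = gender, age = age,
             systolic_bp = NA_real_, diastolic_bp = NA_real_,
             hbp_flag = stats::runif(n) < spec$p_hbp,
             bmi = bmi, neck_circumference = nc, ess = as.integer(ess),
             ahi_before = ahi, ahi_after = NA_real_,
             osa_label = spec$osa_label, stringsAsFactors = FALSE)
}

#' Generate OSA-diagnosed and control screening cohorts
#'
#' Draws two labeled cohorts (OSA-diagnosed and non-OSA control) from their
#' marginal specifications; used to study neck circumference as a screening
#' test. Reproducible given the seed.
#'
#' @param spec_osa,spec_control Cohort specifications
#'   (defaults [d2_cohort_spec()] and [d3_cohort_spec()]).
#' @param seed Integer seed.
#' @return Patient records for both cohorts row-bound, with `osa_label`
#'   distinguishing them.
#' @examples
#' cohorts <- generate_screening_cohorts(seed = 1)
#' table(cohorts$osa_label)
#' @export
generate_screening_cohorts <- function(spec_osa = d2_cohort_spec(),
                                       spec_control = d3_cohort_spec(),
                                       seed = 1L) {
  stopifnot(inherits(spec_osa, "cohort_spec"),
            inherits(spec_control, "cohort_spec"))
  set.seed(seed)
  osa <- draw_cohort(spec_osa, id_prefix = "O")
  ctl <- draw_cohort(spec_control, id_prefix = "N")
  osa$osa_label <- TRUE; ctl$osa_label <- FALSE
  rbind(osa, ctl)
}

#' Generate a CPAP-titration cohort with before/after AHI
#'
#' Draws a D1-like cohort and adds the one-night treatment outcome: every
#' patient severe before CPAP improves to the normal/mild range with the
#' response-model probability of their neck class (thick vs thin, using the
#' default discretization cutoffs), otherwise stays in the moderate/severe
#' range. The after-CPAP AHI value is drawn uniformly inside the selected
#' severity band; non-severe patients are redrawn uniformly below their
#' starting AHI.
#'
#' @param spec Cohort specification (default [d1_cohort_spec()]).
#' @param response Response model from [response_model_spec()].
#' @param seed Integer seed.
#' @return Patient records with `ahi_before` and `ahi_after` populated.
#' @export
generate_d1_like <- function(spec = d1_cohort_spec(),
                             response = response_model_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"),
            inherits(response, "response_model_spec"))
  set.seed(seed)
  rec <- draw_cohort(spec, id_prefix = "D")
  rules <- discretization_rules()
  thick <- rec$neck_circumference >=
    ifelse(rec$gender == "male", rules$nc_thick_male, rules$nc_thick_female)
  p_improve <- ifelse(thick, response$p_improve_thick_neck,
                      response$p_improve_thin_neck)
  severe <- rec$ahi_before >= 30
  improve <- stats::runif(nrow(rec)) < p_improve
  after <- numeric(nrow(rec))
  u <- stats::runif(nrow(rec))
  # improved severe patients land in [0, 15) (norm/mild), the rest in
  # [15, ahi_before] capped below at the moderate bound
  after[severe & improve] <- 15 * u[severe & improve]
  hi <- pmax(rec$ahi_before, 35)
  after[severe & !improve] <- 15 + (hi - 15)[severe & !improve] *
    u[severe & !improve]
  after[!severe] <- rec$ahi_before[!severe] * u[!severe]
  rec$ahi_after <- after
  rec
}

#' Archetype class profiles of the four phenotype communities
#'
#' Majority six-parameter profiles of the four communities the network
#' analysis is designed around: two thick-neck male clusters differing in
#' sleepiness (the best-responding phenotypes), a thin-neck non-obese
#' normotensive male cluster, and a thin-neck hypertensive obese female
#' cluster; all centred on the 40-60 age group.
#'
#' @return Profile data frame (ids C1..C4) usable as `archetypes` in
#'   [generate_clustered_cohort()].
#' @export
archetype_profiles <- function() {
  data.frame(id = c("C1", "C2", "C3", "C4"),
             gender_class = c("M", "M", "M", "F"),
             age_group = c(2L, 2L, 2L, 2L),
             hbp = c(TRUE, TRUE, FALSE, TRUE),
             obese = c(TRUE, TRUE, FALSE, TRUE),
             thick_neck = c(TRUE, TRUE, FALSE, FALSE),
             sleepiness = c(TRUE, FALSE, FALSE, TRUE),
             stringsAsFactors = FALSE)
}

#' Generate a planted-community cohort of class profiles
#'
#' Each patient copies the six parameter classes of its community archetype;
#' every class is then independently perturbed with probability `flip_prob`
#' (booleans flip, gender toggles, the age group is resampled uniformly from
#' the other groups). Ground-truth community labels are returned for
#' recovery benchmarks.
#'
#' @param archetypes Profile data frame, one row per community
#'   (default [archetype_profiles()]).
#' @param sizes Integer community sizes, one per archetype
#'   (default 55, 32, 29, 29).
#' @param flip_prob Per-class perturbation probability in \[0, 0.5).
#' @param seed Integer seed.
#' @param n_age_groups Number of age groups for resampling.
#' @return Profile data frame with a `community` column of ground-truth
#'   labels.
#' @export
generate_clustered_cohort <- function(archetypes = archetype_profiles(),
                                      sizes = c(55L, 32L, 29L, 29L),
                                      flip_prob = 0.05, seed = 1L,
                                      n_age_groups = 4L) {
  if (nrow(archetypes) == 0) stop("empty archetype list")
  stopifnot(length(sizes) == nrow(archetypes), all(sizes > 0),
            flip_prob >= 0, flip_prob < 0.5)
  set.seed(seed)
  truth <- rep(seq_len(nrow(archetypes)), sizes)
  prof <- archetypes[truth, c("gender_class", "age_group", profile_columns[-(1:2)])]
  n <- nrow(prof)
  flip <- function() stats::runif(n) < flip_prob
  gflip <- flip()
  prof$gender_class[gflip] <- ifelse(prof$gender_class[gflip] == "M", "F", "M")
  aflip <- flip()
  if (any(aflip)) {
    cur <- prof$age_group[aflip]
    shift <- 1L + floor(stats::runif(sum(aflip)) * (n_age_groups - 1L))
    prof$age_group[aflip] <- as.integer((cur + shift) %% n_age_groups)
  }
  for (cl in c("hbp", "obese", "thick_neck", "sleepiness"))
    prof[[cl]] <- xor(prof[[cl]], flip())
  out <- cbind(data.frame(id = sprintf("S%04d", seq_len(n)),
                          stringsAsFactors = FALSE),
               prof, data.frame(community = truth))
  rownames(out) <- NULL
  out
}
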