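# Community-level CPAP treatment response: severity transition tables,
# AHI-improvement percentages, best/good response-class labels, and the
# evaluation of a neck-circumference cutoff against those labels.

community_of <- function(records, partition) {
  if (inherits(partition, "community_partition"))
    partition <- partition$membership
  mem <- partition[as.character(records$id)]
  if (anyNA(mem)) stop("partition does not cover all patient records")
  mem
}

#' Severity transition table per community
#'
#' For each community, the fraction of patients in each of the four OSA
#' severity classes before and after one-night CPAP treatment. Records
#' missing the after-treatment AHI are excluded (their count is messaged).
#'
#' @param records Patient records with `ahi_before` and `ahi_after`.
#' @param partition `community_partition` or named membership vector.
#' @return Data frame with one row per community: `community`, `n`,
#'   `before_norm` .. `before_sev`, `after_norm` .. `after_sev` (fractions
#'   summing to 1 within each block).
#' @export
severity_transition_table <- function(records, partition) {
  mem <- community_of(records, partition)
  keep <- !is.na(records$ahi_after)
  if (any(!keep))
    message("severity_transition_table: excluded ", sum(!keep),
            " records without ahi_after")
  records <- records[keep, , drop = FALSE]; mem <- mem[keep]
  before <- classify_ahi_severity(records$ahi_before)
  after <- classify_ahi_severity(records$ahi_after)
  comms <- sort(unique(mem))
  rows <- lapply(comms, function(cm) {
    sel <- mem == cm
    fb <- prop.table(table(before[sel]))
    fa <- prop.table(table(after[sel]))
    out <- data.frame(community = cm, n = sum(sel))
    for (lv in severity_levels) out[[paste0("before_", lv)]] <- unname(fb[lv])
    for (lv in severity_levels) out[[paste0("after_", lv)]] <- unname(fa[lv])
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' AHI improvement percentage
#'
#' Default definition: among patients severe before CPAP, the percentage
#' reclassified to normal or mild after treatment. The alternative
#' `"sev_reduction"` mode reports the relative drop in the severe fraction,
#' `(sev_before - sev_after) / sev_before * 100`.
#'
#' @param records Patient records of one group (community) with both AHI
#'   values.
#' @param mode `"severe_to_normmild"` (default) or `"sev_reduction"`.
#' @return Percentage in \[0, 100\].
#' @export
ahi_improvement <- function(records, mode = c("severe_to_normmild",
                                              "sev_reduction")) {
  mode <- match.arg(mode)
  records <- records[!is.na(records$ahi_after), , drop = FALSE]
  before <- classify_ahi_severity(records$ahi_before)
  after <- classify_ahi_severity(records$ahi_after)
  n_sev <- sum(before == "sev")
  if (n_sev == 0) stop("no patients severe before CPAP; improvement undefined")
  if (mode == "severe_to_normmild") {
    100 * sum(before == "sev" & after %in% c("norm", "mild")) / n_sev
  } else {
    100 * (n_sev - sum(after == "sev")) / n_sev
  }
}

#' Per-community AHI improvement
#'
#' @inheritParams severity_transition_table
#' @inheritParams ahi_improvement
#' @return Named numeric vector of improvement percentages, one per
#'   community.
#' @export
community_improvements <- function(records, partition,
                                   mode = "severe_to_normmild") {
  mem <- community_of(records, partition)
  comms <- sort(unique(mem))
  stats::setNames(vapply(comms, function(cm)
    ahi_improvement(records[mem == cm, , drop = FALSE], mode = mode), 0),
    as.character(comms))
}

#' Label communities as best or good response classes
#'
#' Communities whose AHI-improvement percentage reaches `best_threshold`
#' form the best response class; the rest form the good response class. The
#' default of 85% separates the ~87-89% and ~68-77% improvement ranges the
#' two classes are expected to show.
#'
#' @param improvements Named vector of per-community improvement
#'   percentages (see [community_improvements()]).
#' @param best_threshold Percentage cutoff (default 85).
#' @return Object of class `response_labeling`: list with `label` (named
#'   character vector, "best"/"good") and `improvement`.
#' @examples
#' label_response_classes(c(C1 = 89.29, C2 = 87.50, C3 = 68.75, C4 = 77.78))
#' @export
label_response_classes <- function(improvements, best_threshold = 85) {
  stopifnot(length(improvements) >= 1, !is.null(names(improvements)),
            all(improvements >= 0), all(improvements <= 100))
  structure(list(label = stats::setNames(
    ifelse(improvements >= best_threshold, "best", "good"),
    names(improvements)),
    improvement = improvements,
    best_threshold = best_threshold),
    class = "response_labeling")
}

#' Representative parameter classes per community
#'
#' For each community and each of the six parameters, reports the majority
#' class and its prevalence; the class is marked representative when the
#' prevalence reaches `representative_threshold` (boundary included),
#' otherwise the cell is "-". Booleans are reported as "1"/"0", gender as
#' "M"/"F", the age group by its number.
#'
#' @param profiles Class-profile data frame.
#' @param partition `community_partition` or named membership vector.
#' @param representative_threshold Prevalence needed to call a class
#'   representative (default 0.70).
#' @return Data frame: `community`, then for each parameter a `<param>`
#'   symbol column and a `<param>_prevalence` column.
#' @export
parameter_community_map <- function(profiles, partition,
                                    representative_threshold = 0.70) {
  mem <- community_of(data.frame(id = profiles$id), partition)
  comms <- sort(unique(mem))
  symbol_of <- function(value, param) {
    if (param %in% c("gender_class", "age_group")) as.character(value)
    else if (as.logical(value)) "1" else "0"
  }
  rows <- lapply(comms, function(cm) {
    sel <- profiles[mem == cm, , drop = FALSE]
    out <- data.frame(community = cm, n = nrow(sel))
    for (param in profile_columns) {
      tab <- sort(table(as.character(sel[[param]])), decreasing = TRUE)
      prev <- tab[1] / nrow(sel)
      out[[param]] <- if (prev >= representative_threshold)
        symbol_of(names(tab)[1], param) else "-"
      out[[paste0(param, "_prevalence")]] <- round(unname(prev), 4)
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

contingency_rates <- function(tp, fn, fp, tn) {
  list(TPR = tp / (tp + fn), TNR = tn / (tn + fp),
       PPV = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       NPV = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' Evaluate a neck-circumference cutoff against the response classes
#'
#' Splits the cohort at the cutoff (predicted good if NC <= cutoff,
#' predicted best if NC > cutoff) and scores the prediction against the
#' community-derived response labels, in both orientations. The two
#' orientations are complementary classifiers on the same 2x2 table, so the
#' good-class TPR equals the best-class TNR and vice versa.
#'
#' @param records Patient records with `neck_circumference`.
#' @param partition `community_partition` or named membership vector.
#' @param labeling `response_labeling` covering all communities present.
#' @param cutoff NC cutoff in cm.
#' @return Object of class `nc_cutoff_evaluation`: `cutoff`, `counts`
#'   (communities x predicted groups), and `good`/`best` metric lists with
#'   `TPR`, `TNR`, `PPV`, `NPV`.
#' @export
evaluate_nc_threshold <- function(records, partition, labeling, cutoff) {
  stopifnot(inherits(labeling, "response_labeling"))
  mem <- community_of(records, partition)
  lab <- labeling$label[as.character(mem)]
  if (anyNA(lab)) stop("labeling does not cover all communities")
  predicted_good <- records$neck_circumference <= cutoff
  counts <- table(community = mem,
                  predicted = factor(ifelse(predicted_good, "good", "best"),
                                     levels = c("good", "best")))
  tp_g <- sum(lab == "good" & predicted_good)
  fn_g <- sum(lab == "good" & !predicted_good)
  fp_g <- sum(lab == "best" & predicted_good)
  tn_g <- sum(lab == "best" & !predicted_good)
  structure(list(cutoff = cutoff, counts = counts,
                 n = nrow(records),
                 good = contingency_rates(tp_g, fn_g, fp_g, tn_g),
                 best = contingency_rates(tn_g, fp_g, fn_g, tp_g)),
            class = "nc_cutoff_evaluation")
}

#' @export
print.nc_cutoff_evaluation <- function(x, ...) {
  cat("NC cutoff", x$cutoff, "cm on", x$n, "patients\n")
  cat(sprintf("  good (NC <= %s): TPR %.3f TNR %.3f PPV %.3f NPV %.3f\n",
              x$cutoff, x$good$TPR, x$good$TNR, x$good$PPV, x$good$NPV))
  cat(sprintf("  best (NC >  %s): TPR %.3f TNR %.3f PPV %.3f NPV %.3f\n",
              x$cutoff, x$best$TPR, x$best$TNR, x$best$PPV, x$best$NPV))
  invisible(x)
}

#' Neck-circumference threshold report over several cutoffs
#'
#' @inheritParams evaluate_nc_threshold
#' @param cutoffs Vector of NC cutoffs (default 39:43).
#' @return Data frame with two rows per cutoff (good and best orientation):
#'   totals, per-community counts and TPR/TNR/PPV/NPV.
#' @export
nc_threshold_table <- function(records, partition, labeling,
                               cutoffs = 39:43) {
  rows <- lapply(cutoffs, function(ct) {
    ev <- evaluate_nc_threshold(records, partition, labeling, ct)
    comms <- rownames(ev$counts)
    base <- function(orient, group) {
      r <- data.frame(cutoff = ct, orientation = orient,
                      total = sum(ev$counts[, group]))
      for (cm in comms)
        r[[paste0("C", cm)]] <- ev$counts[cm, group]
      m <- ev[[orient]]
      r$TPR <- m$TPR; r$TNR <- m$TNR; r$PPV <- m$PPV; r$NPV <- m$NPV
      r
    }
    rbind(base("good", "good"), base("best", "best"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
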