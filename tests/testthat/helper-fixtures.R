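# Shared fixtures, all built in code.

# The published ROC metric table for NC against OSA diagnosis
# (sensitivity/specificity per integer cutoff 39-46 cm).
printed_roc_table <- function() {
  data.frame(
    cutoff = 39:46,
    sensitivity = c(0.9237, 0.8755, 0.8099, 0.7376, 0.6305, 0.5489, 0.4391,
                    0.3494),
    specificity = c(0.3889, 0.4259, 0.5185, 0.5741, 0.6667, 0.6852, 0.7963,
                    0.8519),
    lr_pos = c(1.51, 1.53, 1.68, 1.73, 1.89, 1.74, 2.16, 2.36),
    lr_neg = c(0.19, 0.29, 0.37, 0.46, 0.55, 0.66, 0.70, 0.76))
}

# A 145-patient cohort whose per-community NC counts at cutoffs 39 and 41
# reproduce the published contingency rows: community sizes 55/32/29/29,
# with (n at NC<=39, n in (39,41], rest at 45):
#   C1: 0 / 1 / 54;  C2: 0 / 1 / 31;  C3: 11 / 17 / 1;  C4: 18 / 5 / 6.
nc_table_fixture <- function() {
  place <- function(comm, n_low, n_mid, n_total) {
    nc <- c(rep(38, n_low), rep(40.5, n_mid), rep(45, n_total - n_low - n_mid))
    data.frame(community = comm, nc = nc)
  }
  df <- rbind(place(1, 0, 1, 55), place(2, 0, 1, 32),
              place(3, 11, 17, 29), place(4, 18, 5, 29))
  df$id <- sprintf("T%03d", seq_len(nrow(df)))
  records <- data.frame(id = df$id, gender = "male", age = 50,
                        systolic_bp = 120, diastolic_bp = 80, hbp_flag = NA,
                        bmi = 30, neck_circumference = df$nc, ess = 10,
                        ahi_before = 40, ahi_after = NA,
                        stringsAsFactors = FALSE)
  membership <- stats::setNames(df$community, df$id)
  labeling <- label_response_classes(
    c(`1` = 89.29, `2` = 87.50, `3` = 68.75, `4` = 77.78))
  list(records = records, membership = membership, labeling = labeling)
}

# Four archetypes pairwise differing in at least 3 of the 6 classes, for
# planted-community recovery where the planted structure is modular.
separable_archetypes <- function() {
  data.frame(id = c("A", "B", "C", "D"),
             gender_class = c("M", "M", "F", "F"),
             age_group = c(0L, 2L, 1L, 3L),
             hbp = c(TRUE, FALSE, TRUE, FALSE),
             obese = c(TRUE, FALSE, FALSE, TRUE),
             thick_neck = c(TRUE, TRUE, FALSE, FALSE),
             sleepiness = c(FALSE, TRUE, TRUE, FALSE),
             stringsAsFactors = FALSE)
}

# Random small weighted graph for oracle comparisons.
random_small_network <- function(n, p = 0.4) {
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p
  edges <- data.frame(from = letters[pairs[keep, 1]],
                      to = letters[pairs[keep, 2]],
                      weight = sample(1:6, sum(keep), replace = TRUE),
                      stringsAsFactors = FALSE)
  cpapnet:::network_from_edges(letters[seq_len(n)], edges)
}

# Minimal valid patient record(s) with overridable fields.
make_records <- function(n = 1, ...) {
  rec <- data.frame(id = sprintf("p%03d", seq_len(max(n, 1))), gender = "male",
                    age = 50, systolic_bp = 120, diastolic_bp = 80,
                    hbp_flag = NA, bmi = 28, neck_circumference = 42,
                    ess = 8L, ahi_before = 35, ahi_after = NA,
                    osa_label = NA, stringsAsFactors = FALSE)
  rec <- rec[seq_len(n), , drop = FALSE]
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}
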