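test_that("severity transition fractions are conserved per community", {
  rec <- make_records(4, ahi_before = c(45, 50, 20, 10),
                      ahi_after = c(4, 3, 16, 12))
  mem <- stats::setNames(c(1L, 1L, 2L, 2L), rec$id)
  tab <- severity_transition_table(rec, mem)
  expect_equal(tab$before_sev[tab$community == 1], 1)
  expect_equal(tab$after_norm[tab$community == 1], 1)
  blocks <- as.matrix(tab[, grep("^(before|after)_", names(tab))])
  expect_equal(unname(rowSums(blocks[, 1:4])), rep(1, 2))
  expect_equal(unname(rowSums(blocks[, 5:8])), rep(1, 2))
  # records without ahi_after are excluded with a message
  rec$ahi_after[1] <- NA
  expect_message(severity_transition_table(rec, mem), "excluded 1")
})

test_that("AHI improvement counts severe-to-norm/mild reclassification", {
  rec <- make_records(5, ahi_before = c(40, 35, 60, 31, 10),
                      ahi_after = c(4, 14, 40, 20, 3))
  expect_equal(ahi_improvement(rec[1:4, ]), 50)
  rec2 <- make_records(2, ahi_before = c(40, 35), ahi_after = c(35, 31))
  expect_equal(ahi_improvement(rec2), 0)
  expect_equal(ahi_improvement(rec2, mode = "sev_reduction"), 0)
  # no severe-before patients: undefined
  expect_error(ahi_improvement(make_records(2, ahi_before = c(10, 20),
                                            ahi_after = c(5, 10))),
               "undefined")
})

test_that("response-class labels split at the best threshold", {
  imp <- c(C1 = 89.29, C2 = 87.50, C3 = 68.75, C4 = 77.78)
  lab <- label_response_classes(imp, best_threshold = 85)
  expect_equal(unname(lab$label), c("best", "best", "good", "good"))
  expect_equal(unname(label_response_classes(imp, 0)$label), rep("best", 4))
  same <- label_response_classes(c(a = 50, b = 50), 85)
  expect_equal(unname(same$label), c("good", "good"))
  # boundary: improvement equal to the threshold is best
  expect_equal(unname(label_response_classes(c(x = 85), 85)$label), "best")
})

test_that("representative parameter classes follow the prevalence rule", {
  prof <- generate_clustered_cohort(flip_prob = 0, seed = 1)
  mem <- stats::setNames(prof$community, prof$id)
  map <- parameter_community_map(prof, mem)
  expect_equal(map$gender_class, c("M", "M", "M", "F"))
  expect_equal(map$thick_neck, c("1", "1", "0", "0"))
  # a 50/50 split is not representative; exactly at threshold is
  prof2 <- prof[prof$community == 1, ]
  prof2$sleepiness <- rep(c(TRUE, FALSE), length.out = nrow(prof2))
  m2 <- parameter_community_map(prof2, stats::setNames(rep(1, nrow(prof2)),
                                                       prof2$id))
  expect_equal(m2$sleepiness, "-")
  prof3 <- prof2
  prof3$sleepiness <- rep(c(TRUE, TRUE, TRUE, FALSE, FALSE),
                          length.out = 55)[seq_len(nrow(prof3))]
  m3 <- parameter_community_map(prof3,
                                stats::setNames(rep(1, nrow(prof3)),
                                                prof3$id),
                                representative_threshold = 0.6)
  expect_equal(m3$sleepiness, "1")
})

test_that("NC threshold evaluation reproduces the published contingency rows", {
  fx <- nc_table_fixture()
  ev39 <- evaluate_nc_threshold(fx$records, fx$membership, fx$labeling, 39)
  expect_equal(ev39$good$TPR, 29 / 58)
  expect_equal(ev39$good$TNR, 1)
  expect_equal(ev39$good$PPV, 1)
  ev41 <- evaluate_nc_threshold(fx$records, fx$membership, fx$labeling, 41)
  expect_equal(unname(ev41$counts[, "good"]), c(1, 1, 28, 23))
  expect_equal(unname(ev41$counts[, "best"]), c(54, 31, 1, 6))
  expect_equal(ev41$good$PPV, 51 / 53)
  expect_equal(ev41$best$TPR, 85 / 87)
  expect_equal(ev41$best$PPV, 85 / 92)
})

test_that("the two orientations are complementary and internally consistent", {
  fx <- nc_table_fixture()
  for (ct in c(37, 39, 40, 41, 44, 46)) {
    ev <- evaluate_nc_threshold(fx$records, fx$membership, fx$labeling, ct)
    expect_identical(ev$good$TPR, ev$best$TNR)
    expect_identical(ev$good$TNR, ev$best$TPR)
    # rates recompute exactly from the stored counts
    lab <- fx$labeling$label[rownames(ev$counts)]
    tp <- sum(ev$counts[lab == "good", "good"])
    fp <- sum(ev$counts[lab == "best", "good"])
    fn <- sum(ev$counts[lab == "good", "best"])
    expect_equal(ev$good$TPR, tp / (tp + fn))
    if (tp + fp > 0) expect_equal(ev$good$PPV, tp / (tp + fp))
    expect_equal(sum(ev$counts), nrow(fx$records))
  }
  # cutoff below every NC value: everyone predicted best
  ev_lo <- evaluate_nc_threshold(fx$records, fx$membership, fx$labeling, 30)
  expect_equal(ev_lo$good$TPR, 0)
  expect_equal(sum(ev_lo$counts[, "good"]), 0)
})

test_that("raising the cutoff moves patients monotonically into the good group", {
  fx <- nc_table_fixture()
  sizes <- vapply(38:46, function(ct)
    sum(evaluate_nc_threshold(fx$records, fx$membership, fx$labeling,
                              ct)$counts[, "good"]), 0)
  expect_true(all(diff(sizes) >= 0))
})
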