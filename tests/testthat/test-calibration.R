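# ROC construction, AUC, Youden cut-off selection and cohort calibration.

test_that("perfectly separated classes give AUC 1 and the gap midpoint cut-off", {
  roc <- roc_points(c(1, 2, 13, 14), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(roc$auc, 1.0)
  mid <- roc$points[roc$points$threshold == 7.5, ]
  expect_equal(mid$sensitivity, 1)
  expect_equal(mid$specificity, 1)
  expect_equal(select_cutoff(roc), 7.5)

  # anti-separated: positives score HIGH, so AUC is 0 under the low-score
  # positive convention
  expect_equal(roc_points(c(2, 1), c(TRUE, FALSE))$auc, 0.0)
})

test_that("AUC equals the pair-counting oracle on random instances", {
  set.seed(20)
  for (i in 1:50) {
    n <- sample(4:50, 1)
    scores <- round(runif(n, 0, 15), sample(0:2, 1))  # rounding makes ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(labels) || !any(labels)) next
    expect_equal(roc_points(scores, labels)$auc, oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(30)
  for (i in 1:10) {
    scores <- c(rnorm(12, 3), rnorm(15, 10))
    labels <- rep(c(TRUE, FALSE), c(12, 15))
    ref <- pROC::roc(response = labels, predictor = scores,
                     direction = ">", levels = c(FALSE, TRUE), quiet = TRUE)
    expect_equal(roc_points(scores, labels)$auc, as.numeric(pROC::auc(ref)),
                 tolerance = 1e-9)
  }
})

test_that("Youden selection matches a brute-force scan and breaks ties upward", {
  scores <- c(1, 2, 3, 2.5, 3.5, 14)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  roc <- roc_points(scores, labels)
  expect_equal(select_cutoff(roc), oracle_youden(scores, labels))

  set.seed(40)
  for (i in 1:30) {
    s <- round(runif(12, 0, 10), 1)
    l <- sample(c(TRUE, FALSE), 12, replace = TRUE)
    if (all(l) || !any(l)) next
    # a rare random draw has no discriminating threshold; the comparison
    # still holds, so silence the degenerate-curve warning
    expect_equal(suppressWarnings(select_cutoff(roc_points(s, l))),
                 oracle_youden(s, l))
  }

  # no information: J = 0 everywhere, warn and return the largest candidate
  expect_warning(cut <- select_cutoff(roc_points(rep(5, 4), c(TRUE, TRUE, FALSE, FALSE))),
                 "Degenerate")
  expect_equal(cut, 6)
})

test_that("single-class input is a calibration error naming the absent class", {
  expect_error(roc_points(1:3, c(TRUE, TRUE, TRUE)), "negative",
               class = "apoetyper_calibration_error")
  expect_error(roc_points(1:3, c(FALSE, FALSE, FALSE)), "positive",
               class = "apoetyper_calibration_error")
})

test_that("calibration on a synthetic cohort separates the classes and resubstitutes perfectly", {
  sim <- simulate_cohort(n = 114, seed = 99)
  train <- dplyr::filter(pair_channels(sim$plate), role == "SAMPLE") |>
    dplyr::left_join(sim$truth, by = "sample_id")
  cal <- calibrate_cutoffs(train)
  expect_equal(cal$n_train, 114)
  labelled <- label_delta_ct(train)
  for (a in c("E2", "E3", "E4")) {
    d <- dplyr::filter(labelled, reaction == a)
    expect_gt(cal$cutoffs[[a]], max(d$delta_ct[d$allele_present]))
    expect_lt(cal$cutoffs[[a]], min(d$delta_ct[!d$allele_present]))
    expect_equal(cal$reactions$auc[cal$reactions$reaction == a], 1.0)
  }
  # resubstitution: evaluating the recovered cut-offs on the training set
  ev <- evaluate_cutoffs(train, cal$cutoffs)
  expect_equal(ev$concordance, 1.0)
  expect_equal(ev$reactions$sensitivity, rep(1, 3))
  expect_equal(ev$reactions$specificity, rep(1, 3))
})

test_that("a cohort without both classes in every reaction cannot be calibrated", {
  train <- dplyr::bind_rows(lapply(1:5, function(i) {
    m <- make_measurements(15, 2, 16, sample_id = paste0("S", i))
    m$rs429358 <- "T/T"
    m$rs7412 <- "C/C"   # all E3/E3: the E2 reaction has no positives
    m
  }))
  expect_error(calibrate_cutoffs(train), "E2",
               class = "apoetyper_calibration_error")
})

test_that("calibration is order-invariant and shift-equivariant", {
  sim <- simulate_cohort(n = 60, seed = 5)
  train <- dplyr::filter(pair_channels(sim$plate), role == "SAMPLE") |>
    dplyr::left_join(sim$truth, by = "sample_id")
  cal <- calibrate_cutoffs(train)

  perm <- train[sample.int(nrow(train)), ]
  expect_equal(calibrate_cutoffs(perm)$cutoffs, cal$cutoffs)

  # adding c to every delta-Ct (via FAM, and to the ceiling for the
  # undetermined substitution) shifts every cut-off by exactly c
  shifted <- dplyr::mutate(train, fam_ct = fam_ct + 3)
  cal_shift <- calibrate_cutoffs(shifted, max_cycles = 43)
  expect_equal(as.numeric(cal_shift$cutoffs), as.numeric(cal$cutoffs) + 3,
               tolerance = 1e-9)
})

test_that("evaluate_cutoffs degrades as expected under broken cut-offs and label flips", {
  sim <- simulate_cohort(n = 50, seed = 12)
  test_df <- dplyr::filter(pair_channels(sim$plate), role == "SAMPLE") |>
    dplyr::left_join(sim$truth, by = "sample_id")

  # near-zero cut-offs call everything negative: nothing is concordant
  ev0 <- evaluate_cutoffs(test_df, apoe_cutoffs(1e-6, 1e-6, 1e-6))
  expect_equal(ev0$concordance, 0)

  # flipping k truth labels reduces concordance by exactly k/n
  flipped <- test_df
  flip_ids <- unique(flipped$sample_id)[1:5]
  rows <- flipped$sample_id %in% flip_ids
  flipped$rs429358[rows] <- ifelse(flipped$rs429358[rows] == "C/C", "T/T", "C/C")
  flipped$rs7412[rows] <- "C/C"
  before <- evaluate_cutoffs(test_df, apoe_cutoffs())$concordance
  after <- evaluate_cutoffs(flipped, apoe_cutoffs())$concordance
  expect_equal(before - after, 5 / 50, tolerance = 1e-9)
})

test_that("tidy, glance and autoplot work on calibration objects", {
  sim <- simulate_cohort(n = 40, seed = 8)
  train <- dplyr::filter(pair_channels(sim$plate), role == "SAMPLE") |>
    dplyr::left_join(sim$truth, by = "sample_id")
  cal <- calibrate_cutoffs(train)
  td <- tidy(cal)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$reaction, c("E2", "E3", "E4"))
  gl <- glance(cal)
  expect_equal(gl$n_train, 40)
  expect_s3_class(autoplot(cal), "ggplot")
  expect_s3_class(autoplot(cal$curves$E2), "ggplot")
})
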