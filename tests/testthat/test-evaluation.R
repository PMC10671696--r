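test_that("confusion tabulates calls against truth and excludes missing pairs", {
  cm <- confusion(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
  expect_equal(c(cm$tp, cm$fn, cm$tn, cm$fp), c(1, 1, 1, 0))
  all_correct <- confusion(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(all_correct$fp + all_correct$fn, 0)
  with_na <- confusion(c(TRUE, TRUE, FALSE), c(TRUE, NA, FALSE))
  expect_equal(with_na$n, 2)
  expect_equal(with_na$n_excluded, 1)
  expect_error(confusion(logical(0), logical(0)), "empty")
  expect_error(confusion(c(TRUE), c(TRUE, FALSE)), "same length")
})

test_that("metrics reproduce published performance rows from reconstructed counts", {
  # counts recovered by integer reconstruction of the published rounded rows
  row1 <- metrics(list(tp = 22, fp = 3, fn = 4, tn = 2))
  expect_equal(percent_half_up(row1$sensitivity), 84.6)
  expect_equal(percent_half_up(row1$specificity), 40.0)
  expect_equal(percent_half_up(row1$ppv), 88.0)
  expect_equal(percent_half_up(row1$npv), 33.3)
  expect_equal(percent_half_up(row1$accuracy), 77.4)

  row6 <- metrics(list(tp = 23, fp = 1, fn = 1, tn = 4))
  expect_equal(percent_half_up(row6$sensitivity), 95.8)
  expect_equal(percent_half_up(row6$specificity), 80.0)
  expect_equal(percent_half_up(row6$ppv), 95.8)
  expect_equal(percent_half_up(row6$npv), 80.0)
  expect_equal(percent_half_up(row6$accuracy), 93.1)

  # degenerate table: specificity defined, sensitivity undefined (NA, not 0)
  degenerate <- metrics(list(tp = 0, fp = 0, fn = 0, tn = 5))
  expect_equal(degenerate$specificity, 1)
  expect_true(is.na(degenerate$sensitivity))
  expect_true(is.na(degenerate$ppv))
})

test_that("metrics satisfy the Bayes identity and reorder invariance", {
  set.seed(7)
  for (i in 1:20) {
    truth <- runif(40) < 0.6
    calls <- xor(truth, runif(40) < 0.3)
    if (length(unique(truth)) < 2 || length(unique(calls)) < 2) next
    m <- metrics(confusion(truth, calls))
    # PPV from (se, sp, prevalence) must equal the count ratio
    ppv_bayes <- m$sensitivity * m$prevalence /
      (m$sensitivity * m$prevalence + (1 - m$specificity) * (1 - m$prevalence))
    expect_equal(m$ppv, ppv_bayes, tolerance = 1e-12)
    # invariance under subject reordering
    perm <- sample(length(truth))
    expect_identical(m, metrics(confusion(truth[perm], calls[perm])))
  }
})

test_that("Fisher exact p matches the hypergeometric enumeration oracle", {
  # worked examples: family pCVD history by genotype
  expect_equal(round(fisher_exact_p(matrix(c(12, 0, 4, 3), 2)), 3), 0.036)
  expect_equal(round(fisher_exact_p(matrix(c(18, 0, 8, 5), 2)), 3), 0.008)
  expect_equal(fisher_exact_p(matrix(c(1, 1, 1, 1), 2)), 1.0)
  set.seed(13)
  for (i in 1:30) {
    tab <- matrix(rpois(4, 4), 2)
    if (sum(tab) == 0 || sum(tab) > 40) next
    expect_equal(fisher_exact_p(tab), fisher_oracle(tab), tolerance = 1e-9)
  }
  expect_error(fisher_exact_p(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("ROC: trapezoid AUC equals the brute-force pairwise statistic", {
  # perfectly separated scores
  perfect <- roc_curve(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))
  expect_equal(roc_auc(perfect), 1.0)
  expect_equal(youden_optimal(perfect)$J, 1.0)
  # constant score carries no information
  flat <- roc_curve(rep(2, 10), rep(c(0, 1), 5))
  expect_equal(roc_auc(flat), 0.5)
  expect_equal(youden_optimal(flat)$J, 0.0)
  # random draws with ties: trapezoid == pairwise oracle to 1e-12
  set.seed(99)
  for (i in 1:10) {
    truth <- runif(50) < 0.5
    if (length(unique(truth)) < 2) next
    scores <- round(rnorm(50, mean = ifelse(truth, 1, 0)), 1)
    curve <- roc_curve(scores, truth)
    expect_equal(roc_auc(curve), auc_oracle(scores, truth), tolerance = 1e-12)
  }
  expect_error(roc_curve(1:5, rep(TRUE, 5)), "both positive and negative")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(5)
  truth <- runif(60) < 0.5
  scores <- rnorm(60, ifelse(truth, 0.8, 0))
  base <- roc_auc(roc_curve(scores, truth))
  for (f in list(function(x) 3 * x + 2, exp, function(x) x^3)) {
    expect_equal(roc_auc(roc_curve(f(scores), truth)), base, tolerance = 1e-12)
  }
})

test_that("ROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  truth <- runif(80) < 0.5
  scores <- rnorm(80, ifelse(truth, 1, 0))
  ours <- roc_auc(roc_curve(scores, truth))
  theirs <- as.numeric(pROC::auc(pROC::roc(response = truth,
                                           predictor = scores,
                                           direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("Youden optimum equals exhaustive search and breaks ties sensitively", {
  set.seed(21)
  truth <- runif(30) < 0.5
  scores <- round(rnorm(30, ifelse(truth, 1.2, 0)), 1)
  curve <- roc_curve(scores, truth)
  opt <- youden_optimal(curve)
  j_all <- curve$sensitivity + curve$specificity - 1
  expect_equal(opt$J, max(j_all))
  # exhaustive: no threshold does better
  for (k in seq_len(nrow(curve))) expect_lte(j_all[k], opt$J + 1e-12)
  # tie goes to the lower (more sensitive) threshold
  ties <- curve$threshold[j_all == max(j_all)]
  expect_equal(opt$threshold, min(ties))
})

test_that("integer reconstruction finds the published matrices and round-trips", {
  r1 <- reconstruct_confusion(
    c(sensitivity = 84.6, specificity = 40.0, ppv = 88.0, npv = 33.3))
  expect_equal(unlist(r1[1, c("tp", "fp", "fn", "tn")]),
               c(tp = 22, fp = 3, fn = 4, tn = 2))
  r6 <- reconstruct_confusion(
    c(sensitivity = 95.8, specificity = 80.0, ppv = 95.8, npv = 80.0))
  expect_equal(unlist(r6[1, c("tp", "fp", "fn", "tn")]),
               c(tp = 23, fp = 1, fn = 1, tn = 4))
  trivial <- reconstruct_confusion(c(sensitivity = 100, specificity = 100),
                                   n_max = 2)
  expect_equal(unlist(trivial[1, c("tp", "fp", "fn", "tn")]),
               c(tp = 1, fp = 0, fn = 0, tn = 1))
  expect_error(reconstruct_confusion(c(sensitivity = 50)), "at least two")
  # agreement with the independent slow oracle at small n
  targets <- c(sensitivity = 66.7, specificity = 75.0)
  fast <- reconstruct_confusion(targets, n_max = 12)
  slow <- reconstruct_oracle(targets, n_max = 12)
  expect_equal(nrow(fast), nrow(slow))
  expect_equal(fast$tp, slow$tp)
  expect_equal(fast$tn, slow$tn)
})

test_that("reconstruction always contains the generating matrix (round-trip)", {
  set.seed(31)
  for (i in 1:10) {
    cm <- list(tp = sample(0:12, 1), fp = sample(0:6, 1),
               fn = sample(0:6, 1), tn = sample(0:12, 1))
    if (cm$tp + cm$fn == 0 || cm$tn + cm$fp == 0) next
    m <- metrics(cm)
    targets <- c(sensitivity = percent_half_up(m$sensitivity),
                 specificity = percent_half_up(m$specificity))
    found <- reconstruct_confusion(targets, n_max = cm$tp + cm$fp + cm$fn + cm$tn)
    hit <- any(found$tp == cm$tp & found$fp == cm$fp &
                 found$fn == cm$fn & found$tn == cm$tn)
    expect_true(hit)
  }
})

test_that("cohort-level evaluation reproduces the packaged cohort's performance table", {
  cohort <- fh_adult_cohort()
  tab <- evaluate_criteria_on_cohort(cohort)
  expected <- tibble::tribble(
    ~criterion,    ~sensitivity_pct, ~specificity_pct, ~ppv_pct, ~npv_pct, ~accuracy_pct, ~n_effective,
    "SimonBroome", 84.6,             40.0,             88.0,     33.3,     77.4,          31L,
    "MEDPED",      84.6,             40.0,             88.0,     33.3,     77.4,          31L,
    "JFHMC",       84.6,             40.0,             88.0,     33.3,     77.4,          31L,
    "HK_panel",    88.5,             20.0,             85.2,     25.0,     77.4,          31L,
    "LDL55",       80.8,             60.0,             91.3,     37.5,     77.4,          31L,
    "intensity",   95.8,             80.0,             95.8,     80.0,     93.1,          29L,
    "combined",    83.3,             100.0,            100.0,    55.6,     86.2,          29L
  )
  expect_equal(tab[, names(expected)], expected)
  # the intensity rows exclude (not negatively call) the two untreated subjects
  expect_equal(tab$n_excluded[tab$criterion == "intensity"], 2L)
  # association p-values: only the intensity-based rows reach significance
  expect_equal(round(tab$fisher_p[tab$criterion == "SimonBroome"], 3), 0.241)
  expect_lt(tab$fisher_p[tab$criterion == "intensity"], 0.05)
  expect_lt(tab$fisher_p[tab$criterion == "combined"], 0.05)
})
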