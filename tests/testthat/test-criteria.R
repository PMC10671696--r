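test_that("LDL selection prefers measured pretreatment, then corrected, then peak policy", {
  s <- make_subject(pre_ldl = 8.42, on_ldl = 3.0, regimen = "rosuvastatin:10")
  sel <- select_ldl_for_scoring(s)
  expect_equal(sel$ldl, 8.42)
  expect_equal(sel$provenance, "measured")

  s2 <- make_subject(on_ldl = 3.0, regimen = "rosuvastatin:10")
  sel2 <- select_ldl_for_scoring(s2)
  expect_equal(sel2$ldl, 6.0)   # 3.0 x intensity 2.0
  expect_equal(sel2$provenance, "corrected")

  s3 <- make_subject(pre_ldl = 8.77, peak_ldl = 9.24)
  sel3 <- select_ldl_for_scoring(s3, policy = "peak")
  expect_equal(sel3$ldl, 9.24)
  expect_equal(sel3$provenance, "peak")

  s4 <- make_subject("no-ldl")
  expect_error(select_ldl_for_scoring(s4), "no-ldl")
})

test_that("DLCNC scores follow the point table and LDL bands", {
  # LDL 8.6 (8) + tendon xanthoma (6) + first-degree hyperlipidemia (1) = 15
  s <- make_subject(pre_ldl = 8.6, sign_tendon_xanthoma = TRUE,
                    fh_first_degree_hyperlipidemia = TRUE)
  r <- score_dlcnc(s)
  expect_equal(r$score, 15)
  expect_equal(r$category, "definite")
  expect_true(r$binary_call)

  expect_equal(score_dlcnc(make_subject(pre_ldl = 4.9))$score, 1)
  expect_false(score_dlcnc(make_subject(pre_ldl = 4.9))$binary_call)
  expect_equal(score_dlcnc(make_subject(pre_ldl = 3.9))$score, 0)
  # DNA variant adds 8 by default, and is excluded when masked
  s_dna <- make_subject(pre_ldl = 3.9, genetic_confirmed = TRUE)
  expect_equal(score_dlcnc(s_dna)$score, 8)
  expect_equal(score_dlcnc(s_dna, use_genetic = FALSE)$score, 0)
})

test_that("DLCNC category boundaries are exact", {
  cfg <- fh_default_config()
  # engineer scores 9, 8, 3, 2 through LDL bands + family history
  cases <- list(
    list(s = make_subject(pre_ldl = 8.5, fh_first_degree_hyperlipidemia = TRUE),
         score = 9, category = "definite"),
    list(s = make_subject(pre_ldl = 8.5), score = 8, category = "probable"),
    list(s = make_subject(pre_ldl = 5.0), score = 3, category = "possible"),
    list(s = make_subject(pre_ldl = 4.0,
                          fh_first_degree_hyperlipidemia = TRUE),
         score = 2, category = "negative")
  )
  for (cs in cases) {
    r <- score_dlcnc(cs$s, cfg)
    expect_equal(r$score, cs$score)
    expect_equal(r$category, cs$category)
  }
})

test_that("modified DLCNC uses the lower Chinese bands and dominates the original", {
  expect_equal(score_modified_dlcnc(make_subject(pre_ldl = 6.0))$score, 8)
  expect_equal(score_modified_dlcnc(make_subject(pre_ldl = 2.4))$score, 0)
  # band-wise dominance over a fine LDL grid and varied other items
  for (ldl in seq(0.5, 12, by = 0.1)) {
    s <- make_subject(pre_ldl = ldl)
    expect_gte(score_modified_dlcnc(s)$score, score_dlcnc(s)$score)
  }
  set.seed(42)
  for (i in 1:25) {
    s <- make_subject(
      pre_ldl = runif(1, 1, 12),
      fh_first_degree_hyperlipidemia = runif(1) < 0.5,
      fh_first_degree_pcvd = runif(1) < 0.5,
      sign_tendon_xanthoma = runif(1) < 0.3,
      sign_arcus_under_45 = runif(1) < 0.3,
      ph_premature_cad = runif(1) < 0.3,
      genetic_confirmed = runif(1) < 0.5
    )
    expect_gte(score_modified_dlcnc(s)$score, score_dlcnc(s)$score)
  }
})

test_that("pediatric DLCNC is flagged as not validated and can be suppressed", {
  child <- make_subject(age_years = 10, pre_ldl = 6.0)
  r <- score_dlcnc(child)
  expect_true(r$pediatric_not_validated)
  expect_false(is.na(r$binary_call))
  cfg <- fh_default_config()
  cfg$dlcnc$pediatric_policy <- "suppress"
  r2 <- score_dlcnc(child, cfg)
  expect_equal(r2$score, 3)           # score still computed
  expect_true(is.na(r2$binary_call))  # call suppressed
  expect_true(is.na(r2$category))
})

test_that("Simon Broome distinguishes definite, possible and negative", {
  adult_def <- make_subject(pre_ldl = 5.0, sign_tendon_xanthoma = TRUE)
  expect_equal(classify_simon_broome(adult_def)$category, "definite")
  child_pos <- make_subject(age_years = 10, pre_ldl = 4.1,
                            fh_first_degree_hyperlipidemia = TRUE)
  expect_equal(classify_simon_broome(child_pos)$category, "possible")
  # strict '>': adult at exactly 4.9 is negative whatever else holds
  boundary <- make_subject(pre_ldl = 4.9, sign_tendon_xanthoma = TRUE,
                           fh_first_degree_hyperlipidemia = TRUE)
  expect_equal(classify_simon_broome(boundary)$category, "negative")
  # relative's tendon xanthoma promotes to definite when configured
  rel <- make_subject(pre_ldl = 5.0, sign_relative_tendon_xanthoma = TRUE)
  expect_equal(classify_simon_broome(rel)$category, "definite")
  cfg <- fh_default_config()
  cfg$simon_broome$relative_xanthoma_counts <- FALSE
  expect_equal(classify_simon_broome(rel, cfg)$category, "negative")
  # a DNA variant is a definite route unless masked
  dna <- make_subject(pre_ldl = 5.0, genetic_confirmed = TRUE)
  expect_equal(classify_simon_broome(dna)$category, "definite")
  expect_equal(classify_simon_broome(dna, use_genetic = FALSE)$category,
               "negative")
})

test_that("MEDPED uses the age-band x relatedness threshold table, strict '>'", {
  # age 25 with a first-degree FH relative: threshold 5.9
  s <- make_subject(age_years = 25, pre_tc = 6.0, pre_ldl = 4.0,
                    fh_relative_fh_diagnosis = TRUE)
  expect_true(classify_medped(s)$binary_call)
  # same TC without an FH relative: general-population threshold 7.5
  s2 <- make_subject(age_years = 25, pre_tc = 6.0, pre_ldl = 4.0)
  expect_false(classify_medped(s2)$binary_call)
  s3 <- make_subject(age_years = 25, pre_tc = 5.0, pre_ldl = 3.0)
  expect_false(classify_medped(s3)$binary_call)
  # TC exactly at threshold is negative
  s4 <- make_subject(age_years = 25, pre_tc = 5.9, pre_ldl = 4.0,
                     fh_relative_fh_diagnosis = TRUE)
  expect_false(classify_medped(s4)$binary_call)
  s5 <- make_subject(age_years = NA, pre_tc = 9.9, pre_ldl = 4.0)
  expect_error(classify_medped(s5), "age")
})

test_that("JFHMC needs LDL above the age cutoff plus signs or family history", {
  pos <- make_subject(pre_ldl = 4.8, sign_tendon_xanthoma = TRUE)
  expect_true(classify_jfhmc(pos)$binary_call)
  # LDL alone is not enough
  ldl_only <- make_subject(pre_ldl = 4.8)
  expect_false(classify_jfhmc(ldl_only)$binary_call)
  # child boundary is strict
  child <- make_subject(age_years = 10, pre_ldl = 3.6,
                        fh_first_degree_hyperlipidemia = TRUE)
  expect_false(classify_jfhmc(child)$binary_call)
  # homozygous flag from total cholesterol > 15.5
  hofh <- make_subject(pre_tc = 15.6, pre_ldl = 13.0)
  expect_true(classify_jfhmc(hofh)$hofh_flag)
  expect_false(classify_jfhmc(make_subject(pre_tc = 15.5, pre_ldl = 13))$hofh_flag)
})

test_that("Hong Kong panel arms behave as specified for adults and children", {
  expect_true(classify_hk_panel(make_subject(pre_ldl = 5.1))$binary_call)
  with_hist <- make_subject(pre_ldl = 4.6, fh_first_degree_pcvd = TRUE)
  expect_true(classify_hk_panel(with_hist)$binary_call)
  expect_false(classify_hk_panel(make_subject(pre_ldl = 4.6))$binary_call)
  # children: family-history arm, high-LDL arm, physical-signs arm
  child_hist <- make_subject(age_years = 9, pre_ldl = 3.7,
                             fh_relative_fh_diagnosis = TRUE)
  expect_true(classify_hk_panel(child_hist)$binary_call)
  child_ldl <- make_subject(age_years = 9, pre_ldl = 5.0)
  expect_true(classify_hk_panel(child_ldl)$binary_call)
  child_sign <- make_subject(age_years = 9, pre_ldl = 2.0,
                             sign_xanthelasma = TRUE)
  expect_true(classify_hk_panel(child_sign)$binary_call)
  expect_false(classify_hk_panel(make_subject(age_years = 9, pre_ldl = 3.7))$binary_call)
})

test_that("all binary calls are monotone non-decreasing in LDL-C", {
  grid <- seq(1, 12, by = 0.25)
  classifiers <- list(
    function(s) score_dlcnc(s)$binary_call,
    function(s) score_modified_dlcnc(s)$binary_call,
    function(s) classify_simon_broome(s)$binary_call,
    function(s) classify_jfhmc(s)$binary_call,
    function(s) classify_hk_panel(s)$binary_call
  )
  for (fn in classifiers) {
    calls <- vapply(grid, function(ldl) {
      fn(make_subject(pre_ldl = ldl, fh_first_degree_hyperlipidemia = TRUE))
    }, logical(1))
    expect_true(all(diff(as.integer(calls)) >= 0))
  }
  # MEDPED: monotone in total cholesterol
  medped_calls <- vapply(seq(4, 12, by = 0.25), function(tc) {
    classify_medped(make_subject(pre_tc = tc, pre_ldl = 4))$binary_call
  }, logical(1))
  expect_true(all(diff(as.integer(medped_calls)) >= 0))
})

test_that("evaluating all criteria is deterministic and pure", {
  cohort <- make_cohort(
    make_subject("A", pre_ldl = 8.6, pre_tc = 10.4,
                 sign_tendon_xanthoma = TRUE),
    make_subject("B", age_years = 12, pre_ldl = 4.2, pre_tc = 6.0,
                 fh_relative_fh_diagnosis = TRUE),
    make_subject("C", pre_ldl = 5.6, pre_tc = 7.4,
                 fh_first_degree_pcvd = TRUE)
  )
  r1 <- evaluate_all_criteria(cohort)
  r2 <- evaluate_all_criteria(cohort)
  expect_identical(r1, r2)
  expect_equal(unique(r1$criterion),
               c("DLCNC", "modified_DLCNC", "SimonBroome", "MEDPED",
                 "JFHMC", "HK_panel"))
  expect_equal(nrow(r1), 6 * nrow(cohort))
})
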