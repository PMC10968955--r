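test_that("binarization implements the component definitions", {
  r <- blank_respondent()

  jan <- r; jan$birth_month <- "January"
  expect_equal(binarize_exposures(jan)$winter_birth, 1L)
  dec <- r; dec$birth_month <- 12
  expect_equal(binarize_exposures(dec)$winter_birth, 1L)
  mar <- r; mar$birth_month <- 3
  expect_equal(binarize_exposures(mar)$winter_birth, 0L)

  expect_equal(binarize_exposures(r)$obstetric_complications, 0L)
  dk <- r; dk$oc_low_birth_weight <- "I don't know"
  expect_true(is.na(binarize_exposures(dk)$obstetric_complications))
  yes_dk <- dk; yes_dk$oc_csection <- "yes"
  expect_equal(binarize_exposures(yes_dk)$obstetric_complications, 1L)

  pa <- r
  pa$paternal_age <- 34
  p <- binarize_exposures(pa)
  expect_equal(p$advanced_paternal_age, 0L)
  expect_equal(p$paternal_tier, "none")
  pa$paternal_age <- 40
  expect_equal(binarize_exposures(pa)$paternal_tier, "35-54")
  pa$paternal_age <- 60
  expect_equal(binarize_exposures(pa)$paternal_tier, ">=55")
  pa$paternal_age <- NA
  expect_true(is.na(binarize_exposures(pa)$advanced_paternal_age))

  h <- r; h$handedness <- "left"
  expect_equal(binarize_exposures(h)$non_right_handedness, 1L)
  h$handedness <- "mixed"
  expect_equal(binarize_exposures(h)$non_right_handedness, 1L)

  cp <- r; cp$cpq_07 <- "yes"
  expect_equal(binarize_exposures(cp)$cannabis_use, 1L)

  u <- r; u$residence <- "city_gt_500k"
  expect_equal(binarize_exposures(u)$urban_upbringing, 1L)

  bad <- r; bad$birth_month <- "Snowuary"
  expect_error(binarize_exposures(bad), "birth_month")
  badh <- r; badh$handedness <- "ambidextrous-ish"
  expect_error(binarize_exposures(badh), "handedness")
})

test_that("the score engine matches hand-computed reference values", {
  w <- default_weight_table()
  prof <- binarize_exposures(blank_respondent())
  expect_equal(compute_es(prof, w)$score, 0)

  ea_only <- blank_respondent()
  ea_only$emotional_abuse <- "yes"
  es <- compute_es(binarize_exposures(ea_only), w, "fixed_total")
  expect_equal(round(es$score, 3), 0.122)  # ln(3.40)/10
  expect_equal(es$n_recorded, 10)

  all_on <- blank_respondent()
  all_on$birth_month <- 1
  all_on$oc_preterm <- "yes"
  all_on$paternal_age <- 40
  all_on$handedness <- "left"
  all_on$emotional_neglect <- "yes"; all_on$emotional_abuse <- "yes"
  all_on$bullying <- "yes"; all_on$sexual_abuse <- "yes"
  all_on$cpq_01 <- "yes"
  all_on$residence <- "city_le_100k"
  expect_equal(round(compute_es(binarize_exposures(all_on), w)$score, 3),
               0.662)
  older <- all_on; older$paternal_age <- 60
  expect_equal(round(compute_es(binarize_exposures(older), w)$score, 3),
               0.717)
})

test_that("missing components are excluded from the per-respondent denominator", {
  w <- default_weight_table()
  r <- blank_respondent()
  r$emotional_abuse <- "yes"
  r$oc_csection <- "I don't know"
  r$oc_low_birth_weight <- "I don't know"
  r$oc_preterm <- "I don't know"
  prof <- binarize_exposures(r)
  fixed <- compute_es(prof, w, "fixed_total")
  per <- compute_es(prof, w, "per_respondent_recorded")
  expect_equal(fixed$score, log(3.40) / 10)
  expect_equal(per$score, log(3.40) / 9)
  expect_equal(per$n_recorded, 9)

  all_miss <- prof
  for (cmp in es_components()) all_miss[[cmp]] <- NA_integer_
  expect_error(compute_es(all_miss, w, "per_respondent_recorded"),
               "undefined")
  expect_equal(compute_es(all_miss, w, "fixed_total")$score, 0)
})

test_that("flipping any single component from absent to present strictly increases the score", {
  w <- default_weight_table()
  base <- binarize_exposures(blank_respondent())
  for (cmp in es_components()) {
    for (policy in c("fixed_total", "per_respondent_recorded")) {
      flipped <- base
      flipped[[cmp]] <- 1L
      if (cmp == "advanced_paternal_age") flipped$paternal_tier <- "35-54"
      s0 <- compute_es(base, w, policy)$score
      s1 <- compute_es(flipped, w, policy)$score
      expect_gt(s1, s0)
    }
  }
})

test_that("scores stay inside the weight-table bounds", {
  w <- default_weight_table()
  set.seed(71)
  for (i in 1:50) {
    prof <- binarize_exposures(blank_respondent())
    for (cmp in es_components()) {
      prof[[cmp]] <- sample(c(0L, 1L, NA_integer_), 1)
    }
    prof$paternal_tier <- if (isTRUE(prof$advanced_paternal_age == 1L)) {
      sample(c("35-54", ">=55"), 1)
    } else "none"
    s <- compute_es(prof, w, "fixed_total")$score
    expect_gte(s, 0)
    expect_lte(s, 0.7169 + 1e-9)
  }
})

test_that("scoring a calibrated cohort reproduces the analytic mean score", {
  # analytic expectation: sum(prevalence * weight * observed-fraction) / 10
  spec <- cohort_spec(n_respondents = 20000, seed = 5)
  w <- default_weight_table()
  wts <- setNames(w$components$log_odds, w$components$component)
  prev <- spec$exposure_prevalences
  obs <- setNames(rep(1, 10), names(prev))
  obs["obstetric_complications"] <- 1 - spec$missingness[["obstetric_complications"]]
  obs["advanced_paternal_age"] <- 1 - spec$missingness[["paternal_age"]]
  analytic <- sum(prev * wts[names(prev)] * obs) / 10
  es <- score_cohort(generate_cohort(spec))
  expect_lt(abs(mean(es$score) - analytic), 0.02)
})
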