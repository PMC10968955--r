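test_that("the identity resample reproduces the point estimates exactly", {
  d <- sample_mgm(four_node_graph(0.4, 0.2), 500, burn_in = 300, thin = 2,
                  seed = 3)
  run <- nonparametric_boot(d, B = 1, seed = 1,
                            indices = list(seq_len(nrow(d$values))))
  expect_equal(unname(run$edges[1, ]),
               unname(exponet:::upper_tri_vec(
                 exponet:::signed_weights(run$point))))
  expect_equal(unname(run$strengths[1, ]), unname(node_strength(run$point)))
})

test_that("bootstrap runs are deterministic given the seed", {
  d <- sample_mgm(four_node_graph(0.4, 0.2), 300, burn_in = 200, thin = 2,
                  seed = 5)
  r1 <- nonparametric_boot(d, B = 10, seed = 7)
  r2 <- nonparametric_boot(d, B = 10, seed = 7)
  expect_identical(r1$edges, r2$edges)
  r3 <- nonparametric_boot(d, B = 10, seed = 8)
  expect_false(identical(r1$edges, r3$edges))
})

test_that("resamples with a zero-variance column are skipped and logged", {
  set.seed(2)
  vals <- cbind(x = rnorm(60), y = rnorm(60),
                rare = c(1, rep(0, 59)))
  d <- mixed_data(vals, c("continuous", "continuous", "binary"))
  expect_message(run <- nonparametric_boot(d, B = 25, seed = 4),
                 "skipped")
  expect_gt(length(run$skipped), 0)
  expect_true(all(is.na(run$edges[run$skipped, ])))
})

test_that("the CS-coefficient matches hand-constructed bootstrap records", {
  run <- constructed_casedrop(cut = 0.4)
  expect_equal(cs_coefficient(run)$cs_coefficient, 0.4)

  perfect <- constructed_casedrop(cut = 1)  # every proportion qualifies
  expect_equal(cs_coefficient(perfect)$cs_coefficient, 0.75)

  unstable <- constructed_casedrop(cut = 0)  # none qualifies
  expect_equal(cs_coefficient(unstable)$cs_coefficient, 0)
  expect_false(cs_coefficient(unstable)$exceeds_0.25)
  expect_true(cs_coefficient(perfect)$exceeds_0.25)

  expect_error(cs_coefficient(structure(list(mode = "nonparametric"),
                                        class = "bootstrap_run")),
               "case-drop")
})

test_that("raising the threshold or level never increases the CS-coefficient", {
  run <- constructed_casedrop(cut = 0.4)
  base <- cs_coefficient(run, 0.7, 0.95)$cs_coefficient
  for (thr in c(0.8, 0.9)) {
    expect_lte(cs_coefficient(run, thr, 0.95)$cs_coefficient, base)
  }
  for (lvl in c(0.97, 0.99)) {
    expect_lte(cs_coefficient(run, 0.7, lvl)$cs_coefficient, base)
  }
})

test_that("case-drop bootstrap flags degenerate strength vectors and small subsamples", {
  # 2-node network: the strength vector is always constant, so every
  # iteration is flagged and no CS-coefficient is computable
  set.seed(6)
  vals <- cbind(a = rnorm(150), b = rnorm(150))
  vals[, "b"] <- vals[, "a"] * 0.6 + rnorm(150, sd = 0.6)
  d2 <- mixed_data(vals, c("continuous", "continuous"))
  run <- casedrop_boot(d2, proportions = c(0.2, 0.5), B = 5, seed = 2)
  expect_true(all(is.na(run$correlations)))
  expect_error(cs_coefficient(run), "empty")

  d4 <- sample_mgm(four_node_graph(0.4, 0.3), 40, burn_in = 200, thin = 2,
                   seed = 3)
  expect_warning(casedrop_boot(d4, proportions = c(0.2, 0.95), B = 2,
                               seed = 1),
                 "smaller than p \\+ 1")
  expect_error(casedrop_boot(d4, proportions = c(0.5, 0.2), B = 2),
               "increasing")
})

test_that("case-drop correlations are high for a well-determined network", {
  d <- sample_mgm(recovery_graph(), 2000, seed = 19)
  run <- casedrop_boot(d, proportions = c(0.1, 0.3), B = 25, seed = 11)
  med <- apply(run$correlations, 1, median, na.rm = TRUE)
  expect_gte(med[["drop_0.3"]], 0.9)
})

test_that("bootstrap intervals behave sensibly on a well-powered cohort", {
  d <- sample_mgm(four_node_graph(0.4, 0.25), 2000, seed = 29)
  run <- nonparametric_boot(d, B = 150, seed = 9)
  point <- exponet:::upper_tri_vec(exponet:::signed_weights(run$point))
  qs <- apply(run$edges, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  covered <- point >= qs[1, ] & point <= qs[2, ]
  expect_gte(mean(covered), 0.9)
  # a strongly supported edge keeps an interval excluding zero
  expect_gt(qs[1, "x1--x2"], 0)
})

test_that("difference tests compare bootstrapped statistics", {
  d <- sample_mgm(four_node_graph(0.4, 0.05), 2000, seed = 31)
  run <- nonparametric_boot(d, B = 200, seed = 13)
  self <- difference_test(run, "x1--x2", "x1--x2")
  expect_equal(self$result, "not_significant")
  expect_equal(difference_test(run, "x2--x1", "x1--x2")$result,
               "not_significant")  # label order is irrelevant
  strong_vs_weak <- difference_test(run, "x1--x2", "x3--x4")
  expect_equal(strong_vs_weak$result, "significant")
  expect_error(difference_test(run, "x1--x2", "nope--x4"), "not present")

  small <- nonparametric_boot(d, B = 20, seed = 14)
  expect_warning(res <- difference_test(small, "x1--x2", "x3--x4"),
                 "fewer than 100")
  expect_true(res$precision_warning)
})
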