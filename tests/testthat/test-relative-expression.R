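test_that("delta Cq subtracts the per-sample normalization value", {
  cq <- cq_from_matrix(rbind(rep(25, 3), rep(20, 3)),
                       targets = c("goi", "ref"))
  d <- delta_cq(cq, "ref", target = "goi")
  expect_equal(d$delta_cq, rep(5, 3))

  # target normalized against itself: all zero
  expect_equal(delta_cq(cq, "ref", target = "ref")$delta_cq, rep(0, 3))

  # missing target Cq excluded, not imputed
  m <- rbind(c(rep(25, 9), NA), rep(20, 10))
  cqm <- cq_from_matrix(m, targets = c("goi", "ref"))
  expect_equal(nrow(delta_cq(cqm, "ref", target = "goi")), 9)

  # normalization missing for an observed sample is an error
  f <- tibble::tibble(sample_id = c("s01", "s02"), value = c(20, 20))
  expect_error(delta_cq(cq, f, target = "goi"), "s03")
})

test_that("fold changes follow the negative-inverse convention", {
  expect_equal(fold_change_from_ddcq(0), 1)
  expect_equal(fold_change_from_ddcq(-1), 2)
  expect_equal(fold_change_from_ddcq(2), -4)

  fc <- ddcq_fold_change(c(1, 2, 3), c(3, 4, 5))
  expect_equal(fc$ddcq, -2)
  expect_equal(fc$fold_change, 4)

  # |FC| >= 1 always, never inside (-1, 1)
  withr::with_seed(7, {
    fcs <- fold_change_from_ddcq(rnorm(500, 0, 2))
    expect_true(all(abs(fcs) >= 1))
  })

  # case/control swap maps FC x -> -x for |x| > 1, and 1 -> 1
  withr::with_seed(8, {
    for (i in 1:20) {
      a <- rnorm(5); b <- rnorm(4)
      f1 <- ddcq_fold_change(a, b)$fold_change
      f2 <- ddcq_fold_change(b, a)$fold_change
      if (abs(f1) > 1) expect_equal(f2, -f1, tolerance = 1e-12)
    }
  })
  same <- ddcq_fold_change(c(1, 2), c(2, 1))
  expect_equal(same$fold_change, 1)

  expect_error(ddcq_fold_change(numeric(0), 1), "at least one")
})

test_that("the Wilcoxon group test matches full enumeration", {
  # symmetric identical groups
  expect_equal(group_test(c(1, 2, 3), c(1, 2, 3)), 1)

  # the most extreme of the C(6,3) = 20 orderings: two-sided p = 2/20
  expect_equal(group_test(c(10, 11, 12), c(1, 2, 3)), 0.1)

  # rank invariance under a common shift
  withr::with_seed(91, {
    x <- rnorm(6); y <- rnorm(5)
    expect_equal(group_test(x, y), group_test(x + 10, y + 10))
  })

  # exact enumeration oracle across group sizes up to 4+4 (5+5 runs in the
  # acceptance suite)
  withr::with_seed(93, {
    for (n1 in 2:4) {
      for (n2 in 2:4) {
        x <- rnorm(n1); y <- rnorm(n2)
        expect_equal(group_test(x, y), oracle_wilcox_p(x, y),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("relative expression is invariant to a global Cq shift", {
  sim <- simulate_cq_dataset(n_targets = 8, groups = c(case = 6, control = 6),
                             missingness = 0, seed = 17)
  ref <- sim$cq$target_id[1]
  r1 <- relative_expression(sim$cq, ref, "case", "control")
  shifted <- sim$cq; shifted$cq <- shifted$cq + 3
  r2 <- relative_expression(shifted, ref, "case", "control")
  expect_equal(r1$ddcq, r2$ddcq, tolerance = 1e-10)
  expect_equal(r1$fold_change, r2$fold_change, tolerance = 1e-10)
  expect_equal(r1$p_value, r2$p_value)
  nf <- normalization_factor(sim$cq, "geomean")

  # result carries the broom verbs
  expect_s3_class(glance(r1), "tbl_df")
  expect_false(inherits(tidy(r1), "expression_result"))
  expect_error(relative_expression(sim$cq, nf, "case", "nope"), "nope")
})

test_that("Dunn's post hoc matches hand-computed z statistics", {
  # 1..9 split a/b/c: mean ranks 2, 5, 8; se = sqrt(90/12 * 2/3) = sqrt(5)
  x <- 1:9
  g <- rep(c("a", "b", "c"), each = 3)
  d <- dunn_posthoc(x, g, p_adjust = "none")
  expect_equal(d$z[d$group1 == "a" & d$group2 == "b"], -3 / sqrt(5),
               tolerance = 1e-12)
  expect_equal(d$z[d$group1 == "a" & d$group2 == "c"], -6 / sqrt(5),
               tolerance = 1e-12)
  expect_equal(d$p_value, 2 * pnorm(-abs(d$z)), tolerance = 1e-12)

  # tie correction: duplicated values reduce the variance term
  xt <- c(1, 1, 2, 3, 4, 4, 5, 6, 7)
  dt_ <- dunn_posthoc(xt, g)
  expect_true(all(is.finite(dt_$z)))
  # Holm adjustment never lowers a p-value
  expect_true(all(dt_$p_adj >= dt_$p_value - 1e-15))
})

test_that("threshold comparison flags only genuinely shifted methods", {
  sim <- simulate_cq_dataset(n_targets = 6, groups = c(case = 15, control = 15),
                             missingness = 0, seed = 19)
  same <- list(fixed = sim$cq, automatic = sim$cq, relative = sim$cq)
  tc0 <- compare_thresholds(same)
  expect_true(all(tc0$tests$kw_p == 1))
  expect_false(any(tc0$tests$flagged))

  # one method shifted +3 cycles on one 30-sample target
  hits <- withr::with_seed(97, {
    vapply(1:5, function(r) {
      base <- cq_from_matrix(matrix(25 + rnorm(30, 0, 0.7), 1, 30),
                             targets = "t")
      shifted <- base; shifted$cq <- shifted$cq + 3
      tc <- compare_thresholds(list(fixed = shifted, automatic = base,
                                    relative = base))
      ph <- tc$posthoc
      involves <- ph$group1 == "fixed" | ph$group2 == "fixed"
      tc$tests$kw_p < 0.01 && all(ph$p_adj[involves] < 0.05) &&
        all(ph$p_adj[!involves] > 0.05)
    }, logical(1))
  })
  expect_equal(mean(hits), 1)

  # flag sets are monotone in the threshold: 0.01 flags are a subset of 0.05
  shifted <- sim$cq
  shifted$cq[shifted$target_id == "miR-A-002"] <-
    shifted$cq[shifted$target_id == "miR-A-002"] + 1
  t1 <- compare_thresholds(list(a = sim$cq, b = shifted), flag_p = 0.01)
  t5 <- compare_thresholds(list(a = sim$cq, b = shifted), flag_p = 0.05)
  expect_true(all(t1$tests$target_id[t1$tests$flagged] %in%
                    t5$tests$target_id[t5$tests$flagged]))

  expect_error(compare_thresholds(list(a = sim$cq)), "two methods")
})

test_that("cross-method agreement correlations behave as matrices", {
  sim <- simulate_cq_dataset(n_targets = 10, groups = c(case = 8, control = 8),
                             missingness = 0, seed = 23)
  nf <- normalization_factor(sim$cq, "geomean")
  r1 <- relative_expression(sim$cq, nf, "case", "control", method_label = "m1")

  # identical inputs: r = 1 everywhere
  ag <- cross_method_agreement(list(m1 = r1, m2 = r1))
  expect_equal(unname(ag$fc), matrix(1, 2, 2))
  expect_equal(unname(ag$p), matrix(1, 2, 2))
  expect_equal(diag(ag$fc), c(m1 = 1, m2 = 1))

  # a heavily perturbed third method correlates less than the matched pair
  # (per-call perturbation SD 1.0 vs shared-call noise SD 0.05)
  pert <- sim$cq
  withr::with_seed(29, {
    pert$cq <- pert$cq + rnorm(nrow(pert), 0, 1)
    noisy <- sim$cq; noisy$cq <- noisy$cq + rnorm(nrow(noisy), 0, 0.05)
  })
  r2 <- relative_expression(noisy, normalization_factor(noisy, "geomean"),
                            "case", "control", method_label = "m2")
  r3 <- relative_expression(pert, normalization_factor(pert, "geomean"),
                            "case", "control", method_label = "m3")
  ag3 <- cross_method_agreement(list(m1 = r1, m2 = r2, m3 = r3))
  expect_gt(ag3$fc["m1", "m2"], ag3$fc["m1", "m3"])
  expect_gt(ag3$fc["m1", "m2"], ag3$fc["m2", "m3"])
  expect_equal(ag3$fc, t(ag3$fc))

  long <- tidy(ag3)
  expect_setequal(unique(long$quantity), c("fold_change", "p_value"))

  expect_error(cross_method_agreement(list(m1 = r1[1:2, ], m2 = r1[1:2, ])),
               "3 shared")
})
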