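genorm_fixture <- function() {
  cq_from_matrix(rbind(c(20, 21, 22), c(20, 21, 22), c(20, 22, 24)),
                 targets = c("A", "B", "C"))
}

test_that("BestKeeper SD and CV match hand computation", {
  cq <- cq_from_matrix(matrix(c(20, 22, 24), 1), targets = "A")
  bk <- bestkeeper_stats(cq)
  expect_equal(bk$bestkeeper_sd, 2)
  expect_equal(bk$bestkeeper_cv, 100 * 2 / 22, tolerance = 1e-12)

  # constant target: SD and CV are 0
  const <- bestkeeper_stats(cq_from_matrix(matrix(20, 1, 5), targets = "A"))
  expect_equal(const$bestkeeper_sd, 0)
  expect_equal(const$bestkeeper_cv, 0)

  # shifting all Cq leaves the SD alone but changes the CV
  sh <- bestkeeper_stats(cq_from_matrix(matrix(c(30, 32, 34), 1), targets = "A"))
  expect_equal(sh$bestkeeper_sd, 2)
  expect_false(isTRUE(all.equal(sh$bestkeeper_cv, bk$bestkeeper_cv)))

  expect_error(bestkeeper_stats(cq_from_matrix(matrix(c(20, 21), 1))),
               "3 samples")
})

test_that("geNorm M and delta-Ct reproduce the worked example", {
  cq <- genorm_fixture()
  gm <- genorm_m(cq)
  expect_equal(gm$genorm_m[gm$target_id == "A"], 0.5)
  expect_equal(gm$genorm_m[gm$target_id == "B"], 0.5)
  expect_equal(gm$genorm_m[gm$target_id == "C"], 1.0)

  dc <- deltact_stability(cq)
  expect_equal(dc$deltact_mean_sd, c(0.5, 0.5, 1.0))

  # identical profiles: every pairwise variation, hence every M, is zero
  same <- cq_from_matrix(matrix(rep(c(20, 21, 22), each = 4), nrow = 4,
                                byrow = FALSE))
  expect_true(all(genorm_m(same)$genorm_m == 0))

  expect_error(genorm_m(cq[cq$target_id != "C", ]), "3 candidates")
})

test_that("pairwise statistics equal an independent brute force", {
  withr::with_seed(67, {
    for (i in 1:10) {
      m <- matrix(rnorm(8 * 20, 25, 2), nrow = 8)
      cq <- cq_from_matrix(m)
      oracle <- oracle_pairwise_stats(m)
      expect_equal(genorm_m(cq)$genorm_m, oracle, tolerance = 1e-10)
      expect_equal(deltact_stability(cq)$deltact_mean_sd, oracle,
                   tolerance = 1e-10)
    }
  })
})

test_that("geNorm stepwise exclusion ranks the worst candidate last", {
  withr::with_seed(3, {
    m <- rbind(matrix(rnorm(5 * 12, 25, 0.2), nrow = 5),
               25 + rnorm(12, 0, 3))
  })
  gm <- genorm_m(cq_from_matrix(m), stepwise = TRUE)
  expect_equal(gm$genorm_stepwise_rank[6], 6)
  expect_equal(sort(gm$genorm_stepwise_rank)[1:2], c(1.5, 1.5))
})

test_that("NormFinder behaves per its variance-decomposition contract", {
  # single group: the zero-variance candidate attains the minimum
  withr::with_seed(71, {
    m <- rbind(rep(25, 12), matrix(rnorm(4 * 12, 25, 1), nrow = 4))
  })
  nf <- normfinder_stability(cq_from_matrix(m))
  expect_equal(which.min(nf$normfinder_value), 1L)

  # adding a constant to every cell changes nothing
  nf2 <- normfinder_stability(cq_from_matrix(m + 7))
  expect_equal(nf$normfinder_value, nf2$normfinder_value, tolerance = 1e-12)

  # two groups: a +1 Cq group-shifted candidate ranks strictly worse than
  # shift-free candidates of equal intragroup variance
  worse <- withr::with_seed(73, {
    vapply(1:20, function(r) {
      k <- 8; n <- 15
      m <- runif(k, 20, 30) + matrix(rnorm(k * 2 * n, 0, 0.3), k)
      m[1, seq_len(n)] <- m[1, seq_len(n)] + 1
      cq <- cq_from_matrix(m, groups = rep(c("g1", "g2"), each = n))
      v <- normfinder_stability(cq)$normfinder_value
      all(v[1] > v[-1])
    }, logical(1))
  })
  expect_gte(mean(worse), 0.95)

  # tiny groups rejected
  tiny <- cq_from_matrix(matrix(rnorm(8), 2), groups = c("a", "a", "a", "b"))
  expect_error(normfinder_stability(tiny), "at least 2 samples")
})

test_that("the comprehensive rank is the geometric mean of method ranks", {
  two <- comprehensive_rank(tibble::tibble(
    target_id = c("x", "y"), m1 = c(1, 2), m2 = c(2, 1),
    m3 = c(1, 2), m4 = c(2, 1)
  ))
  expect_equal(two$comprehensive_score, c(sqrt(2), sqrt(2)))
  expect_equal(two$final_rank[two$target_id == "x"], 1L) # tie broken by id

  unanimous <- comprehensive_rank(tibble::tibble(
    target_id = c("b", "a"), m1 = c(1, 2), m2 = c(1, 2),
    m3 = c(1, 2), m4 = c(2, 1)
  ))
  expect_equal(unanimous$target_id[unanimous$final_rank == 1], "b")

  # random rank tuples match a brute-force geometric-mean sort
  withr::with_seed(79, {
    for (i in 1:10) {
      k <- 5
      ranks <- tibble::tibble(
        target_id = sprintf("t%d", 1:k),
        m1 = sample(k), m2 = sample(k), m3 = sample(k), m4 = sample(k)
      )
      out <- comprehensive_rank(ranks)
      brute <- (ranks$m1 * ranks$m2 * ranks$m3 * ranks$m4)^(1 / 4)
      expect_equal(out$comprehensive_score[match(ranks$target_id, out$target_id)],
                   brute, tolerance = 1e-12)
      expect_equal(out$target_id, ranks$target_id[order(brute, ranks$target_id)])
    }
  })

  expect_error(comprehensive_rank(tibble::tibble(target_id = "a", m1 = NA_real_)),
               "complete")
})

test_that("stability input is restricted to 100% call-rate candidates", {
  cq <- genorm_fixture()
  cq$cq[2] <- NA
  expect_error(rank_stability(cq), "100% call rate")
  expect_error(genorm_m(cq), "B")
})

test_that("the full stability report is coherent and rank-recovers", {
  sim <- simulate_cq_dataset(missingness = 0, seed = 101)
  rep <- rank_stability(sim$cq)
  expect_s3_class(rep, "stability_report")
  expect_equal(sort(rep$final_rank), seq_len(nrow(rep)))
  stable <- sim$truth$target_id[sim$truth$stable]
  expect_equal(rep$target_id[rep$final_rank == 1], stable)
  # every statistic agrees that lower = more stable for the designated target
  row <- rep[rep$target_id == stable, ]
  expect_equal(row$rank_bestkeeper, 1)
  expect_equal(row$rank_deltact, 1)

  expect_equal(nrow(glance(rep)), 1)
  expect_s3_class(tidy(rep), "tbl_df")
  expect_false(inherits(tidy(rep), "stability_report"))

  # all four statistics are invariant to a constant shift of the matrix
  shifted <- sim$cq; shifted$cq <- shifted$cq + 5
  rep2 <- rank_stability(shifted)
  expect_equal(rep2$genorm_m, rep$genorm_m, tolerance = 1e-12)
  expect_equal(rep2$deltact_mean_sd, rep$deltact_mean_sd, tolerance = 1e-12)
  expect_equal(rep2$normfinder_value, rep$normfinder_value, tolerance = 1e-12)
  expect_equal(rep2$bestkeeper_sd, rep$bestkeeper_sd, tolerance = 1e-12)
})

test_that("geometric-mean normalization factors obey the positivity rule", {
  expect_equal(geometric_mean(c(2, 8)), 4)
  expect_error(geometric_mean(c(2, 0)), "zero or negative")

  cq <- cq_from_matrix(matrix(20, 4, 5))
  nf <- normalization_factor(cq, "geomean")
  expect_equal(nf$value, rep(20, 5), tolerance = 1e-12)
  expect_equal(nf$kind[1], "geometric_mean")
  expect_equal(unique(nf$n_targets), 4L)

  bad <- cq; bad$cq[1] <- 0
  expect_error(normalization_factor(bad, "geomean"), "zero")

  # reference-target factor is that target's raw Cq
  rf <- normalization_factor(genorm_fixture(), "reference", reference = "C")
  expect_equal(rf$value, c(20, 22, 24))
  expect_equal(rf$kind[1], "reference_target")
})

test_that("factor group stability flags real group differences only", {
  # symmetric data with permuted labels: stable, p near 1
  vals <- rep(c(19, 20, 21), 4)
  f <- tibble::tibble(sample_id = sprintf("s%02d", 1:12), card = "A",
                      group = rep(c("a", "b"), 6), value = vals,
                      kind = "geometric_mean")
  r <- factor_group_stability(f)
  expect_equal(r$verdict, "stable")
  expect_gt(r$p_value, 0.5)

  # all tied, 3 vs 3 -> p = 1 with a small-sample warning
  tied <- tibble::tibble(sample_id = sprintf("s%d", 1:6), card = "A",
                         group = rep(c("a", "b"), each = 3), value = 20,
                         kind = "geometric_mean")
  rt <- factor_group_stability(tied)
  expect_equal(rt$p_value, 1)
  expect_equal(rt$verdict, "stable")
  expect_warning(factor_group_stability(tied[-1, ]), "fewer than 3")

  # a +2 Cq shift in one group of 15 vs 15 is flagged unstable
  hits <- withr::with_seed(83, {
    vapply(1:10, function(r) {
      v <- c(rnorm(15, 22, 0.1), rnorm(15, 20, 0.1))
      f <- tibble::tibble(sample_id = sprintf("s%02d", 1:30), card = "A",
                          group = rep(c("a", "b"), each = 15), value = v,
                          kind = "geometric_mean")
      factor_group_stability(f)$verdict == "unstable"
    }, logical(1))
  })
  expect_equal(mean(hits), 1)
})

test_that("reference vs global factor agreement mirrors a shared global shift", {
  cq <- cq_from_matrix(matrix(c(20, 21, 22, 23), 1, 4), targets = "r")
  f <- tibble::tibble(sample_id = sprintf("s%02d", 1:4),
                      value = c(20, 21, 22, 23))
  expect_equal(reference_factor_agreement(cq, "r", f)$estimate, 1)

  # per-sample global shift (SD 1) dominating small independent noise
  withr::with_seed(89, {
    shift <- rnorm(30, 0, 1)
    m <- 25 + matrix(rnorm(12 * 30, 0, 0.05), 12, 30) +
      matrix(shift, 12, 30, byrow = TRUE)
    cqg <- cq_from_matrix(m)
    nf <- normalization_factor(cqg, "geomean")
    r <- reference_factor_agreement(cqg, "t01", nf)$estimate
    expect_gt(r, 0.95)

    # an independent reference decorrelates
    indep <- cq_from_matrix(matrix(25 + rnorm(30), 1, 30), targets = "z")
    r2 <- reference_factor_agreement(indep, "z", nf)$estimate
    expect_lt(abs(r2), 0.5)
  })
  expect_error(reference_factor_agreement(cq[1:2, ], "r", f[1:2, ]),
               "3 samples")
})
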