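test_that("baseline subtraction removes linear drift", {
  # pure drift, no amplification: corrected signal ~ 0 everywhere
  drift <- make_curve(amplitude = 0, intercept = 0.3, slope = 0.005,
                      noise_sd = 0.002, seed = 5)
  corr <- suppressWarnings(subtract_baseline(drift))
  expect_lt(max(abs(corr$rn_corrected)), 3 * 0.002 * 3)
  expect_true(all(c("bl_start", "bl_end", "bl_noise_sd") %in% names(corr)))

  # zero-baseline noise-free logistic: correction is a no-op over the window
  clean <- make_curve(intercept = 0, slope = 0, noise_sd = 0)
  cc <- subtract_baseline(clean)
  win <- cc$bl_start[1]:cc$bl_end[1]
  expect_lt(max(abs(cc$rn_corrected[win] - clean$rn[win])), 1e-4)

  # drift does not displace the threshold crossing
  p <- curve_params(baseline_intercept = 0.1, baseline_slope = 0.005,
                    amplitude = 1, midpoint_cycle = 25, steepness = 1.5,
                    noise_sd = 0)
  drifted <- simulate_curve(p, seed = 1)
  cq <- call_cq(drifted, "fixed", 0.2)$cq
  expect_equal(cq, analytic_crossing(p, 0.2), tolerance = 0.1)

  # flat curve falls back with a warning
  expect_warning(subtract_baseline(make_curve(amplitude = 0, noise_sd = 0.01)),
                 "fell back")
})

test_that("fixed-threshold Cq matches the analytic oracle", {
  cv <- make_curve()
  call <- call_cq(cv, "fixed", 0.2)
  expect_equal(call$cq, 25 + 1.5 * log(0.25), tolerance = 0.02)
  expect_equal(call$threshold_used, 0.2)

  # flat zero curve -> no call
  flat <- make_curve(amplitude = 0, intercept = 0, slope = 0, noise_sd = 0)
  expect_true(is.na(suppressWarnings(call_cq(flat, "fixed", 0.2))$cq))

  # fixed threshold is NOT scale invariant: x10 amplitude lowers Cq
  big <- make_curve(amplitude = 10)
  expect_lt(call_cq(big, "fixed", 0.2)$cq, call$cq)
  expect_equal(call_cq(big, "fixed", 0.2)$cq,
               analytic_crossing(curve_params(amplitude = 10,
                                              midpoint_cycle = 25,
                                              steepness = 1.5, noise_sd = 0),
                                 0.2),
               tolerance = 0.02)

  expect_error(call_cq(cv, "fixed", -1), "threshold")
})

test_that("fixed-threshold recovery holds across random noise-free logistics", {
  pars <- withr::with_seed(31, tibble::tibble(
    amplitude = runif(200, 0.6, 2.5),
    midpoint = runif(200, 22, 32),
    steepness = runif(200, 1.35, 1.7),
    intercept = runif(200, 0, 0.2),
    slope = runif(200, -0.002, 0.004),
    sample_id = sprintf("s%03d", 1:200)
  ))
  curves <- purrr::pmap(pars, function(amplitude, midpoint, steepness,
                                       intercept, slope, sample_id) {
    make_curve(amplitude = amplitude, midpoint = midpoint,
               steepness = steepness, intercept = intercept, slope = slope,
               noise_sd = 0, sample_id = sample_id)
  }) |> purrr::list_rbind()
  truth <- pars$midpoint + pars$steepness * log(0.2 / (pars$amplitude - 0.2))
  calls <- call_cq(curves, "fixed", 0.2)
  err <- calls$cq[match(pars$sample_id, calls$sample_id)] - truth
  expect_lt(max(abs(err)), 0.02)
})

test_that("raising the fixed threshold never decreases Cq", {
  cv <- make_curve(amplitude = 2, noise_sd = 0.005, seed = 3)
  cqs <- vapply(c(0.1, 0.2, 0.4, 0.8, 1.2),
                function(th) call_cq(cv, "fixed", th)$cq, numeric(1))
  expect_true(all(diff(cqs) >= 0))
})

test_that("all methods are translation equivariant", {
  for (k in c(2, 4)) {
    base <- make_curve(midpoint = 24, noise_sd = 0)
    moved <- make_curve(midpoint = 24 + k, noise_sd = 0)
    for (m in c("fixed", "relative")) {
      d <- call_cq(moved, m)$cq - call_cq(base, m)$cq
      expect_equal(d, k, tolerance = 0.05)
    }
    d_auto <- suppressWarnings(call_cq(moved, "automatic")$cq -
                                 call_cq(base, "automatic")$cq)
    expect_equal(d_auto, k, tolerance = 0.3) # midpoint detection is grid-based
  }
})

test_that("automatic threshold is shared per target and tracks the fixed call", {
  # single clean unit-amplitude logistic: within 1 cycle of fixed at 0.2
  cv <- make_curve()
  auto <- suppressWarnings(call_cq(cv, "automatic"))
  expect_equal(auto$cq, call_cq(cv, "fixed", 0.2)$cq, tolerance = 1)
  expect_true(is.na(call_cq(cv, "relative")$threshold_used))

  # two identical curves share the threshold and the Cq
  two <- dplyr::bind_rows(make_curve(sample_id = "a"),
                          make_curve(sample_id = "b"))
  calls <- suppressWarnings(call_cq(two, "automatic"))
  expect_equal(calls$cq[1], calls$cq[2])
  expect_equal(calls$threshold_used[1], calls$threshold_used[2])

  # a non-amplifying curve in the set gets NA without disturbing the others
  mixed <- dplyr::bind_rows(
    make_curve(sample_id = "a"),
    make_curve(sample_id = "b", amplitude = 0, noise_sd = 0.005, seed = 9)
  )
  cm <- suppressWarnings(call_cq(mixed, "automatic"))
  expect_true(is.na(cm$cq[cm$sample_id == "b"]))
  expect_equal(cm$cq[cm$sample_id == "a"], calls$cq[1], tolerance = 1e-6)
})

test_that("relative threshold is affine invariant, fixed is not", {
  cv <- make_curve(noise_sd = 0.01, seed = 13)
  r0 <- call_cq(cv, "relative")$cq
  for (a in c(0.5, 2, 10)) {
    for (b in c(0, 3)) {
      tr <- cv; tr$rn <- a * cv$rn + b
      expect_equal(call_cq(tr, "relative")$cq, r0, tolerance = 1e-6)
    }
  }
  sc <- cv; sc$rn <- 10 * cv$rn
  expect_gt(abs(call_cq(sc, "fixed", 0.2)$cq - call_cq(cv, "fixed", 0.2)$cq),
            0.5)
})

test_that("relative threshold ignores amplitude and refuses flat curves", {
  ra <- call_cq(make_curve(amplitude = 0.5, noise_sd = 0), "relative")$cq
  rb <- call_cq(make_curve(amplitude = 2.0, noise_sd = 0), "relative")$cq
  expect_equal(ra, rb, tolerance = 0.05)

  flat <- make_curve(amplitude = 0, noise_sd = 0.01, seed = 2)
  expect_true(is.na(suppressWarnings(call_cq(flat, "relative"))$cq))
})
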