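test_that("C1 mean estimator reproduces hand-evaluated cases", {
  expect_identical(mean_c1_hozo(0, 5, 10, simplified = TRUE), 5)
  expect_identical(mean_c1_hozo(3, 3, 3, simplified = TRUE), 3)
  expect_identical(mean_c1_hozo(10, 20, 70, simplified = TRUE), 30)
  # full form keeps the 1/n correction: (10+40+70)/4 + (10-40+70)/(4*5)
  expect_equal(mean_c1_hozo(10, 20, 70, n = 5), 32)
  # the correction vanishes as n grows
  expect_equal(mean_c1_hozo(10, 20, 70, n = 1e8),
               mean_c1_hozo(10, 20, 70, simplified = TRUE),
               tolerance = 1e-6)
  expect_error(mean_c1_hozo(10, 20, 70), "simplified")
  expect_error(mean_c1_hozo(5, 2, 10, simplified = TRUE),
               "min \\(5\\) exceeds median \\(2\\)")
})

test_that("Hozo's adaptive SD rule follows its three sample-size branches", {
  # n <= 15, symmetric summary: a - 2m + b = 0 so sqrt(1/12)
  expect_equal(sd_c1_hozo(0, 0.5, 1, 10), sqrt(1 / 12))
  expect_equal(sd_c1_hozo(0, 5, 20, 50), 5)    # (b-a)/4 branch
  expect_equal(sd_c1_hozo(0, 5, 30, 100), 5)   # (b-a)/6 branch
  # boundary semantics: n = 15 still the small-sample formula, n = 70
  # still (b-a)/4
  expect_equal(sd_c1_hozo(0, 0.5, 1, 15), sqrt(1 / 12))
  expect_equal(sd_c1_hozo(0, 0.5, 1, 16), 0.25)
  expect_equal(sd_c1_hozo(0, 5, 20, 70), 5)
  expect_equal(sd_c1_hozo(0, 5, 30, 71), 5)
  expect_warning(sd_c1_hozo(-2, 0, 2, 10), "non-negative")
})

test_that("fixed range rules divide by their constants", {
  expect_identical(sd_range_rule(0, 8), 2)
  expect_identical(sd_range_rule(0, 12, 6), 2)
  expect_error(sd_range_rule(0, 1, 0), "positive")
})

test_that("range-based SD estimator scales by xi(n)", {
  expect_identical(sd_c1(3, 3, 25), 0)
  # a range equal to xi(2) = 1.128 estimates SD 1 at n = 2
  expect_equal(sd_c1(0, 1.128, 2, "exact"), 1, tolerance = 1e-3)
  expect_error(sd_c1(0, 1, 1), ">= 2")
  # the closed-form divisor reaches 6 near n = 463
  n_star <- (0.375 + 0.25 * pnorm(3)) / (1 - pnorm(3))
  expect_equal(round(n_star), 463)
  expect_equal(as.numeric(xi_n(463, "approx")), 6, tolerance = 0.01)
})

test_that("C2 mean estimator reproduces hand-evaluated cases", {
  expect_identical(mean_c2_bland(2, 2, 2, 2, 2), 2)
  expect_identical(mean_c2_bland(0, 2.5, 5, 7.5, 10), 5)
  expect_equal(mean_c2_bland(1, 2, 3, 5, 10), 3.875)
  # full form: (Q*(a+2q1+2m+2q3+b) + a + b)/(2n), converging to Eq-10 form
  expect_equal(mean_c2_bland(1, 2, 3, 5, 10, n = 9, full = TRUE),
               (2 * 31 + 11) / 18)
  expect_equal(mean_c2_bland(1, 2, 3, 5, 10, n = 4e6 + 1, full = TRUE),
               3.875, tolerance = 1e-5)
})

test_that("Bland's SD formula matches its hand transcription", {
  expect_identical(sd_c2_bland(4, 4, 4, 4, 4), 0)
  # frozen hand evaluation of the printed formula on a symmetric summary
  expect_equal(sd_c2_bland(0, 2.5, 5, 7.5, 10), 2.795085, tolerance = 1e-6)
  # the radicand is [4*sum(u^2) - (sum u)^2]/64 over adjacent pair sums,
  # nonnegative for any ordered (even degenerate) input
  u <- c(0 + 5, 5 + 5, 5 + 5, 5 + 5)
  expect_equal(sd_c2_bland(0, 5, 5, 5, 5)^2,
               (4 * sum(u^2) - sum(u)^2) / 64)
  expect_error(sd_c2_bland(0, 6, 5, 7, 10), "exceeds")
})

test_that("Bland's SD tracks the true SD only at moderate n", {
  set.seed(11)
  errs <- replicate(400, {
    x <- sort(rnorm(25, 5, 1))
    relative_error(sd_c2_bland(x[1], x[7], x[13], x[19], x[25]), sd(x))
  })
  expect_lt(abs(mean(errs)), 10)
})

test_that("combined SD estimator averages range and IQR components", {
  expect_identical(sd_c2(1, 1, 1, 1, 25), 0)
  # forced arithmetic with tabulated constants at n = 41:
  # 0.5 * (1.5/4.341 + 0.6/1.303) = 0.40301
  expect_equal(sd_c2(0, 0.4, 1.0, 1.5, 41, "exact"), 0.40301,
               tolerance = 5e-4)
  # exact identity: the average of the range-only and IQR-only estimators
  set.seed(3)
  for (i in 1:20) {
    v <- sort(rnorm(4))
    n <- 4 * sample(1:50, 1) + 1
    expect_equal(sd_c2(v[1], v[2], v[3], v[4], n, "exact"),
                 (sd_c1(v[1], v[4], n, "exact") +
                    sd_c3(v[2], v[3], n, "exact")) / 2)
  }
  expect_error(sd_c2(0, 1, 2, 3, 40, "exact"), "4Q \\+ 1")
})

test_that("C3 mean estimator reproduces hand-evaluated cases", {
  expect_identical(mean_c3(7, 7, 7), 7)
  expect_identical(mean_c3(2, 5, 8), 5)
  expect_identical(mean_c3(1, 2, 6), 3)
  expect_error(mean_c3(3, 2, 6), "q1 \\(3\\) exceeds median \\(2\\)")
})

test_that("IQR-based SD estimator scales by eta(n)", {
  expect_identical(sd_c3(2, 2, 9), 0)
  # IQR equal to eta(5) = 0.990 estimates SD 1 at n = 5
  expect_equal(sd_c3(0, 0.990, 5, "exact"), 1, tolerance = 1e-3)
  # and eta(201) = 1.340 at Q = 50
  expect_equal(sd_c3(0, 1.340, 201, "exact"), 1, tolerance = 1e-3)
  expect_error(sd_c3(0, 1, 4), ">= 5")
})

test_that("Cochrane rule divides the IQR by 1.35", {
  expect_identical(sd_c3_cochrane(0, 1.35), 1)
  expect_identical(sd_c3_cochrane(0, 0), 0)
  expect_equal(sd_c3_cochrane(2, 4.7), 2)
})

test_that("IQR estimator converges to the Cochrane rule", {
  # the closed-form eta(n) approaches 2*qnorm(0.75) like ~1.96/n, so the
  # two estimators differ by < 0.2% once n exceeds ~1200 and the ratio
  # tends to 1.35/1.34898
  for (n in c(1201, 5001))
    expect_lt(abs(sd_c3(0, 1, n, "approx") / sd_c3_cochrane(0, 1) - 1),
              0.002)
  expect_equal(sd_c3(0, 1, 4e6 + 1, "approx") / sd_c3_cochrane(0, 1),
               1.35 / 1.34898, tolerance = 1e-5)
  # convergence is monotone from below
  diffs <- vapply(c(101, 401, 1601, 6401), function(n)
    abs(sd_c3(0, 1, n, "approx") / sd_c3_cochrane(0, 1) - 1), numeric(1))
  expect_true(all(diff(diffs) < 0))
})

test_that("all mean estimators return the median on symmetric summaries", {
  set.seed(7)
  for (i in 1:25) {
    m <- rnorm(1, 0, 10)
    s <- abs(rnorm(1)) + 0.1
    d1 <- runif(1, 0.5, 2) * s
    d2 <- runif(1, 0, 0.4) * s
    a <- m - d1; b <- m + d1; q1 <- m - d2; q3 <- m + d2
    expect_equal(mean_c1_hozo(a, m, b, simplified = TRUE), m)
    expect_equal(mean_c1_hozo(a, m, b, n = 17), m)
    expect_equal(mean_c2_bland(a, q1, m, q3, b), m)
    expect_equal(mean_c3(q1, m, q3), m)
  }
})

test_that("estimators are location-scale equivariant", {
  set.seed(8)
  for (i in 1:15) {
    v <- sort(rnorm(5, 10, 4))
    n <- 4 * sample(2:30, 1) + 1
    cc <- runif(1, 0.3, 3)
    d <- rnorm(1, 0, 5)
    w <- cc * v + d
    expect_equal(mean_c1_hozo(w[1], w[3], w[5], simplified = TRUE),
                 cc * mean_c1_hozo(v[1], v[3], v[5], simplified = TRUE) + d)
    expect_equal(mean_c2_bland(w[1], w[2], w[3], w[4], w[5]),
                 cc * mean_c2_bland(v[1], v[2], v[3], v[4], v[5]) + d)
    expect_equal(mean_c3(w[2], w[3], w[4]),
                 cc * mean_c3(v[2], v[3], v[4]) + d)
    for (pair in list(
      c(sd_c1(w[1], w[5], n), sd_c1(v[1], v[5], n)),
      c(sd_c2(w[1], w[2], w[4], w[5], n), sd_c2(v[1], v[2], v[4], v[5], n)),
      c(sd_c3(w[2], w[4], n), sd_c3(v[2], v[4], n)),
      c(sd_c2_bland(w[1], w[2], w[3], w[4], w[5]),
        sd_c2_bland(v[1], v[2], v[3], v[4], v[5])),
      c(suppressWarnings(sd_c1_hozo(w[1], w[3], w[5], n)),
        suppressWarnings(sd_c1_hozo(v[1], v[3], v[5], n))),
      c(sd_range_rule(w[1], w[5]), sd_range_rule(v[1], v[5])),
      c(sd_c3_cochrane(w[2], w[4]), sd_c3_cochrane(v[2], v[4]))))
      expect_equal(pair[1], cc * pair[2])
  }
})

test_that("SD estimates are nonnegative, zero only at zero spread", {
  set.seed(9)
  for (i in 1:10) {
    v <- sort(rnorm(5))
    n <- 4 * sample(2:40, 1) + 1
    ests <- c(sd_c1(v[1], v[5], n), sd_c2(v[1], v[2], v[4], v[5], n),
              sd_c3(v[2], v[4], n), sd_c2_bland(v[1], v[2], v[3], v[4], v[5]),
              sd_c3_cochrane(v[2], v[4]))
    expect_true(all(ests >= 0))
  }
  expect_identical(sd_c2(2, 2, 2, 2, 9), 0)
})

test_that("summary_input detects the reporting scenario", {
  expect_identical(summary_input(41, min = 1, median = 2, max = 3)$scenario,
                   "C1")
  expect_identical(summary_input(41, q1 = 1, median = 2, q3 = 3)$scenario,
                   "C3")
  expect_identical(
    summary_input(41, min = 0, q1 = 1, median = 2, q3 = 3, max = 4)$scenario,
    "C2")
  expect_identical(
    summary_input(41, min = 0, q1 = 1, q3 = 3, max = 4)$scenario,
    "unsupported")
  expect_error(summary_input(41, min = 5, q1 = 1, median = 2, q3 = 3,
                             max = 4), "min \\(5\\) exceeds q1 \\(1\\)")
  expect_error(summary_input(0, median = 1), "integer")
})

test_that("estimate_moments dispatches by scenario and policy", {
  c1 <- estimate_moments(summary_input(41, min = 10, median = 20, max = 70))
  expect_identical(unique(c1$scenario), "C1")
  expect_setequal(c1$method, c("hozo_mean", "range_sd"))
  expect_identical(c1$mean_est[c1$method == "hozo_mean"], 30)

  c3 <- estimate_moments(summary_input(41, q1 = 15, median = 20, q3 = 28))
  expect_identical(unique(c3$scenario), "C3")
  expect_setequal(c3$method, c("quantile_mean", "iqr_sd"))

  full <- summary_input(41, min = 0, q1 = 1, median = 2, q3 = 3, max = 4)
  all_res <- estimate_moments(full, policy = "all")
  expect_gte(sum(!is.na(all_res$mean_est)), 2)
  expect_gte(sum(!is.na(all_res$sd_est)), 3)
  expect_true(all(c("combined_sd", "bland_sd", "cochrane_sd",
                    "range_sd") %in% all_res$method))

  leg <- estimate_moments(full, policy = "legacy")
  expect_setequal(leg$method, c("bland_mean", "bland_sd"))

  expect_error(
    estimate_moments(summary_input(41, min = 0, q1 = 1, q3 = 3, max = 4)),
    "scenario not covered")
})

test_that("mean estimates stay within reported bounds", {
  set.seed(10)
  for (i in 1:20) {
    v <- sort(rnorm(5, 3, 2))
    s <- summary_input(4 * sample(2:30, 1) + 1, min = v[1], q1 = v[2],
                       median = v[3], q3 = v[4], max = v[5])
    # the legacy rule warns on negative minima; irrelevant to the bound check
    res <- suppressWarnings(estimate_moments(s, policy = "all"))
    mu <- res$mean_est[!is.na(res$mean_est)]
    expect_true(all(mu >= v[1] & mu <= v[5]))
  }
})

test_that("exact-mode requests off the 4Q+1 grid fall back gracefully", {
  s <- summary_input(40, min = 0, q1 = 1, median = 2, q3 = 3, max = 4)
  res <- estimate_moments(s, mode = "exact")
  expect_equal(res$sd_est[res$method == "combined_sd"],
               sd_c2(0, 1, 3, 4, 40, mode = "approx"))
})
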