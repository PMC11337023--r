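test_that("yield arithmetic and input policing", {
  expect_equal(compute_ffb_yield(2.72, 2.0), 1.36)
  expect_equal(compute_ffb_yield(0, 5.0), 0)
  expect_equal(compute_ffb_yield(6.1, 1.0), 6.1)   # kept here, filtered later
  expect_error(compute_ffb_yield(1, 0), "positive")
  expect_error(compute_ffb_yield(-1, 2), ">= 0")
  expect_equal(compute_oil_yield(1.36, 18.71), 0.254456)
  expect_equal(compute_oil_yield(5, 0), 0)
  expect_equal(compute_oil_yield(2.0, 25.0), 0.5)
  expect_true(is.na(compute_oil_yield(2.0, NA)))
  expect_error(compute_oil_yield(1, 101), "\\[0, 100\\]")
})

test_that("exclusions are strict, pure and idempotent", {
  rec <- data.frame(estate_id = letters[1:5],
                    ffb_yield = c(6.0, 6.5, 1.2, 2.0, 3.0),
                    oer = c(30.0, 18, 31, NA, 20))
  out <- apply_exclusions(rec)
  expect_equal(out$n_excluded, 2L)            # 6.5 yield, 31 oer
  expect_equal(out$records$estate_id, c("a", "d", "e"))
  expect_equal(out$log$reason, c("ffb_yield > 6", "oer > 30"))
  # boundary values 6.0 / 30.0 retained (strict inequalities)
  expect_true("a" %in% out$records$estate_id)
  # pure: retained rows identical to input rows
  expect_equal(out$records, rec[c(1, 4, 5), ], ignore_attr = TRUE)
  # idempotent
  out2 <- apply_exclusions(out$records)
  expect_equal(out2$n_excluded, 0L)
  expect_equal(out2$records, out$records)
})

test_that("missing-category coding and the fertilizer reference rule", {
  f <- encode_missing_category(c(1.2, NA, 3.4))
  expect_equal(as.character(f), c("1.2", "MISSING", "3.4"))
  expect_setequal(levels(f), c("1.2", "3.4", "MISSING"))
  # non-missing values are recoverable from the labels (round trip)
  v <- as.numeric(as.character(f)[f != "MISSING"])
  expect_equal(v, c(1.2, 3.4))
  expect_warning(fm <- encode_missing_category(c(NA_real_, NA_real_)),
                 "non-identifiable")
  expect_true(attr(fm, "non_identifiable"))
  # fertilizer: {0, missing} merge into the reference level
  ff <- encode_fertilizer(c(0, NA, 500))
  expect_equal(as.character(ff), c("REF", "REF", "Q1"))
  ff4 <- encode_fertilizer(c(0, NA, 10, 20, 30, 40))
  expect_equal(as.character(ff4), c("REF", "REF", "Q1", "Q2", "Q3", "Q4"))
})

test_that("quantile groups follow the fixed convention", {
  g <- quantile_groups(1:12, k = 3)
  expect_equal(as.vector(table(g)), c(4L, 4L, 4L))
  g4 <- quantile_groups(c(1, 2, 3, 4), k = 4)
  expect_equal(as.vector(table(g4)), rep(1L, 4))
  expect_error(quantile_groups(rep(5, 10), k = 3), "distinct")
  gm <- quantile_groups(c(1:8, NA), k = 4)
  expect_equal(as.character(gm[9]), "MISSING")
  # ties go to the lower group: value at an internal cutpoint
  gt <- quantile_groups(c(1, 2, 2, 3), k = 2)   # median 2
  expect_equal(as.integer(gt), c(1L, 1L, 1L, 2L))
})

test_that("rolling 24-month averages and precipitation conversion", {
  s <- tiny_series(rep(7.09, 30))
  expect_equal(rolling_24m_average(s, "2015-01"), 7.09)
  s2 <- tiny_series(c(rep(0, 23), 24))
  expect_equal(rolling_24m_average(s2, "2014-12"), 1.0)
  s3 <- tiny_series(1:24)
  expect_equal(rolling_24m_average(s3, "2014-12"), 12.5)
  expect_error(rolling_24m_average(s3, "2014-11"), "24 months")
  expect_equal(daily_to_monthly_precip(7.09), 212.7)
  expect_equal(daily_to_monthly_precip(0), 0)
  expect_equal(daily_to_monthly_precip(1), 30)
})

test_that("state quadratic fits recover coefficients", {
  x <- seq(-2, 2.5, length.out = 40)
  w <- 1 + 2 * x - 0.5 * x^2
  fit <- fit_state_quadratic(w, x, rep("S01", 40))
  expect_equal(unlist(fit[, c("a", "b", "c")]), c(a = 1, b = 2, c = -0.5),
               tolerance = 1e-9)
  # constant response: (wbar, 0, 0)
  fitc <- fit_state_quadratic(rep(3.3, 40), x, rep("S01", 40))
  expect_equal(unlist(fitc[, c("a", "b", "c")]), c(a = 3.3, b = 0, c = 0),
               tolerance = 1e-9)
  # noisy case agrees with the lm() oracle per state
  set.seed(8)
  st <- rep(c("A", "B"), each = 500)
  xx <- rnorm(1000)
  ww <- ifelse(st == "A", 2 + xx - 0.3 * xx^2, 1 - 0.5 * xx + 0.2 * xx^2) +
    rnorm(1000, 0, 0.4)
  ours <- fit_state_quadratic(ww, xx, st)
  for (s in c("A", "B")) {
    ref <- stats::coef(stats::lm(ww[st == s] ~ xx[st == s] + I(xx[st == s]^2)))
    expect_equal(unlist(ours[ours$state == s, c("a", "b", "c")]),
                 unname(ref), tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_error(fit_state_quadratic(1:2, c(1, 1), c("A", "A")), "distinct")
})

test_that("describe reports mean/sd/min/max and errors on empty input", {
  d <- describe(data.frame(v = c(1, 2, 3), g = c("a", "a", "b")))
  row <- d$numeric[d$numeric$variable == "v", ]
  expect_equal(unlist(row[c("mean", "sd", "min", "max")]),
               c(mean = 2, sd = 1, min = 1, max = 3))
  expect_equal(as.vector(d$counts$g), c(2L, 1L))
  expect_error(describe(data.frame()), "no records")
})

test_that("preprocess_panel recomputes outcomes and filters", {
  p <- generate_panel(sim_config(n_estates = 25, seed = 13))
  p$ffb_mass[1] <- p$harvested_area[1] * 7    # implausible yield
  pp <- preprocess_panel(p)
  expect_gte(pp$n_excluded, 1L)
  expect_true(all(pp$records$ffb_yield <= 6))
  expect_equal(pp$records$oil_yield,
               pp$records$ffb_yield * pp$records$oer / 100, tolerance = 1e-12)
})
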