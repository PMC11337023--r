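test_that("log_knots places knots at equal log-scale steps", {
  # closed form L^(i/(nk+1)), checked by brute-force exponentiation
  expect_equal(log_knots(23, 3), 23^(1:3 / 4), tolerance = 1e-12)
  expect_equal(log_knots(23, 3), c(2.18994, 4.79583, 10.50258), tolerance = 1e-5)
  expect_equal(log_knots(10, 3), 10^(1:3 / 4), tolerance = 1e-12)
  expect_equal(log_knots(4, 1), 2)
  expect_error(log_knots(1, 3), "L must be")
})

test_that("bspline_basis matches hat functions and partition of unity", {
  sp <- basis_spec(degree = 1L, boundary = c(0, 1), intercept = TRUE)
  expect_equal(drop(bspline_basis(0.25, sp)), c(0.75, 0.25))
  # partition of unity for intercept bases of degrees 1-3 with random knots
  set.seed(1)
  for (d in 1:3) {
    kn <- sort(runif(3, 1, 9))
    sp <- basis_spec(d, kn, c(0, 10), intercept = TRUE)
    x <- runif(200, 0, 10)
    expect_equal(rowSums(bspline_basis(x, sp)), rep(1, 200), tolerance = 1e-12)
  }
  # boundary evaluation is defined and still sums to 1
  expect_equal(rowSums(bspline_basis(c(0, 10), sp)), c(1, 1), tolerance = 1e-12)
  expect_error(bspline_basis(10.01, sp), "outside basis boundary")
})

test_that("bspline_basis agrees with the splines::splineDesign oracle", {
  set.seed(2)
  for (case in list(list(d = 3L, kn = c(2.19, 4.80, 10.50), b = c(0, 23)),
                    list(d = 2L, kn = c(1.78, 3.16, 5.62), b = c(0, 10)),
                    list(d = 3L, kn = numeric(0), b = c(-2, 3)))) {
    x <- runif(100, case$b[1], case$b[2])
    full <- c(rep(case$b[1], case$d + 1), case$kn, rep(case$b[2], case$d + 1))
    oracle <- splines::splineDesign(full, x, ord = case$d + 1, outer.ok = TRUE)
    sp_i <- basis_spec(case$d, case$kn, case$b, intercept = TRUE)
    expect_equal(bspline_basis(x, sp_i), oracle, tolerance = 1e-10,
                 ignore_attr = TRUE)
    sp_n <- basis_spec(case$d, case$kn, case$b, intercept = FALSE)
    expect_equal(bspline_basis(x, sp_n), oracle[, -1, drop = FALSE],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("exposure histories index the series correctly", {
  s <- tiny_series(1:40)
  # constant series: all rows constant
  Q <- build_exposure_history(tiny_series(rep(7, 40)), c("2014-06", "2015-02"), 5L)
  expect_true(all(Q == 7))
  expect_equal(dim(Q), c(2L, 6L))
  # last period with L = 2 gives (a0, a-1, a-2)
  Q2 <- build_exposure_history(s, "2016-04", 2L)   # month 40 of the series
  expect_equal(drop(Q2), c(40, 39, 38), ignore_attr = TRUE)
  # observations one month apart share L overlapping values
  Q3 <- build_exposure_history(s, c("2016-03", "2016-04"), 3L)
  expect_equal(Q3[1, 1:3], Q3[2, 2:4], ignore_attr = TRUE)
  # missing history errors with the earliest missing month
  expect_error(build_exposure_history(s, "2013-01", 2L), "2012-11")
})

test_that("cross-basis equals the naive double-loop construction", {
  set.seed(3)
  Q <- matrix(rnorm(50 * 11), 50, 11)
  xs <- basis_spec(3L, stats::quantile(Q, c(.25, .5, .75), names = FALSE),
                   range(Q), intercept = FALSE)
  ls <- basis_spec(3L, log_knots(10, 3), c(0, 10), intercept = TRUE)
  cb <- build_crossbasis(Q, xs, ls)
  expect_equal(cb$W, cb_oracle(Q, xs, ls), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(ncol(cb$W), basis_df(xs) * basis_df(ls))
})

test_that("cross-basis factorizes under constant exposure", {
  # all lags at xbar: row = b(xbar) (x) colSums(C)
  xs <- basis_spec(2L, c(0.5), c(-2, 2), intercept = FALSE)
  ls <- basis_spec(2L, c(2), c(0, 6), intercept = TRUE)
  Q <- matrix(1.3, 15, 7)
  cb <- build_crossbasis(Q, xs, ls)
  bx <- drop(bspline_basis(1.3, xs))
  cl <- colSums(bspline_basis(0:6, ls))
  expect_equal(cb$W[1, ], as.numeric(rep(bx, each = length(cl)) *
                                       rep(cl, times = length(bx))),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("cross-basis is linear in rows and shift invariant", {
  set.seed(4)
  vals <- rnorm(60)
  s <- tiny_series(vals)
  periods <- ensopalm:::format_ym(ensopalm:::parse_ym("2014-01") + 0:20)
  Q <- build_exposure_history(s, periods, 6L)
  xs <- basis_spec(3L, numeric(0), c(-4, 4), intercept = FALSE)
  ls <- basis_spec(3L, log_knots(6, 3), c(0, 6), intercept = TRUE)
  W <- build_crossbasis(Q, xs, ls)$W
  # row concatenation
  W12 <- build_crossbasis(rbind(Q, Q[1:5, ]), xs, ls)$W
  expect_equal(W12, rbind(W, W[1:5, ]), tolerance = 1e-14)
  # shifting calendar labels of both series and periods leaves Q and W alone
  s2 <- tiny_series(vals, start = "2016-01")
  periods2 <- ensopalm:::format_ym(ensopalm:::parse_ym("2017-01") + 0:20)
  Q2 <- build_exposure_history(s2, periods2, 6L)
  expect_equal(unclass(Q2), unclass(Q), ignore_attr = TRUE)
  expect_equal(build_crossbasis(Q2, xs, ls)$W, W, tolerance = 1e-14)
})

test_that("cross-basis CSV export carries a reproducibility sidecar", {
  set.seed(5)
  Q <- matrix(rnorm(60 * 7), 60, 7)
  cb <- build_crossbasis(Q)
  f <- tempfile(fileext = ".csv")
  write_crossbasis_csv(cb, f)
  W2 <- as.matrix(utils::read.csv(f))
  expect_equal(unname(W2), unname(cb$W), tolerance = 1e-9)
  side <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(side$L, 6L)
  expect_equal(side$x0, 0)
  expect_equal(side$l_spec$degree, cb$l_spec$degree)
  unlink(c(f, paste0(f, ".json")))
})

test_that("ENSO CSV round-trips", {
  s <- tiny_series(rnorm(30))
  f <- tempfile(fileext = ".csv")
  write_enso_csv(s, f, index_name = "MEI")
  s2 <- read_enso_csv(f, index = "MEI")
  expect_equal(s2$period, s$period)
  expect_equal(s2$value, s$value, tolerance = 1e-12)
  unlink(f)
})
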