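test_that("significance thresholds follow the group-count rule", {
  expect_equal(significance_threshold(2), 0.05)
  expect_equal(significance_threshold(3), 0.025)
  expect_equal(significance_threshold(5), 0.0125)
  expect_equal(significance_threshold(4), 0.05 / 3)
  expect_error(significance_threshold(1), "n_groups")
})

test_that("z-test arithmetic matches the back-computed printed example", {
  # subgroup contrast with SEs recovered from reported CIs:
  # b1 = -2.01 (-2.25, -1.76), b2 = -2.55 (-2.79, -2.32)
  se1 <- se_from_ci(-2.25, -1.76)
  se2 <- se_from_ci(-2.79, -2.32)
  expect_equal(se1, 0.125, tolerance = 0.001)
  expect_equal(se2, 0.120, tolerance = 0.001)
  zt <- z_test_difference(-2.01, se1, -2.55, se2, n_groups = 4)
  expect_equal(zt$difference, 0.54, tolerance = 1e-12)
  expect_equal(zt$lo, 0.20, tolerance = 0.005)
  expect_equal(zt$hi, 0.88, tolerance = 0.005)
  expect_gt(zt$lo, 0)                          # CI excludes zero
  expect_true(zt$significant)                  # p ~ 0.002 < 0.05/3
})

test_that("z-test is antisymmetric and handles edge cases", {
  zt <- z_test_difference(1.2, 0.3, 0.7, 0.4, 2)
  zr <- z_test_difference(0.7, 0.4, 1.2, 0.3, 2)
  expect_equal(zt$difference, -zr$difference)
  expect_equal(zt$z, -zr$z)
  expect_equal(zt$p, zr$p)
  expect_equal(zt$lo, -zr$hi)
  expect_equal(zt$hi, -zr$lo)
  # equal estimates: difference 0, symmetric CI, not significant
  z0 <- z_test_difference(1.5, 0.2, 1.5, 0.3, 2)
  expect_equal(z0$difference, 0)
  expect_equal(z0$lo, -z0$hi)
  expect_false(z0$significant)
  # z = 1.97: significant at alpha 0.05 but not 0.025
  z1 <- z_test_difference(1.97, 1, 0, 0, 2)
  expect_equal(z1$z, 1.97)
  expect_equal(z1$p, 2 * stats::pnorm(-1.97), tolerance = 1e-12)
  expect_true(z1$significant)
  expect_false(z_test_difference(1.97, 1, 0, 0, 3)$significant)
  # degenerate: both SEs zero with differing estimates
  expect_warning(zd <- z_test_difference(1, 0, 0, 0, 2), "degenerate")
  expect_true(zd$significant)
  expect_true(zd$degenerate)
  expect_error(z_test_difference(1, -0.1, 0, 0.1, 2), ">= 0")
})

test_that("a single-stratum grouping reproduces the pooled fit", {
  p <- generate_panel(sim_config(n_estates = 30, seed = 71))
  enso <- attr(p, "enso")
  fits <- stratified_fit(p, rep("all", nrow(p)), "ffb_yield", enso, 8L,
                         x_boundary = c(-4, 4), min_n = 10)
  pooled <- fit_cells(p, "ffb_yield", enso, 8L,
                      x_spec = fits$all$crossbasis$x_spec,
                      l_spec = fits$all$crossbasis$l_spec)
  expect_equal(fits$all$beta, pooled$beta, tolerance = 1e-9)
  expect_equal(fits$all$aic, pooled$aic, tolerance = 1e-8)
})

test_that("strata partition the sample and small strata are skipped", {
  p <- generate_panel(sim_config(n_estates = 30, seed = 72))
  enso <- attr(p, "enso")
  g <- quantile_groups(p$labor_intensity, k = 3)
  fits <- stratified_fit(p, g, "ffb_yield", enso, 6L,
                         x_boundary = c(-4, 4), min_n = 100)
  expect_equal(sum(vapply(fits, function(f) f$n, numeric(1))), nrow(p))
  expect_named(fits, levels(g))
  # a stratum below min_n is skipped with a warning
  g2 <- factor(c("tiny", as.character(g[-1])), levels = c(levels(g), "tiny"))
  expect_warning(f2 <- stratified_fit(p, g2, "ffb_yield", enso, 6L,
                                      x_boundary = c(-4, 4), min_n = 100),
                 "skipped")
  expect_false("tiny" %in% names(f2))
})

test_that("a strongly amplified stratum shows the larger cumulative effect", {
  # planted effect modification: stratum B has 8x the default curvature;
  # shared ENSO realization, independent estates
  hits <- vapply(1:8, function(s) {
    sA <- surface_params(0.1, 0.2, L_true = 12L)
    sB <- surface_params(0.8, 1.6, L_true = 12L)
    pA <- generate_panel(sim_config(n_estates = 300, seed = 7100 + 2 * s,
                                    surface = sA, enso_seed = 7300 + s))
    pB <- generate_panel(sim_config(n_estates = 300, seed = 7101 + 2 * s,
                                    surface = sB, enso_seed = 7300 + s))
    enso <- attr(pA, "enso")
    both <- rbind(pA, pB)
    g <- rep(c("A", "B"), times = c(nrow(pA), nrow(pB)))
    fits <- stratified_fit(both, g, "ffb_yield", enso, 12L,
                           x_boundary = c(-4, 4), min_n = 100)
    cA <- cumulative_association(fits$A, 2)
    cB <- cumulative_association(fits$B, 2)
    abs(cB$effect) > abs(cA$effect)
  }, logical(1))
  expect_gte(mean(hits), 7 / 8)
})

test_that("compare_subgroups reports each-vs-reference rows", {
  p <- generate_panel(sim_config(n_estates = 45, seed = 73))
  enso <- attr(p, "enso")
  g <- quantile_groups(p$labor_intensity, k = 3)
  fits <- stratified_fit(p, g, "ffb_yield", enso, 6L,
                         x_boundary = c(-4, 4), min_n = 100)
  cmp <- compare_subgroups(fits, x = 2)
  expect_equal(nrow(cmp), 2L)
  expect_equal(cmp$alpha, rep(0.025, 2))       # three strata
  expect_true(all(grepl("vs G1$", cmp$pair)))
  rep_tab <- subgroup_report(fits, x_values = c(-1, 2), grouping = "labor")
  expect_equal(nrow(rep_tab), 3L * 2L)
  expect_true(all(rep_tab$lo <= rep_tab$effect & rep_tab$effect <= rep_tab$hi))
})
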