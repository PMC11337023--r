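# Cumulative and lag-specific exposure-response associations with
# delta-method confidence intervals relative to the zero reference.

cb_block <- function(fit) {
  list(beta = fit$beta[fit$cb_cols],
       V = fit$V[fit$cb_cols, fit$cb_cols, drop = FALSE])
}

#' Cumulative exposure-response curve
#'
#' Effect of exposure `x`, relative to the reference (0), cumulated over lags
#' 0..L: Delta(x) = z(x)' beta_cb with contrast z(x) = sum_l (b(x) - b(0))
#' (x) c(l), SE from the delta method, pointwise 95 % CI = Delta +/- 1.96 SE.
#'
#' @param fit an `enso_fit`.
#' @param x exposure values (inside the exposure-basis boundary; no
#'   extrapolation).
#' @return object of class `association_curve`: data.frame (x, effect, se,
#'   lo, hi) with attributes `L` and `lag_label`.
#' @export
cumulative_association <- function(fit, x) {
  cb <- fit$crossbasis
  blk <- cb_block(fit)
  rows <- lapply(x, function(xx) {
    z <- cb_contrast(cb, xx)
    eff <- sum(z * blk$beta)
    se <- sqrt(max(drop(t(z) %*% blk$V %*% z), 0))
    c(eff, se)
  })
  m <- do.call(rbind, rows)
  out <- data.frame(x = x, effect = m[, 1], se = m[, 2],
                    lo = m[, 1] - 1.96 * m[, 2], hi = m[, 1] + 1.96 * m[, 2])
  structure(out, L = cb$L, lag_label = paste0("0-", cb$L),
            class = c("association_curve", "data.frame"))
}

#' Lag-specific association
#'
#' Effect at a single lag: z = (b(x) - b(0)) (x) c(l).
#'
#' @param fit an `enso_fit`.
#' @param x exposure value.
#' @param l lag (0..L; non-integer values are allowed, the basis being
#'   continuous in lag, and are flagged with a message).
#' @return named numeric: effect, se, lo, hi.
#' @export
lag_association <- function(fit, x, l) {
  blk <- cb_block(fit)
  z <- cb_contrast(fit$crossbasis, x, lag = l)
  eff <- sum(z * blk$beta)
  se <- sqrt(max(drop(t(z) %*% blk$V %*% z), 0))
  c(effect = eff, se = se, lo = eff - 1.96 * se, hi = eff + 1.96 * se)
}

#' Cumulative-association summary table
#'
#' One row per contrast exposure value, formatted "a.bc (lo, hi)" alongside
#' the raw numbers, the per-month equivalent (cumulative / (L + 1)) and the
#' percent of a supplied outcome mean.
#'
#' @param fit an `enso_fit`.
#' @param x_values contrast exposure values (default -1 and +2: moderate cool
#'   phase and strong warm phase).
#' @param index label for the ENSO index column.
#' @param outcome_mean optional mean monthly outcome for the percent column.
#' @export
association_table <- function(fit, x_values = c(-1, 2), index = "MEI",
                              outcome_mean = NULL) {
  cur <- cumulative_association(fit, x_values)
  L <- attr(cur, "L")
  out <- data.frame(index = index, value = cur$x, outcome = fit$outcome,
                    lag_months = attr(cur, "lag_label"),
                    effect = cur$effect, lo = cur$lo, hi = cur$hi,
                    formatted = sprintf("%.2f (%.2f, %.2f)",
                                        cur$effect, cur$lo, cur$hi),
                    monthly_equivalent = monthly_equivalent(cur$effect, L))
  if (!is.null(outcome_mean))
    out$pct_of_mean <- percent_of_mean(cur$effect, outcome_mean, L)
  out
}

#' Per-month equivalent of a cumulative effect
#'
#' A cumulative effect over lags 0..L divides by the L + 1 lag months, e.g.
#' -2.30 t/ha over lags 0-23 is -0.10 t/ha/month.
#'
#' @param cumulative cumulative effect(s).
#' @param L maximum lag of the window.
#' @export
monthly_equivalent <- function(cumulative, L) cumulative / (L + 1)

#' Cumulative effect as a percentage of the outcome mean
#'
#' The per-month equivalent divided by the mean monthly outcome, times 100.
#'
#' @param cumulative cumulative effect(s).
#' @param outcome_mean mean monthly outcome (same units as the monthly
#'   effect).
#' @param L maximum lag of the window.
#' @export
percent_of_mean <- function(cumulative, outcome_mean, L) {
  100 * abs(monthly_equivalent(cumulative, L)) / outcome_mean
}

#' Exposure-lag effect surface for contour plots
#'
#' Dense matrix of lag-specific effects over an exposure grid and a lag grid,
#' relative to the zero reference. Summing the surface over integer lags
#' 0..L reproduces the cumulative curve exactly (linearity of contrasts).
#'
#' @param fit an `enso_fit`.
#' @param x_grid exposure grid (default 60 points over the basis boundary).
#' @param l_grid lag grid (default integer lags 0..L).
#' @return object of class `lag_surface`: list with `x`, `l`, `effect`
#'   (length(x) x length(l) matrix) and `se` (same shape).
#' @export
contour_matrix <- function(fit, x_grid = NULL, l_grid = NULL) {
  cb <- fit$crossbasis
  if (is.null(x_grid))
    x_grid <- seq(cb$x_spec$boundary[1], cb$x_spec$boundary[2], length.out = 60)
  if (is.null(l_grid)) l_grid <- 0:cb$L
  blk <- cb_block(fit)
  eff <- se <- matrix(NA_real_, length(x_grid), length(l_grid))
  Cl <- bspline_basis(l_grid, cb$l_spec)
  b0 <- bspline_basis(cb$x0, cb$x_spec)
  for (i in seq_along(x_grid)) {
    bxd <- drop(bspline_basis(x_grid[i], cb$x_spec) - b0)
    for (k in seq_along(l_grid)) {
      z <- rep(bxd, each = cb$df_l) * rep(Cl[k, ], times = cb$df_x)
      eff[i, k] <- sum(z * blk$beta)
      se[i, k] <- sqrt(max(drop(t(z) %*% blk$V %*% z), 0))
    }
  }
  structure(list(x = x_grid, l = l_grid, effect = eff, se = se),
            class = "lag_surface")
}

#' Write an association curve to CSV
#' @param curve an `association_curve`.
#' @param path output path.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Write a lag surface to long-format CSV (x, l, effect, se)
#' @param surface a `lag_surface`.
#' @param path output path.
#' @export
write_surface_csv <- function(surface, path) {
  long <- expand.grid(x = surface$x, l = surface$l)
  long$effect <- as.vector(surface$effect)
  long$se <- as.vector(surface$se)
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
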