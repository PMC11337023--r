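# Stratified refits by effect modifiers and two-sample z-test comparisons of
# cumulative associations, with group-count-dependent significance
# thresholds.

#' Significance threshold for subgroup comparisons
#'
#' 0.05 for two subgroups, 0.025 for three and 0.0125 for five; other group
#' counts follow the same 0.05 / (n_groups - 1) rule (so four groups use
#' 0.05 / 3).
#'
#' @param n_groups number of subgroups compared (>= 2).
#' @export
significance_threshold <- function(n_groups) {
  if (!is.numeric(n_groups) || length(n_groups) != 1L || n_groups < 2)
    stop("n_groups must be >= 2")
  0.05 / (n_groups - 1)
}

#' Two-sample z-test for a difference in cumulative associations
#'
#' Tests beta1 - beta2 with SE sqrt(SE1^2 + SE2^2); the 95 % CI of the
#' difference is (beta1 - beta2) +/- 1.96 sqrt(SE1^2 + SE2^2), and
#' significance uses the group-count-dependent alpha from
#' [significance_threshold()].
#'
#' @param b1,se1 estimate and SE in the first subgroup.
#' @param b2,se2 estimate and SE in the second subgroup.
#' @param n_groups number of subgroups in the comparison family.
#' @return list: `difference`, `se`, `lo`, `hi`, `z`, `p`, `alpha`,
#'   `significant`, `degenerate` (TRUE when both SEs are zero).
#' @export
z_test_difference <- function(b1, se1, b2, se2, n_groups = 2L) {
  if (se1 < 0 || se2 < 0) stop("standard errors must be >= 0")
  alpha <- significance_threshold(n_groups)
  diff <- b1 - b2
  se <- sqrt(se1^2 + se2^2)
  degenerate <- se == 0
  if (degenerate) {
    if (diff != 0)
      warning("zero SEs with a nonzero difference: degenerate comparison")
    z <- if (diff == 0) 0 else Inf * sign(diff)
    p <- if (diff == 0) 1 else 0
  } else {
    z <- diff / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(difference = diff, se = se,
       lo = diff - 1.96 * se, hi = diff + 1.96 * se,
       z = z, p = p, alpha = alpha,
       significant = p < alpha, degenerate = degenerate)
}

#' Back-compute a standard error from a reported 95 % CI
#' @param lo,hi confidence limits.
#' @export
se_from_ci <- function(lo, hi) (hi - lo) / (2 * 1.96)

#' Stratified cross-basis fits
#'
#' Refits the outcome model independently within each level of a grouping
#' factor; all strata share the exposure grid, basis specifications and the
#' zero reference, so their cumulative associations are directly comparable.
#' Underpopulated strata are skipped with a warning.
#'
#' @param records panel data.frame.
#' @param group factor (or vector coercible to one) aligned with `records`.
#' @param outcome outcome column name.
#' @param series ENSO series (`period`, `value`).
#' @param L maximum lag.
#' @param x_boundary explicit exposure-basis boundary shared by all strata
#'   (default: the pooled exposure range).
#' @param covariates optional covariate matrix aligned with `records`
#'   (pooled covariate selection is reused across strata).
#' @param min_n minimum stratum size (default 500).
#' @return named list of `enso_fit` objects, one per retained level.
#' @export
stratified_fit <- function(records, group, outcome, series, L,
                           x_boundary = NULL, covariates = NULL, min_n = 500L) {
  group <- as.factor(group)
  if (length(group) != nrow(records)) stop("group length must match records")
  # shared basis specifications from the pooled exposures so all strata use
  # the same surface parameterization and reference
  Qm <- build_exposure_history(series, unique(records$period), L)
  bnd <- x_boundary %||% range(Qm)
  sp <- default_cb_specs(Qm, L, x_boundary = bnd)
  fits <- list()
  for (lev in levels(group)) {
    sel <- which(group == lev)
    if (length(sel) < min_n) {
      warning("stratum '", lev, "' has n = ", length(sel), " < ", min_n,
              "; skipped")
      next
    }
    rs <- records[sel, , drop = FALSE]
    if (is.null(covariates)) {
      fits[[lev]] <- fit_cells(rs, outcome, series, L,
                               x_spec = sp$x_spec, l_spec = sp$l_spec)
    } else {
      Q <- build_exposure_history(series, rs$period, L)
      cb <- build_crossbasis(Q, sp$x_spec, sp$l_spec)
      fits[[lev]] <- fit_fixed(rs, outcome, cb,
                               as.matrix(covariates)[sel, , drop = FALSE])
    }
  }
  fits
}

#' Compare subgroup cumulative associations at a contrast value
#'
#' Each non-reference stratum is compared with the reference stratum (the
#' first level by default) using [z_test_difference()] at the alpha implied
#' by the number of strata.
#'
#' @param fits named list of stratified `enso_fit`s (from [stratified_fit()]).
#' @param x contrast exposure value (e.g. -1 or 2).
#' @param reference name of the reference stratum (default: first).
#' @return data.frame: pair, estimates, difference, CI, alpha, significant.
#' @export
compare_subgroups <- function(fits, x, reference = names(fits)[1]) {
  if (length(fits) < 2L) stop("need at least two strata to compare")
  if (!reference %in% names(fits)) stop("unknown reference stratum: ", reference)
  est <- lapply(fits, function(f) cumulative_association(f, x))
  ng <- length(fits)
  ref <- est[[reference]]
  rows <- lapply(setdiff(names(fits), reference), function(lev) {
    zt <- z_test_difference(est[[lev]]$effect, est[[lev]]$se,
                            ref$effect, ref$se, n_groups = ng)
    data.frame(pair = paste(lev, "vs", reference), x = x,
               effect_1 = est[[lev]]$effect, se_1 = est[[lev]]$se,
               effect_ref = ref$effect, se_ref = ref$se,
               difference = zt$difference, lo = zt$lo, hi = zt$hi,
               z = zt$z, p = zt$p, alpha = zt$alpha,
               significant = zt$significant)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Subgroup association report
#'
#' Cumulative effects with CIs per stratum at the contrast values, plus the
#' stratum sizes, in the long format used for forest-style displays.
#'
#' @param fits named list of stratified `enso_fit`s.
#' @param x_values contrast exposure values.
#' @param grouping label for the grouping variable.
#' @export
subgroup_report <- function(fits, x_values = c(-1, 2), grouping = "group") {
  rows <- lapply(names(fits), function(lev) {
    cur <- cumulative_association(fits[[lev]], x_values)
    data.frame(grouping = grouping, level = lev, x = cur$x,
               effect = cur$effect, lo = cur$lo, hi = cur$hi,
               n = fits[[lev]]$n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
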