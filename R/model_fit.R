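# Outcome models: cross-basis + selected covariates + calendar-month and
# state fixed effects, fitted by least squares; AIC-based lag-window
# selection; random-intercept robustness fit.
#
# The additive model is fully parametric: all nonlinearity lives in the
# cross-basis, which keeps the Gaussian AIC exact and the delta-method
# contrast covariance closed-form.

#' Build the fixed-effects design matrix
#'
#' Columns: intercept, the cross-basis block, optional covariate columns,
#' calendar-month dummies (12 levels, reference dropped) and state dummies
#' (reference dropped). Month effects are calendar-month seasonality dummies,
#' not period dummies, which would be collinear with the month-indexed
#' exposure.
#'
#' @param records panel data.frame with `period` and `state`.
#' @param cb a `crossbasis` whose rows align with `records`.
#' @param covariates optional numeric matrix of extra columns (already
#'   aligned with `records`).
#' @param month_ref,state_ref reference levels to drop (defaults: first).
#' @return list: `X`, `cb_cols` (column index range of the cross-basis),
#'   `y_names` = colnames.
#' @keywords internal
build_design <- function(records, cb, covariates = NULL,
                         month_ref = 1L, state_ref = NULL) {
  n <- nrow(records)
  if (nrow(cb$W) != n) stop("cross-basis rows do not match records")
  mon <- month_of(parse_ym(records$period))
  mlev <- setdiff(1:12, month_ref)
  M <- vapply(mlev, function(m) as.numeric(mon == m), numeric(n))
  colnames(M) <- paste0("month", mlev)
  st <- factor(records$state)
  state_ref <- state_ref %||% levels(st)[1]
  slev <- setdiff(levels(st), state_ref)
  S <- vapply(slev, function(s) as.numeric(st == s), numeric(n))
  colnames(S) <- paste0("state", slev)
  Xparts <- list(`(Intercept)` = rep(1, n), cb$W)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    Xparts <- c(Xparts, list(covariates))
  }
  Xparts <- c(Xparts, list(M, S))
  X <- do.call(cbind, Xparts)
  cb_cols <- 1L + seq_len(ncol(cb$W))
  list(X = X, cb_cols = cb_cols)
}

#' Fit the fixed-effects outcome model
#'
#' Ordinary least squares of the outcome on the cross-basis, covariates and
#' month/state fixed effects. The coefficient covariance is the model-based
#' V = sigma^2 (X'X)^-1 with sigma^2 = RSS / (n - p), and the AIC is the
#' Gaussian maximum-likelihood criterion
#' n log(RSS/n) + 2 (p + 1) + n (1 + log 2 pi).
#'
#' @param records panel data.frame.
#' @param outcome name of the outcome column (rows with missing outcome are
#'   dropped, together with their cross-basis rows).
#' @param cb a `crossbasis` aligned with `records`.
#' @param covariates optional covariate matrix aligned with `records`.
#' @param month_ref,state_ref reference levels for the fixed-effect blocks.
#' @return object of class `enso_fit`: coefficients `beta`, covariance `V`,
#'   `sigma2`, `aic`, `rss`, `n`, `p`, `cb_cols`, and the `crossbasis` used.
#' @export
fit_fixed <- function(records, outcome, cb, covariates = NULL,
                      month_ref = 1L, state_ref = NULL) {
  y <- records[[outcome]]
  if (is.null(y)) stop("outcome column not found: ", outcome)
  keep <- !is.na(y)
  if (!all(keep)) {
    records <- records[keep, , drop = FALSE]
    cb$W <- cb$W[keep, , drop = FALSE]
    if (!is.null(covariates)) covariates <- as.matrix(covariates)[keep, , drop = FALSE]
    y <- y[keep]
  }
  d <- build_design(records, cb, covariates, month_ref, state_ref)
  X <- d$X
  n <- nrow(X); p <- ncol(X)
  zero <- which(colSums(abs(X)) == 0)
  if (length(zero))
    stop("all-zero design columns: ", paste(colnames(X)[zero], collapse = ", "))
  XtX <- crossprod(X)
  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch)) {
    qx <- qr(X)
    aliased <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, p)]]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  Xty <- crossprod(X, y)
  beta <- drop(backsolve(ch, forwardsolve(t(ch), Xty)))
  names(beta) <- colnames(X)
  res <- y - drop(X %*% beta)
  rss <- sum(res^2)
  sigma2 <- rss / (n - p)
  V <- sigma2 * chol2inv(ch)
  dimnames(V) <- list(colnames(X), colnames(X))
  aic <- n * log(rss / n) + 2 * (p + 1) + n * (1 + log(2 * pi))
  structure(list(beta = beta, V = V, sigma2 = sigma2, aic = aic, rss = rss,
                 n = n, p = p, cb_cols = d$cb_cols, crossbasis = cb,
                 outcome = outcome, random_intercept = FALSE),
            class = "enso_fit")
}

#' Fit the fixed-effects model on period-by-state cells
#'
#' Exact sufficient-statistics version of [fit_fixed()] for models without
#' estate-level covariates: every regressor (cross-basis, month and state
#' dummies) is constant within a period-by-state cell, so ordinary least
#' squares on the full panel is reproduced exactly - identical coefficients,
#' covariance, residual variance and AIC - by a weighted fit on cell means
#' with the within-cell sum of squares added back into the RSS. This makes
#' fits on very large simulated panels cheap.
#'
#' @param records panel data.frame.
#' @param outcome outcome column name.
#' @param series ENSO series (`period`, `value`).
#' @param L maximum lag.
#' @param x_spec,l_spec optional explicit [basis_spec()]s; defaults from
#'   [default_cb_specs()] on the cell-level exposure histories.
#' @param x_boundary optional explicit exposure boundary for the default
#'   specs.
#' @param month_ref,state_ref reference levels for the fixed-effect blocks.
#' @return an `enso_fit`, as from [fit_fixed()] (its `crossbasis` holds one
#'   row per cell).
#' @export
fit_cells <- function(records, outcome, series, L,
                      x_spec = NULL, l_spec = NULL, x_boundary = NULL,
                      month_ref = 1L, state_ref = NULL) {
  y <- records[[outcome]]
  if (is.null(y)) stop("outcome column not found: ", outcome)
  keep <- !is.na(y)
  records <- records[keep, , drop = FALSE]
  y <- y[keep]
  upd <- unique(records$period)
  per <- parse_ym(upd)[match(records$period, upd)]
  stu <- sort(unique(records$state))
  code <- (per - min(per)) * length(stu) + match(records$state, stu)
  ucode <- sort(unique(code))
  cell <- match(code, ucode)
  w <- tabulate(cell, nbins = length(ucode))
  ybar <- drop(rowsum(y, cell)) / w
  ss_within <- sum(y^2) - sum(w * ybar^2)
  cells <- data.frame(
    period = format_ym(min(per) + (ucode - 1L) %/% length(stu)),
    state = stu[(ucode - 1L) %% length(stu) + 1L])
  Q <- build_exposure_history(series, cells$period, L)
  if (is.null(x_spec) || is.null(l_spec)) {
    sp <- default_cb_specs(Q, L, x_boundary = x_boundary)
    x_spec <- x_spec %||% sp$x_spec
    l_spec <- l_spec %||% sp$l_spec
  }
  cb <- build_crossbasis(Q, x_spec, l_spec)
  d <- build_design(cells, cb, NULL, month_ref, state_ref)
  X <- d$X
  n <- sum(w); p <- ncol(X)
  sw <- sqrt(w)
  XtWX <- crossprod(X * sw)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) {
    qx <- qr(X * sw)
    aliased <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, p)]]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  XtWy <- crossprod(X, w * ybar)
  beta <- drop(backsolve(ch, forwardsolve(t(ch), XtWy)))
  names(beta) <- colnames(X)
  rss <- ss_within + sum(w * (ybar - drop(X %*% beta))^2)
  sigma2 <- rss / (n - p)
  V <- sigma2 * chol2inv(ch)
  dimnames(V) <- list(colnames(X), colnames(X))
  aic <- n * log(rss / n) + 2 * (p + 1) + n * (1 + log(2 * pi))
  structure(list(beta = beta, V = V, sigma2 = sigma2, aic = aic, rss = rss,
                 n = n, p = p, cb_cols = d$cb_cols, crossbasis = cb,
                 outcome = outcome, random_intercept = FALSE),
            class = "enso_fit")
}

#' AIC selection of the maximum lag
#'
#' Refits the model for each candidate lag window and returns the candidate
#' with the smallest Gaussian AIC; ties (within `tie_tol`) are broken toward
#' the smallest L for parsimony.
#'
#' @param records panel data.frame.
#' @param outcome outcome column name.
#' @param series ENSO series (`period`, `value`).
#' @param candidates integer vector of candidate maximum lags.
#' @param x_boundary optional explicit exposure-basis boundary passed to
#'   [default_cb_specs()].
#' @param covariates optional covariate matrix aligned with `records`.
#' @param tie_tol AIC differences below this count as ties (default 1e-8).
#' @return list: `L` (selected), `aic_table` (candidate, aic), `fits`
#'   (the fit for the selected candidate).
#' @export
select_max_lag <- function(records, outcome, series, candidates,
                           x_boundary = NULL, covariates = NULL,
                           tie_tol = 1e-8) {
  if (!length(candidates)) stop("need at least one candidate lag")
  candidates <- sort(as.integer(candidates))
  fits <- lapply(candidates, function(L) {
    if (is.null(covariates))        # exact collapsed fit, same AIC
      return(fit_cells(records, outcome, series, L, x_boundary = x_boundary))
    Q <- build_exposure_history(series, records$period, L)
    sp <- default_cb_specs(Q, L, x_boundary = x_boundary)
    cb <- build_crossbasis(Q, sp$x_spec, sp$l_spec)
    fit_fixed(records, outcome, cb, covariates)
  })
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  best <- which(aics <= min(aics) + tie_tol)[1L]   # smallest L wins ties
  list(L = candidates[best],
       aic_table = data.frame(L = candidates, aic = aics),
       fit = fits[[best]])
}

#' Random-intercept robustness fit
#'
#' Gaussian linear mixed model with an estate random intercept, the
#' penalized-quasi-likelihood analogue for an identity-link Gaussian outcome.
#' Estimation delegates to `lme4::lmer` (REML); the returned object carries
#' the same contrast machinery as the fixed-effects fit.
#'
#' @inheritParams fit_fixed
#' @return an `enso_fit` with `sigma2_b` (random-intercept variance) set and
#'   `random_intercept = TRUE`.
#' @export
fit_random_intercept <- function(records, outcome, cb, covariates = NULL,
                                 month_ref = 1L, state_ref = NULL) {
  y <- records[[outcome]]
  keep <- !is.na(y)
  if (!all(keep)) {
    records <- records[keep, , drop = FALSE]
    cb$W <- cb$W[keep, , drop = FALSE]
    if (!is.null(covariates)) covariates <- as.matrix(covariates)[keep, , drop = FALSE]
    y <- y[keep]
  }
  tab <- table(records$estate_id)
  if (sum(tab >= 2L) < 2L)
    stop("need at least 2 estates with at least 2 observations each")
  d <- build_design(records, cb, covariates, month_ref, state_ref)
  eng <- lmm_ranint(y, d$X, factor(records$estate_id))
  structure(c(eng,
              list(cb_cols = d$cb_cols, crossbasis = cb, outcome = outcome,
                   random_intercept = TRUE)),
            class = "enso_fit")
}

# Gaussian random-intercept engine (REML via lme4). For an identity-link
# Gaussian outcome the penalized-quasi-likelihood scheme coincides with the
# linear mixed model, so estimation is delegated to a mature LMM solver; on
# balanced one-way data the REML variance components equal the ANOVA
# method-of-moments estimators, which the tests use as an oracle.
lmm_ranint <- function(y, X, g) {
  env <- new.env()
  env$y <- y; env$X <- X; env$g <- g
  ctrl <- lme4::lmerControl(calc.derivs = FALSE)
  fm <- stats::as.formula("y ~ 0 + X + (1 | g)", env = env)
  fit <- lme4::lmer(fm, REML = TRUE, control = ctrl)
  conv <- fit@optinfo$conv$opt
  if (!is.null(conv) && conv != 0)
    stop("random-intercept fit did not converge (optimizer code ", conv, ")")
  beta <- lme4::fixef(fit)
  names(beta) <- colnames(X)
  V <- as.matrix(stats::vcov(fit))
  dimnames(V) <- list(colnames(X), colnames(X))
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(beta = beta, V = V,
       sigma2 = vc$vcov[vc$grp == "Residual"],
       sigma2_b = vc$vcov[vc$grp == "g"],
       aic = stats::AIC(fit), rss = NA_real_,
       n = nrow(X), p = ncol(X))
}

#' @export
print.enso_fit <- function(x, ...) {
  cat(if (x$random_intercept) "Random-intercept" else "Fixed-effects",
      "DLNM fit:", x$outcome, "\n")
  cat("  n =", x$n, " p =", x$p, " AIC =", format(x$aic, digits = 8), "\n")
  cat("  cross-basis columns:", length(x$cb_cols),
      "(L =", x$crossbasis$L, ")\n")
  if (x$random_intercept)
    cat("  sigma2_b =", format(x$sigma2_b, digits = 4),
        " sigma2 =", format(x$sigma2, digits = 4), "\n")
  invisible(x)
}

#' Serialize a fit to a JSON + CSV bundle
#' @param fit an `enso_fit`.
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @export
write_fit_bundle <- function(fit, dir, stem = fit$outcome) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(term = names(fit$beta), estimate = unname(fit$beta)),
                   file.path(dir, paste0(stem, "_coef.csv")), row.names = FALSE)
  utils::write.csv(as.data.frame(fit$V),
                   file.path(dir, paste0(stem, "_vcov.csv")), row.names = FALSE)
  jsonlite::write_json(
    list(outcome = fit$outcome, n = fit$n, p = fit$p, aic = fit$aic,
         sigma2 = fit$sigma2, random_intercept = fit$random_intercept,
         L = fit$crossbasis$L),
    file.path(dir, paste0(stem, "_fit.json")), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
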