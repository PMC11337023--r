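# LASSO screening of candidate covariates.
#
# Objective: (1/2n) ||y - b0 - X b||^2 + lambda ||b||_1 with an unpenalized
# intercept and standardized columns, solved by cyclic coordinate descent on
# the Gram matrix (p is small, so Gram updates are cheap). The exposure
# cross-basis is never screened: selection applies to candidate confounders
# only, and month/state fixed effects are always retained downstream.

#' Build the standardized candidate-covariate matrix
#'
#' Continuous candidates are standardized to mean 0, SD 1; categorical
#' candidates (fertilizer investment category, soil-quality quartile with a
#' missing level, lockdown) are expanded to indicator columns, which are then
#' standardized too. Constant columns are dropped with a warning.
#'
#' @param records panel data.frame.
#' @return standardized matrix with attribute `meta` (data.frame: column,
#'   source variable, level).
#' @export
build_covariate_matrix <- function(records) {
  cont <- c("labor_intensity", "age_profile", "covid_cases",
            "price_cpo", "price_rock", "price_dap", "price_tsp",
            "price_urea", "price_mop", "cpi", "exchange_rate")
  cont <- intersect(cont, names(records))
  cols <- list(); meta <- list()
  for (v in cont) {
    cols[[v]] <- records[[v]]
    meta[[v]] <- data.frame(column = v, source = v, level = NA_character_)
  }
  add_dummies <- function(f, source) {
    lev <- levels(f)
    for (l in lev[-1L]) {                     # first level is the reference
      cn <- paste0(source, ".", l)
      cols[[cn]] <<- as.numeric(f == l)
      meta[[cn]] <<- data.frame(column = cn, source = source, level = l)
    }
  }
  if ("fertilizer_cost" %in% names(records))
    add_dummies(encode_fertilizer(records$fertilizer_cost), "fertilizer")
  if ("soil_score" %in% names(records))
    add_dummies(quantile_groups(records$soil_score, k = 4L), "soil")
  if ("lockdown" %in% names(records)) {
    cols[["lockdown"]] <- as.numeric(records$lockdown)
    meta[["lockdown"]] <- data.frame(column = "lockdown", source = "lockdown",
                                     level = "TRUE")
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X <- standardize_columns(X)
  attr(X, "meta") <- do.call(rbind, meta[colnames(X)])
  X
}

standardize_columns <- function(X) {
  mu <- colMeans(X)
  # population (1/n) scaling so t(x) x / n = 1, the soft-threshold convention
  sdv <- sqrt(colMeans(sweep(X, 2, mu)^2))
  keep <- sdv > 0
  if (!all(keep)) {
    warning("dropping constant columns: ", paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]; mu <- mu[keep]; sdv <- sdv[keep]
  }
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  attr(Xs, "center") <- mu
  attr(Xs, "scale") <- sdv
  Xs
}

#' Smallest penalty that zeroes every coefficient
#' @param X standardized covariate matrix.
#' @param y outcome vector.
#' @export
lambda_max <- function(X, y) {
  max(abs(crossprod(X, y - mean(y))) / nrow(X))
}

#' LASSO fit at a fixed penalty
#'
#' Cyclic coordinate descent for the Gaussian LASSO with unpenalized
#' intercept. Columns must be standardized (mean 0, 1/n-SD 1).
#'
#' @param X standardized covariate matrix (no missing entries).
#' @param y outcome vector.
#' @param lambda penalty, >= 0.
#' @param tol convergence tolerance on the max coefficient change.
#' @param max_iter iteration cap; exceeding it is an error.
#' @param beta_init optional warm start.
#' @return list: `beta0` (intercept), `beta` (named coefficients on the
#'   standardized scale), `lambda`, `n_iter`.
#' @export
lasso_fit <- function(X, y, lambda, tol = 1e-8, max_iter = 10000L,
                      beta_init = NULL) {
  if (inherits(X, "crossbasis"))
    stop("the exposure cross-basis must not enter covariate screening")
  if (lambda < 0) stop("lambda must be >= 0")
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) != nrow(X)")
  mu <- colMeans(X)
  if (max(abs(mu)) > 1e-6 || max(abs(colMeans(X^2) - 1)) > 1e-6)
    stop("X must be standardized (use build_covariate_matrix/standardize_columns)")
  yc <- y - mean(y)
  G <- crossprod(X) / n                       # p x p, diag = 1
  cvec <- drop(crossprod(X, yc)) / n
  beta <- beta_init %||% numeric(p)
  st <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  sc <- max(stats::sd(y), .Machine$double.eps)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      zj <- cvec[j] - sum(G[j, ] * beta) + beta[j]
      bj <- st(zj, lambda)
      delta <- max(delta, abs(bj - beta[j]))
      beta[j] <- bj
    }
    if (delta < tol * sc) break
    if (it == max_iter)
      stop("coordinate descent did not converge in ", max_iter,
           " iterations (last max change ", signif(delta, 3), ")")
  }
  names(beta) <- colnames(X)
  list(beta0 = mean(y), beta = beta, lambda = lambda, n_iter = it)
}

#' Cross-validated LASSO selection
#'
#' K-fold cross-validation over a log-spaced penalty grid from `lambda_max`
#' down to 1e-4 of it; the penalty minimizing mean CV squared error is
#' refitted on the full data, and covariates with nonzero coefficients form
#' the selected set.
#'
#' @param X standardized covariate matrix.
#' @param y outcome vector.
#' @param k_folds number of folds (default 10).
#' @param lambda_grid optional explicit penalty grid (decreasing).
#' @param n_lambda grid size when `lambda_grid` is NULL.
#' @param seed integer seed controlling the fold assignment.
#' @return object of class `selection_result`: `lambda_min`, `cv_curve`
#'   (lambda, mean CV error, SE), `selected` (column names), `beta`
#'   (coefficients at `lambda_min`), `seed`.
#' @export
cv_select <- function(X, y, k_folds = 10L, lambda_grid = NULL,
                      n_lambda = 100L, seed = 1L) {
  if (inherits(X, "crossbasis"))
    stop("the exposure cross-basis must not enter covariate screening")
  n <- nrow(X)
  if (n < k_folds) stop("need n >= k_folds")
  if (is.null(lambda_grid)) {
    lmax <- lambda_max(X, y)
    lambda_grid <- exp(seq(log(lmax), log(1e-4 * lmax), length.out = n_lambda))
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k_folds), n))
  errs <- matrix(NA_real_, length(lambda_grid), k_folds)
  for (f in seq_len(k_folds)) {
    tr <- fold != f
    if (stats::sd(y[tr]) == 0 || stats::sd(y[!tr]) == 0)
      warning("fold ", f, ": outcome constant within a fold")
    Xt <- standardize_columns(X[tr, , drop = FALSE])
    ctr <- attr(Xt, "center"); sct <- attr(Xt, "scale")
    Xv <- sweep(sweep(X[!tr, colnames(Xt), drop = FALSE], 2, ctr), 2, sct, "/")
    b <- NULL
    for (i in seq_along(lambda_grid)) {
      fit <- lasso_fit(Xt, y[tr], lambda_grid[i], beta_init = b)
      b <- fit$beta
      pred <- fit$beta0 + drop(Xv %*% fit$beta)
      errs[i, f] <- mean((y[!tr] - pred)^2)
    }
  }
  cv_mean <- rowMeans(errs)
  cv_se <- apply(errs, 1, stats::sd) / sqrt(k_folds)
  i_min <- which.min(cv_mean)
  lambda_min <- lambda_grid[i_min]
  # warm-started path on the full data down to lambda_min
  b <- NULL
  for (i in seq_len(i_min)) {
    fit <- lasso_fit(X, y, lambda_grid[i], beta_init = b)
    b <- fit$beta
  }
  selected <- names(b)[abs(b) > 1e-10]
  structure(list(lambda_min = lambda_min,
                 cv_curve = data.frame(lambda = lambda_grid, cv_error = cv_mean,
                                       cv_se = cv_se),
                 selected = selected, beta = b, beta0 = fit$beta0, seed = seed),
            class = "selection_result")
}

#' Write a selection report CSV
#' @param sel a `selection_result`.
#' @param X the covariate matrix it was computed on (for metadata).
#' @param path output CSV path.
#' @export
write_selection_csv <- function(sel, X, path) {
  meta <- attr(X, "meta")
  out <- data.frame(column = names(sel$beta),
                    coefficient = unname(sel$beta),
                    selected = names(sel$beta) %in% sel$selected)
  if (!is.null(meta)) out <- merge(meta, out, by = "column", sort = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
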