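# Shared fixtures and independent oracles, built in code at test time.

# gap-free monthly series from a numeric vector
tiny_series <- function(values, start = "2013-01") {
  ym <- ensopalm:::parse_ym(start) + seq_along(values) - 1L
  data.frame(period = ensopalm:::format_ym(ym), value = values)
}

# naive double-loop cross-basis: the brute-force oracle for build_crossbasis
cb_oracle <- function(Q, x_spec, l_spec) {
  L <- ncol(Q) - 1L
  n <- nrow(Q)
  Cl <- bspline_basis(0:L, l_spec)
  dfx <- basis_df(x_spec)
  dfl <- ncol(Cl)
  W <- matrix(0, n, dfx * dfl)
  for (i in seq_len(n)) {
    for (l in 0:L) {
      bx <- drop(bspline_basis(Q[i, l + 1L], x_spec))
      for (j in seq_len(dfx)) {
        for (k in seq_len(dfl)) {
          W[i, (j - 1L) * dfl + k] <- W[i, (j - 1L) * dfl + k] + bx[j] * Cl[l + 1L, k]
        }
      }
    }
  }
  W
}

# small panel + crossbasis + fixed fit, shared by association/model tests
quick_fit <- function(n_estates = 80, seed = 42, L = 12L, outcome = "ffb_yield",
                      x_boundary = c(-4, 4)) {
  p <- generate_panel(sim_config(n_estates = n_estates, seed = seed))
  enso <- attr(p, "enso")
  Q <- build_exposure_history(enso, p$period, L)
  sp <- default_cb_specs(Q, L, x_boundary = x_boundary)
  cb <- build_crossbasis(Q, sp$x_spec, sp$l_spec)
  list(panel = p, enso = enso, Q = Q, cb = cb,
       fit = fit_fixed(p, outcome, cb))
}

# covariate-free simulation world: the exposure-recovery criteria fit the
# model without covariates, so the world they generate carries no covariate
# effects (adjustment is covariate_select's job, tested separately)
zero_betas <- list(labor = 0, fertilizer = 0, soil = 0, age = 0)

# fit with the spec-default exposure boundary (observed range), minimally
# expanded so the contrast points and the evaluation grid (-1.5..2) are
# always evaluable
acc_fit <- function(p, L) {
  enso <- attr(p, "enso")
  Qm <- build_exposure_history(enso, unique(p$period), L)
  bnd <- c(min(min(Qm), -1.6) - 0.01, max(max(Qm), 2.2) + 0.01)
  fit_cells(p, "ffb_yield", enso, L, x_boundary = bnd)
}

# standardized random covariate matrix for LASSO tests
random_X <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  ensopalm:::standardize_columns(X)
}
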