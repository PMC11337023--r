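# Cross-basis construction for the distributed lag non-linear model (DLNM).
#
# The exposure-lag-response surface is parameterized as a tensor product of a
# B-spline basis in exposure intensity (x) and a B-spline basis in lag (l).
# For observation i with exposure history Q[i, l] (l = 0..L), the cross-basis
# row is W[i, (j,k)] = sum_l b_j(Q[i, l]) * c_k(l), with columns ordered
# exposure-major: column index (j - 1) * df_l + k.

#' B-spline basis specification
#'
#' @param degree spline degree (>= 1; 3 for cubic).
#' @param knots ordered internal knot locations, strictly inside `boundary`.
#' @param boundary length-2 numeric, the interval on which the basis lives.
#'   Evaluation outside it is an error (no extrapolation).
#' @param intercept logical; keep the full basis (rows sum to 1) or drop the
#'   first basis function so the span excludes the constant.
#' @return an object of class `basis_spec`.
#' @export
basis_spec <- function(degree = 3L, knots = numeric(0), boundary, intercept = FALSE) {
  if (!is.numeric(degree) || length(degree) != 1L || degree < 1)
    stop("degree must be an integer >= 1")
  degree <- as.integer(degree)
  if (length(boundary) != 2L || !is.numeric(boundary) || boundary[1] >= boundary[2])
    stop("boundary must be an increasing length-2 numeric")
  knots <- sort(as.numeric(knots))
  if (length(knots) && (min(knots) <= boundary[1] || max(knots) >= boundary[2]))
    stop("internal knots must lie strictly inside the boundary")
  structure(list(degree = degree, knots = knots,
                 boundary = as.numeric(boundary), intercept = isTRUE(intercept)),
            class = "basis_spec")
}

#' Dimension of a B-spline basis
#' @param spec a [basis_spec()].
#' @return number of basis columns: internal knots + degree (+ 1 with intercept).
#' @export
basis_df <- function(spec) {
  length(spec$knots) + spec$degree + as.integer(spec$intercept)
}

#' Evaluate a B-spline basis (Cox-de Boor recursion)
#'
#' Evaluates all B-spline basis functions of `spec$degree` on the knot vector
#' obtained by repeating each boundary knot degree + 1 times. With
#' `intercept = TRUE` the rows form a partition of unity; with
#' `intercept = FALSE` the first basis function is dropped.
#'
#' @param x numeric vector of evaluation points, inside the boundary.
#' @param spec a [basis_spec()].
#' @return matrix with `length(x)` rows and [basis_df()] columns.
#' @export
bspline_basis <- function(x, spec) {
  if (!inherits(spec, "basis_spec")) stop("spec must be a basis_spec")
  x <- as.numeric(x)
  lo <- spec$boundary[1]; hi <- spec$boundary[2]
  bad <- !is.finite(x) | x < lo | x > hi
  if (any(bad))
    stop("values outside basis boundary [", lo, ", ", hi, "]: ",
         paste(utils::head(x[bad], 5), collapse = ", "))
  d <- spec$degree
  tk <- c(rep(lo, d + 1L), spec$knots, rep(hi, d + 1L))
  nb <- length(tk) - 1L
  n <- length(x)
  # degree-0 indicators, right-open intervals; x == hi assigned to the last
  # non-empty interval so the basis is left-continuous at the upper boundary
  B <- matrix(0, n, nb)
  for (j in seq_len(nb)) if (tk[j + 1L] > tk[j]) B[, j] <- (x >= tk[j] & x < tk[j + 1L])
  at_hi <- which(x == hi)
  if (length(at_hi)) {
    j_hi <- max(which(tk < hi))
    B[at_hi, ] <- 0
    B[at_hi, j_hi] <- 1
  }
  for (k in seq_len(d)) {
    ncols <- nb - k
    Bn <- matrix(0, n, ncols)
    for (j in seq_len(ncols)) {
      den1 <- tk[j + k] - tk[j]
      den2 <- tk[j + k + 1L] - tk[j + 1L]
      v <- 0
      if (den1 > 0) v <- v + (x - tk[j]) / den1 * B[, j]
      if (den2 > 0) v <- v + (tk[j + k + 1L] - x) / den2 * B[, j + 1L]
      Bn[, j] <- v
    }
    B <- Bn
  }
  if (!spec$intercept) B <- B[, -1L, drop = FALSE]
  B
}

#' Log-scale knot placement on the lag axis
#'
#' Places `nk` knots at equal steps on the log scale of the lag range, i.e.
#' at L^(i / (nk + 1)) for i = 1..nk. This is the customary knot layout for
#' DLNM lag bases, concentrating flexibility at short lags.
#'
#' @param L maximum lag (>= 2).
#' @param nk number of knots (default 3).
#' @return numeric vector of knot locations in (1, L).
#' @export
log_knots <- function(L, nk = 3L) {
  if (!is.numeric(L) || length(L) != 1L || L < 2) stop("L must be >= 2")
  if (!is.numeric(nk) || length(nk) != 1L || nk < 1) stop("nk must be >= 1")
  exp(seq_len(nk) * log(L) / (nk + 1))
}

#' Build per-observation exposure histories
#'
#' For each observation period t, collects the exposure series value at lags
#' 0..L, i.e. the row (x_t, x_{t-1}, ..., x_{t-L}). The series is shared by
#' all estates observed in the same calendar month.
#'
#' @param series an ENSO series: data.frame with columns `period` ("YYYY-MM")
#'   and `value`, gap-free.
#' @param periods character vector of observation periods ("YYYY-MM"),
#'   possibly repeated across estates.
#' @param L maximum lag in months.
#' @return matrix Q with `length(periods)` rows and L + 1 columns; column l+1
#'   holds the exposure l months before each period. Class `exposure_history`
#'   with attribute `L`.
#' @export
build_exposure_history <- function(series, periods, L) {
  if (!all(c("period", "value") %in% names(series)))
    stop("series must have columns 'period' and 'value'")
  L <- as.integer(L)
  if (L < 0) stop("L must be >= 0")
  sym <- parse_ym(series$period)
  o <- order(sym)
  sym <- sym[o]
  val <- as.numeric(series$value)[o]
  if (any(diff(sym) != 1L)) stop("exposure series has calendar gaps")
  pym <- parse_ym(periods)
  need <- (min(pym) - L):max(pym)
  miss <- setdiff(need, sym)
  if (length(miss))
    stop("exposure series does not cover required history; earliest missing month: ",
         format_ym(min(miss)))
  base <- match(pym, sym)
  Q <- vapply(0:L, function(l) val[base - l], numeric(length(pym)))
  Q <- matrix(Q, nrow = length(pym), ncol = L + 1L,
              dimnames = list(NULL, paste0("lag", 0:L)))
  structure(Q, L = L, class = c("exposure_history", "matrix", "array"))
}

#' Default basis specifications for a cross-basis
#'
#' Exposure dimension: cubic B-spline, internal knots at the 25th/50th/75th
#' percentiles of the observed exposures, no intercept (the model intercept
#' absorbs the constant), boundary the observed exposure range unless given.
#' Lag dimension: cubic B-spline with intercept, internal knots from
#' [log_knots()], boundary (0, L). Because the lag basis is only ever
#' evaluated at the L + 1 integer lags, its dimension must not exceed L + 1;
#' for short windows the knot count (and below L = 3 the degree) is reduced
#' accordingly.
#'
#' @param Q exposure history matrix.
#' @param L maximum lag.
#' @param x_boundary optional explicit exposure boundary.
#' @param x_knots optional explicit exposure knots.
#' @return list with elements `x_spec` and `l_spec`.
#' @export
default_cb_specs <- function(Q, L, x_boundary = NULL, x_knots = NULL) {
  rng <- range(Q)
  bnd <- x_boundary %||% rng
  if (is.null(x_knots)) {
    x_knots <- stats::quantile(Q, c(.25, .5, .75), names = FALSE, type = 7)
    x_knots <- unique(x_knots[x_knots > bnd[1] & x_knots < bnd[2]])
  }
  deg_l <- min(3L, L)
  nk_l <- max(0L, min(3L, L - deg_l))         # df_l = deg_l + 1 + nk_l <= L + 1
  l_knots <- if (nk_l > 0L) log_knots(L, nk_l) else numeric(0)
  list(x_spec = basis_spec(3L, x_knots, bnd, intercept = FALSE),
       l_spec = basis_spec(deg_l, l_knots, c(0, L), intercept = TRUE))
}

#' Build the DLNM cross-basis
#'
#' @param Q exposure history from [build_exposure_history()] (n x (L+1)).
#' @param x_spec,l_spec [basis_spec()] objects for the exposure and lag
#'   dimensions; defaults from [default_cb_specs()].
#' @param x0 reference exposure value shared by all downstream contrasts
#'   (default 0, the approximately neutral ENSO state).
#' @return object of class `crossbasis`: list with the design block `W`
#'   (n x df_x*df_l), the specs, `L` and `x0`.
#' @export
build_crossbasis <- function(Q, x_spec = NULL, l_spec = NULL, x0 = 0) {
  L <- ncol(Q) - 1L
  if (is.null(x_spec) || is.null(l_spec)) {
    sp <- default_cb_specs(Q, L)
    x_spec <- x_spec %||% sp$x_spec
    l_spec <- l_spec %||% sp$l_spec
  }
  Cl <- bspline_basis(0:L, l_spec)            # (L+1) x df_l
  df_x <- basis_df(x_spec); df_l <- ncol(Cl)
  n <- nrow(Q)
  if (df_x * df_l > n)
    warning("cross-basis dimension (", df_x * df_l, ") exceeds n (", n, ")")
  idx_j <- rep(seq_len(df_x), each = df_l)
  W <- matrix(0, n, df_x * df_l)
  for (l in 0:L) {
    Bx <- bspline_basis(Q[, l + 1L], x_spec)
    cl <- Cl[l + 1L, rep(seq_len(df_l), times = df_x)]
    W <- W + Bx[, idx_j, drop = FALSE] * matrix(cl, n, df_x * df_l, byrow = TRUE)
  }
  colnames(W) <- paste0("cb.x", idx_j, ".l", rep(seq_len(df_l), times = df_x))
  structure(list(W = W, x_spec = x_spec, l_spec = l_spec, L = L, x0 = x0,
                 df_x = df_x, df_l = df_l),
            class = "crossbasis")
}

#' Contrast vector for a cross-basis effect relative to the reference
#'
#' Cumulative contrast: z[(j,k)] = (b_j(x) - b_j(x0)) * sum_l c_k(l);
#' lag-specific contrast at lag l: z[(j,k)] = (b_j(x) - b_j(x0)) * c_k(l).
#'
#' @param cb a `crossbasis`.
#' @param x exposure value (inside the exposure boundary).
#' @param lag `NULL` for the cumulative contrast over lags 0..L, or a single
#'   lag value in [0, L].
#' @return numeric contrast vector of length df_x * df_l.
#' @export
cb_contrast <- function(cb, x, lag = NULL) {
  stopifnot(inherits(cb, "crossbasis"))
  bxd <- bspline_basis(x, cb$x_spec) - bspline_basis(cb$x0, cb$x_spec)
  if (is.null(lag)) {
    clv <- colSums(bspline_basis(0:cb$L, cb$l_spec))
  } else {
    if (lag < 0 || lag > cb$L) stop("lag must be in [0, L]")
    if (lag != round(lag))
      message("non-integer lag ", lag, ": basis is continuous in lag, proceeding")
    clv <- drop(bspline_basis(lag, cb$l_spec))
  }
  as.numeric(rep(drop(bxd), each = cb$df_l) * rep(clv, times = cb$df_x))
}

#' Export a cross-basis as CSV with a JSON spec sidecar
#'
#' Writes the design block `W` as a headed CSV and the basis specifications,
#' maximum lag and reference value to `<path>.json` so the construction is
#' reproducible.
#'
#' @param cb a `crossbasis`.
#' @param path CSV output path (the sidecar takes the same path + ".json").
#' @export
write_crossbasis_csv <- function(cb, path) {
  stopifnot(inherits(cb, "crossbasis"))
  utils::write.csv(as.data.frame(cb$W), path, row.names = FALSE)
  jsonlite::write_json(
    list(x_spec = unclass(cb$x_spec), l_spec = unclass(cb$l_spec),
         L = cb$L, x0 = cb$x0, df_x = cb$df_x, df_l = cb$df_l),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ENSO index series from CSV
#'
#' Expects columns `year`, `month`, `index_name`, `value` and returns the
#' gap-free series for one index as a data.frame (`period`, `value`).
#'
#' @param path CSV path.
#' @param index which `index_name` to extract (default: the only one present).
#' @export
read_enso_csv <- function(path, index = NULL) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("year", "month", "index_name", "value")
  if (!all(req %in% names(d))) stop("ENSO CSV needs columns: ", paste(req, collapse = ", "))
  if (is.null(index)) {
    index <- unique(d$index_name)
    if (length(index) != 1L) stop("multiple indices present; pick one of: ",
                                  paste(index, collapse = ", "))
  }
  d <- d[d$index_name == index, ]
  if (!nrow(d)) stop("index not found: ", index)
  out <- data.frame(period = sprintf("%04d-%02d", d$year, d$month),
                    value = as.numeric(d$value))
  out <- out[order(parse_ym(out$period)), ]
  rownames(out) <- NULL
  out
}

#' Write an ENSO series to CSV
#' @param series data.frame (`period`, `value`).
#' @param path output CSV.
#' @param index_name label stored in the `index_name` column.
#' @export
write_enso_csv <- function(series, path, index_name = "MEI") {
  ym <- parse_ym(series$period)
  utils::write.csv(data.frame(year = ym %/% 12L, month = ym %% 12L + 1L,
                              index_name = index_name, value = series$value),
                   path, row.names = FALSE)
  invisible(path)
}
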