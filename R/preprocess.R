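# Outcome construction, exclusion filters, missing-category coding,
# quantile groupings, rolling weather averages and descriptive statistics.

#' Fresh fruit bunch yield
#'
#' @param ffb_mass harvested FFB mass (t), >= 0.
#' @param harvested_area harvested area (ha), > 0.
#' @return yield in t/ha/month.
#' @export
compute_ffb_yield <- function(ffb_mass, harvested_area) {
  if (any(!is.finite(harvested_area)) || any(harvested_area <= 0))
    stop("harvested_area must be positive")
  if (any(ffb_mass < 0, na.rm = TRUE)) stop("ffb_mass must be >= 0")
  ffb_mass / harvested_area
}

#' Oil yield
#'
#' Oil yield is FFB yield times the oil extraction rate. A missing OER
#' propagates to a missing oil yield.
#'
#' @param ffb_yield FFB yield (t/ha/month).
#' @param oer oil extraction rate (%), in \[0, 100\] or NA.
#' @return oil yield in t/ha/month.
#' @export
compute_oil_yield <- function(ffb_yield, oer) {
  if (any(oer < 0 | oer > 100, na.rm = TRUE)) stop("oer must be in [0, 100]")
  ffb_yield * oer / 100
}

#' Exclude implausible estate-months
#'
#' Drops rows with FFB yield strictly greater than 6 t/ha/month or OER
#' strictly over 30 % (boundary values are kept; missing OER never triggers
#' exclusion). The filter is pure: retained rows are unchanged, and it is
#' idempotent.
#'
#' @param records panel data.frame with `ffb_yield` and `oer` columns.
#' @return list with `records` (filtered), `n_excluded`, and `log`
#'   (data.frame: row index in the input, reason).
#' @export
apply_exclusions <- function(records) {
  drop_yield <- !is.na(records$ffb_yield) & records$ffb_yield > 6
  drop_oer <- !is.na(records$oer) & records$oer > 30
  drop <- drop_yield | drop_oer
  log <- data.frame(
    row = which(drop),
    reason = ifelse(drop_yield[drop], "ffb_yield > 6", "oer > 30"))
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, n_excluded = sum(drop), log = log)
}

#' Code missing values as an explicit category
#'
#' Non-missing values keep their own label; NA becomes a dedicated level. An
#' all-missing input yields a single-level factor flagged as non-identifiable
#' (attribute `non_identifiable`).
#'
#' @param values vector (numeric, character or factor).
#' @param label_missing label for the missing level.
#' @export
encode_missing_category <- function(values, label_missing = "MISSING") {
  lab <- as.character(values)
  lab[is.na(lab)] <- label_missing
  f <- factor(lab)
  if (all(is.na(values))) {
    warning("all values missing: single-level category is non-identifiable")
    attr(f, "non_identifiable") <- TRUE
  }
  f
}

#' Fertilizer investment categories
#'
#' Estate-months with missing records or zero fertilizer investment form one
#' reference level `"REF"`; positive costs are binned by empirical quartiles
#' (or `k` quantile groups).
#'
#' @param cost fertilizer cost; NA or 0 maps to the reference level.
#' @param k number of quantile bins for positive costs.
#' @export
encode_fertilizer <- function(cost, k = 4L) {
  ref <- is.na(cost) | cost == 0
  lab <- rep("REF", length(cost))
  if (any(!ref)) {
    k_eff <- min(k, length(unique(cost[!ref])))
    if (k_eff < 2L) {
      lab[!ref] <- "Q1"        # too few distinct positive costs for quantile bins
    } else {
      g <- quantile_groups(cost[!ref], k = k_eff)
      lab[!ref] <- paste0("Q", as.integer(g))
    }
  }
  f <- factor(lab, levels = c("REF", paste0("Q", seq_len(k))))
  droplevels(f)
}

#' Empirical quantile groups
#'
#' Cuts values at linear-interpolation (type 7) sample quantiles into `k`
#' groups; a value equal to an internal cutpoint goes to the lower group.
#' Missing values get their own `"MISSING"` level.
#'
#' @param values numeric vector.
#' @param k number of groups (3 for tertiles, 4 for quartiles).
#' @param labels optional group labels (length `k`).
#' @export
quantile_groups <- function(values, k = 4L, labels = NULL) {
  k <- as.integer(k)
  nm <- values[!is.na(values)]
  if (length(unique(nm)) < k)
    stop("need at least ", k, " distinct non-missing values")
  br <- stats::quantile(nm, probs = seq(0, 1, length.out = k + 1L),
                        names = FALSE, type = 7)
  if (anyDuplicated(br))
    stop("quantile cutpoints are not distinct; too many ties for k = ", k)
  if (is.null(labels)) labels <- paste0("G", seq_len(k))
  g <- cut(values, breaks = br, labels = labels,
           include.lowest = TRUE, right = TRUE)
  if (anyNA(values)) {
    g <- factor(g, levels = c(labels, "MISSING"))
    g[is.na(values)] <- "MISSING"
  }
  g
}

#' Trailing 24-month average
#'
#' Mean of a monthly series over the current month and the previous 23.
#'
#' @param series data.frame (`period`, `value`), gap-free.
#' @param at "YYYY-MM" month at which to evaluate.
#' @export
rolling_24m_average <- function(series, at) {
  ym <- parse_ym(series$period)
  need <- (parse_ym(at) - 23L):parse_ym(at)
  idx <- match(need, ym)
  if (anyNA(idx))
    stop("series does not cover the 24 months ending at ", at)
  mean(series$value[idx])
}

#' Convert daily precipitation to a monthly total
#'
#' Uses a fixed 30-day month, so 7.09 mm/day is 212.7 mm/month.
#'
#' @param mm_per_day precipitation rate (mm/day).
#' @return mm per month.
#' @export
daily_to_monthly_precip <- function(mm_per_day) 30 * mm_per_day

#' State-wise quadratic teleconnection fits
#'
#' Ordinary least squares of a local weather variable on the 2-month-lagged
#' ENSO index and its square, separately by state.
#'
#' @param weather numeric response (e.g. air temperature or precipitation).
#' @param enso_lag2 index value two months before each observation.
#' @param state state labels (same length).
#' @return data.frame: state, intercept `a`, linear `b`, quadratic `c`,
#'   `r_squared`, `n`.
#' @export
fit_state_quadratic <- function(weather, enso_lag2, state) {
  stopifnot(length(weather) == length(enso_lag2), length(weather) == length(state))
  states <- sort(unique(as.character(state)))
  rows <- lapply(states, function(s) {
    sel <- state == s & !is.na(weather) & !is.na(enso_lag2)
    x <- enso_lag2[sel]; w <- weather[sel]
    if (length(unique(x)) < 3L)
      stop("state ", s, ": need >= 3 distinct exposure values")
    X <- cbind(1, x, x^2)
    qx <- qr(X)
    if (qx$rank < 3L) stop("state ", s, ": rank-deficient quadratic design")
    cf <- qr.coef(qx, w)
    res <- w - X %*% cf
    tss <- sum((w - mean(w))^2)
    data.frame(state = s, a = cf[1], b = cf[2], c = cf[3],
               r_squared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
               n = length(w))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Descriptive statistics
#'
#' Mean, sample SD, min and max for each numeric variable, plus observation
#' and estate counts and level counts for categorical variables.
#'
#' @param records panel data.frame.
#' @return list with `numeric` (data.frame), `counts` (list) and `n`,
#'   `n_estates`.
#' @export
describe <- function(records) {
  if (!nrow(records)) stop("no records to describe")
  num <- vapply(records, is.numeric, logical(1))
  tab <- do.call(rbind, lapply(names(records)[num], function(v) {
    x <- records[[v]][!is.na(records[[v]])]
    data.frame(variable = v, mean = mean(x), sd = stats::sd(x),
               min = min(x), max = max(x), n = length(x))
  }))
  rownames(tab) <- NULL
  cats <- names(records)[vapply(records, function(x)
    is.character(x) || is.factor(x) || is.logical(x), logical(1))]
  counts <- lapply(records[cats], function(x) table(x, useNA = "ifany"))
  list(numeric = tab, counts = counts, n = nrow(records),
       n_estates = if ("estate_id" %in% names(records))
         length(unique(records$estate_id)) else NA_integer_)
}

#' Preprocess a raw panel
#'
#' Recomputes outcomes from their primitives, applies the exclusion filter
#' and returns the cleaned records plus the exclusion log.
#'
#' @param records raw panel data.frame.
#' @return list: `records`, `n_excluded`, `log`.
#' @export
preprocess_panel <- function(records) {
  records$ffb_yield <- compute_ffb_yield(records$ffb_mass, records$harvested_area)
  records$oil_yield <- compute_oil_yield(records$ffb_yield, records$oer)
  apply_exclusions(records)
}
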