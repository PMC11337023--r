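# Orchestration: simulate -> preprocess -> select -> fit -> associate ->
# subgroup -> report, with one structured config, a run manifest and
# deterministic outputs. All randomness flows from a single root seed via
# fixed offsets (simulation: seed; panel body: seed + 1; CV folds: seed + 2).

#' Pipeline run configuration
#'
#' @param out_dir output directory.
#' @param panel_csv,enso_csv input paths; when NULL the simulate stage must
#'   run first and writes them under `out_dir`.
#' @param outcomes outcome columns to model.
#' @param index ENSO index name.
#' @param lag_candidates candidate maximum lags for AIC selection.
#' @param x_boundary optional explicit exposure-basis boundary.
#' @param contrast_values exposure contrasts reported in tables.
#' @param k_folds CV folds for LASSO selection.
#' @param subgroups named list of grouping variables for stratified fits;
#'   each entry is a function of the panel returning a factor, or a column
#'   name.
#' @param min_stratum_n minimum stratum size.
#' @param random_intercept also run the random-intercept robustness fit.
#' @param sim a [sim_config()] used by the simulate stage.
#' @param seed root seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, panel_csv = NULL, enso_csv = NULL,
                       outcomes = c("ffb_yield", "oer", "oil_yield"),
                       index = "MEI", lag_candidates = c(10L, 23L),
                       x_boundary = NULL, contrast_values = c(-1, 2),
                       k_folds = 10L, subgroups = list(labor = "labor_quartile"),
                       min_stratum_n = 500L, random_intercept = FALSE,
                       sim = sim_config(), seed = 1L) {
  structure(list(out_dir = out_dir, panel_csv = panel_csv, enso_csv = enso_csv,
                 outcomes = outcomes, index = index,
                 lag_candidates = as.integer(lag_candidates),
                 x_boundary = x_boundary, contrast_values = contrast_values,
                 k_folds = as.integer(k_folds), subgroups = subgroups,
                 min_stratum_n = as.integer(min_stratum_n),
                 random_intercept = isTRUE(random_intercept),
                 sim = sim, seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  # paths are excluded: the hash identifies the analysis, not its location
  slim <- config[setdiff(names(config),
                         c("subgroups", "out_dir", "panel_csv", "enso_csv"))]
  slim$sim <- unclass(slim$sim)
  slim$sim$surface <- unclass(slim$sim$surface)
  slim$sim$oer_surface <- unclass(slim$sim$oer_surface)
  jsonlite::write_json(slim, f, auto_unbox = TRUE, digits = 12, force = TRUE)
  unname(tools::md5sum(f))
}

write_stamped_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order and writes CSV artifacts, a run
#' manifest (config hash, seed, stage log) and a plain-text summary under
#' `config$out_dir`. Any stage failure aborts with the stage name.
#'
#' @param config a [run_config()].
#' @param stages subset of
#'   c("simulate", "preprocess", "select", "fit", "associate", "subgroup",
#'   "report"), or "all".
#' @return invisibly, a list with the run artifacts (panel, fits, curves,
#'   tables, manifest path).
#' @export
run_pipeline <- function(config, stages = "all") {
  all_stages <- c("simulate", "preprocess", "select", "fit", "associate",
                  "subgroup", "report")
  if (identical(stages, "all")) stages <- all_stages
  if (!all(stages %in% all_stages))
    stop("unknown stage(s): ", paste(setdiff(stages, all_stages), collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log <- character(0)
  note <- function(stage, msg) {
    line <- sprintf("[%s] %s", stage, msg)
    log <<- c(log, line)
    message(line)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out <- list(hash = hash)

  if ("simulate" %in% stages) run_stage("simulate", {
    cfg <- config$sim
    cfg$seed <- config$seed
    panel <- generate_panel(cfg)
    enso <- attr(panel, "enso")
    config$panel_csv <- file.path(config$out_dir, "panel.csv")
    config$enso_csv <- file.path(config$out_dir, "enso.csv")
    write_panel_csv(panel, config$panel_csv)
    write_enso_csv(enso, config$enso_csv, index_name = config$index)
    note("simulate", sprintf("wrote %d estate-months, %d index months",
                             nrow(panel), nrow(enso)))
  })
  if (is.null(config$panel_csv) || is.null(config$enso_csv)) {
    if (length(setdiff(stages, "simulate")))
      stop("panel_csv/enso_csv required unless the simulate stage runs first")
    panel <- NULL
  } else {
    panel <- read_panel_csv(config$panel_csv)
    series <- read_enso_csv(config$enso_csv, index = config$index)
  }

  if ("preprocess" %in% stages) run_stage("preprocess", {
    pp <- preprocess_panel(panel)
    note("preprocess", sprintf("rows in %d, excluded %d, rows out %d",
                               nrow(panel) + 0L, pp$n_excluded, nrow(pp$records)))
    write_stamped_csv(pp$log, file.path(config$out_dir, "exclusion_log.csv"), hash)
    write_stamped_csv(pp$records, file.path(config$out_dir, "panel_clean.csv"), hash)
    panel <- pp$records
    out$panel <- panel
  })
  if (is.null(out$panel) && !is.null(panel)) out$panel <- panel
  panel <- out$panel

  Xcov <- NULL
  if ("select" %in% stages) run_stage("select", {
    Xcov <- build_covariate_matrix(panel)
    out$selection <- list()
    for (oc in config$outcomes) {
      y <- panel[[oc]]
      keep <- !is.na(y)
      sel <- cv_select(Xcov[keep, , drop = FALSE], y[keep],
                       k_folds = config$k_folds, seed = config$seed + 2L)
      out$selection[[oc]] <- sel
      write_selection_csv(sel, Xcov,
                          file.path(config$out_dir, paste0("selection_", oc, ".csv")))
      write_stamped_csv(sel$cv_curve,
                        file.path(config$out_dir, paste0("cv_curve_", oc, ".csv")),
                        hash)
      note("select", sprintf("%s: lambda_min = %.5g, %d of %d columns selected",
                             oc, sel$lambda_min, length(sel$selected), ncol(Xcov)))
    }
    out$Xcov <- Xcov
  })

  if ("fit" %in% stages) run_stage("fit", {
    out$fits <- list()
    for (oc in config$outcomes) {
      covm <- NULL
      if (!is.null(out$selection[[oc]]) && length(out$selection[[oc]]$selected))
        covm <- out$Xcov[, out$selection[[oc]]$selected, drop = FALSE]
      ml <- select_max_lag(panel, oc, series, config$lag_candidates,
                           x_boundary = config$x_boundary, covariates = covm)
      out$fits[[oc]] <- ml$fit
      write_stamped_csv(ml$aic_table,
                        file.path(config$out_dir, paste0("aic_", oc, ".csv")), hash)
      write_fit_bundle(ml$fit, config$out_dir, paste0("fit_", oc))
      note("fit", sprintf("%s: selected L = %d (AIC %.2f), n = %d",
                          oc, ml$L, ml$fit$aic, ml$fit$n))
      if (config$random_intercept) {
        ri <- fit_random_intercept(panel, oc, ml$fit$crossbasis, covm)
        out$fits_ri[[oc]] <- ri
        write_fit_bundle(ri, config$out_dir, paste0("fit_ri_", oc))
        note("fit", sprintf("%s: random-intercept sigma_b = %.4f",
                            oc, sqrt(ri$sigma2_b)))
      }
    }
  })

  if ("associate" %in% stages) run_stage("associate", {
    tabs <- list()
    for (oc in names(out$fits)) {
      fit <- out$fits[[oc]]
      bnd <- fit$crossbasis$x_spec$boundary
      grid <- seq(bnd[1], bnd[2], length.out = 60)
      curve <- cumulative_association(fit, grid)
      write_stamped_csv(as.data.frame(curve),
                        file.path(config$out_dir, paste0("curve_", oc, ".csv")), hash)
      surf <- contour_matrix(fit)
      write_surface_csv(surf, file.path(config$out_dir, paste0("surface_", oc, ".csv")))
      tabs[[oc]] <- association_table(fit, config$contrast_values,
                                      index = config$index,
                                      outcome_mean = mean(panel[[oc]], na.rm = TRUE))
      note("associate", sprintf("%s: curve (%d pts), surface, table", oc, length(grid)))
    }
    out$table <- do.call(rbind, tabs)
    rownames(out$table) <- NULL
    write_stamped_csv(out$table, file.path(config$out_dir, "association_table.csv"),
                      hash)
  })

  if ("subgroup" %in% stages) run_stage("subgroup", {
    reports <- list(); comps <- list()
    for (gname in names(config$subgroups)) {
      gdef <- config$subgroups[[gname]]
      g <- if (is.function(gdef)) gdef(panel) else default_grouping(panel, gdef)
      L <- out$fits[[config$outcomes[1]]]$crossbasis$L
      sf <- stratified_fit(panel, g, config$outcomes[1], series, L,
                           x_boundary = config$x_boundary,
                           min_n = config$min_stratum_n)
      if (length(sf) < 2L) { note("subgroup", paste0(gname, ": < 2 strata, skipped")); next }
      reports[[gname]] <- subgroup_report(sf, config$contrast_values, gname)
      comps[[gname]] <- do.call(rbind, lapply(config$contrast_values, function(xx)
        cbind(grouping = gname, compare_subgroups(sf, xx))))
      note("subgroup", sprintf("%s: %d strata", gname, length(sf)))
    }
    if (length(reports)) {
      out$subgroups <- do.call(rbind, reports); rownames(out$subgroups) <- NULL
      out$comparisons <- do.call(rbind, comps); rownames(out$comparisons) <- NULL
      write_stamped_csv(out$subgroups, file.path(config$out_dir, "subgroup_report.csv"),
                        hash)
      write_stamped_csv(out$comparisons,
                        file.path(config$out_dir, "subgroup_comparisons.csv"), hash)
    }
  })

  if ("report" %in% stages) run_stage("report", {
    manifest <- list(config_hash = hash, seed = config$seed,
                     r_version = as.character(getRversion()),
                     package_version = as.character(utils::packageVersion("ensopalm")),
                     stages = stages, log = log,
                     files = list.files(config$out_dir))
    mf <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
    out$manifest <- mf
    writeLines(c(sprintf("ensopalm run %s (seed %d)", hash, config$seed), log),
               file.path(config$out_dir, "summary.txt"))
    note("report", "manifest and summary written")
  })
  invisible(out)
}

# built-in groupings addressable by name in run_config()$subgroups
default_grouping <- function(panel, name) {
  switch(name,
    labor_quartile = quantile_groups(panel$labor_intensity, k = 4L,
                                     labels = c("low", "medium-low",
                                                "medium-high", "high")),
    fertilizer = encode_fertilizer(panel$fertilizer_cost),
    soil_quartile = quantile_groups(panel$soil_score, k = 4L,
                                    labels = c("worst", "fair", "good", "best")),
    age_band = cut(panel$age_profile, c(0, 3, 8, 18, 23, Inf),
                   labels = c("immature", "young", "prime", "ageing", "old"),
                   include.lowest = TRUE),
    air_tertile = quantile_groups(panel$air_temp, k = 3L),
    soil_temp_tertile = quantile_groups(panel$soil_temp, k = 3L),
    precip_tertile = quantile_groups(panel$precip, k = 3L),
    if (name %in% names(panel)) as.factor(panel[[name]])
    else stop("unknown grouping: ", name))
}
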