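#' Fit every patient in a dataset with one or both Bayesian engines
#'
#' Runs the nonparametric discrete-posterior engine and/or the parametric
#' MAP engine on each patient record and assembles a per-patient report:
#' posterior-predicted concentrations at the observation times and
#' steady-state exposure under the patient's own regimen. Per-patient
#' failures are caught, recorded and skipped; an error is raised only if
#' every patient fails.
#'
#' @param patients A `tdm_patients` list from [read_dataset()] or a
#'   `tdm_cohort` from [generate_cohort()].
#' @param engine `"nonparametric"`, `"parametric"` or `"both"`.
#' @param np An [np_prior()] (required for the nonparametric engine).
#' @param pp A [parametric_prior()] (required for the parametric engine).
#' @param error An [assay_error()] model.
#' @return An object of class `fit_set`: per patient a list with `id`,
#'   `obs`, and per engine the fit, predictions at observation times and
#'   [posterior_exposure()]. Failed patients appear in
#'   `attr(, "failures")`.
#' @export
fit_dataset <- function(patients,
                        engine = c("both", "nonparametric", "parametric"),
                        np = NULL, pp = NULL, error = assay_error()) {
  engine <- match.arg(engine)
  if (length(patients) == 0L) stop("no patients in dataset", call. = FALSE)
  use_np <- engine %in% c("both", "nonparametric")
  use_pp <- engine %in% c("both", "parametric")
  if (use_np && is.null(np))
    stop("nonparametric engine requested without an np prior", call. = FALSE)
  if (use_pp && is.null(pp))
    stop("parametric engine requested without a parametric prior", call. = FALSE)
  failures <- list()
  fits <- lapply(patients, function(p) {
    tryCatch({
      out <- list(id = p$id, obs = p$obs)
      if (use_np) {
        f <- np_posterior(np, p$obs, error)
        out$np <- list(fit = f,
                       pred = posterior_predict(f, p$obs$time_h),
                       exposure = posterior_exposure(f))
      }
      if (use_pp) {
        f <- map_fit(pp, p$obs, error)
        out$map <- list(fit = f,
                        pred = posterior_predict(f, p$obs$time_h),
                        exposure = posterior_exposure(f))
      }
      out
    }, error = function(cnd) {
      failures[[length(failures) + 1L]] <<- list(id = p$id,
                                                 message = conditionMessage(cnd))
      NULL
    })
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L)
    stop("all patients failed to fit; first error: ", failures[[1]]$message,
         call. = FALSE)
  structure(fits, class = "fit_set", failures = failures)
}

#' Target-dose table for a fitted dataset
#'
#' Computes the minimum effective dose (AUC target) and maximum tolerated
#' dose (trough bound) for every patient and engine.
#'
#' @param fits A `fit_set` from [fit_dataset()].
#' @param template Schedule template; see [unit_dose_response()].
#' @param targets An [exposure_targets()] object.
#' @param mode Dose objective; see [compute_dmin()].
#' @return A data frame with one row per patient x engine: `id`, `engine`,
#'   `weight_kg`, `dmin_mg_day`, `dmin_mg_kg`, `dmax_mg_day`, `dmax_mg_kg`,
#'   `mode`.
#' @export
dose_dataset <- function(fits,
                         template = list(interval_h = 24,
                                         infusion_duration_h = 0.5),
                         targets = exposure_targets(),
                         mode = c("mm_squared_error", "expectation")) {
  mode <- match.arg(mode)
  rows <- lapply(fits, function(p) {
    engines <- c(if (!is.null(p$np)) "nonparametric",
                 if (!is.null(p$map)) "parametric")
    do.call(rbind, lapply(engines, function(en) {
      fit <- if (en == "nonparametric") p$np$fit else p$map$fit
      rec <- recommend_doses(fit, template, targets, mode)
      data.frame(id = p$id, engine = en, weight_kg = fit$cov$weight_kg,
                 dmin_mg_day = rec$dmin$dose_mg_day,
                 dmin_mg_kg = rec$dmin$dose_mg_kg,
                 dmax_mg_day = rec$dmax$dose_mg_day,
                 dmax_mg_kg = rec$dmax$dose_mg_kg,
                 mode = mode)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validation and agreement report for a fitted dataset
#'
#' Assembles the comparison a tool evaluation reports: per-engine bias
#' (mean error) and imprecision (MAPE) of predicted versus observed
#' concentrations, an engine-versus-engine comparison table
#' (mean +/- sd per engine, rank-test p, R-squared) over concentrations,
#' AUC24, half-life, V1, CL and target doses, and Bland-Altman agreement
#' analyses for concentrations, AUC24, Dmin and Dmax.
#'
#' @param fits A `fit_set` fitted with both engines.
#' @param doses Optional dose table from [dose_dataset()]; computed with
#'   defaults when omitted.
#' @param template,targets Passed to [dose_dataset()] when `doses` is
#'   missing.
#' @return An object of class `evaluation_report`: `predictive` (per-engine
#'   ME and MAPE with n), `comparison` (an [compare_engines()] table) and
#'   `bland_altman` (named list of [bland_altman()] results).
#' @export
evaluate_fits <- function(fits, doses = NULL,
                          template = list(interval_h = 24,
                                          infusion_duration_h = 0.5),
                          targets = exposure_targets()) {
  has_np <- !is.null(fits[[1]]$np)
  has_map <- !is.null(fits[[1]]$map)
  if (!has_np || !has_map)
    stop("evaluate_fits needs a fit_set produced with engine = 'both'",
         call. = FALSE)
  obs <- unlist(lapply(fits, function(p) p$obs$conc_mg_l))
  blq <- unlist(lapply(fits, function(p) p$obs$below_lloq))
  pred_np <- unlist(lapply(fits, function(p) p$np$pred))
  pred_map <- unlist(lapply(fits, function(p) p$map$pred))
  pp_np <- prediction_pairs(pred_np, obs, blq)
  pp_map <- prediction_pairs(pred_map, obs, blq)
  predictive <- data.frame(
    engine = c("nonparametric", "parametric"),
    me_mg_l = c(mean_error(pp_np), mean_error(pp_map)),
    mape_pct = c(mape(pp_np), mape(pp_map)),
    n = length(pp_np$pred), n_censored = pp_np$n_censored)
  if (is.null(doses)) doses <- dose_dataset(fits, template, targets)
  dn <- doses[doses$engine == "nonparametric", ]
  dm <- doses[doses$engine == "parametric", ]
  ex <- function(side, field) vapply(fits, function(p)
    p[[side]]$exposure[[field]], numeric(1))
  quantities <- list(
    concentrations = list(x = pred_np[!blq], y = pred_map[!blq], paired = TRUE),
    auc24 = list(x = ex("np", "auc24_ss"), y = ex("map", "auc24_ss"),
                 paired = FALSE),
    dmin_mg_kg = list(x = dn$dmin_mg_kg, y = dm$dmin_mg_kg, paired = FALSE),
    dmax_mg_kg = list(x = dn$dmax_mg_kg, y = dm$dmax_mg_kg, paired = FALSE),
    v1 = list(x = vapply(fits, function(p) {
                res <- .resolve_support(p$np$fit$support, p$np$fit$cov)
                sum(p$np$fit$weights * res$v1)
              }, numeric(1)),
              y = vapply(fits, function(p) p$map$fit$macro[["v1"]], numeric(1)),
              paired = FALSE),
    t_half = list(x = ex("np", "t_half_terminal"),
                  y = ex("map", "t_half_terminal"), paired = FALSE),
    cl = list(x = ex("np", "cl"), y = ex("map", "cl"), paired = FALSE)
  )
  ba <- lapply(quantities[c("concentrations", "auc24", "dmin_mg_kg",
                            "dmax_mg_kg")],
               function(q) bland_altman(q$x, q$y))
  structure(list(predictive = predictive,
                 comparison = compare_engines(quantities),
                 bland_altman = ba),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Predictive performance (predicted vs observed concentrations):\n")
  print(x$predictive, row.names = FALSE)
  cat("\nEngine comparison:\n")
  cmp <- x$comparison
  cmp$p_value <- signif(cmp$p_value, 3)
  cmp$r_squared <- round(cmp$r_squared, 2)
  print(cmp[, c("quantity", "mean_x", "sd_x", "mean_y", "sd_y",
                "p_value", "r_squared")], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits the comparison table as CSV, the full report as JSON, and the
#' Bland-Altman plot data (differences, averages and agreement bands) as
#' one CSV per quantity.
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_evaluation_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "comparison.csv")
  utils::write.csv(report$comparison, p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "report.json")
  jsonlite::write_json(list(
    predictive = report$predictive,
    comparison = report$comparison,
    bland_altman = lapply(report$bland_altman, function(b)
      b[c("mean_difference", "sd_difference", "loa_lower", "loa_upper",
          "slope", "intercept", "slope_p", "mode")])
  ), p, auto_unbox = TRUE, digits = NA, na = "null")
  paths <- c(paths, p)
  for (nm in names(report$bland_altman)) {
    p <- file.path(dir, paste0("bland_altman_", nm, ".csv"))
    utils::write.csv(report$bland_altman[[nm]]$data, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
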