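#' Exposure targets for dose individualization
#'
#' Defaults are the daptomycin efficacy and safety targets: a daily AUC of
#' 666 mg.h/L (bactericidal threshold against *S. aureus* for an MIC of
#' 1 mg/L) and a steady-state trough of 24.3 mg/L (the cut-off associated
#' with increased risk of creatine-phosphokinase elevation).
#'
#' @param auc_target Daily AUC target, mg.h/L.
#' @param cmin_limit Trough safety bound, mg/L.
#' @return An object of class `exposure_targets`.
#' @export
exposure_targets <- function(auc_target = 666, cmin_limit = 24.3) {
  if (auc_target <= 0 || cmin_limit <= 0)
    stop("targets must be > 0", call. = FALSE)
  structure(list(auc_target = auc_target, cmin_limit = cmin_limit),
            class = "exposure_targets")
}

# Template regimen for 1 mg/day: per-administration dose = interval/24 mg.
.template_regimen <- function(template, daily_dose = 1) {
  dosing_regimen(dose_mg = daily_dose * template$interval_h / 24,
                 start_time_h = 0,
                 infusion_duration_h = template$infusion_duration_h,
                 interval_h = template$interval_h)
}

#' Per-support exposure sensitivities to a unit daily dose
#'
#' Exploits dose linearity: for each support point (nonparametric fit) or
#' the point estimate (MAP fit), the steady-state daily AUC and trough
#' produced by 1 mg/day on the template schedule. `s_auc = 1/CL` exactly.
#'
#' @param fit An `np_fit` or `map_fit`.
#' @param template List with `interval_h` and `infusion_duration_h` fixing
#'   the schedule (default q24h, 0.5 h infusion).
#' @return A data frame with columns `weight`, `s_auc` (mg.h/L per mg/day)
#'   and `s_cmin` (mg/L per mg/day), one row per support point.
#' @export
unit_dose_response <- function(fit,
                               template = list(interval_h = 24,
                                               infusion_duration_h = 0.5)) {
  reg <- .template_regimen(template)
  tab <- if (inherits(fit, "np_fit")) {
    res <- .resolve_support(fit$support, fit$cov)
    .exposure_table(res$v1, res$ke, res$kcp, res$kpc, fit$weights, reg)
  } else if (inherits(fit, "map_fit")) {
    r <- fit$resolved
    .exposure_table(r$v1_abs, r$ke, r$kcp, r$kpc, 1, reg)
  } else stop("fit must be an np_fit or map_fit", call. = FALSE)
  data.frame(weight = tab$weight, s_auc = tab$auc24_ss, s_cmin = tab$cmin_ss)
}

# Shared target-dose machinery: s = per-support sensitivity of the target
# metric to 1 mg/day.
.target_dose <- function(fit, template, target_value, metric, mode) {
  udr <- unit_dose_response(fit, template)
  s <- udr[[metric]]
  w <- udr$weight
  es <- sum(w * s)
  es2 <- sum(w * s^2)
  if (es <= 0 || es2 <= 0)
    stop("degenerate zero sensitivity; cannot compute a target dose",
         call. = FALSE)
  dose <- switch(mode,
    expectation = target_value / es,
    mm_squared_error = target_value * es / es2
  )
  wt <- fit$cov$weight_kg
  structure(list(dose_mg_day = dose,
                 dose_mg_kg = dose / wt,
                 practical_mg_day = round(dose / 10) * 10,
                 target_metric = metric, target_value = target_value,
                 objective_mode = mode, weight_kg = wt),
            class = "dose_rec")
}

#' Minimum effective dose for the AUC target
#'
#' The daily dose achieving the efficacy AUC target. In `"expectation"`
#' mode, the dose whose posterior-expected AUC24 equals the target
#' (`D = T / E[s_auc]`). In `"mm_squared_error"` mode (default), the
#' multiple-model dose minimizing the posterior-expected squared deviation
#' of AUC24 from the target (`D = T * E[s_auc] / E[s_auc^2]`). Both
#' coincide for a one-point posterior.
#'
#' @param fit An `np_fit` or `map_fit`.
#' @param template Schedule template; see [unit_dose_response()].
#' @param targets An [exposure_targets()] object.
#' @param mode `"mm_squared_error"` or `"expectation"`.
#' @return An object of class `dose_rec` with `dose_mg_day`, `dose_mg_kg`,
#'   a `practical_mg_day` rounding (nearest 10 mg, reporting only), the
#'   target that produced it and the objective mode.
#' @export
compute_dmin <- function(fit,
                         template = list(interval_h = 24,
                                         infusion_duration_h = 0.5),
                         targets = exposure_targets(),
                         mode = c("mm_squared_error", "expectation")) {
  mode <- match.arg(mode)
  .target_dose(fit, template, targets$auc_target, "s_auc", mode)
}

#' Maximum tolerated dose for the trough safety bound
#'
#' Same construction as [compute_dmin()] with the steady-state trough in
#' place of the AUC: the daily dose at which the (expected) trough sits at
#' the safety limit.
#'
#' @inheritParams compute_dmin
#' @return A `dose_rec` object.
#' @export
compute_dmax <- function(fit,
                         template = list(interval_h = 24,
                                         infusion_duration_h = 0.5),
                         targets = exposure_targets(),
                         mode = c("mm_squared_error", "expectation")) {
  mode <- match.arg(mode)
  .target_dose(fit, template, targets$cmin_limit, "s_cmin", mode)
}

#' @export
print.dose_rec <- function(x, ...) {
  lab <- if (x$target_metric == "s_auc") {
    sprintf("AUC24 target %.0f mg.h/L", x$target_value)
  } else {
    sprintf("Cmin limit %.1f mg/L", x$target_value)
  }
  cat(sprintf("Dose for %s (%s mode): %.1f mg/day (%.2f mg/kg), practical %.0f mg/day\n",
              lab, x$objective_mode, x$dose_mg_day, x$dose_mg_kg,
              x$practical_mg_day))
  invisible(x)
}

#' Both target doses for one fitted patient
#'
#' Convenience wrapper returning the minimum effective dose (AUC target)
#' and the maximum tolerated dose (trough bound) together.
#'
#' @inheritParams compute_dmin
#' @return A list with elements `dmin` and `dmax` (both `dose_rec`).
#' @export
recommend_doses <- function(fit,
                            template = list(interval_h = 24,
                                            infusion_duration_h = 0.5),
                            targets = exposure_targets(),
                            mode = c("mm_squared_error", "expectation")) {
  mode <- match.arg(mode)
  list(dmin = compute_dmin(fit, template, targets, mode),
       dmax = compute_dmax(fit, template, targets, mode))
}
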