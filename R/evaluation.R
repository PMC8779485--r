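#' Aligned predicted/observed concentration pairs
#'
#' @param pred Predicted concentrations, mg/L.
#' @param obs Observed concentrations, mg/L.
#' @param below_lloq Optional flags; flagged pairs are excluded (their count
#'   is kept) because percent errors are undefined for censored values.
#' @return An object of class `prediction_pairs`.
#' @export
prediction_pairs <- function(pred, obs, below_lloq = FALSE) {
  if (length(pred) != length(obs))
    stop("pred and obs must have equal length", call. = FALSE)
  below_lloq <- rep_len(as.logical(below_lloq), length(pred))
  keep <- !below_lloq
  structure(list(pred = as.numeric(pred[keep]), obs = as.numeric(obs[keep]),
                 n_censored = sum(below_lloq)),
            class = "prediction_pairs")
}

#' Mean error of prediction (bias)
#'
#' `ME = sum(pred_i - obs_i) / n`, in mg/L.
#'
#' @param p A [prediction_pairs()] object.
#' @return Mean error, mg/L.
#' @export
mean_error <- function(p) {
  stopifnot(inherits(p, "prediction_pairs"))
  if (length(p$pred) == 0L) stop("no prediction pairs", call. = FALSE)
  mean(p$pred - p$obs)
}

#' Mean absolute percent error of prediction (imprecision)
#'
#' `MAPE = mean(|pred_i - obs_i| / obs_i)`, reported in percent. All
#' observed values must be strictly positive.
#'
#' @param p A [prediction_pairs()] object.
#' @return MAPE, percent.
#' @export
mape <- function(p) {
  stopifnot(inherits(p, "prediction_pairs"))
  if (length(p$pred) == 0L) stop("no prediction pairs", call. = FALSE)
  if (any(p$obs <= 0))
    stop("MAPE is undefined for non-positive observed concentrations",
         call. = FALSE)
  100 * mean(abs(p$pred - p$obs) / p$obs)
}

#' Bland-Altman agreement analysis
#'
#' Plots-ready agreement statistics for two paired measurement series:
#' differences `d = x - y` against averages `a = (x + y)/2`; classic limits
#' of agreement `mean(d) +/- 1.96 sd(d)`; and a regression of the
#' differences on the averages. When the regression slope differs
#' significantly from zero (proportional bias), regression-based limits of
#' agreement (fitted line `+/- 1.96` residual sd) become the reporting mode.
#'
#' @param x,y Paired measurements (e.g. the same quantity estimated by two
#'   dosing tools), equal length, n >= 3.
#' @param alpha Significance level of the slope test that switches the
#'   reporting mode (default 0.05).
#' @return An object of class `bland_altman`: `mean_difference`,
#'   `sd_difference`, `loa_lower`/`loa_upper` (classic), `slope`,
#'   `intercept`, `slope_p`, `residual_sd`, `mode`
#'   (`"classic"`/`"regression"`), and a `data` frame of differences,
#'   averages and per-point regression bands.
#' @export
bland_altman <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- x - y
  a <- (x + y) / 2
  md <- mean(d)
  sdd <- stats::sd(d)
  out <- list(mean_difference = md, sd_difference = sdd,
              loa_lower = md - 1.96 * sdd, loa_upper = md + 1.96 * sdd,
              slope = NA_real_, intercept = NA_real_, slope_p = NA_real_,
              residual_sd = NA_real_, mode = "classic", alpha = alpha)
  dat <- data.frame(average = a, difference = d,
                    band_lower = out$loa_lower, band_upper = out$loa_upper)
  if (stats::var(a) > 0) {
    fit <- stats::lm(d ~ a)
    sm <- summary(fit)
    out$intercept <- unname(stats::coef(fit)[1])
    out$slope <- unname(stats::coef(fit)[2])
    out$slope_p <- sm$coefficients[2, 4]
    out$residual_sd <- sm$sigma
    if (is.finite(out$slope_p) && out$slope_p < alpha) {
      out$mode <- "regression"
      fitted <- out$intercept + out$slope * a
      dat$band_lower <- fitted - 1.96 * out$residual_sd
      dat$band_upper <- fitted + 1.96 * out$residual_sd
    }
  }
  out$data <- dat
  structure(out, class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean difference %.3f, classic LoA [%.3f, %.3f]\n",
              x$mean_difference, x$loa_lower, x$loa_upper))
  if (x$mode == "regression") {
    cat(sprintf("  proportional bias detected (slope %.3f, p = %.3g); ",
                x$slope, x$slope_p))
    cat("regression-based limits of agreement reported\n")
  }
  invisible(x)
}

#' Compare paired estimates from two engines
#'
#' For each quantity: per-engine mean and sd, a rank-test p-value (Wilcoxon
#' signed-rank for paired quantities, Mann-Whitney otherwise; exact for
#' n <= 25, normal approximation with continuity correction above), and the
#' linear determination coefficient between engines.
#'
#' @param quantities Named list; each element a list with numeric `x` and
#'   `y` (engine A and B) and logical `paired`.
#' @return An object of class `engine_comparison`: a data frame with one
#'   row per quantity (`quantity`, `mean_x`, `sd_x`, `mean_y`, `sd_y`,
#'   `p_value`, `r_squared`, `test`, `note`).
#' @export
compare_engines <- function(quantities) {
  rows <- lapply(names(quantities), function(nm) {
    q <- quantities[[nm]]
    x <- as.numeric(q$x); y <- as.numeric(q$y)
    if (length(x) != length(y) || length(x) < 3)
      stop("quantity '", nm, "' needs >= 3 pairs of equal length", call. = FALSE)
    paired <- isTRUE(q$paired)
    n <- length(x)
    note <- ""
    p <- if (paired && all(x == y)) {
      note <- "all differences zero; test undefined"
      NA_real_
    } else {
      tryCatch(
        suppressWarnings(stats::wilcox.test(
          x, y, paired = paired, exact = n <= 25, correct = TRUE
        ))$p.value,
        error = function(cnd) {
          note <<- conditionMessage(cnd)
          NA_real_
        })
    }
    r2 <- if (stats::sd(x) > 0 && stats::sd(y) > 0) stats::cor(x, y)^2 else NA_real_
    data.frame(quantity = nm,
               mean_x = mean(x), sd_x = stats::sd(x),
               mean_y = mean(y), sd_y = stats::sd(y),
               p_value = p, r_squared = r2,
               test = if (paired) "wilcoxon_signed_rank" else "mann_whitney",
               note = note)
  })
  structure(do.call(rbind, rows), class = c("engine_comparison", "data.frame"))
}

#' Fractions of patients outside the exposure targets
#'
#' Underexposure is a daily AUC strictly below the efficacy target;
#' overexposure is a trough strictly above the safety limit.
#'
#' @param auc24 Vector of individual daily AUC estimates, mg.h/L.
#' @param cmin Vector of individual steady-state troughs, mg/L.
#' @param targets An [exposure_targets()] object.
#' @return List with `underexposed`, `overexposed` (fractions in `[0, 1]`)
#'   and `n`.
#' @export
target_attainment <- function(auc24, cmin, targets = exposure_targets()) {
  if (length(auc24) < 1L || length(cmin) < 1L)
    stop("need at least one patient", call. = FALSE)
  list(underexposed = mean(auc24 < targets$auc_target),
       overexposed = mean(cmin > targets$cmin_limit),
       n = length(auc24))
}
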