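#' A patient's TDM observations with their context
#'
#' Timed plasma concentrations tied to the covariates and dosing history
#' that generated them. Observations below the assay's lower limit of
#' quantification are flagged and handled as left-censored in the
#' likelihood.
#'
#' @param time_h Observation times, h since first dose.
#' @param conc_mg_l Measured concentrations, mg/L (>= 0).
#' @param below_lloq Logical flags; flagged observations must have
#'   `conc_mg_l < lloq`.
#' @param cov A [covariates()] object.
#' @param reg A [dosing_regimen()].
#' @param lloq LLOQ used to validate the flags, mg/L.
#' @return An object of class `observation_set`.
#' @export
observation_set <- function(time_h, conc_mg_l, below_lloq = FALSE,
                            cov, reg, lloq = 2) {
  n <- length(time_h)
  conc_mg_l <- rep_len(as.numeric(conc_mg_l), n)
  below_lloq <- rep_len(as.logical(below_lloq), n)
  if (any(conc_mg_l < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (any(below_lloq & conc_mg_l >= lloq))
    stop("below-LLOQ flagged observations must have conc < lloq", call. = FALSE)
  stopifnot(inherits(cov, "pk_covariates"), inherits(reg, "dosing_regimen"))
  structure(list(time_h = as.numeric(time_h), conc_mg_l = conc_mg_l,
                 below_lloq = below_lloq, cov = cov, reg = reg),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("Observation set: %d sample(s), %d below LLOQ; %d dose event(s)\n",
              length(x$time_h), sum(x$below_lloq), nrow(x$reg$events)))
  invisible(x)
}

# Log-likelihood rows for an N x n_obs prediction matrix; returns length-N
# vector. Censored observations contribute the left tail at the LLOQ.
.loglik_matrix <- function(pred, obs, e) {
  sd <- e$c0 + e$c1 * pred + e$c2 * pred^2 + e$c3 * pred^3
  sd[sd <= 0] <- NA_real_ # pathological sigma -> -Inf below
  ll <- matrix(0, nrow(pred), ncol(pred))
  cens <- obs$below_lloq
  if (any(!cens)) {
    y <- matrix(rep(obs$conc_mg_l[!cens], each = nrow(pred)), nrow = nrow(pred))
    ll[, !cens] <- stats::dnorm(y, pred[, !cens, drop = FALSE],
                                sd[, !cens, drop = FALSE], log = TRUE)
  }
  if (any(cens)) {
    ll[, cens] <- stats::pnorm(e$lloq, pred[, cens, drop = FALSE],
                               sd[, cens, drop = FALSE], log.p = TRUE)
  }
  ll[is.na(ll)] <- -Inf
  rowSums(ll)
}

#' Gaussian log-likelihood of an observation set
#'
#' Sum over observations of the normal log-density of the measured
#' concentration around the model prediction, with standard deviation given
#' by the assay error polynomial evaluated at the predicted concentration.
#' Below-LLOQ observations contribute the left-tail log-probability at the
#' LLOQ (M3-style censoring).
#'
#' @param r A [resolved_pk()] parameter set.
#' @param obs An [observation_set()].
#' @param e An [assay_error()] model.
#' @return The log-likelihood (scalar; `-Inf` permitted).
#' @export
log_likelihood <- function(r, obs, e) {
  stopifnot(inherits(r, "resolved_pk"), inherits(obs, "observation_set"),
            inherits(e, "assay_error"))
  if (length(obs$time_h) == 0L) return(0)
  pred <- .conc_profile(r$v1_abs, r$ke, r$kcp, r$kpc, obs$reg$events, obs$time_h)
  .loglik_matrix(pred, obs, e)
}

# Resolve every support point of an np_prior at given covariates.
# Returns list of vectors v1, ke, kcp, kpc, cl.
.resolve_support <- function(support, cov) {
  v1 <- support[, "v1_std"] * cov$weight_kg / 70
  ke <- support[, "ks"] * (cov$clcr_ml_min / 100) + support[, "ki"]
  list(v1 = v1, ke = ke, kcp = support[, "kcp"], kpc = support[, "kpc"],
       cl = ke * v1)
}

#' Nonparametric discrete Bayesian posterior
#'
#' Reweights the prior's support points by each point's data likelihood:
#' `w_j` proportional to `prior_j * exp(loglik_j)`, computed in log space
#' with max subtraction for numerical stability. With no observations the
#' posterior equals the prior exactly.
#'
#' @param prior An [np_prior()].
#' @param obs An [observation_set()] (carries covariates and dosing history).
#' @param e An [assay_error()] model.
#' @return An object of class `np_fit`: the support, posterior `weights`,
#'   prior weights, the per-point log-likelihoods, and the patient context.
#' @export
np_posterior <- function(prior, obs, e) {
  stopifnot(inherits(prior, "np_prior"), inherits(obs, "observation_set"),
            inherits(e, "assay_error"))
  res <- .resolve_support(prior$support, obs$cov)
  if (length(obs$time_h) == 0L) {
    ll <- rep(0, nrow(prior$support))
    w <- prior$weights
  } else {
    pred <- .conc_profile(res$v1, res$ke, res$kcp, res$kpc,
                          obs$reg$events, obs$time_h)
    ll <- .loglik_matrix(pred, obs, e)
    lw <- log(prior$weights) + ll
    m <- max(lw)
    if (!is.finite(m))
      stop("degenerate posterior: all support points have zero likelihood; ",
           "check observation times, units and the error model", call. = FALSE)
    w <- exp(lw - m)
    w <- w / sum(w)
  }
  structure(list(support = prior$support, weights = w,
                 prior_weights = prior$weights, loglik = ll,
                 cov = obs$cov, reg = obs$reg, error = e),
            class = "np_fit")
}

#' @export
print.np_fit <- function(x, ...) {
  ess <- 1 / sum(x$weights^2)
  cat(sprintf("Nonparametric posterior: %d support points, ESS = %.1f\n",
              length(x$weights), ess))
  res <- .resolve_support(x$support, x$cov)
  cat(sprintf("  E[CL] = %.3f L/h, E[V1] = %.2f L\n",
              sum(x$weights * res$cl), sum(x$weights * res$v1)))
  invisible(x)
}

#' Maximum a posteriori fit of the parametric model
#'
#' Minimizes the negative log-posterior (Gaussian likelihood with the assay
#' error model, independent normal priors on log CL, V1, Q, V2 centred at
#' the covariate-adjusted typical values) over the log parameters, using
#' quasi-Newton optimization from a fixed, deterministic multi-start
#' schedule (the prior mode and four +/- one-prior-sd perturbations).
#' Parameters with zero between-subject variability are held at their
#' typical values. With no observations the covariate-adjusted prior mode
#' is returned exactly.
#'
#' @param prior A [parametric_prior()].
#' @param obs An [observation_set()].
#' @param e An [assay_error()] model.
#' @return An object of class `map_fit`: `macro` (named CL/V1/Q/V2 vector),
#'   `resolved` ([resolved_pk()]), `objective` (negative log-posterior up to
#'   a constant), `convergence` and the patient context.
#' @export
map_fit <- function(prior, obs, e) {
  stopifnot(inherits(prior, "parametric_prior"),
            inherits(obs, "observation_set"), inherits(e, "assay_error"))
  mult <- .parametric_multipliers(prior, obs$cov)
  tvadj <- prior$tv * mult
  mode_r <- macro_to_micro(tvadj[["cl"]], tvadj[["v1"]],
                           tvadj[["q"]], tvadj[["v2"]])
  mu <- log(tvadj)
  om <- prior$omega
  free <- om > 0
  neg_ll <- function(theta) {
    full <- mu
    full[free] <- theta
    val <- tryCatch({
      r <- macro_to_micro(exp(full[["cl"]]), exp(full[["v1"]]),
                          exp(full[["q"]]), exp(full[["v2"]]))
      pen <- sum(((full[free] - mu[free]) / om[free])^2) / 2
      pen - log_likelihood(r, obs, e)
    }, error = function(cnd) Inf)
    # keep line searches finite when they wander into overflow territory
    if (!is.finite(val)) 1e12 + sum((full[free] - mu[free])^2) else val
  }
  if (length(obs$time_h) == 0L || !any(free)) {
    return(structure(list(macro = tvadj, resolved = mode_r,
                          objective = 0, convergence = 0L,
                          cov = obs$cov, reg = obs$reg, error = e),
                     class = "map_fit"))
  }
  d <- sum(free)
  signs <- list(rep(0, d), rep(1, d), rep(-1, d),
                rep_len(c(1, -1), d), rep_len(c(-1, 1), d))
  best <- NULL
  for (s in signs) {
    start <- mu[free] + s * om[free]
    fit <- tryCatch(
      stats::optim(start, neg_ll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(cnd) NULL)
    if (is.null(fit)) next
    # simplex polish: BFGS with numerical gradients can stall short of the
    # optimum when residuals are near zero
    polish <- tryCatch(
      stats::optim(fit$par, neg_ll, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-14)),
      error = function(cnd) NULL)
    if (!is.null(polish) && polish$value < fit$value) fit <- polish
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("MAP optimization failed from every start; data may be inconsistent ",
         "with the model", call. = FALSE)
  full <- mu
  full[free] <- best$par
  est <- exp(full)
  structure(list(macro = est,
                 resolved = macro_to_micro(est[["cl"]], est[["v1"]],
                                           est[["q"]], est[["v2"]]),
                 objective = best$value, convergence = best$convergence,
                 cov = obs$cov, reg = obs$reg, error = e),
            class = "map_fit")
}

#' @export
print.map_fit <- function(x, ...) {
  cat("MAP estimate (parametric engine)\n")
  cat(sprintf("  CL = %.3f L/h  V1 = %.2f L  Q = %.3f L/h  V2 = %.2f L\n",
              x$macro[["cl"]], x$macro[["v1"]], x$macro[["q"]], x$macro[["v2"]]))
  cat(sprintf("  objective = %.4f (convergence code %d)\n",
              x$objective, x$convergence))
  invisible(x)
}

#' Posterior-predicted concentrations
#'
#' For a nonparametric fit, the posterior-weighted average of the
#' concentration profiles of all support points (a convex combination); for
#' a MAP fit, the profile at the point estimate.
#'
#' @param fit An `np_fit` or `map_fit` object.
#' @param times Times, h since first dose.
#' @param reg Optional [dosing_regimen()] overriding the fitted history.
#' @return Numeric vector of concentrations, mg/L.
#' @export
posterior_predict <- function(fit, times, reg = NULL) {
  UseMethod("posterior_predict")
}

#' @export
posterior_predict.np_fit <- function(fit, times, reg = NULL) {
  if (is.null(reg)) reg <- fit$reg
  res <- .resolve_support(fit$support, fit$cov)
  pred <- .conc_profile(res$v1, res$ke, res$kcp, res$kpc, reg$events,
                        as.numeric(times))
  drop(crossprod(pred, fit$weights))[seq_along(times)]
}

#' @export
posterior_predict.map_fit <- function(fit, times, reg = NULL) {
  if (is.null(reg)) reg <- fit$reg
  predict_concentrations(fit$resolved, reg, times)
}

#' Posterior steady-state exposure
#'
#' Steady-state exposure metrics under a template regimen: per-support
#' metrics and their posterior expectations for the nonparametric engine,
#' point metrics for the MAP engine.
#'
#' @param fit An `np_fit` or `map_fit`.
#' @param reg A [dosing_regimen()] giving the dose, infusion duration and
#'   interval to evaluate; defaults to the fitted history.
#' @return An object of class `posterior_exposure`: expectations `auc24_ss`,
#'   `cmin_ss`, `cmax_ss`, `t_half_terminal`, `cl`, plus a `per_support`
#'   data frame with the full posterior distribution (weights included) for
#'   the nonparametric engine (single row for MAP).
#' @export
posterior_exposure <- function(fit, reg = NULL) {
  UseMethod("posterior_exposure")
}

.exposure_table <- function(v1, ke, kcp, kpc, weights, reg) {
  ev <- reg$events[nrow(reg$events), ]
  ss <- .steady_state_conc(v1, ke, kcp, kpc, ev$dose, ev$dur, reg$interval_h)
  cl <- ke * v1
  s <- ke + kcp + kpc
  beta <- (s - sqrt(s * s - 4 * ke * kpc)) / 2
  data.frame(
    weight = weights,
    auc24_ss = (24 / reg$interval_h) * ev$dose / cl,
    cmin_ss = ss$cmin, cmax_ss = ss$cmax,
    t_half_terminal = log(2) / beta, cl = cl
  )
}

.exposure_from_table <- function(tab) {
  ex <- lapply(c("auc24_ss", "cmin_ss", "cmax_ss", "t_half_terminal", "cl"),
               function(col) sum(tab$weight * tab[[col]]))
  names(ex) <- c("auc24_ss", "cmin_ss", "cmax_ss", "t_half_terminal", "cl")
  structure(c(ex, list(per_support = tab)), class = "posterior_exposure")
}

#' @export
posterior_exposure.np_fit <- function(fit, reg = NULL) {
  if (is.null(reg)) reg <- fit$reg
  res <- .resolve_support(fit$support, fit$cov)
  .exposure_from_table(.exposure_table(res$v1, res$ke, res$kcp, res$kpc,
                                       fit$weights, reg))
}

#' @export
posterior_exposure.map_fit <- function(fit, reg = NULL) {
  if (is.null(reg)) reg <- fit$reg
  r <- fit$resolved
  .exposure_from_table(.exposure_table(r$v1_abs, r$ke, r$kcp, r$kpc, 1, reg))
}

#' @export
print.posterior_exposure <- function(x, ...) {
  cat(sprintf(
    "Posterior exposure: E[AUC24] = %.1f mg.h/L, E[Cmin] = %.2f mg/L, E[Cmax] = %.2f mg/L\n",
    x$auc24_ss, x$cmin_ss, x$cmax_ss))
  invisible(x)
}
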