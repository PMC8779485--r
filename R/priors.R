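#' Summary moments of the population micro-constants
#'
#' Arithmetic mean and coefficient of variation (as a fraction) per
#' parameter, used to construct a discrete prior when the original support
#' points of a nonparametric population analysis are not available.
#'
#' @param mean Named numeric vector of means with names
#'   `v1_std, ks, ki, kcp, kpc`.
#' @param cv Named numeric vector of coefficients of variation (fractions),
#'   same names.
#' @return An object of class `param_moments`.
#' @export
param_moments <- function(mean, cv) {
  nm <- c("v1_std", "ks", "ki", "kcp", "kpc")
  if (!all(nm %in% names(mean)) || !all(nm %in% names(cv)))
    stop("mean and cv must be named with: ", paste(nm, collapse = ", "),
         call. = FALSE)
  mean <- mean[nm]; cv <- cv[nm]
  if (any(mean <= 0) || any(cv <= 0) || any(!is.finite(c(mean, cv))))
    stop("moments must be positive and finite", call. = FALSE)
  structure(list(mean = mean, cv = cv), class = "param_moments")
}

#' Default population moments for daptomycin in bone and joint infection
#'
#' The published summary statistics of the nonparametric two-compartment
#' population model estimated in adults with bone and joint infection:
#' V1 6.90 L/70 kg (CV 39.4%), Ks 0.050 /h per 100 mL/min CLCR (CV 89.6%),
#' Ki 0.060 /h (CV 83.2%), Kcp 0.693 /h (CV 118.0%), Kpc 0.667 /h (CV 97.7%).
#'
#' @return A [param_moments()] object.
#' @export
default_param_moments <- function() {
  param_moments(
    mean = c(v1_std = 6.90, ks = 0.050, ki = 0.060, kcp = 0.693, kpc = 0.667),
    cv = c(v1_std = 0.394, ks = 0.896, ki = 0.832, kcp = 1.180, kpc = 0.977)
  )
}

#' Discrete nonparametric prior
#'
#' @param support Numeric matrix, one row per support point, columns
#'   `v1_std, ks, ki, kcp, kpc` (all entries positive).
#' @param weights Probability masses, one per support point; must be
#'   non-negative and sum to 1 (renormalized if within 1e-12 of 1, rejected
#'   otherwise).
#' @return An object of class `np_prior`.
#' @export
np_prior <- function(support, weights = NULL) {
  support <- as.matrix(support)
  nm <- c("v1_std", "ks", "ki", "kcp", "kpc")
  if (ncol(support) != 5L)
    stop("support must have 5 columns (v1_std, ks, ki, kcp, kpc)", call. = FALSE)
  colnames(support) <- nm
  if (any(support <= 0) || any(!is.finite(support)))
    stop("all support points must be strictly positive and finite", call. = FALSE)
  n <- nrow(support)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n || any(weights < 0))
    stop("weights must be non-negative, one per support point", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-12)
    stop("weights must sum to 1", call. = FALSE)
  weights <- weights / sum(weights)
  structure(list(support = support, weights = weights), class = "np_prior")
}

#' @export
print.np_prior <- function(x, ...) {
  cat(sprintf("Nonparametric prior: %d support points\n", nrow(x$support)))
  mu <- colSums(x$support * x$weights)
  cat("  weighted means:",
      paste(sprintf("%s=%.3g", names(mu), mu), collapse = "  "), "\n")
  invisible(x)
}

#' Build a discrete prior from summary moments
#'
#' Draws `n_support` support points from independent log-normal
#' distributions whose arithmetic mean and CV match the supplied moments
#' (`sdlog^2 = log(1 + cv^2)`, `meanlog = log(mean) - sdlog^2/2`), with
#' equal weights. Log-normals are chosen for positivity and the right skew
#' typical of PK parameter distributions. Reproducible for a given seed.
#'
#' @param m A [param_moments()] object.
#' @param n_support Number of support points (>= 1).
#' @param seed Integer seed.
#' @return An [np_prior()] object. With `n_support = 1` the single point sits
#'   exactly at the means.
#' @export
build_np_prior <- function(m, n_support = 1000L, seed = 1L) {
  stopifnot(inherits(m, "param_moments"))
  n_support <- as.integer(n_support)
  if (n_support < 1L) stop("n_support must be >= 1", call. = FALSE)
  if (n_support == 1L) {
    return(np_prior(matrix(m$mean, nrow = 1,
                           dimnames = list(NULL, names(m$mean)))))
  }
  sdlog <- sqrt(log(1 + m$cv^2))
  meanlog <- log(m$mean) - sdlog^2 / 2
  support <- .with_seed(seed, {
    vapply(seq_along(meanlog),
           function(j) stats::rlnorm(n_support, meanlog[j], sdlog[j]),
           numeric(n_support))
  })
  colnames(support) <- names(m$mean)
  np_prior(support)
}

# Evaluate expr under a temporary RNG state; restores the caller's stream.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Parametric population prior (clearance parameterization)
#'
#' Typical values of CL, V1, Q and V2 with log-normal between-subject
#' variability and an explicit covariate model: creatinine clearance and sex
#' act on CL, body weight acts on Q and V2 (power of weight/70). Body
#' temperature is deliberately not part of the covariate model. The CLCR
#' effect form must be declared: `"linear_renal"` models
#' `CL = tv_cl * ((1 - f_renal) + f_renal * clcr/100)` (a renal/non-renal
#' split), `"power"` models `CL = tv_cl * (clcr/100)^theta_clcr`.
#'
#' @param tv_cl,tv_v1,tv_q,tv_v2 Typical values (L/h, L, L/h, L) at the
#'   reference covariates (70 kg, CLCR 100 mL/min, female).
#' @param omega Named numeric vector of between-subject standard deviations
#'   on the log scale for `cl, v1, q, v2` (>= 0; 0 fixes the parameter).
#'   Defaults propagate the micro-constant CVs to the clearance
#'   parameterization (delta method, independence assumed) and convert to
#'   log-normal sd via `sqrt(log(1 + cv^2))`.
#' @param clcr_form `"linear_renal"` or `"power"`.
#' @param f_renal Renal fraction of clearance at CLCR 100 (linear_renal form).
#' @param theta_clcr Exponent of clcr/100 (power form).
#' @param male_cl_factor Multiplicative sex effect on CL for males (> 0).
#' @param wt_exp_q,wt_exp_v2 Exponents of weight/70 on Q and V2.
#' @return An object of class `parametric_prior`.
#' @export
parametric_prior <- function(tv_cl, tv_v1, tv_q, tv_v2,
                             omega = c(cl = 0.65, v1 = 0.38, q = 0.95, v2 = 1.1),
                             clcr_form = c("linear_renal", "power"),
                             f_renal = 0.4545, theta_clcr = 0.75,
                             male_cl_factor = 1, wt_exp_q = 1, wt_exp_v2 = 1) {
  clcr_form <- match.arg(clcr_form)
  tv <- c(cl = tv_cl, v1 = tv_v1, q = tv_q, v2 = tv_v2)
  if (any(tv <= 0) || any(!is.finite(tv)))
    stop("typical values must be positive and finite", call. = FALSE)
  nm <- c("cl", "v1", "q", "v2")
  if (!all(nm %in% names(omega))) stop("omega must name cl, v1, q, v2", call. = FALSE)
  omega <- omega[nm]
  if (any(omega < 0)) stop("omega must be >= 0", call. = FALSE)
  if (male_cl_factor <= 0) stop("male_cl_factor must be > 0", call. = FALSE)
  structure(list(tv = tv, omega = omega, clcr_form = clcr_form,
                 f_renal = f_renal, theta_clcr = theta_clcr,
                 male_cl_factor = male_cl_factor,
                 wt_exp_q = wt_exp_q, wt_exp_v2 = wt_exp_v2),
            class = "parametric_prior")
}

#' Default parametric prior
#'
#' Typical values derived from the nonparametric population moments
#' converted to the clearance parameterization at reference covariates
#' (70 kg, CLCR 100 mL/min): CL = 0.759 L/h, V1 = 6.90 L, Q = 4.782 L/h,
#' V2 = 7.169 L, with a renal-fraction linear CLCR effect matching the
#' Ks/Ki split and a neutral sex effect. Intended as a self-contained,
#' documented default; published manufacturer coefficients can be supplied
#' through [parametric_prior()] or a config file instead.
#'
#' @return A `parametric_prior` object.
#' @export
default_parametric_prior <- function() {
  m <- default_param_moments()$mean
  ke_ref <- m[["ks"]] + m[["ki"]] # at CLCR = 100 mL/min
  v1 <- m[["v1_std"]]
  q <- m[["kcp"]] * v1
  parametric_prior(
    tv_cl = ke_ref * v1, tv_v1 = v1, tv_q = q, tv_v2 = q / m[["kpc"]],
    clcr_form = "linear_renal", f_renal = m[["ks"]] / ke_ref
  )
}

# Covariate multipliers on (cl, v1, q, v2); returns named vector.
.parametric_multipliers <- function(p, cov) {
  clcr_mult <- switch(p$clcr_form,
    linear_renal = (1 - p$f_renal) + p$f_renal * cov$clcr_ml_min / 100,
    power = (cov$clcr_ml_min / 100)^p$theta_clcr
  )
  sex_mult <- if (cov$sex == "M") p$male_cl_factor else 1
  w <- cov$weight_kg / 70
  c(cl = clcr_mult * sex_mult, v1 = 1, q = w^p$wt_exp_q, v2 = w^p$wt_exp_v2)
}

#' Resolve the parametric prior at a patient's covariates
#'
#' Applies the covariate model to the typical values and converts the
#' clearance parameterization to micro-constants (`ke = CL/V1`,
#' `kcp = Q/V1`, `kpc = Q/V2`).
#'
#' @param p A [parametric_prior()] object.
#' @param cov A [covariates()] object.
#' @return A [resolved_pk()] object (the covariate-adjusted typical
#'   individual).
#' @export
resolve_parametric <- function(p, cov) {
  stopifnot(inherits(p, "parametric_prior"), inherits(cov, "pk_covariates"))
  mult <- .parametric_multipliers(p, cov)
  if (any(mult <= 0) || any(!is.finite(mult)))
    stop("covariate multiplier must be positive; check covariates and ",
         "covariate-model coefficients", call. = FALSE)
  tv <- p$tv * mult
  macro_to_micro(tv[["cl"]], tv[["v1"]], tv[["q"]], tv[["v2"]])
}

#' Residual (assay) error model
#'
#' Polynomial standard deviation
#' `sigma(C) = c0 + c1*C + c2*C^2 + c3*C^3`, mg/L, evaluated at the
#' model-predicted concentration, plus the assay's lower limit of
#' quantification. Defaults: `c0 = 0.5` mg/L (a quarter of the 2 mg/L LLOQ)
#' and `c1 = 0.1` (roughly the assay's stated interday precision).
#'
#' @param c0 Additive term, mg/L.
#' @param c1,c2,c3 Proportional, quadratic, cubic coefficients.
#' @param lloq Lower limit of quantification, mg/L.
#' @return An object of class `assay_error`.
#' @export
assay_error <- function(c0 = 0.5, c1 = 0.1, c2 = 0, c3 = 0, lloq = 2) {
  if (lloq <= 0) stop("lloq must be > 0", call. = FALSE)
  e <- structure(list(c0 = c0, c1 = c1, c2 = c2, c3 = c3, lloq = lloq),
                 class = "assay_error")
  probe <- assay_sd(e, c(0, 1, 10, 100, 1000))
  if (any(probe <= 0) || any(!is.finite(probe)))
    stop("error polynomial must be strictly positive for all C >= 0",
         call. = FALSE)
  e
}

#' Assay standard deviation at a concentration
#'
#' @param e An [assay_error()] object.
#' @param conc Concentration(s), mg/L (>= 0).
#' @return Standard deviation(s), mg/L.
#' @export
assay_sd <- function(e, conc) {
  stopifnot(inherits(e, "assay_error"))
  if (any(conc < 0)) stop("conc must be >= 0", call. = FALSE)
  sd <- e$c0 + e$c1 * conc + e$c2 * conc^2 + e$c3 * conc^3
  if (any(sd <= 0)) stop("assay error polynomial produced non-positive sd",
                         call. = FALSE)
  sd
}

#' Read model, error and target definitions from a config file
#'
#' Accepts YAML or JSON (decided by file extension). Recognized top-level
#' blocks: `np_moments` (mean/cv lists), `np_support` (explicit support
#' table with optional weights), `parametric` (arguments of
#' [parametric_prior()]), `error` (arguments of [assay_error()]), `targets`
#' (`auc_target`, `cmin_limit`), `template` (`interval_h`,
#' `infusion_duration_h`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `np_moments` ([param_moments()] or NULL),
#'   `np_support` ([np_prior()] or NULL), `parametric`
#'   ([parametric_prior()] or NULL), `error` ([assay_error()]), `targets`
#'   ([exposure_targets()]), `template` (list).
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("config must be .yaml, .yml or .json", call. = FALSE)
  )
  out <- list(np_moments = NULL, np_support = NULL, parametric = NULL)
  if (!is.null(raw$np_moments)) {
    out$np_moments <- param_moments(unlist(raw$np_moments$mean),
                                    unlist(raw$np_moments$cv))
  }
  if (!is.null(raw$np_support)) {
    sup <- as.matrix(as.data.frame(raw$np_support[c("v1_std", "ks", "ki",
                                                    "kcp", "kpc")]))
    out$np_support <- np_prior(sup, raw$np_support$weights)
  }
  if (!is.null(raw$parametric)) {
    out$parametric <- do.call(parametric_prior, lapply(raw$parametric, unlist))
  }
  out$error <- if (is.null(raw$error)) assay_error()
               else do.call(assay_error, raw$error)
  out$targets <- if (is.null(raw$targets)) exposure_targets()
                 else do.call(exposure_targets, raw$targets)
  out$template <- utils::modifyList(list(interval_h = 24,
                                         infusion_duration_h = 0.5),
                                    if (is.null(raw$template)) list()
                                    else raw$template)
  out
}
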