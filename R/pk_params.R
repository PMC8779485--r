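#' Micro-constant parameters of the two-compartment daptomycin model
#'
#' Container for the five population parameters of the rate-constant
#' parameterization: central volume of distribution standardized to a 70 kg
#' body weight, the renal (`ks`) and non-renal (`ki`) components of the
#' elimination rate constant, and the central-to-peripheral (`kcp`) and
#' peripheral-to-central (`kpc`) transfer rate constants. The individual
#' elimination rate constant is `ke = ks * (clcr/100) + ki`, so `ks` carries
#' units of 1/h per 100 mL/min of creatinine clearance.
#'
#' @param v1_std Central volume of distribution, L per 70 kg body weight.
#' @param ks Renal elimination rate component, 1/h per 100 mL/min of CLCR.
#' @param ki Non-renal elimination rate constant, 1/h.
#' @param kcp Central-to-peripheral transfer rate constant, 1/h.
#' @param kpc Peripheral-to-central transfer rate constant, 1/h.
#'
#' @return An object of class `pk_microparams`.
#' @examples
#' pk_microparams(v1_std = 6.90, ks = 0.050, ki = 0.060, kcp = 0.693, kpc = 0.667)
#' @export
pk_microparams <- function(v1_std, ks, ki, kcp, kpc) {
  p <- c(v1_std = as.numeric(v1_std), ks = as.numeric(ks), ki = as.numeric(ki),
         kcp = as.numeric(kcp), kpc = as.numeric(kpc))
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("all micro-constant parameters must be strictly positive and finite",
         call. = FALSE)
  }
  structure(as.list(p), class = "pk_microparams")
}

#' Patient covariates
#'
#' @param weight_kg Body weight, kg (must be > 0).
#' @param clcr_ml_min Creatinine clearance (Cockcroft-Gault), mL/min (>= 0).
#' @param sex `"F"` or `"M"`.
#' @param age_years Optional age in years (carried through, not used by the
#'   PK model itself).
#'
#' @return An object of class `pk_covariates`.
#' @export
covariates <- function(weight_kg, clcr_ml_min, sex = c("F", "M"),
                       age_years = NA_real_) {
  sex <- match.arg(sex)
  weight_kg <- as.numeric(weight_kg)
  clcr_ml_min <- as.numeric(clcr_ml_min)
  if (!is.finite(weight_kg) || weight_kg <= 0)
    stop("weight_kg must be positive and finite", call. = FALSE)
  if (!is.finite(clcr_ml_min) || clcr_ml_min < 0)
    stop("clcr_ml_min must be non-negative and finite", call. = FALSE)
  structure(list(weight_kg = weight_kg, clcr_ml_min = clcr_ml_min,
                 sex = sex, age_years = as.numeric(age_years)),
            class = "pk_covariates")
}

#' Resolve population micro-constants to an individual parameter set
#'
#' Applies the covariate model of the nonparametric population model:
#' the central volume scales linearly with body weight
#' (`v1_abs = v1_std * weight/70`) and the elimination rate constant splits
#' into a renal component proportional to creatinine clearance and a
#' non-renal component (`ke = ks * (clcr/100) + ki`). Transfer constants are
#' covariate-free. Total body clearance is derived as `cl = ke * v1_abs`.
#'
#' @param p A [pk_microparams()] object.
#' @param cov A [covariates()] object.
#'
#' @return An object of class `resolved_pk` with fields `v1_abs` (L), `ke`,
#'   `kcp`, `kpc` (1/h) and `cl` (L/h).
#' @examples
#' p <- pk_microparams(6.90, 0.050, 0.060, 0.693, 0.667)
#' resolve_parameters(p, covariates(70, 100, "F"))
#' @export
resolve_parameters <- function(p, cov) {
  stopifnot(inherits(p, "pk_microparams"), inherits(cov, "pk_covariates"))
  v1_abs <- p$v1_std * cov$weight_kg / 70
  ke <- p$ks * (cov$clcr_ml_min / 100) + p$ki
  resolved_pk(v1_abs = v1_abs, ke = ke, kcp = p$kcp, kpc = p$kpc)
}

#' Individual (resolved) two-compartment parameters
#'
#' @param v1_abs Central volume, L.
#' @param ke Elimination rate constant, 1/h.
#' @param kcp,kpc Transfer rate constants, 1/h.
#' @return An object of class `resolved_pk`; `cl` is always `ke * v1_abs`.
#' @export
resolved_pk <- function(v1_abs, ke, kcp, kpc) {
  vals <- c(v1_abs = v1_abs, ke = ke, kcp = kcp, kpc = kpc)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("invalid resolved parameters: all of v1_abs, ke, kcp, kpc must be ",
         "strictly positive and finite", call. = FALSE)
  }
  structure(list(v1_abs = v1_abs, ke = ke, kcp = kcp, kpc = kpc,
                 cl = ke * v1_abs),
            class = "resolved_pk")
}

#' @export
print.resolved_pk <- function(x, ...) {
  cat("Two-compartment individual parameters\n")
  cat(sprintf("  V1 = %.3f L   Ke = %.4f 1/h   Kcp = %.4f 1/h   Kpc = %.4f 1/h\n",
              x$v1_abs, x$ke, x$kcp, x$kpc))
  cat(sprintf("  CL = %.4f L/h   terminal t1/2 = %.2f h\n",
              x$cl, terminal_half_life(x)))
  invisible(x)
}

#' Convert micro-constants to the clearance parameterization
#'
#' `CL = ke * V1`, `Q = kcp * V1`, `V2 = Q / kpc`.
#'
#' @param r A [resolved_pk()] object.
#' @return Named numeric vector with `cl`, `v1`, `q`, `v2`.
#' @export
micro_to_macro <- function(r) {
  stopifnot(inherits(r, "resolved_pk"))
  q <- r$kcp * r$v1_abs
  c(cl = r$ke * r$v1_abs, v1 = r$v1_abs, q = q, v2 = q / r$kpc)
}

#' Convert clearance parameterization to micro-constants
#'
#' Inverse of [micro_to_macro()]: `ke = CL/V1`, `kcp = Q/V1`, `kpc = Q/V2`.
#'
#' @param cl Clearance, L/h.
#' @param v1 Central volume, L.
#' @param q Intercompartmental clearance, L/h.
#' @param v2 Peripheral volume, L.
#' @return A [resolved_pk()] object.
#' @export
macro_to_micro <- function(cl, v1, q, v2) {
  resolved_pk(v1_abs = v1, ke = cl / v1, kcp = q / v1, kpc = q / v2)
}
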