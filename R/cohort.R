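#' Configuration of a virtual TDM cohort
#'
#' Defaults reproduce the covariate distributions, dosing practice and
#' sparse sampling design of an adult bone-and-joint-infection TDM
#' population: weight 76 +/- 18 kg, creatinine clearance 103 +/- 56 mL/min,
#' 42.5% women, age 62 +/- 17 y, initial dose 7.6 +/- 1.3 mg/kg/day, and a
#' three-sample occasion (pre-dose trough, ~30 min after administration,
#' and 5-6 h post dose) with +/- 15 min sampling-time jitter.
#'
#' @param n_patients Number of virtual patients (>= 1).
#' @param weight_mean,weight_sd Body weight distribution, kg (truncated
#'   below 30 kg).
#' @param clcr_mean,clcr_sd Creatinine clearance distribution, mL/min
#'   (truncated below 10).
#' @param frac_female Fraction of women.
#' @param age_mean,age_sd Age distribution, years (truncated to 18-100).
#' @param dose_mean_mg_kg,dose_sd_mg_kg Daily dose policy, mg/kg/day.
#' @param occasion Index of the dose around which samples are drawn
#'   (default 5, near steady state for a ~13-17 h terminal half-life).
#' @param pre_dose_h Nominal pre-dose sampling offset before the occasion
#'   dose, h.
#' @param peak_offset_h Nominal offset of the early sample, h (default 0.5).
#' @param peak_after `"start"` (default) or `"end"`: whether the early
#'   sample offset counts from infusion start or infusion end.
#' @param late_window_h Two-element window for the late sample, h after the
#'   occasion dose start.
#' @param jitter_h Half-width of the uniform sampling-time jitter, h.
#' @param infusion_duration_h Infusion duration, h.
#' @param interval_h Dosing interval, h.
#' @param noise_scale Multiplier on the assay error sd when generating
#'   observations (0 gives noiseless data).
#' @param seed Integer seed; the generator is fully reproducible.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 100L,
                          weight_mean = 76, weight_sd = 18,
                          clcr_mean = 103, clcr_sd = 56,
                          frac_female = 0.425,
                          age_mean = 62, age_sd = 17,
                          dose_mean_mg_kg = 7.6, dose_sd_mg_kg = 1.3,
                          occasion = 5L,
                          pre_dose_h = 0.25,
                          peak_offset_h = 0.5,
                          peak_after = c("start", "end"),
                          late_window_h = c(5, 6),
                          jitter_h = 0.25,
                          infusion_duration_h = 0.5,
                          interval_h = 24,
                          noise_scale = 1,
                          seed = 1L) {
  peak_after <- match.arg(peak_after)
  if (n_patients < 1L) stop("n_patients must be >= 1", call. = FALSE)
  sds <- c(weight_sd, clcr_sd, age_sd, dose_sd_mg_kg, jitter_h)
  if (any(sds < 0)) stop("spread parameters must be >= 0", call. = FALSE)
  if (frac_female < 0 || frac_female > 1)
    stop("frac_female must be in [0, 1]", call. = FALSE)
  structure(as.list(environment()), class = "cohort_config")
}

# Truncated-normal draws by rejection; bounds are wide relative to the sd so
# rejection is cheap.
.rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (lower >= upper) stop("impossible truncation bounds", call. = FALSE)
  if (sd == 0) {
    if (mean < lower || mean > upper)
      stop("impossible truncation bounds for a degenerate distribution",
           call. = FALSE)
    return(rep(mean, n))
  }
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

#' Generate a virtual TDM cohort
#'
#' Draws covariates from truncated normals, samples each patient's true
#' micro-constants from the prior's support (by weight), doses at
#' `round(policy draw * weight)` mg every `interval_h` h up to the sampling
#' occasion, simulates the three-sample design with timing jitter, adds
#' assay noise from the error model, and left-censors values below the
#' LLOQ (flagged). The generating truth (parameters and steady-state
#' exposure) is retained on each patient for recovery testing.
#'
#' @param cfg A [cohort_config()].
#' @param prior An [np_prior()] supplying the true parameter distribution.
#' @param error An [assay_error()] model (noise and LLOQ).
#' @return An object of class `tdm_cohort`: a list of `virtual_patient`
#'   objects, each with `id`, `cov`, `true_params`, `reg`, `obs` (an
#'   [observation_set()]) and `true_exposure` ([steady_state_metrics()] at
#'   the patient's own regimen).
#' @export
generate_cohort <- function(cfg, prior, error = assay_error()) {
  stopifnot(inherits(cfg, "cohort_config"), inherits(prior, "np_prior"))
  n <- cfg$n_patients
  .with_seed(cfg$seed, {
    wt <- .rtnorm(n, cfg$weight_mean, cfg$weight_sd, lower = 30)
    clcr <- .rtnorm(n, cfg$clcr_mean, cfg$clcr_sd, lower = 10)
    age <- .rtnorm(n, cfg$age_mean, cfg$age_sd, lower = 18, upper = 100)
    sex <- ifelse(stats::runif(n) < cfg$frac_female, "F", "M")
    mgkg <- .rtnorm(n, cfg$dose_mean_mg_kg, cfg$dose_sd_mg_kg, lower = 0.5)
    pick <- sample.int(nrow(prior$support), n, replace = TRUE,
                       prob = prior$weights)
    occ_start <- (cfg$occasion - 1) * cfg$interval_h
    lapply(seq_len(n), function(i) {
      cov <- covariates(wt[i], clcr[i], sex[i], age[i])
      truth <- do.call(pk_microparams, as.list(prior$support[pick[i], ]))
      dose <- max(1, round(mgkg[i] * wt[i]))
      reg <- dosing_regimen(
        dose_mg = dose,
        start_time_h = (seq_len(cfg$occasion) - 1) * cfg$interval_h,
        infusion_duration_h = cfg$infusion_duration_h,
        interval_h = cfg$interval_h)
      jit <- function() if (cfg$jitter_h > 0)
        stats::runif(1, -cfg$jitter_h, cfg$jitter_h) else 0
      t_pre <- min(occ_start - 1 / 60,
                   occ_start - cfg$pre_dose_h + jit())
      t_peak <- occ_start + cfg$peak_offset_h + jit() +
        if (cfg$peak_after == "end") cfg$infusion_duration_h else 0
      t_late <- occ_start + stats::runif(1, cfg$late_window_h[1],
                                         cfg$late_window_h[2]) + jit()
      times <- c(t_pre, t_peak, t_late)
      r <- resolve_parameters(truth, cov)
      ctrue <- predict_concentrations(r, reg, times)
      cobs <- pmax(0, ctrue + cfg$noise_scale *
                     stats::rnorm(3, 0, assay_sd(error, ctrue)))
      blq <- cobs < error$lloq
      structure(list(
        id = i, cov = cov, true_params = truth, reg = reg,
        obs = observation_set(times, cobs, blq, cov, reg, lloq = error$lloq),
        true_exposure = steady_state_metrics(r, reg)
      ), class = "virtual_patient")
    })
  }) -> patients
  structure(patients, class = "tdm_cohort")
}

#' @export
print.tdm_cohort <- function(x, ...) {
  nobs <- sum(vapply(x, function(p) length(p$obs$time_h), numeric(1)))
  nblq <- sum(vapply(x, function(p) sum(p$obs$below_lloq), numeric(1)))
  cat(sprintf("Virtual TDM cohort: %d patients, %d observations (%d below LLOQ)\n",
              length(x), nobs, nblq))
  invisible(x)
}

#' Write a cohort as a NONMEM-style event-record table
#'
#' One row per event: infusions as `EVID = 1` rows with `AMT` (mg) and
#' `RATE` (mg/h), observations as `EVID = 0` rows with the measurement in
#' `DV` and `MDV = 0`. Covariates (`WT`, `CLCR`, `SEX` coded 0 = F / 1 = M,
#' `AGE`) repeat on every row. Below-LLOQ observations carry `BLQ = 1` with
#' `DV` set to the LLOQ (the censoring bound), `BLQ = 0` rows carry the
#' measured value. Missing numeric cells are written as `"."` in the CSV.
#'
#' @param cohort A `tdm_cohort`, or any list of patient records with `id`,
#'   `cov`, `reg`, `obs`.
#' @param file Optional path; when given, the table is also written as CSV.
#' @param lloq LLOQ written into censored `DV` cells, mg/L.
#' @return The event-record `data.frame`, invisibly when `file` is given.
#' @export
write_dataset <- function(cohort, file = NULL, lloq = 2) {
  rows <- lapply(cohort, function(p) {
    covrow <- data.frame(WT = p$cov$weight_kg, CLCR = p$cov$clcr_ml_min,
                         SEX = as.integer(p$cov$sex == "M"),
                         AGE = p$cov$age_years)
    ev <- p$reg$events
    d <- data.frame(ID = p$id, TIME = ev$start, AMT = ev$dose,
                    RATE = ev$dose / ev$dur, DV = NA_real_,
                    EVID = 1L, MDV = 1L, BLQ = 0L, covrow)
    o <- data.frame(ID = p$id, TIME = p$obs$time_h, AMT = NA_real_,
                    RATE = NA_real_,
                    DV = ifelse(p$obs$below_lloq, lloq, p$obs$conc_mg_l),
                    EVID = 0L, MDV = 0L,
                    BLQ = as.integer(p$obs$below_lloq), covrow)
    x <- rbind(d, o)
    x[order(x$TIME, -x$EVID), ]
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(file)) {
    out <- tab
    for (col in names(out)) out[[col]] <- ifelse(is.na(out[[col]]), ".",
                                                 as.character(out[[col]]))
    utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Read a NONMEM-style event-record table into patient records
#'
#' Inverse of [write_dataset()] minus the simulation truth: parses dose
#' events (`EVID = 1`, infusion duration recovered as `AMT/RATE`),
#' observations (`EVID = 0`, censoring from `BLQ`) and covariates. The
#' dosing interval is inferred as the median gap between consecutive dose
#' starts (24 h for single-dose histories).
#'
#' @param x Path to a CSV written by [write_dataset()] (with `"."` for
#'   missing) or an equivalent `data.frame`.
#' @param lloq LLOQ used to validate censoring flags, mg/L.
#' @return A list of patient records (class `tdm_patients`), each with
#'   `id`, `cov`, `reg` and `obs`.
#' @export
read_dataset <- function(x, lloq = 2) {
  tab <- if (is.character(x)) {
    utils::read.csv(x, na.strings = ".", stringsAsFactors = FALSE)
  } else as.data.frame(x)
  needed <- c("ID", "TIME", "AMT", "RATE", "DV", "EVID", "MDV",
              "WT", "CLCR", "SEX")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols))
    stop("dataset is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!"BLQ" %in% names(tab)) tab$BLQ <- 0L
  if (!"AGE" %in% names(tab)) tab$AGE <- NA_real_
  bad <- which(!(tab$EVID %in% c(0L, 1L)))
  if (length(bad))
    stop("malformed rows (EVID must be 0 or 1): row ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  patients <- lapply(split(tab, tab$ID), function(px) {
    px <- px[order(px$TIME, -px$EVID), ]
    dv_rows <- px[px$EVID == 0L, , drop = FALSE]
    dose_rows <- px[px$EVID == 1L, , drop = FALSE]
    if (nrow(dose_rows) == 0L)
      stop("patient ", px$ID[1], " has no dose events", call. = FALSE)
    if (any(is.na(dose_rows$AMT)) || any(is.na(dose_rows$RATE)))
      stop("patient ", px$ID[1], ": dose rows need AMT and RATE",
           call. = FALSE)
    starts <- dose_rows$TIME
    interval <- if (length(starts) > 1) stats::median(diff(starts)) else 24
    cov <- covariates(px$WT[1], px$CLCR[1],
                      if (px$SEX[1] == 1) "M" else "F", px$AGE[1])
    reg <- dosing_regimen(dose_mg = dose_rows$AMT, start_time_h = starts,
                          infusion_duration_h = dose_rows$AMT / dose_rows$RATE,
                          interval_h = interval)
    blq <- dv_rows$BLQ == 1L
    conc <- dv_rows$DV
    conc[blq] <- pmin(conc[blq], lloq - 1e-9) # DV holds the censoring bound
    obs <- observation_set(dv_rows$TIME, conc, blq, cov, reg, lloq = lloq)
    list(id = px$ID[1], cov = cov, reg = reg, obs = obs)
  })
  names(patients) <- NULL
  structure(patients[order(vapply(patients, function(p) p$id, numeric(1)))],
            class = "tdm_patients")
}
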