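# Shared fixtures: population values, random parameter generators, a
# rich-design simulated patient, and small independent oracles.

pop_means <- function() default_param_moments()$mean

typical_resolved <- function(weight = 70, clcr = 100) {
  resolve_parameters(do.call(pk_microparams, as.list(pop_means())),
                     covariates(weight, clcr, "F"))
}

# Random but physiologically plausible two-compartment parameter sets.
random_resolved <- function() {
  resolved_pk(v1_abs = runif(1, 3, 20),
              ke = runif(1, 0.02, 0.4),
              kcp = runif(1, 0.05, 2),
              kpc = runif(1, 0.05, 2))
}

random_regimen <- function() {
  n_dose <- sample(1:6, 1)
  dosing_regimen(dose_mg = runif(1, 200, 900),
                 start_time_h = (seq_len(n_dose) - 1) * 24,
                 infusion_duration_h = runif(1, 0.25, 2),
                 interval_h = 24)
}

# A simulated patient with a dense, informative sampling design.
rich_patient <- function(truth_r, cov = covariates(70, 100, "F"),
                         dose = 500, n_dose = 5, noise = 0,
                         error = assay_error()) {
  reg <- dosing_regimen(dose, (seq_len(n_dose) - 1) * 24, 0.5, 24)
  t0 <- (n_dose - 1) * 24
  times <- t0 + c(0.25, 0.5, 0.75, 1.5, 3, 6, 12, 23.5)
  ctrue <- predict_concentrations(truth_r, reg, times)
  cobs <- pmax(0, ctrue + noise * rnorm(length(times), 0,
                                        assay_sd(error, ctrue)))
  blq <- cobs < error$lloq
  observation_set(times, cobs, blq, cov, reg, lloq = error$lloq)
}

# Exact two-sided signed-rank p-value by enumeration of all sign patterns
# (ties and zeros not handled; fixtures avoid them).
signed_rank_p_enum <- function(d) {
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- drop(signs %*% rk)
  p <- 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs))
  min(p, 1)
}
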