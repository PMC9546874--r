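#' Parameters of the CDK4/6-Rb-E2F-CDK2 commitment circuit
#'
#' Builds the generative parameter set for [simulate_population()]. The model
#' is phenomenological: per cell, CDK4/6 activity rises saturatingly after a
#' stochastic onset; Rb is inactive while CDK4/6 activity exceeds `theta_rb`
#' or once CDK2 activity has ever exceeded `theta_commit` (the commitment
#' latch); an E2F driver integrates while Rb is inactive; CDK2 activity is
#' produced from the E2F driver plus a saturating positive-feedback term,
#' gated on the Rb-inactive state, and relaxes toward `a2_baseline`
#' otherwise. Observed reporter values add cross-talk (`crosstalk_rho` of
#' CDK2 activity leaks into the CDK4/6 reporter) and Gaussian noise.
#'
#' @param p_active Probability a cell activates CDK4/6 within the horizon.
#' @param onset_min Earliest CDK4/6 activation onset, hours after
#'   stimulation. Default 3 h.
#' @param onset_scale Scale (mean) of the shifted-exponential onset
#'   distribution, hours.
#' @param a46_max Plateau CDK4/6 activity, reporter ratio units.
#' @param rise_tau CDK4/6 activation time constant, hours.
#' @param theta_rb CDK4/6 activity above which Rb is inactivated.
#' @param e2f_rate,e2f_decay Production (while Rb inactive) and decay rates
#'   of the E2F driver, per hour.
#' @param cdk2_rate CDK2 production per E2F-driver unit per hour.
#' @param cdk2_fb CDK2 positive-feedback production rate, per hour.
#' @param cdk2_decay CDK2 relaxation rate toward baseline, per hour.
#' @param a2_baseline Quiescent CDK2 activity on the reporter scale.
#' @param a2_max Saturating ceiling of CDK2 activity.
#' @param theta_commit CDK2 activity that engages the commitment latch
#'   (irreversible Rb inactivation). Default 1 reporter unit.
#' @param theta_on2 CDK2 activity defining the true CDK2-on event recorded
#'   in the cell truth table. Default 0.6, the cohort-selection gate.
#' @param theta_apc CDK2 activity at APC/C-Cdh1 inactivation (degron onset).
#' @param degron_rate Linear rise rate of the APC/C degron after onset,
#'   arbitrary units per hour.
#' @param crosstalk_rho Fraction of CDK2 activity read by the CDK4/6
#'   reporter. Default 0.35.
#' @param noise_sd Observation noise s.d., reporter units.
#' @param dt Sampling interval, hours. Default 0.2 (12 min).
#' @param horizon Simulated duration, hours.
#' @param mrna_base,mrna_per_e2f Poisson mean of FISH puncta per cell:
#'   `mrna_base + mrna_per_e2f * E2F(horizon)`.
#'
#' @return An object of class `circuit_params` (a named list).
#' @seealso [calib_paper_params()] for the packaged calibrated defaults.
#' @export
circuit_params <- function(p_active = 0.6,
                           onset_min = 3,
                           onset_scale = 6,
                           a46_max = 1.5,
                           rise_tau = 1,
                           theta_rb = 0.3,
                           e2f_rate = 0.25,
                           e2f_decay = 0.25,
                           cdk2_rate = 0.12,
                           cdk2_fb = 0.75,
                           cdk2_decay = 0.25,
                           a2_baseline = 0.1,
                           a2_max = 2.8,
                           theta_commit = 1,
                           theta_on2 = 0.6,
                           theta_apc = 1.2,
                           degron_rate = 1,
                           crosstalk_rho = 0.35,
                           noise_sd = 0.05,
                           dt = 0.2,
                           horizon = 14,
                           mrna_base = 2,
                           mrna_per_e2f = 30) {
  p <- list(
    p_active = p_active, onset_min = onset_min, onset_scale = onset_scale,
    a46_max = a46_max, rise_tau = rise_tau, theta_rb = theta_rb,
    e2f_rate = e2f_rate, e2f_decay = e2f_decay,
    cdk2_rate = cdk2_rate, cdk2_fb = cdk2_fb, cdk2_decay = cdk2_decay,
    a2_baseline = a2_baseline, a2_max = a2_max,
    theta_commit = theta_commit, theta_on2 = theta_on2,
    theta_apc = theta_apc, degron_rate = degron_rate,
    crosstalk_rho = crosstalk_rho, noise_sd = noise_sd,
    dt = dt, horizon = horizon,
    mrna_base = mrna_base, mrna_per_e2f = mrna_per_e2f
  )
  class(p) <- "circuit_params"
  validate_circuit_params(p)
  p
}

validate_circuit_params <- function(p) {
  stopifnot(inherits(p, "circuit_params"))
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("circuit_params: all fields must be finite scalars; offending: ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  }
  rates <- c("onset_scale", "a46_max", "rise_tau", "theta_rb", "e2f_rate",
             "e2f_decay", "cdk2_rate", "cdk2_fb", "cdk2_decay", "a2_baseline",
             "theta_on2", "theta_apc", "degron_rate", "noise_sd",
             "mrna_base", "mrna_per_e2f")
  bad <- rates[vapply(rates, function(f) p[[f]] < 0, logical(1))]
  if (length(bad)) {
    stop("circuit_params: negative rate(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (p$p_active < 0 || p$p_active > 1)
    stop("circuit_params: p_active must lie in [0, 1]", call. = FALSE)
  if (p$dt <= 0) stop("circuit_params: dt must be > 0", call. = FALSE)
  if (p$horizon <= 0) stop("circuit_params: horizon must be > 0", call. = FALSE)
  if (p$theta_commit <= 0)
    stop("circuit_params: theta_commit must be positive", call. = FALSE)
  if (p$crosstalk_rho < 0 || p$crosstalk_rho >= 1)
    stop("circuit_params: crosstalk_rho must lie in [0, 1)", call. = FALSE)
  if (p$a2_max <= p$a2_baseline)
    stop("circuit_params: a2_max must exceed a2_baseline", call. = FALSE)
  invisible(p)
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("<circuit_params>\n")
  flds <- unlist(x)
  for (nm in names(flds)) cat(sprintf("  %-14s %g\n", nm, flds[[nm]]))
  invisible(x)
}

#' Perturbation applied to the commitment circuit
#'
#' Describes a treatment that shuts off CDK4/6 production at `t_treat`.
#' Rapid modes (`rapid_inhibitor`, modelling a CDK4/6 inhibitor such as
#' palbociclib, and `ncs_pulse`, modelling a DNA-damage pulse) start an
#' exponential decay of CDK4/6 activity immediately at `t_treat`;
#' `mitogen_withdrawal` starts it after a per-cell uniform delay drawn from
#' `withdrawal_delay_range` (default 4-5 h).
#'
#' @param mode One of `"none"`, `"rapid_inhibitor"`, `"ncs_pulse"`,
#'   `"mitogen_withdrawal"`.
#' @param t_treat Treatment time, hours after stimulation.
#' @param fast_decay_tau CDK4/6 decay time constant once shut off, hours.
#' @param withdrawal_delay_range Length-2 numeric, bounds (h) of the uniform
#'   per-cell lag before decay in withdrawal mode.
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(mode = c("none", "rapid_inhibitor", "ncs_pulse",
                                       "mitogen_withdrawal"),
                              t_treat = 11,
                              fast_decay_tau = 0.1,
                              withdrawal_delay_range = c(4, 5)) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(t_treat), length(t_treat) == 1, t_treat >= 0,
            is.numeric(fast_decay_tau), fast_decay_tau > 0,
            is.numeric(withdrawal_delay_range),
            length(withdrawal_delay_range) == 2)
  if (any(withdrawal_delay_range < 0) ||
      withdrawal_delay_range[1] > withdrawal_delay_range[2]) {
    stop("perturbation_spec: withdrawal_delay_range must be ordered and >= 0",
         call. = FALSE)
  }
  structure(list(mode = mode, t_treat = t_treat,
                 fast_decay_tau = fast_decay_tau,
                 withdrawal_delay_range = withdrawal_delay_range),
            class = "perturbation_spec")
}

#' @export
print.perturbation_spec <- function(x, ...) {
  cat("<perturbation_spec> mode =", x$mode)
  if (x$mode != "none") {
    cat(", t_treat =", x$t_treat, "h, fast_decay_tau =", x$fast_decay_tau, "h")
    if (x$mode == "mitogen_withdrawal")
      cat(", delay ", x$withdrawal_delay_range[1], "-",
          x$withdrawal_delay_range[2], " h", sep = "")
  }
  cat("\n")
  invisible(x)
}
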