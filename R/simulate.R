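#' Simulate a single-cell cohort from the commitment circuit
#'
#' Generates per-cell, per-frame CDK4/6 and CDK2 activity traces from the
#' phenomenological commitment circuit described in [circuit_params()],
#' together with the observed reporter values (cross-talk plus Gaussian
#' noise) and a per-cell ground-truth table. Cells activate CDK4/6 with
#' probability `p_active`; activation onsets follow a shifted exponential
#' (`onset_min + Exp(onset_scale)`). A perturbation shuts off CDK4/6
#' production at its treatment time (immediately for rapid modes, after a
#' per-cell uniform lag for mitogen withdrawal), after which CDK4/6 activity
#' decays exponentially. Cells whose CDK2 activity has ever reached
#' `theta_commit` are latched committed: Rb stays inactive and CDK2 keeps
#' rising regardless of CDK4/6.
#'
#' @param params A [circuit_params()] object.
#' @param pert A [perturbation_spec()] object.
#' @param n_cells Number of cells to simulate (>= 1).
#' @param seed Integer seed; identical inputs give identical output.
#'
#' @return A tibble of class `trace_set` keyed by `(cell_id, frame)` with
#'   columns `t`, `a46_true`, `a2_true`, `e2f_true`, `degron_true`,
#'   `r46_obs`, `r2_obs`, `degron_obs`. The per-cell truth table is attached
#'   as attribute `"truth"` (see [cell_truth()]); the generating `params`,
#'   `pert` and `seed` are attached as attributes of the same names.
#' @examples
#' ts <- simulate_population(circuit_params(noise_sd = 0), n_cells = 5, seed = 1)
#' head(ts)
#' cell_truth(ts)
#' @export
simulate_population <- function(params, pert = perturbation_spec("none"),
                                n_cells, seed = 1) {
  validate_circuit_params(params)
  stopifnot(inherits(pert, "perturbation_spec"))
  if (pert$mode != "none" && pert$t_treat > params$horizon)
    stop("perturbation t_treat exceeds the simulation horizon", call. = FALSE)
  if (!is.numeric(n_cells) || length(n_cells) != 1 || n_cells < 1)
    stop("n_cells must be a positive count (empty cohorts are not simulated)",
         call. = FALSE)
  n_cells <- as.integer(n_cells)

  set.seed(as.integer(seed))
  active <- stats::rbinom(n_cells, 1L, params$p_active) == 1L
  onset46 <- ifelse(active,
                    params$onset_min + stats::rexp(n_cells,
                                                   rate = 1 / params$onset_scale),
                    Inf)
  # CDK4/6 production shut-off time per cell
  lag <- stats::runif(n_cells, pert$withdrawal_delay_range[1],
                      pert$withdrawal_delay_range[2])
  t_off <- switch(pert$mode,
                  none = rep(Inf, n_cells),
                  rapid_inhibitor = rep(pert$t_treat, n_cells),
                  ncs_pulse = rep(pert$t_treat, n_cells),
                  mitogen_withdrawal = pert$t_treat + lag)

  dyn <- integrate_circuit(params, onset46, t_off,
                           fast_decay_tau = pert$fast_decay_tau)

  nT <- dyn$n_frames
  noise <- function() {
    if (params$noise_sd == 0) 0 else
      matrix(stats::rnorm(n_cells * nT, 0, params$noise_sd), n_cells, nT)
  }
  r46 <- dyn$a46 + params$crosstalk_rho * dyn$a2 + noise()
  r2 <- dyn$a2 + noise()
  dg <- dyn$degron + noise()
  mrna <- stats::rpois(n_cells,
                       params$mrna_base + params$mrna_per_e2f * dyn$e2f_end)

  t_ref <- if (pert$mode == "none") params$horizon else pert$t_treat
  committed <- is.finite(dyn$t_commit) & dyn$t_commit <= t_ref
  activated <- active & onset46 <= params$horizon
  outcome <- ifelse(!activated, "quiescent",
                    ifelse(is.finite(dyn$t_commit) &
                             dyn$t_commit <= params$horizon, "inc", "low"))

  truth <- tibble::tibble(
    cell_id = seq_len(n_cells),
    is_active46 = activated,
    onset46_true = ifelse(activated, onset46, NA_real_),
    onset2_true = ifelse(is.finite(dyn$t_on2), dyn$t_on2, NA_real_),
    commit_time_true = ifelse(is.finite(dyn$t_commit), dyn$t_commit, NA_real_),
    committed = committed,
    apc_off_true = ifelse(is.finite(dyn$t_apc), dyn$t_apc, NA_real_),
    shutoff_time = ifelse(is.finite(t_off), t_off, NA_real_),
    outcome_true = outcome,
    mrna_true = mrna
  )

  out <- tibble::tibble(
    cell_id = rep(seq_len(n_cells), each = nT),
    frame = rep(seq_len(nT), times = n_cells),
    t = rep(dyn$t_frames, times = n_cells),
    a46_true = as.vector(t(dyn$a46)),
    a2_true = as.vector(t(dyn$a2)),
    e2f_true = as.vector(t(dyn$e2f)),
    degron_true = as.vector(t(dyn$degron)),
    r46_obs = as.vector(t(r46)),
    r2_obs = as.vector(t(r2)),
    degron_obs = as.vector(t(dg))
  )
  attr(out, "truth") <- truth
  attr(out, "params") <- params
  attr(out, "pert") <- pert
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("trace_set", class(out))
  out
}

#' Per-cell ground truth of a simulated trace set
#'
#' @param traces A `trace_set` from [simulate_population()].
#' @return The per-cell truth tibble (activation flags, true onset times,
#'   commitment and APC/C-off times, outcome labels, FISH transcript counts).
#' @export
cell_truth <- function(traces) {
  tr <- attr(traces, "truth")
  if (is.null(tr)) stop("no truth table attached; not a simulated trace_set",
                        call. = FALSE)
  tr
}

# Deterministic circuit integration for a vector of cells.
# onset46, t_off: per-cell times (Inf = never). Euler on `n_sub` substeps per
# frame; activities recorded on the frame grid t = 0, dt, ..., horizon.
integrate_circuit <- function(p, onset46, t_off, fast_decay_tau = 0.2,
                              n_sub = 5L) {
  n <- length(onset46)
  nT <- as.integer(floor(p$horizon / p$dt + 1e-9)) + 1L
  t_frames <- (seq_len(nT) - 1L) * p$dt
  h <- p$dt / n_sub

  a46_of <- function(tt) {
    # rise from onset, exponential decay after shut-off
    base <- ifelse(tt >= onset46,
                   p$a46_max * (1 - exp(-(tt - onset46) / p$rise_tau)), 0)
    peak <- ifelse(t_off >= onset46,
                   p$a46_max * (1 - exp(-(t_off - onset46) / p$rise_tau)), 0)
    ifelse(tt < t_off, base, peak * exp(-(tt - t_off) / fast_decay_tau))
  }

  E <- numeric(n)
  A2 <- rep(p$a2_baseline, n)
  latch <- logical(n)
  t_on2 <- rep(Inf, n)
  t_commit <- rep(Inf, n)
  t_apc <- rep(Inf, n)

  a46_m <- matrix(0, n, nT)
  a2_m <- matrix(0, n, nT)
  e_m <- matrix(0, n, nT)
  dg_m <- matrix(0, n, nT)

  step <- 0L
  for (k in seq_len((nT - 1L) * n_sub + 1L)) {
    tt <- (k - 1L) * h
    A46 <- a46_of(tt)
    rb_off <- (A46 >= p$theta_rb) | latch
    # record on frame grid
    if ((k - 1L) %% n_sub == 0L) {
      fr <- (k - 1L) %/% n_sub + 1L
      a46_m[, fr] <- A46
      a2_m[, fr] <- A2
      e_m[, fr] <- E
      dg_m[, fr] <- ifelse(tt > t_apc, p$degron_rate * (tt - t_apc), 0)
    }
    if (k > (nT - 1L) * n_sub) break
    prod2 <- (p$cdk2_rate * E + p$cdk2_fb * pmax(A2 - p$a2_baseline, 0)) *
      rb_off * pmax(1 - A2 / p$a2_max, 0)
    E <- E + h * (p$e2f_rate * rb_off - p$e2f_decay * E)
    A2 <- A2 + h * (prod2 - p$cdk2_decay * (A2 - p$a2_baseline))
    tn <- tt + h
    t_on2 <- ifelse(A2 >= p$theta_on2 & !is.finite(t_on2), tn, t_on2)
    t_commit <- ifelse(A2 >= p$theta_commit & !is.finite(t_commit), tn, t_commit)
    t_apc <- ifelse(A2 >= p$theta_apc & !is.finite(t_apc), tn, t_apc)
    latch <- latch | A2 >= p$theta_commit
  }

  list(a46 = a46_m, a2 = a2_m, e2f = e_m, degron = dg_m,
       e2f_end = E, t_on2 = t_on2, t_commit = t_commit, t_apc = t_apc,
       t_frames = t_frames, n_frames = nT)
}

#' Simulate a cross-talk calibration experiment
#'
#' Emulates the calibration condition used to estimate reporter cross-talk:
#' cells under full CDK4/6 inhibition (true CDK4/6 activity 0) across a range
#' of CDK2 activities, so that any CDK4/6-reporter signal is the CDK2
#' leak-through plus noise.
#'
#' @param rho True cross-talk coefficient in `[0, 1)`.
#' @param n Number of cells (>= 2).
#' @param a2_range Length-2 range of true CDK2 activities (uniform draw).
#' @param noise_sd Observation noise s.d. applied to both reporters.
#' @param seed Integer seed.
#' @return A tibble with columns `a2_true`, `r46_obs`, `r2_obs`.
#' @seealso [estimate_crosstalk()]
#' @export
simulate_calibration_pairs <- function(rho = 0.35, n = 500,
                                       a2_range = c(0, 2), noise_sd = 0.05,
                                       seed = 1) {
  if (!is.numeric(n) || n < 2)
    stop("calibration needs at least 2 cells", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  n <- as.integer(n)
  set.seed(as.integer(seed))
  a2 <- stats::runif(n, a2_range[1], a2_range[2])
  e1 <- if (noise_sd == 0) 0 else stats::rnorm(n, 0, noise_sd)
  e2 <- if (noise_sd == 0) 0 else stats::rnorm(n, 0, noise_sd)
  tibble::tibble(a2_true = a2, r46_obs = rho * a2 + e1, r2_obs = a2 + e2)
}
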