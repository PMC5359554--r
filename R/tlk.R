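# Two-lesion kinetic (TLK) repair/mis-repair model. Simple DSBs (L1) and
# complex DSBs (L2) are removed by first-order repair (rates lambda_i =
# ln(2)/tau_i) and by second-order pairwise interaction between break ends;
# a fraction of each channel produces irreversible lethal aberrations:
#
#   dL1/dt = -lambda1 L1 - eta L1 (L1 + L2)
#   dL2/dt = -lambda2 L2 - eta L2 (L1 + L2)
#   dL_lethal/dt = beta1 lambda1 L1 + beta2 lambda2 L2
#                  + lethal_pair_frac * eta * (L1 + L2)^2
#
# The 0.25 default of lethal_pair_frac is the probability that a pairwise
# exchange forms a lethal aberration (a dicentric). Cell survival is the
# Poisson zero-class probability exp(-L_lethal(T)).

#' TLK model parameters
#'
#' @param tau1_h Fast (simple-DSB) repair half-time, hours.
#' @param tau2_h Slow (complex-DSB) repair half-time, hours.
#' @param beta1 Lethality probability of simple-DSB linear mis-repair.
#' @param beta2 Lethality probability of complex-DSB linear mis-repair.
#' @param eta_per_h Second-order pairwise interaction probability, per hour.
#' @param lethal_pair_frac Probability that a pairwise interaction yields a
#'   lethal chromosome aberration (default 0.25).
#'
#' Defaults for `beta1`, `beta2`, `eta_per_h` are values calibrated for the
#' A549 non-small-cell lung cancer line; `tau1_h`/`tau2_h` defaults are the
#' means of the fast/slow repair-time distributions.
#'
#' @return A `tlk_params` list with derived rates `lambda1`, `lambda2`
#'   (`ln(2)/tau`).
#' @export
#' @examples
#' tlk_params()
tlk_params <- function(tau1_h = 0.25, tau2_h = 8,
                       beta1 = 0.00026, beta2 = 0.011,
                       eta_per_h = 1.6e-5, lethal_pair_frac = 0.25) {
  check_number(tau1_h, "tau1_h", min = 0, allow_min = FALSE)
  check_number(tau2_h, "tau2_h", min = 0, allow_min = FALSE)
  check_number(beta1, "beta1", min = 0, max = 1)
  check_number(beta2, "beta2", min = 0, max = 1)
  check_number(eta_per_h, "eta_per_h", min = 0)
  check_number(lethal_pair_frac, "lethal_pair_frac", min = 0, max = 1)
  structure(
    list(tau1_h = tau1_h, tau2_h = tau2_h,
         beta1 = beta1, beta2 = beta2,
         eta_per_h = eta_per_h, lethal_pair_frac = lethal_pair_frac,
         lambda1 = log(2) / tau1_h, lambda2 = log(2) / tau2_h),
    class = "tlk_params"
  )
}

#' @export
print.tlk_params <- function(x, ...) {
  cat(sprintf(
    "<tlk_params> tau1 = %g h, tau2 = %g h, beta1 = %g, beta2 = %g, eta = %g /h, pair frac = %g\n",
    x$tau1_h, x$tau2_h, x$beta1, x$beta2, x$eta_per_h, x$lethal_pair_frac))
  invisible(x)
}

update_params <- function(params, ...) {
  new <- list(...)
  args <- list(tau1_h = params$tau1_h, tau2_h = params$tau2_h,
               beta1 = params$beta1, beta2 = params$beta2,
               eta_per_h = params$eta_per_h,
               lethal_pair_frac = params$lethal_pair_frac)
  args[names(new)] <- new
  do.call(tlk_params, args)
}

#' Read / write TLK parameters (JSON or YAML)
#'
#' Keys: `tau1_h, tau2_h, beta1, beta2, eta_per_h, lethal_pair_frac`; the
#' format is inferred from the file extension.
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return A [tlk_params].
#' @export
read_tlk_params <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  keep <- intersect(names(vals), names(formals(tlk_params)))
  do.call(tlk_params, vals[keep])
}

#' @rdname read_tlk_params
#' @param params A [tlk_params] to serialise.
#' @export
write_tlk_params <- function(params, path) {
  vals <- params[c("tau1_h", "tau2_h", "beta1", "beta2", "eta_per_h",
                   "lethal_pair_frac")]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}

#' TLK right-hand side
#'
#' Instantaneous rates of change of the simple-DSB count, complex-DSB count
#' and cumulative lethal-damage count. Mostly useful for inspection and
#' testing; integration happens in compiled code.
#'
#' @param L1,L2 Current simple/complex DSB counts (>= 0).
#' @param params A [tlk_params].
#' @return Named numeric: `dL1`, `dL2`, `dL_lethal` (per hour).
#' @export
#' @examples
#' tlk_rhs(100, 50, tlk_params())
tlk_rhs <- function(L1, L2, params) {
  if (L1 < 0 || L2 < 0) abort_bad("lesion counts must be non-negative")
  tot <- L1 + L2
  c(dL1 = -params$lambda1 * L1 - params$eta_per_h * L1 * tot,
    dL2 = -params$lambda2 * L2 - params$eta_per_h * L2 * tot,
    dL_lethal = params$beta1 * params$lambda1 * L1 +
      params$beta2 * params$lambda2 * L2 +
      params$lethal_pair_frac * params$eta_per_h * tot^2)
}

as_initial_damage <- function(state) {
  if (is.data.frame(state)) {
    stopifnot(all(c("L1_0", "L2_0") %in% names(state)))
    list(L1 = state$L1_0, L2 = state$L2_0,
         id = if ("nucleus_id" %in% names(state)) state$nucleus_id
              else seq_len(nrow(state)))
  } else if (is.numeric(state) && length(state) == 2) {
    list(L1 = state[[1]], L2 = state[[2]], id = 1L)
  } else {
    abort_bad("`state` must be a damage_state tibble or c(L1_0, L2_0)")
  }
}

#' Solve the TLK equations for one nucleus
#'
#' Fixed-step classical Runge-Kutta (RK4) integration from the initial
#' damage burden, returning the full trajectory. Default horizon and step
#' (24 h, 0.005 h) are the acute post-irradiation repair settings; use 96 h
#' with dt = 0.001 h for long calibration-style repair.
#'
#' @param state One-row `damage_state` tibble (from [accumulate]) or a
#'   numeric pair `c(L1_0, L2_0)`.
#' @param params A [tlk_params].
#' @param T_h Repair time horizon, hours.
#' @param dt_h Integration step, hours.
#' @return A `tlk_trajectory` tibble: `time_h, L1, L2, L_lethal`, with the
#'   parameters attached as an attribute.
#' @export
#' @examples
#' traj <- tlk_solve(c(60, 50), tlk_params(), T_h = 24, dt_h = 0.005)
#' utils::tail(traj, 1)
tlk_solve <- function(state, params, T_h = 24, dt_h = 0.005) {
  stopifnot(inherits(params, "tlk_params"))
  init <- as_initial_damage(state)
  if (length(init$L1) != 1) {
    abort_bad("tlk_solve() integrates one nucleus; use tlk_final() for a batch")
  }
  m <- tlk_integrate_trajectory(init$L1, init$L2,
                                params$lambda1, params$lambda2,
                                params$beta1, params$beta2, params$eta_per_h,
                                params$lethal_pair_frac, T_h, dt_h)
  out <- tibble::tibble(time_h = m[, 1], L1 = m[, 2], L2 = m[, 3],
                        L_lethal = m[, 4])
  class(out) <- c("tlk_trajectory", class(out))
  attr(out, "params") <- params
  out
}

#' Final TLK state for a batch of nuclei
#'
#' Integrates every nucleus to `T_h` with its own repair half-times (if
#' `taus` is given) and reports final lesion counts and survival
#' probability.
#'
#' @param states `damage_state` tibble, one row per nucleus.
#' @param params A [tlk_params]; its `tau1_h`/`tau2_h` are used for nuclei
#'   without per-nucleus values.
#' @param taus Optional tibble `tau1_h, tau2_h` with one row per nucleus
#'   (see [assign_repair_times]).
#' @inheritParams tlk_solve
#' @return Tibble `nucleus_id, L1_T, L2_T, L_lethal_T, p_survival`.
#' @export
tlk_final <- function(states, params, T_h = 24, dt_h = 0.005, taus = NULL) {
  stopifnot(inherits(params, "tlk_params"))
  init <- as_initial_damage(states)
  n <- length(init$L1)
  if (is.null(taus)) {
    lam1 <- rep(params$lambda1, n); lam2 <- rep(params$lambda2, n)
  } else {
    if (nrow(taus) != n) abort_bad("`taus` must have one row per nucleus (%d != %d)", nrow(taus), n)
    lam1 <- log(2) / taus$tau1_h; lam2 <- log(2) / taus$tau2_h
  }
  m <- tlk_integrate_batch(init$L1, init$L2, lam1, lam2,
                           params$beta1, params$beta2, params$eta_per_h,
                           params$lethal_pair_frac, T_h, dt_h)
  tibble::tibble(nucleus_id = init$id,
                 L1_T = m[, 1], L2_T = m[, 2], L_lethal_T = m[, 3],
                 p_survival = survival_probability(m[, 3]))
}

#' Cell survival probability from lethal damage
#'
#' The probability that a cell carrying a mean lethal-damage burden
#' `L_lethal` at assay time has zero lethal events: `exp(-L_lethal)`.
#'
#' @param L_lethal Lethal damage count(s), >= 0.
#' @return Survival probability in (0, 1].
#' @export
#' @examples
#' survival_probability(1)  # exp(-1)
survival_probability <- function(L_lethal) {
  check_number(L_lethal, "L_lethal", min = 0)
  exp(-L_lethal)
}

#' Plot a TLK trajectory
#'
#' Lesion counts against repair time: decaying simple and complex DSB
#' populations and the accumulating lethal-damage curve.
#'
#' @param object A `tlk_trajectory` from [tlk_solve].
#' @param ... Unused.
#' @export
autoplot.tlk_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), -"time_h",
                            names_to = "pool", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$count,
                                   colour = .data$pool)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "repair time (h)", y = "lesions per cell", colour = NULL)
}
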