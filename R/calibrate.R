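# Calibration of the TLK lethality parameters (beta1, beta2, eta) against a
# measured clonogenic survival curve: a deterministic expected-mode survival
# simulator, a least-squares objective on log10 survival, one-at-a-time
# sensitivity scans, and sensitivity-ordered coordinate descent with a
# Nelder-Mead polish in log10 parameter space.

#' Measured survival-curve data
#'
#' @param doses_gy Doses, Gy (>= 0).
#' @param sf Measured surviving fractions, in (0, 1].
#' @param sf_err Optional uncertainties.
#' @return A `survival_curve` tibble `dose_gy, sf(, sf_err)`.
#' @export
survival_curve_data <- function(doses_gy, sf, sf_err = NULL) {
  if (length(doses_gy) != length(sf)) abort_bad("doses and sf differ in length")
  check_number(doses_gy, "doses_gy", min = 0)
  if (any(sf <= 0 | sf > 1)) abort_bad("sf values must lie in (0, 1]")
  out <- tibble::tibble(dose_gy = doses_gy, sf = sf)
  if (!is.null(sf_err)) out$sf_err <- sf_err
  class(out) <- c("survival_curve", class(out))
  out
}

#' Read a survival-curve CSV (`dose_gy, sf[, sf_err]`)
#' @param path CSV path.
#' @return A [survival_curve_data] tibble.
#' @export
read_survival_curve <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  survival_curve_data(df$dose_gy, df$sf,
                      if ("sf_err" %in% names(df)) df$sf_err else NULL)
}

#' Deterministic survival simulation configuration
#'
#' Bundles everything the expected-mode survival simulator needs: a
#' reference per-nucleus damage state (expected lesion burdens at some
#' reference dose), the per-nucleus repair half-times, and the integration
#' settings. At each requested dose the reference burdens are rescaled
#' linearly, integrated through the TLK model, and averaged into
#' `SF(d) = mean_i exp(-L_lethal,i(T))`.
#'
#' @param states Reference `damage_state` tibble (all doses > 0).
#' @param taus Tibble `tau1_h, tau2_h` per nucleus, or `NULL` for shared
#'   half-times from the parameter set.
#' @param T_h Repair horizon, hours (calibration default 96).
#' @param dt_h Integration step, hours.
#' @return A `tlk_sim_config`.
#' @export
sim_config <- function(states, taus = NULL, T_h = 96, dt_h = 0.005) {
  if (any(states$dose_gy <= 0)) abort_bad("reference states must carry positive dose")
  if (!is.null(taus) && nrow(taus) != nrow(states)) {
    abort_bad("`states` and `taus` must have the same length")
  }
  structure(list(states = states, taus = taus, T_h = T_h, dt_h = dt_h),
            class = "tlk_sim_config")
}

#' Expected survival fraction at a set of doses
#'
#' @param config A [sim_config].
#' @param params A [tlk_params].
#' @param doses_gy Doses, Gy.
#' @return Tibble `dose_gy, sf` of class `dose_response`.
#' @export
simulate_sf <- function(config, params, doses_gy) {
  stopifnot(inherits(config, "tlk_sim_config"))
  n <- nrow(config$states)
  # batch all doses into one compiled call
  scaled <- purrr::map(doses_gy, function(d) {
    if (d == 0) {
      dplyr::mutate(config$states, dose_gy = 0, L1_0 = 0, L2_0 = 0)
    } else {
      rescale_to_dose(config$states, d)
    }
  })
  states_all <- dplyr::bind_rows(scaled)
  taus_all <- if (is.null(config$taus)) NULL else {
    config$taus[rep(seq_len(n), times = length(doses_gy)), ]
  }
  finals <- tlk_final(states_all, params, T_h = config$T_h, dt_h = config$dt_h,
                      taus = taus_all)
  sf <- tapply(finals$p_survival, rep(seq_along(doses_gy), each = n), mean)
  out <- tibble::tibble(dose_gy = doses_gy, sf = as.numeric(sf))
  class(out) <- c("dose_response", class(out))
  out
}

#' Calibration objective: least squares on log10 survival
#'
#' `OBJ = sum_d (log10 SF_sim(d) - log10 SF_meas(d))^2`, computed with the
#' deterministic expected-mode simulator so the objective surface is smooth.
#' Survival spans orders of magnitude over the calibration dose range, hence
#' the log scale; `scale = "linear"` switches to plain squared differences
#' for comparison.
#'
#' @param params A [tlk_params].
#' @param data A [survival_curve_data] tibble.
#' @param config A [sim_config].
#' @param scale `"log10"` (default) or `"linear"`.
#' @return The scalar objective value (lower is better).
#' @export
objective <- function(params, data, config, scale = c("log10", "linear")) {
  scale <- match.arg(scale)
  sim <- simulate_sf(config, params, data$dose_gy)$sf
  if (scale == "log10") {
    if (any(sim <= 0)) {
      abort_bad(paste0("simulated SF underflowed to 0 at dose %g Gy; ",
                       "log10 objective undefined - tighten parameter bounds"),
                data$dose_gy[which(sim <= 0)[1]])
    }
    sum((log10(sim) - log10(data$sf))^2)
  } else {
    sum((sim - data$sf)^2)
  }
}

param_or_abort <- function(name) {
  ok <- c("beta1", "beta2", "eta_per_h", "lethal_pair_frac")
  if (!name %in% ok) abort_bad("unknown scan parameter `%s`", name)
  name
}

#' One-at-a-time parameter sensitivity scan
#'
#' Multiplies one parameter by each factor of a (>= 2 decade) grid while
#' holding the others fixed, and records the objective at each point. The
#' max-minus-min objective over the grid is the parameter's sensitivity
#' range; ranking parameters by this range decides the calibration order
#' (most sensitive first).
#'
#' @inheritParams objective
#' @param param Parameter name: `"beta1"`, `"beta2"`, `"eta_per_h"` or
#'   `"lethal_pair_frac"`.
#' @param factors Multiplicative grid (default `10^seq(-2, 2, 0.5)`).
#' @return A `sensitivity_scan` tibble `param, factor, value, obj` with an
#'   `obj_range` attribute.
#' @export
sensitivity_scan <- function(data, config, params, param,
                             factors = 10^seq(-2, 2, by = 0.5),
                             scale = "log10") {
  param <- param_or_abort(param)
  if (length(factors) < 2) abort_bad("sensitivity grid must have >= 2 points")
  base <- params[[param]]
  values <- base * factors
  # the lethality fractions are probabilities; clamp the scan to [0, 1]
  if (param %in% c("beta1", "beta2", "lethal_pair_frac")) values <- pmin(values, 1)
  obj <- purrr::map_dbl(values, function(v) {
    objective(do.call(update_params, stats::setNames(list(params, v), c("params", param))),
              data, config, scale = scale)
  })
  out <- tibble::tibble(param = param, factor = factors, value = values, obj = obj)
  class(out) <- c("sensitivity_scan", class(out))
  attr(out, "obj_range") <- max(obj) - min(obj)
  out
}

#' Rank parameters by sensitivity
#'
#' @inheritParams sensitivity_scan
#' @param param_names Parameters to scan.
#' @return Tibble `param, obj_range`, most sensitive first, with the scans
#'   attached as a list column.
#' @export
sensitivity_rank <- function(data, config, params,
                             param_names = c("beta1", "beta2", "eta_per_h"),
                             factors = 10^seq(-2, 2, by = 0.5),
                             scale = "log10") {
  scans <- purrr::map(param_names, function(p) {
    sensitivity_scan(data, config, params, p, factors = factors, scale = scale)
  })
  tibble::tibble(
    param = param_names,
    obj_range = purrr::map_dbl(scans, attr, "obj_range"),
    scan = scans
  ) |>
    dplyr::arrange(dplyr::desc(.data$obj_range))
}

# beta-independent lethality integrals for every (nucleus, dose) pair:
# I1 = int lambda1 L1 dt, I2 = int lambda2 L2 dt, J3 = int (L1+L2)^2 dt,
# each an n_nuclei x n_doses matrix. Given eta,
#   L_lethal(T) = beta1 I1 + beta2 I2 + lethal_pair_frac * eta * J3
# exactly on the RK4 grid.
lethality_design <- function(config, eta, doses_gy, tau1_fallback, tau2_fallback) {
  n <- nrow(config$states)
  scaled <- purrr::map(doses_gy, rescale_to_dose, state = config$states)
  states_all <- dplyr::bind_rows(scaled)
  if (is.null(config$taus)) {
    lam1 <- rep(log(2) / tau1_fallback, n * length(doses_gy))
    lam2 <- rep(log(2) / tau2_fallback, n * length(doses_gy))
  } else {
    lam1 <- rep(log(2) / config$taus$tau1_h, times = length(doses_gy))
    lam2 <- rep(log(2) / config$taus$tau2_h, times = length(doses_gy))
  }
  m <- tlk_lethality_integrals(states_all$L1_0, states_all$L2_0, lam1, lam2,
                               eta, config$T_h, config$dt_h)
  list(I1 = matrix(m[, 1], nrow = n), I2 = matrix(m[, 2], nrow = n),
       J3 = matrix(m[, 3], nrow = n))
}

# inner fit of the linear lethality fractions at fixed eta: a 2-parameter
# nonlinear least squares over the precomputed design (no ODE solves),
# solved by damped Gauss-Newton with the analytic Jacobian. The beta1/beta2
# design columns are nearly collinear, so the step is computed from the
# rectangular Jacobian by QR (never from normal equations).
fit_betas <- function(design, data, eta, frac, bounds, start, scale) {
  y <- data$sf
  pair <- frac * eta * design$J3
  lo <- c(bounds$beta1[1], bounds$beta2[1])
  hi <- c(bounds$beta1[2], bounds$beta2[2])
  clamp <- function(b) pmin(pmax(b, lo), hi)
  resid_jac <- function(b) {
    lth <- b[1] * design$I1 + b[2] * design$I2 + pair
    E <- exp(-lth)
    S <- colMeans(E)
    if (scale == "log10") {
      r <- log10(S) - log10(y)
      J <- cbind(colMeans(-design$I1 * E) / (S * log(10)),
                 colMeans(-design$I2 * E) / (S * log(10)))
    } else {
      r <- S - y
      J <- cbind(colMeans(-design$I1 * E), colMeans(-design$I2 * E))
    }
    list(r = r, J = J)
  }
  gauss_newton <- function(b) {
    g <- sum(resid_jac(b)$r^2)
    for (iter in 1:80) {
      rj <- resid_jac(b)
      step <- tryCatch(qr.solve(rj$J, -rj$r), error = function(e) NULL)
      if (is.null(step) || anyNA(step)) break
      # backtracking line search with projection onto the bounds
      improved <- FALSE
      alpha <- 1
      for (k in 1:25) {
        cand <- clamp(b + alpha * step)
        gc_ <- sum(resid_jac(cand)$r^2)
        if (gc_ < g) {
          b <- cand; g <- gc_; improved <- TRUE
          break
        }
        alpha <- alpha / 2
      }
      if (!improved || g < 1e-28) break
    }
    list(b = b, g = g)
  }
  # the two beta design columns are nearly collinear, so a single descent
  # can settle on the wrong branch of the valley; evaluations are cheap,
  # so seed Gauss-Newton from a coarse global grid plus the warm start
  grid1 <- 10^seq(log10(lo[1]), log10(hi[1]), length.out = 9)
  grid2 <- 10^seq(log10(lo[2]), log10(hi[2]), length.out = 9)
  starts <- rbind(as.matrix(expand.grid(grid1, grid2)), clamp(start))
  g0 <- apply(starts, 1, function(b) sum(resid_jac(b)$r^2))
  best <- list(b = clamp(start), g = Inf)
  for (i in order(g0)[1:4]) {
    cand <- gauss_newton(as.numeric(starts[i, ]))
    if (cand$g < best$g) best <- cand
  }
  list(beta1 = best$b[1], beta2 = best$b[2], obj = best$g)
}

#' Calibrate TLK lethality parameters against a survival curve
#'
#' Strategy: (1) one-at-a-time sensitivity scans of `beta1`, `beta2` and
#' `eta_per_h` around the starting point, reported as the sensitivity
#' ranking; (2) a profiled search that exploits the model structure: the
#' lethality fractions enter the lethal-damage integral linearly (they do
#' not feed back into the lesion dynamics), so for any trial `eta` the best
#' `(beta1, beta2)` are found by a cheap smooth 2-D fit over precomputed
#' lethality integrals, and the search reduces to one dimension over
#' log10(eta) — the most strongly nonlinear (and most sensitive) parameter
#' is adjusted in the outer loop; (3) a Nelder-Mead polish over all three
#' log10 parameters. Deterministic for a fixed start; `start = "random"`
#' draws a log-uniform starting point from `bounds` under `seed`.
#'
#' @inheritParams objective
#' @param bounds Named list of `c(lower, upper)` search bounds.
#' @param start `"default"` (geometric mid-point of bounds), `"random"`, or
#'   a [tlk_params] object.
#' @param seed Seed for a random start.
#' @return A `tlk_calibration`: fitted `params`, `obj_value`,
#'   `initial_obj`, the `sensitivity` ranking, the optimisation `trace`, and
#'   the fitted curve.
#' @export
calibrate <- function(data, config,
                      bounds = list(beta1 = c(1e-5, 0.5),
                                    beta2 = c(1e-5, 0.5),
                                    eta_per_h = c(1e-7, 1e-3)),
                      start = "default", scale = "log10", seed = NULL) {
  stopifnot(all(c("beta1", "beta2", "eta_per_h") %in% names(bounds)))
  free <- names(bounds)
  start_params <- if (inherits(start, "tlk_params")) {
    start
  } else if (identical(start, "random")) {
    vals <- with_seed_maybe(seed, purrr::map_dbl(bounds, function(b) {
      10^stats::runif(1, log10(b[1]), log10(b[2]))
    }))
    do.call(update_params, c(list(tlk_params()), as.list(vals)))
  } else {
    vals <- purrr::map_dbl(bounds, function(b) sqrt(b[1] * b[2]))
    do.call(update_params, c(list(tlk_params()), as.list(vals)))
  }
  obj_of <- function(p) objective(p, data, config, scale = scale)
  initial_obj <- obj_of(start_params)

  # 1. sensitivity ordering around the start
  rank <- sensitivity_rank(data, config, start_params, param_names = free,
                           scale = scale)

  trace <- list(tibble::tibble(stage = "start",
                               beta1 = start_params$beta1,
                               beta2 = start_params$beta2,
                               eta_per_h = start_params$eta_per_h,
                               obj = initial_obj))
  current <- start_params

  # 2. profiled search: outer 1-D over log10(eta), inner exact-structure
  # fit of the linear lethality fractions
  beta_start <- c(start_params$beta1, start_params$beta2)
  profile_eta <- function(eta) {
    design <- lethality_design(config, eta, data$dose_gy,
                               start_params$tau1_h, start_params$tau2_h)
    fit_betas(design, data, eta, start_params$lethal_pair_frac, bounds,
              beta_start, scale)
  }
  eta_grid <- 10^seq(log10(bounds$eta_per_h[1]), log10(bounds$eta_per_h[2]),
                     length.out = 15)
  grid_fits <- purrr::map(eta_grid, profile_eta)
  grid_obj <- purrr::map_dbl(grid_fits, "obj")
  i_best <- which.min(grid_obj)
  beta_start <- c(grid_fits[[i_best]]$beta1, grid_fits[[i_best]]$beta2)
  lo_i <- max(1L, i_best - 1L); hi_i <- min(length(eta_grid), i_best + 1L)
  refine <- stats::optimize(function(l10e) profile_eta(10^l10e)$obj,
                            interval = log10(c(eta_grid[lo_i], eta_grid[hi_i])),
                            tol = 1e-7)
  best_eta <- 10^refine$minimum
  best_fit <- profile_eta(best_eta)
  cand <- update_params(current, beta1 = best_fit$beta1,
                        beta2 = best_fit$beta2, eta_per_h = best_eta)
  if (best_fit$obj <= initial_obj) current <- cand
  trace <- c(trace, list(tibble::tibble(
    stage = "profile_eta", beta1 = current$beta1, beta2 = current$beta2,
    eta_per_h = current$eta_per_h, obj = obj_of(current))))

  # 3. derivative-free polish over all free parameters in log10 space
  # (skipped when the profiled search already sits at the numerical floor)
  if (obj_of(current) > 1e-14) {
    fn <- function(l10) {
      for (i in seq_along(free)) {
        if (l10[i] < log10(bounds[[free[i]]][1]) ||
            l10[i] > log10(bounds[[free[i]]][2])) return(1e10)
      }
      obj_of(do.call(update_params,
                     c(list(current), stats::setNames(as.list(10^l10), free))))
    }
    p0 <- log10(purrr::map_dbl(free, function(p) current[[p]]))
    opt <- stats::optim(p0, fn, method = "Nelder-Mead",
                        control = list(maxit = 120, reltol = 1e-8))
    polished <- do.call(update_params,
                        c(list(current), stats::setNames(as.list(10^opt$par), free)))
    if (opt$value <= obj_of(current)) current <- polished
  }
  final_obj <- obj_of(current)
  # never return anything worse than the starting point
  if (final_obj > initial_obj) {
    current <- start_params
    final_obj <- initial_obj
  }
  trace <- c(trace, list(tibble::tibble(
    stage = "polish", beta1 = current$beta1, beta2 = current$beta2,
    eta_per_h = current$eta_per_h, obj = final_obj)))

  structure(
    list(params = current, obj_value = final_obj, initial_obj = initial_obj,
         sensitivity = rank[c("param", "obj_range")],
         trace = dplyr::bind_rows(trace),
         data = data,
         fitted = simulate_sf(config, current, data$dose_gy),
         scale = scale),
    class = "tlk_calibration"
  )
}

#' @export
print.tlk_calibration <- function(x, ...) {
  cat(sprintf(
    "<tlk_calibration> beta1 = %.3g, beta2 = %.3g, eta = %.3g /h; OBJ = %.3g (start %.3g)\n",
    x$params$beta1, x$params$beta2, x$params$eta_per_h,
    x$obj_value, x$initial_obj))
  cat("sensitivity order:", paste(x$sensitivity$param, collapse = " > "), "\n")
  invisible(x)
}

#' @export
tidy.tlk_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("beta1", "beta2", "eta_per_h"),
    estimate = c(x$params$beta1, x$params$beta2, x$params$eta_per_h)
  )
}

#' @export
glance.tlk_calibration <- function(x, ...) {
  tibble::tibble(obj_value = x$obj_value, initial_obj = x$initial_obj,
                 n_points = nrow(x$data), scale = x$scale,
                 most_sensitive = x$sensitivity$param[1])
}

#' Plot calibration fit: measured points and fitted survival curve
#' @param object A `tlk_calibration`.
#' @param ... Unused.
#' @export
autoplot.tlk_calibration <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$dose_gy, .data$sf)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = object$fitted, colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "dose (Gy)", y = "surviving fraction")
}

#' Plot a sensitivity scan
#' @param object A `sensitivity_scan`.
#' @param ... Unused.
#' @export
autoplot.sensitivity_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$value, .data$obj)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = object$param[1], y = "objective")
}

#' Write a calibration report as JSON
#' @param x A `tlk_calibration`.
#' @param path Output JSON path.
#' @export
write_calibration_report <- function(x, path) {
  stopifnot(inherits(x, "tlk_calibration"))
  jsonlite::write_json(
    list(
      params = list(beta1 = x$params$beta1, beta2 = x$params$beta2,
                    eta_per_h = x$params$eta_per_h,
                    lethal_pair_frac = x$params$lethal_pair_frac),
      obj_value = x$obj_value, initial_obj = x$initial_obj,
      scale = x$scale,
      sensitivity = as.list(stats::setNames(x$sensitivity$obj_range,
                                            x$sensitivity$param)),
      data = list(dose_gy = x$data$dose_gy, sf = x$data$sf),
      fitted_sf = x$fitted$sf
    ),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
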