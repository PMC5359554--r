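# Derived radiobiological endpoints: linear-quadratic comparison curves,
# dose-response from the full pipeline, hypoxia reduction factors, and
# relative biological effectiveness between beam qualities.

#' Linear-quadratic model parameters
#'
#' Defaults are published A549 coefficients used for survival-fraction
#' comparison against the mechanistic pipeline.
#'
#' @param alpha_per_gy Linear coefficient, 1/Gy.
#' @param beta_per_gy2 Quadratic coefficient, 1/Gy^2.
#' @return An `lq_params` list.
#' @export
lq_params <- function(alpha_per_gy = 0.2432, beta_per_gy2 = 0.0257) {
  check_number(alpha_per_gy, "alpha_per_gy", min = 0)
  check_number(beta_per_gy2, "beta_per_gy2", min = 0)
  structure(list(alpha_per_gy = alpha_per_gy, beta_per_gy2 = beta_per_gy2),
            class = "lq_params")
}

#' Linear-quadratic survival fraction
#'
#' `SF = exp(-alpha D - beta D^2)`.
#'
#' @param dose_gy Dose(s), Gy (>= 0).
#' @param params An [lq_params].
#' @return Surviving fraction(s) in (0, 1].
#' @export
#' @examples
#' lq_survival(2.2)   # 0.517 for the default A549 coefficients
#' lq_survival(2.06)  # 0.543
lq_survival <- function(dose_gy, params = lq_params()) {
  check_number(dose_gy, "dose_gy", min = 0)
  exp(-params$alpha_per_gy * dose_gy - params$beta_per_gy2 * dose_gy^2)
}

#' Dose-response curve from the mechanistic pipeline
#'
#' Expected-mode survival at each dose: rescale the reference damage state,
#' integrate the TLK model per nucleus, average `exp(-L_lethal(T))`.
#' A thin, endpoint-named wrapper around [simulate_sf].
#'
#' @param doses_gy Ascending doses, Gy.
#' @param config A [sim_config].
#' @param params A [tlk_params].
#' @return A `dose_response` tibble `dose_gy, sf`.
#' @export
sf_vs_dose <- function(doses_gy, config, params = tlk_params()) {
  check_number(doses_gy, "doses_gy", min = 0)
  if (is.unsorted(doses_gy)) abort_bad("doses must be ascending")
  simulate_sf(config, params, doses_gy)
}

#' @export
autoplot.dose_response <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$dose_gy, .data$sf)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "dose (Gy)", y = "surviving fraction")
}

#' Voxel pipeline configuration
#'
#' Couples a voxel electron spectrum, a specific-energy model and a yield
#' table with a nucleus cohort (repair half-times) and TLK settings, so
#' oxygen-dependent endpoints can rebuild the damage state at any oxygen
#' level.
#'
#' @param spectrum An [electron_spectrum] (shared voxel spectrum).
#' @param zbar A zF source accepted by [accumulate].
#' @param table A [yield_table].
#' @param taus Per-nucleus repair half-times tibble (or `NULL`).
#' @param params A [tlk_params].
#' @param oxygen_pct Nominal oxygen level, % (default normoxic 21).
#' @param T_h,dt_h TLK integration settings.
#' @return A `voxel_config`.
#' @export
voxel_config <- function(spectrum, zbar, table, taus = NULL,
                         params = tlk_params(), oxygen_pct = OXYGEN_NORMOXIC,
                         T_h = 24, dt_h = 0.005) {
  structure(list(spectrum = spectrum, zbar = zbar, table = table, taus = taus,
                 params = params, oxygen_pct = oxygen_pct,
                 T_h = T_h, dt_h = dt_h),
            class = "voxel_config")
}

# expected-mode sim_config for one oxygen level of a voxel_config
config_at_oxygen <- function(config, oxygen) {
  n <- if (is.null(config$taus)) 1L else nrow(config$taus)
  states <- accumulate_population(config$spectrum, n, config$zbar,
                                  config$table, oxygen, mode = "expected",
                                  fluctuate_counts = FALSE)
  sim_config(states, taus = config$taus, T_h = config$T_h, dt_h = config$dt_h)
}

# expected SF at one (dose, oxygen); sc may be precomputed via config_at_oxygen
voxel_sf <- function(config, dose_gy, oxygen, sc = NULL) {
  sc <- sc %||% config_at_oxygen(config, oxygen)
  simulate_sf(sc, config$params, dose_gy)$sf
}

# Bisection on a monotone-decreasing SF(D), terminating when the SF residual
# drops below tol_sf. f(d) = SF(d) - target.
bisect_dose <- function(f, lower, upper, tol_sf = 1e-6, max_iter = 200) {
  flo <- f(lower); fhi <- f(upper)
  if (abs(flo) < tol_sf) return(lower)
  if (abs(fhi) < tol_sf) return(upper)
  if (sign(flo) == sign(fhi)) {
    abort_bad("iso-effect dose not bracketed in [%g, %g] Gy", lower, upper)
  }
  for (i in seq_len(max_iter)) {
    mid <- (lower + upper) / 2
    fm <- f(mid)
    if (abs(fm) < tol_sf) return(mid)
    if (sign(fm) == sign(flo)) {
      lower <- mid; flo <- fm
    } else {
      upper <- mid
    }
  }
  (lower + upper) / 2
}

#' Hypoxia reduction factor
#'
#' The dose under the given oxygen concentration producing the same
#' expected cell killing as the reference dose under normoxia (21%),
#' divided by the reference dose. Solved by bisection over
#' `[dose_ref, 20 dose_ref]` to an SF residual below `tol_sf`; the normoxic
#' level itself returns exactly 1.
#'
#' @param config A [voxel_config].
#' @param oxygen_pct Oxygen concentration, %.
#' @param dose_ref_gy Reference (normoxic) dose, Gy.
#' @param tol_sf SF matching tolerance.
#' @return The HRF (scalar >= 1 for hypoxic oxygen levels).
#' @export
hrf <- function(config, oxygen_pct, dose_ref_gy, tol_sf = 1e-6) {
  check_number(dose_ref_gy, "dose_ref_gy", min = 0, allow_min = FALSE)
  if (oxygen_pct == OXYGEN_NORMOXIC) return(1.0)
  target <- voxel_sf(config, dose_ref_gy, OXYGEN_NORMOXIC)
  sc <- config_at_oxygen(config, oxygen_pct)
  d_star <- bisect_dose(function(d) voxel_sf(config, d, oxygen_pct, sc) - target,
                        dose_ref_gy, 20 * dose_ref_gy, tol_sf = tol_sf)
  d_star / dose_ref_gy
}

#' Survival and HRF across oxygen levels
#'
#' @param config A [voxel_config].
#' @param oxygens_pct Oxygen levels, % (default spans normoxic to extreme
#'   anoxic).
#' @param dose_ref_gy Reference dose for both the SF column and the HRF.
#' @return An `oxygen_response` tibble `oxygen_pct, sf, hrf`.
#' @export
oxygen_response <- function(config, oxygens_pct = c(21, 10, 1, 0.1, 0.01, 0.001),
                            dose_ref_gy) {
  out <- tibble::tibble(
    oxygen_pct = oxygens_pct,
    sf = purrr::map_dbl(oxygens_pct, function(o) voxel_sf(config, dose_ref_gy, o)),
    hrf = purrr::map_dbl(oxygens_pct, function(o) hrf(config, o, dose_ref_gy))
  )
  class(out) <- c("oxygen_response", class(out))
  out
}

#' @export
autoplot.oxygen_response <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), c("sf", "hrf"),
                            names_to = "endpoint", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$oxygen_pct, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~endpoint, scales = "free_y") +
    ggplot2::labs(x = "oxygen concentration (%)", y = NULL)
}

#' Relative biological effectiveness of a test beam
#'
#' Iso-effect definition: the reference-beam dose producing the same
#' expected survival as dose `dose_gy` of the test beam, divided by
#' `dose_gy`. Both configurations must share nucleus and TLK parameters; a
#' configuration compared against itself returns exactly 1.
#'
#' @param test_config,ref_config [voxel_config]s for the test and reference
#'   beam qualities.
#' @param dose_gy Test-beam dose, Gy.
#' @param tol_sf SF matching tolerance for the bisection.
#' @return The RBE (dose ratio).
#' @export
rbe <- function(test_config, ref_config, dose_gy, tol_sf = 1e-6) {
  check_number(dose_gy, "dose_gy", min = 0, allow_min = FALSE)
  if (identical(test_config, ref_config)) return(1.0)
  target <- voxel_sf(test_config, dose_gy, test_config$oxygen_pct)
  sc_ref <- config_at_oxygen(ref_config, ref_config$oxygen_pct)
  d_star <- bisect_dose(
    function(d) voxel_sf(ref_config, d, ref_config$oxygen_pct, sc_ref) - target,
    dose_gy / 20, 20 * dose_gy, tol_sf = tol_sf)
  d_star / dose_gy
}
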