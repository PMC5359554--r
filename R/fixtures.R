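# Synthetic-data generators standing in for the external transport and
# damage-simulation stages: analytic electron spectra, fixture zF/yield
# sources, and synthetic survival curves for calibration experiments. Every
# generator writes/returns the same formats the consuming modules read, so
# fixture output passes validation unchanged.

#' Electron-spectrum generator configuration
#'
#' Analytic spectrum families at the nucleus scale:
#' * `monoenergetic` — a single bin at `energy_eV`;
#' * `two_component` — log-spaced bins split into a sub-100-keV component
#'   and a high-energy component, with component weights chosen so the
#'   count fraction below 100 keV equals `low_energy_fraction` exactly;
#' * `power_law` — counts proportional to `E^-gamma` over log-spaced bins.
#'
#' The low-energy fraction is the beam-quality knob: sweeping it from ~0.1
#' (megavoltage beams) towards 1 (kilovoltage beams) emulates progressively
#' softer irradiation.
#'
#' @param kind Spectrum family.
#' @param energy_eV Energy of the monoenergetic line, eV.
#' @param low_energy_fraction Target count fraction below 100 keV
#'   (two-component family).
#' @param energy_range_eV Overall energy span, eV.
#' @param n_bins Number of bins.
#' @param total_count Total traversal count carried by the spectrum.
#' @param gamma Power-law exponent.
#' @param jitter_sd Lognormal sd of seeded within-component count jitter
#'   (0 = smooth analytic weights).
#' @param seed Seed for the jitter.
#' @return A `spectrum_config`.
#' @export
spectrum_config <- function(kind = c("two_component", "monoenergetic", "power_law"),
                            energy_eV = 1e6, low_energy_fraction = 0.2,
                            energy_range_eV = c(1e3, ENERGY_MAX_EV),
                            n_bins = 24, total_count = 1, gamma = 0.7,
                            jitter_sd = 0, seed = NULL) {
  kind <- match.arg(kind)
  check_number(low_energy_fraction, "low_energy_fraction", min = 0, max = 1)
  if (energy_range_eV[1] < ENERGY_MIN_EV || energy_range_eV[2] > ENERGY_MAX_EV) {
    abort_bad("spectrum energies must stay within [%g, %g] eV",
              ENERGY_MIN_EV, ENERGY_MAX_EV)
  }
  structure(list(kind = kind, energy_eV = energy_eV,
                 low_energy_fraction = low_energy_fraction,
                 energy_range_eV = energy_range_eV, n_bins = n_bins,
                 total_count = total_count, gamma = gamma,
                 jitter_sd = jitter_sd, seed = seed),
            class = "spectrum_config")
}

log_spaced <- function(lo, hi, n) {
  x <- 10^seq(log10(lo), log10(hi), length.out = n)
  x[1] <- lo
  x[n] <- hi  # undo round-off at the span edges
  x
}

#' Generate an electron spectrum from a configuration
#'
#' @param config A [spectrum_config].
#' @return An [electron_spectrum] tibble `energy_eV, count`.
#' @export
#' @examples
#' sp <- make_spectrum(spectrum_config("two_component", low_energy_fraction = 0.2))
#' spectrum_summary(sp)
make_spectrum <- function(config) {
  stopifnot(inherits(config, "spectrum_config"))
  e_knee <- 1e5
  sp <- switch(
    config$kind,
    monoenergetic = tibble::tibble(energy_eV = config$energy_eV,
                                   count = config$total_count),
    power_law = {
      e <- log_spaced(config$energy_range_eV[1], config$energy_range_eV[2],
                      config$n_bins)
      w <- e^(-config$gamma)
      tibble::tibble(energy_eV = e, count = config$total_count * w / sum(w))
    },
    two_component = {
      f <- config$low_energy_fraction
      n_lo <- max(2L, round(config$n_bins / 2))
      n_hi <- config$n_bins - n_lo
      lo <- if (f > 0) {
        e <- log_spaced(config$energy_range_eV[1], e_knee * 0.999, n_lo)
        w <- e^(-config$gamma)
        tibble::tibble(energy_eV = e, count = w / sum(w) * f)
      }
      hi <- if (f < 1) {
        e <- log_spaced(e_knee * 1.001, config$energy_range_eV[2], max(2L, n_hi))
        w <- e^(-config$gamma / 2)
        tibble::tibble(energy_eV = e, count = w / sum(w) * (1 - f))
      }
      out <- dplyr::bind_rows(lo, hi)
      if (config$jitter_sd > 0) {
        # seeded jitter, renormalised per component so the low-energy
        # fraction is preserved exactly
        out$count <- with_seed_maybe(config$seed, {
          j <- out$count * stats::rlnorm(nrow(out), 0, config$jitter_sd)
          low <- out$energy_eV < e_knee
          if (any(low)) j[low] <- j[low] / sum(j[low]) * f
          if (any(!low)) j[!low] <- j[!low] / sum(j[!low]) * (1 - f)
          j
        })
      }
      out$count <- out$count * config$total_count
      out
    }
  )
  electron_spectrum(sp)
}

#' Default fixture nucleus cohort and voxel configuration
#'
#' Bundles the packaged fixtures into a ready-to-run [voxel_config]: the
#' phenomenological yield table, the chord-LET specific-energy model over
#' the synthetic stopping-power curve, a two-component spectrum scaled to a
#' target nucleus dose, and a seeded repair-time cohort.
#'
#' @param n_nuclei Cohort size.
#' @param low_energy_fraction Spectrum softness knob.
#' @param dose_gy Expected nucleus dose carried by the spectrum, Gy.
#' @param oxygen_pct Nominal oxygen level, %.
#' @param params A [tlk_params].
#' @param T_h,dt_h TLK integration settings.
#' @param seed Master seed (repair-time assignment).
#' @return A [voxel_config].
#' @export
fixture_voxel_config <- function(n_nuclei = 64, low_energy_fraction = 0.2,
                                 dose_gy = 1, oxygen_pct = OXYGEN_NORMOXIC,
                                 params = tlk_params(), T_h = 24, dt_h = 0.005,
                                 seed = 1) {
  nucleus <- nucleus_model()
  table <- generate_yield_table()
  zmodel <- specific_energy_model(stopping_power = fixture_stopping_power())
  zfun <- zbar_function(zmodel, nucleus)
  sp <- make_spectrum(spectrum_config("two_component",
                                      low_energy_fraction = low_energy_fraction))
  # scale total count so the expected nucleus dose equals dose_gy
  d0 <- sum(sp$count * zfun(sp$energy_eV))
  sp$count <- sp$count * dose_gy / d0
  taus <- assign_repair_times(n_nuclei, seed = derive_seeds(seed, 1))
  voxel_config(sp, zfun, table, taus = taus, params = params,
               oxygen_pct = oxygen_pct, T_h = T_h, dt_h = dt_h)
}

#' Fixture calibration setup
#'
#' Expected-mode [sim_config] emulating a clonogenic calibration experiment:
#' a cohort of nuclei sharing the fixture voxel spectrum at a 1 Gy
#' reference dose, with seeded heterogeneous repair half-times and a 96 h
#' repair horizon.
#'
#' @param n_nuclei Cohort size (a tau-quadrature choice, not a Monte Carlo
#'   population).
#' @param oxygen_pct Oxygen level of the experiment, %.
#' @param T_h,dt_h Integration settings.
#' @param seed Master seed.
#' @return A [sim_config].
#' @export
fixture_calibration_config <- function(n_nuclei = 64, oxygen_pct = OXYGEN_NORMOXIC,
                                       T_h = 96, dt_h = 0.01, seed = 1) {
  vc <- fixture_voxel_config(n_nuclei = n_nuclei, dose_gy = 1,
                             oxygen_pct = oxygen_pct, seed = seed)
  states <- accumulate_population(vc$spectrum, n_nuclei, vc$zbar, vc$table,
                                  oxygen_pct, mode = "expected")
  sim_config(states, taus = vc$taus, T_h = T_h, dt_h = dt_h)
}

#' Generate a synthetic clonogenic survival curve
#'
#' Runs the expected-mode pipeline at each dose and optionally multiplies
#' the survival fractions by seeded lognormal noise — a stand-in for a
#' measured survival curve in calibration recovery experiments.
#'
#' @param config A [sim_config].
#' @param params Generating [tlk_params].
#' @param doses_gy Doses, Gy (ascending; default the six standard
#'   calibration doses).
#' @param noise Multiplicative lognormal sd (0 = noise-free).
#' @param seed Seed for the noise.
#' @return A [survival_curve_data] tibble.
#' @export
make_survival_curve <- function(config, params = tlk_params(),
                                doses_gy = c(0.1, 1, 2, 3, 4, 5),
                                noise = 0, seed = NULL) {
  if (is.unsorted(doses_gy)) abort_bad("doses must be ascending")
  check_number(noise, "noise", min = 0)
  sf <- simulate_sf(config, params, doses_gy)$sf
  if (noise > 0) {
    sf <- pmin(1, sf * with_seed_maybe(seed, stats::rlnorm(length(sf), 0, noise)))
  }
  survival_curve_data(doses_gy, sf)
}
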