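# Microdosimetry of a spherical nucleus: specific energy z (energy imparted
# by a single event over the site mass, Gy) and its frequency mean zF(E),
# either imported as a table from an external transport run or approximated
# analytically as mean chord length x collision stopping power.

#' Spherical nucleus geometry
#'
#' @param diameter_um Diameter in microns (default 10, a typical mammalian
#'   nucleus).
#' @param density_g_cm3 Tissue density in g/cm^3.
#' @return A `nucleus_model` with derived `mass_kg` and `mean_chord_um`
#'   (Cauchy mean chord 2d/3 for an isotropic uniform surface source).
#' @export
#' @examples
#' nucleus_model()$mass_kg  # 5.236e-13 kg
nucleus_model <- function(diameter_um = 10, density_g_cm3 = 1.0) {
  check_number(diameter_um, "diameter_um", min = 0, allow_min = FALSE)
  check_number(density_g_cm3, "density_g_cm3", min = 0, allow_min = FALSE)
  d_m <- diameter_um * 1e-6
  mass_kg <- density_g_cm3 * 1000 * pi / 6 * d_m^3
  structure(
    list(diameter_um = diameter_um, density_g_cm3 = density_g_cm3,
         mass_kg = mass_kg, mean_chord_um = 2 / 3 * diameter_um),
    class = "nucleus_model"
  )
}

#' @export
print.nucleus_model <- function(x, ...) {
  cat(sprintf("<nucleus_model> d = %g um, rho = %g g/cm^3, m = %.4g kg\n",
              x$diameter_um, x$density_g_cm3, x$mass_kg))
  invisible(x)
}

#' Specific energy of a single energy-deposition event
#'
#' z = epsilon / m: energy imparted to the nucleus by one event divided by
#' the nucleus mass, the stochastic microscopic analogue of absorbed dose.
#'
#' @param nucleus A [nucleus_model].
#' @param energy_imparted_keV Energy imparted per event, keV (vectorised,
#'   must be >= 0).
#' @return Specific energy in Gy.
#' @export
#' @examples
#' specific_energy(nucleus_model(), 1)  # 3.06e-4 Gy
specific_energy <- function(nucleus, energy_imparted_keV) {
  stopifnot(inherits(nucleus, "nucleus_model"))
  check_number(energy_imparted_keV, "energy_imparted_keV", min = 0)
  energy_imparted_keV * KEV_TO_J / nucleus$mass_kg
}

#' Frequency-mean specific energy of a sample of single events
#'
#' The arithmetic mean of single-event specific energies, i.e. the first
#' moment of the single-event distribution f(z), with its standard error.
#' Zero-deposition traversals are excluded by convention: f(z) is defined
#' over energy-depositing events only.
#'
#' @param samples Single-event specific energies, Gy (all > 0).
#' @return Tibble with `zbar_gy`, `stderr_gy`, `n_events`.
#' @export
zbar_frequency <- function(samples) {
  if (length(samples) == 0) abort_bad("need at least one single-event sample")
  check_number(samples, "samples", min = 0, allow_min = FALSE)
  tibble::tibble(
    zbar_gy = mean(samples),
    stderr_gy = stats::sd(samples) / sqrt(length(samples)),
    n_events = length(samples)
  )
}

#' Specific-energy model: tabulated or chord-LET
#'
#' Two ways to supply the energy dependence zF(E):
#' * `tabulated`: a table `energy_eV, zbar_gy` imported from an external
#'   track-structure/transport run, interpolated linearly on log10(E).
#' * `chord_let`: the analytic approximation `zF(E) = S(E) * lbar / m`, with
#'   `S` a collision stopping-power curve (`energy_eV, let_kev_per_um`) and
#'   `lbar = 2d/3` the mean chord of the sphere; capped at `E/m`, since one
#'   traversal cannot impart more than the electron's kinetic energy.
#'
#' @param table For `tabulated` mode: data frame `energy_eV, zbar_gy`.
#' @param stopping_power For `chord_let` mode: data frame
#'   `energy_eV, let_kev_per_um`.
#' @return A `specific_energy_model`.
#' @export
specific_energy_model <- function(table = NULL, stopping_power = NULL) {
  if (is.null(table) == is.null(stopping_power)) {
    abort_bad("supply exactly one of `table` (tabulated) or `stopping_power` (chord-LET)")
  }
  if (!is.null(table)) {
    stopifnot(all(c("energy_eV", "zbar_gy") %in% names(table)))
    table <- dplyr::arrange(tibble::as_tibble(table), .data$energy_eV)
    if (any(diff(table$energy_eV) <= 0)) abort_bad("tabulated energies must be strictly increasing")
    if (any(table$zbar_gy <= 0)) abort_bad("tabulated zbar values must be positive")
    mode <- "tabulated"
  } else {
    stopifnot(all(c("energy_eV", "let_kev_per_um") %in% names(stopping_power)))
    stopping_power <- dplyr::arrange(tibble::as_tibble(stopping_power), .data$energy_eV)
    if (any(diff(stopping_power$energy_eV) <= 0)) abort_bad("stopping-power energies must be strictly increasing")
    if (any(stopping_power$let_kev_per_um <= 0)) abort_bad("stopping power must be positive")
    mode <- "chord_let"
  }
  structure(list(mode = mode, table = table, stopping_power = stopping_power),
            class = "specific_energy_model")
}

#' Read a tabulated zF curve or stopping-power curve from CSV
#'
#' @param path CSV with header `energy_eV, zbar_gy` (tabulated mode) or
#'   `energy_eV, let_kev_per_um` (chord-LET mode); the mode is inferred from
#'   the header.
#' @return A [specific_energy_model].
#' @export
read_specific_energy_model <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if ("zbar_gy" %in% names(df)) {
    specific_energy_model(table = df)
  } else if ("let_kev_per_um" %in% names(df)) {
    specific_energy_model(stopping_power = df)
  } else {
    abort_bad("expected a `zbar_gy` or `let_kev_per_um` column in %s", path)
  }
}

model_energy_range <- function(model) {
  src <- model$table %||% model$stopping_power
  range(src$energy_eV)
}

#' Frequency-mean specific energy as a function of electron energy
#'
#' Evaluates zF(E) for each requested energy: interpolated stored values in
#' tabulated mode (linear on log10 E), or `S(E) * lbar / m` capped at `E/m`
#' in chord-LET mode.
#'
#' @param model A [specific_energy_model].
#' @param nucleus A [nucleus_model].
#' @param energies Electron kinetic energies, eV; must lie within the
#'   model's tabulated range.
#' @return Tibble `energy_eV, zbar_gy`.
#' @export
zbar_curve <- function(model, nucleus, energies) {
  stopifnot(inherits(model, "specific_energy_model"),
            inherits(nucleus, "nucleus_model"))
  rng <- model_energy_range(model)
  bad <- which(energies < rng[1] | energies > rng[2])
  if (length(bad) > 0) {
    abort_bad("energy %g eV outside model range [%g, %g] eV",
              energies[bad[1]], rng[1], rng[2])
  }
  if (model$mode == "tabulated") {
    z <- stats::approx(log10(model$table$energy_eV), model$table$zbar_gy,
                       xout = log10(energies))$y
  } else {
    S <- stats::approx(log10(model$stopping_power$energy_eV),
                       model$stopping_power$let_kev_per_um,
                       xout = log10(energies))$y
    z <- S * nucleus$mean_chord_um * KEV_TO_J / nucleus$mass_kg
    cap <- energies / 1000 * KEV_TO_J / nucleus$mass_kg  # E/m in Gy
    z <- pmin(z, cap)
  }
  tibble::tibble(energy_eV = energies, zbar_gy = z)
}

#' Interpolating function E -> zF
#'
#' Convenience closure over [zbar_curve], used by the damage-accumulation
#' step.
#'
#' @inheritParams zbar_curve
#' @return A vectorised function mapping energy (eV) to zF (Gy).
#' @export
zbar_function <- function(model, nucleus) {
  force(model); force(nucleus)
  function(energies) zbar_curve(model, nucleus, energies)$zbar_gy
}

#' Approximate electron stopping-power fixture curve
#'
#' A synthetic, hand-tabulated approximation to the collision stopping power
#' of electrons in unit-density soft tissue (keV/um), spanning 50 eV to
#' 6 MeV. Only intended as a self-contained stand-in for an imported
#' transport-derived zF table; magnitudes are approximate (within tens of
#' percent of reference water values at intermediate energies, cruder at the
#' extremes).
#'
#' @return Tibble `energy_eV, let_kev_per_um`.
#' @export
fixture_stopping_power <- function() {
  tibble::tibble(
    energy_eV = c(50, 100, 300, 1e3, 3e3, 1e4, 3e4,
                  1e5, 3e5, 1e6, 3e6, 6e6),
    let_kev_per_um = c(18, 22, 18, 12.6, 5.9, 2.3, 1.0,
                       0.43, 0.25, 0.186, 0.180, 0.183)
  )
}
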