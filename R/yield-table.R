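# Cellular DSB damage database: a rectangular (energy x oxygen) grid of
# simple-DSB and complex-DSB yields per cell per Gy, with log-log bilinear
# interpolation. Real databases (e.g. an MCDS-style damage simulation run)
# are imported through the CSV exchange format; a phenomenological generator
# provides self-contained fixtures.

#' Construct a validated DSB yield table
#'
#' A yield table is a tibble with one row per (energy, oxygen) grid node and
#' columns `energy_eV`, `oxygen_pct`, `sdsb_per_cell_gy`, `cdsb_per_cell_gy`.
#' The grid must be complete (every energy x oxygen combination present
#' exactly once) so that bilinear interpolation is unambiguous. Yields are
#' simple DSBs (two opposite-strand SSBs within 10 bp) and complex DSBs
#' (an sDSB with at least one additional nearby break), the lesion classes
#' repaired by fast and slow rejoining kinetics respectively.
#'
#' @param records Data frame with the four columns above.
#' @param diameter_um Nucleus diameter the yields were scored for (microns).
#' @param provenance `"imported"` for an external database, `"fixture"` for
#'   the built-in generator.
#' @return A `yield_table`: a tibble sorted by oxygen then energy, with
#'   `diameter_um` and `provenance` attributes.
#' @export
yield_table <- function(records, diameter_um = 10,
                        provenance = c("imported", "fixture")) {
  provenance <- match.arg(provenance)
  needed <- c("energy_eV", "oxygen_pct", "sdsb_per_cell_gy", "cdsb_per_cell_gy")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort_bad("yield table is missing column(s): %s",
              paste(missing_cols, collapse = ", "))
  }
  records <- tibble::as_tibble(records)[needed]
  for (nm in needed) {
    if (!is.numeric(records[[nm]]) || anyNA(records[[nm]])) {
      abort_bad("yield table column `%s` must be numeric with no missing values", nm)
    }
  }
  bad <- which(records$energy_eV < ENERGY_MIN_EV)
  if (length(bad) > 0) {
    abort_bad("row %d: energy %g eV below the %g eV database floor",
              bad[1], records$energy_eV[bad[1]], ENERGY_MIN_EV)
  }
  bad <- which(records$oxygen_pct <= 0 | records$oxygen_pct > 100)
  if (length(bad) > 0) {
    abort_bad(paste0(
      "row %d: oxygen %g%% outside (0, 100]; store anoxic (0%%) conditions ",
      "as %g%% (the log-axis floor)"),
      bad[1], records$oxygen_pct[bad[1]], OXYGEN_FLOOR)
  }
  bad <- which(records$sdsb_per_cell_gy < 0 | records$cdsb_per_cell_gy < 0)
  if (length(bad) > 0) {
    abort_bad("row %d: negative yield", bad[1])
  }
  key <- paste(records$energy_eV, records$oxygen_pct)
  if (anyDuplicated(key)) {
    abort_bad("row %d: duplicate grid point (energy %g eV, oxygen %g%%)",
              which(duplicated(key))[1],
              records$energy_eV[which(duplicated(key))[1]],
              records$oxygen_pct[which(duplicated(key))[1]])
  }
  energies <- sort(unique(records$energy_eV))
  oxygens <- sort(unique(records$oxygen_pct))
  if (nrow(records) != length(energies) * length(oxygens)) {
    abort_bad("grid not rectangular: %d rows but %d energies x %d oxygen levels",
              nrow(records), length(energies), length(oxygens))
  }
  records <- dplyr::arrange(records, .data$oxygen_pct, .data$energy_eV)
  structure(records,
            class = c("yield_table", class(tibble::tibble()))) |>
    `attr<-`("diameter_um", diameter_um) |>
    `attr<-`("provenance", provenance)
}

#' Read a yield table from its CSV exchange format
#'
#' Expected header: `energy_eV, oxygen_pct, sdsb_per_cell_gy,
#' cdsb_per_cell_gy` (UTF-8, `.` decimal separator). Validation errors name
#' the offending row.
#'
#' @param path CSV file path.
#' @inheritParams yield_table
#' @return A [yield_table].
#' @export
read_yield_table <- function(path, diameter_um = 10, provenance = "imported") {
  df <- readr::read_csv(path, show_col_types = FALSE)
  yield_table(df, diameter_um = diameter_um, provenance = provenance)
}

#' Write a yield table to CSV
#'
#' Full printed precision, so `read_yield_table(write_yield_table(x))`
#' round-trips losslessly.
#'
#' @param table A [yield_table].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_yield_table <- function(table, path) {
  stopifnot(inherits(table, "yield_table"))
  readr::write_csv(tibble::as_tibble(table), path)
  invisible(path)
}

yield_grid_axes <- function(table) {
  list(
    energy = sort(unique(table$energy_eV)),
    oxygen = sort(unique(table$oxygen_pct))
  )
}

# Bilinear interpolation of one yield column on (log10 E, log10 O2) axes.
# `table` rows are sorted oxygen-major then energy, so the column reshapes
# into an energy x oxygen matrix directly.
interp_bilinear <- function(table, column, energy, oxygen) {
  ax <- yield_grid_axes(table)
  le <- log10(ax$energy); lo <- log10(ax$oxygen)
  z <- matrix(table[[column]], nrow = length(ax$energy), ncol = length(ax$oxygen))
  qe <- log10(energy); qo <- log10(oxygen)
  ie <- pmin(pmax(findInterval(qe, le), 1L), length(le) - 1L)
  io <- pmin(pmax(findInterval(qo, lo), 1L), length(lo) - 1L)
  we <- (qe - le[ie]) / (le[ie + 1L] - le[ie])
  wo <- (qo - lo[io]) / (lo[io + 1L] - lo[io])
  (1 - we) * (1 - wo) * z[cbind(ie, io)] +
    we * (1 - wo) * z[cbind(ie + 1L, io)] +
    (1 - we) * wo * z[cbind(ie, io + 1L)] +
    we * wo * z[cbind(ie + 1L, io + 1L)]
}

#' Interpolate DSB yields at arbitrary energy and oxygen
#'
#' Bilinear interpolation on log10(energy) and log10(oxygen) axes — yields
#' vary over decades in both variables, so linear-in-log is the stable choice.
#' Queries are exact at grid nodes. Queries outside the grid hull are
#' rejected, never extrapolated or clamped.
#'
#' @param table A [yield_table].
#' @param energy Electron kinetic energy in eV (vectorised).
#' @param oxygen Oxygen concentration in % v/v (vectorised, recycled).
#' @return Tibble with columns `energy_eV`, `oxygen_pct`, `sdsb_per_gy`,
#'   `cdsb_per_gy`.
#' @export
#' @examples
#' tab <- generate_yield_table()
#' interpolate_yield(tab, energy = c(1e3, 1e6), oxygen = 21)
interpolate_yield <- function(table, energy, oxygen) {
  stopifnot(inherits(table, "yield_table"))
  n <- max(length(energy), length(oxygen))
  energy <- rep_len(energy, n); oxygen <- rep_len(oxygen, n)
  ax <- yield_grid_axes(table)
  bad <- which(energy < min(ax$energy) | energy > max(ax$energy))
  if (length(bad) > 0) {
    abort_bad("energy %g eV outside table range [%g, %g] eV",
              energy[bad[1]], min(ax$energy), max(ax$energy))
  }
  bad <- which(oxygen < min(ax$oxygen) | oxygen > max(ax$oxygen))
  if (length(bad) > 0) {
    abort_bad("oxygen %g%% outside table range [%g, %g]%%",
              oxygen[bad[1]], min(ax$oxygen), max(ax$oxygen))
  }
  tibble::tibble(
    energy_eV = energy,
    oxygen_pct = oxygen,
    sdsb_per_gy = interp_bilinear(table, "sdsb_per_cell_gy", energy, oxygen),
    cdsb_per_gy = interp_bilinear(table, "cdsb_per_cell_gy", energy, oxygen)
  )
}

#' Oxygen scaling factor of the fixture yield model
#'
#' `g(c) = (1 + (m - 1) c / (c + K)) / m`: a saturating oxygen-enhancement
#' curve with `g(0) = 1/m` (anoxic yields reduced m-fold) rising to
#' `g(100) ~ 1`. Strictly increasing in `c`.
#'
#' @param oxygen Oxygen concentration, % v/v. Zero is mapped to the 0.001%
#'   log-axis floor.
#' @param m Maximum yield reduction factor at full anoxia.
#' @param K Half-saturation oxygen concentration, %.
#' @export
oxygen_scaling <- function(oxygen, m = 3.0, K = 0.3) {
  if (m <= 0 || K <= 0) abort_bad("oxygen scaling parameters must be positive")
  oxygen <- ifelse(oxygen <= 0, OXYGEN_FLOOR, oxygen)
  (1 + (m - 1) * oxygen / (oxygen + K)) / m
}

#' Generate a phenomenological fixture yield table
#'
#' A self-contained stand-in for an imported damage-simulation database,
#' reproducing the qualitative behaviour of measured DSB yield curves: total
#' yield flat above ~100 keV and rising steeply below; yields suppressed at
#' low oxygen via [oxygen_scaling]; complex-DSB fraction growing as energy
#' and oxygen decrease. Magnitudes are conventions, not measurements.
#'
#' Total yield is `Y_inf * (1 + A * max((E/E0)^-b - 1, eps))` with
#' `E0 = 100 keV`: a power-law rise below the knee and a plateau
#' `~Y_inf` above it, continuous at the knee.
#'
#' @param energies Grid energies, eV (default 25 log-spaced points spanning
#'   50 eV to 6 MeV).
#' @param oxygens Grid oxygen levels, % (0 is stored as 0.001%).
#' @param y_inf Plateau total DSB yield per cell per Gy at full oxygen.
#' @param A,b Low-energy rise amplitude and exponent.
#' @param m,K Oxygen model parameters, see [oxygen_scaling].
#' @param cdsb_base High-energy normoxic complex-DSB fraction.
#' @param cdsb_energy_gain,cdsb_oxygen_gain Increments of the complex
#'   fraction toward low energy / low oxygen.
#' @param plateau_eps Residual plateau slope term.
#' @param diameter_um Nominal nucleus diameter tag, microns.
#' @return A [yield_table] with `provenance = "fixture"`.
#' @export
#' @examples
#' tab <- generate_yield_table()
#' interpolate_yield(tab, 1e6, 21)
generate_yield_table <- function(
    energies = 10^seq(log10(ENERGY_MIN_EV), log10(ENERGY_MAX_EV), length.out = 25),
    oxygens = c(0.001, 0.01, 0.1, 1, 3, 10, 21, 100),
    y_inf = 8, A = 2.5, b = 0.5, m = 3.0, K = 0.3,
    cdsb_base = 0.40, cdsb_energy_gain = 0.2, cdsb_oxygen_gain = 0.1,
    plateau_eps = 0.01, diameter_um = 10) {
  if (y_inf <= 0 || A <= 0 || b <= 0 || m <= 0 || K <= 0 || plateau_eps <= 0) {
    abort_bad("fixture shape parameters must be positive")
  }
  oxygens <- sort(unique(ifelse(oxygens <= 0, OXYGEN_FLOOR, oxygens)))
  # snap round-off at the span edges back onto the database bounds
  energies <- sort(unique(pmin(pmax(energies, ENERGY_MIN_EV), ENERGY_MAX_EV)))
  e0 <- 1e5  # 100 keV knee
  grid <- tidyr::expand_grid(oxygen_pct = oxygens, energy_eV = energies)
  total <- y_inf * (1 + A * pmax((grid$energy_eV / e0)^(-b) - 1, plateau_eps)) *
    oxygen_scaling(grid$oxygen_pct, m = m, K = K)
  # complex fraction: decreasing in E (logistic in sqrt scale), decreasing in O2
  fc <- cdsb_base +
    cdsb_energy_gain / (1 + (grid$energy_eV / e0)^0.5) +
    cdsb_oxygen_gain * (1 - grid$oxygen_pct / (grid$oxygen_pct + 1))
  fc <- pmin(fc, 0.95)
  yield_table(
    tibble::tibble(
      energy_eV = grid$energy_eV,
      oxygen_pct = grid$oxygen_pct,
      sdsb_per_cell_gy = total * (1 - fc),
      cdsb_per_cell_gy = total * fc
    ),
    diameter_um = diameter_um, provenance = "fixture"
  )
}

#' @export
print.yield_table <- function(x, ...) {
  ax <- yield_grid_axes(x)
  cat(sprintf(
    "<yield_table> %d energies x %d oxygen levels (%s, %g um nucleus)\n",
    length(ax$energy), length(ax$oxygen),
    attr(x, "provenance") %||% "imported", attr(x, "diameter_um") %||% NA
  ))
  NextMethod()
}

#' Plot a yield table
#'
#' Total, simple and complex DSB yields per cell per Gy against electron
#' energy, one line per oxygen level, log-log axes.
#'
#' @param object A [yield_table].
#' @param ... Unused.
#' @export
autoplot.yield_table <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(total = .data$sdsb_per_cell_gy + .data$cdsb_per_cell_gy) |>
    tidyr::pivot_longer(c("sdsb_per_cell_gy", "cdsb_per_cell_gy", "total"),
                        names_to = "lesion", values_to = "yield")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$energy_eV, y = .data$yield,
    colour = factor(.data$oxygen_pct), linetype = .data$lesion
  )) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "electron energy (eV)", y = "DSB / cell / Gy",
                  colour = "oxygen (%)", linetype = NULL)
}
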