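# Spectrum-based damage accumulation: microscopic dose and initial sDSB/cDSB
# counts per nucleus from an electron fluence spectrum, following the
# microdosimetric rule dose = (number of traversals) x zF, and yield =
# sum over the spectrum of count x zF(E) x Sigma(E, oxygen).

#' Build a validated electron spectrum
#'
#' A spectrum is a tibble of bins `energy_eV, count`, where `count` is the
#' (possibly fractional) number of electrons traversing the nucleus at that
#' energy. An optional `nucleus_id` column carries per-nucleus spectra.
#'
#' @param df Data frame with `energy_eV` and `count` (and optionally
#'   `nucleus_id`).
#' @return A tibble of class `electron_spectrum`.
#' @export
electron_spectrum <- function(df) {
  stopifnot(all(c("energy_eV", "count") %in% names(df)))
  df <- tibble::as_tibble(df)
  if (any(df$count < 0)) abort_bad("spectrum counts must be >= 0")
  if (any(df$energy_eV < ENERGY_MIN_EV | df$energy_eV > ENERGY_MAX_EV)) {
    bad <- which(df$energy_eV < ENERGY_MIN_EV | df$energy_eV > ENERGY_MAX_EV)[1]
    abort_bad("bin %d: energy %g eV outside [%g eV, %g eV]",
              bad, df$energy_eV[bad], ENERGY_MIN_EV, ENERGY_MAX_EV)
  }
  class(df) <- c("electron_spectrum", class(tibble::tibble()))
  df
}

#' Read a radiation-pattern CSV
#'
#' Columns `energy_eV, count`, plus optional `nucleus_id`; a file without
#' `nucleus_id` is a shared voxel spectrum.
#'
#' @param path CSV path.
#' @return An [electron_spectrum].
#' @export
read_spectrum <- function(path) {
  electron_spectrum(readr::read_csv(path, show_col_types = FALSE))
}

#' Write a radiation-pattern CSV
#' @param spectrum An [electron_spectrum].
#' @param path Output path.
#' @export
write_spectrum <- function(spectrum, path) {
  readr::write_csv(tibble::as_tibble(spectrum), path)
  invisible(path)
}

#' Summarise an electron spectrum
#'
#' Total traversal count, count-weighted mean energy, and the fraction of
#' electrons below 100 keV — the low-energy fraction that drives yield
#' differences between beam qualities.
#'
#' @param spectrum An [electron_spectrum] (or data frame with `energy_eV`,
#'   `count`).
#' @return One-row tibble `total_count, mean_energy_eV, frac_below_100keV`.
#' @export
spectrum_summary <- function(spectrum) {
  if (nrow(spectrum) == 0 || sum(spectrum$count) <= 0) {
    abort_bad("spectrum is empty (no counts)")
  }
  w <- spectrum$count / sum(spectrum$count)
  tibble::tibble(
    total_count = sum(spectrum$count),
    mean_energy_eV = sum(w * spectrum$energy_eV),
    frac_below_100keV = sum(w[spectrum$energy_eV < 1e5])
  )
}

resolve_zbar <- function(zbar) {
  if (is.function(zbar)) return(zbar)
  if (is.data.frame(zbar) && all(c("energy_eV", "zbar_gy") %in% names(zbar))) {
    model <- specific_energy_model(table = zbar)
    return(function(E) {
      stats::approx(log10(model$table$energy_eV), model$table$zbar_gy,
                    xout = log10(E))$y
    })
  }
  abort_bad("`zbar` must be a function of energy or a table with energy_eV, zbar_gy")
}

accumulate_one <- function(spectrum, zbar_fn, table, oxygen, mode, seed, nucleus_id) {
  if (nrow(spectrum) == 0) {
    return(tibble::tibble(nucleus_id = nucleus_id, dose_gy = 0,
                          L1_0 = 0, L2_0 = 0, oxygen_pct = oxygen))
  }
  z <- zbar_fn(spectrum$energy_eV)
  if (anyNA(z)) {
    abort_bad("bin %d: energy %g eV outside the zbar model range",
              which(is.na(z))[1], spectrum$energy_eV[which(is.na(z))[1]])
  }
  yields <- interpolate_yield(table, spectrum$energy_eV, oxygen)
  dose <- sum(spectrum$count * z)
  y_s <- sum(spectrum$count * z * yields$sdsb_per_gy)
  y_c <- sum(spectrum$count * z * yields$cdsb_per_gy)
  if (mode == "sampled") {
    draws <- with_seed_maybe(seed, stats::rpois(2L, c(y_s, y_c)))
    y_s <- draws[1]; y_c <- draws[2]
  }
  tibble::tibble(nucleus_id = nucleus_id, dose_gy = dose,
                 L1_0 = y_s, L2_0 = y_c, oxygen_pct = oxygen)
}

#' Accumulate microscopic dose and DSB damage from a spectrum
#'
#' For each spectrum bin, the microscopic dose contribution is
#' `count * zF(E)` and the damage contribution is that dose times the
#' interpolated yield per Gy at `(E, oxygen)`; summing over bins gives the
#' nucleus dose `D` and the initial simple/complex DSB burdens `L1_0, L2_0`.
#' `mode = "expected"` stores the real-valued means; `mode = "sampled"`
#' replaces them with independent Poisson draws at those means (integer
#' lesion counts for stochastic per-cell survival).
#'
#' If the spectrum carries a `nucleus_id` column, each nucleus is
#' accumulated from its own bins.
#'
#' @param spectrum An [electron_spectrum].
#' @param zbar A function E -> zF(E) (see [zbar_function]) or a tibble
#'   `energy_eV, zbar_gy`.
#' @param table A [yield_table].
#' @param oxygen Oxygen concentration, % v/v.
#' @param mode `"expected"` or `"sampled"`.
#' @param seed Seed for `mode = "sampled"`.
#' @return A `damage_state` tibble: `nucleus_id, dose_gy, L1_0, L2_0,
#'   oxygen_pct`, one row per nucleus.
#' @export
#' @examples
#' tab <- generate_yield_table()
#' sp <- make_spectrum(spectrum_config("monoenergetic", energy_eV = 1e6))
#' accumulate(sp, function(E) rep(1e-3, length(E)), tab, oxygen = 21)
accumulate <- function(spectrum, zbar, table, oxygen,
                       mode = c("expected", "sampled"), seed = NULL) {
  mode <- match.arg(mode)
  check_number(oxygen, "oxygen", min = 0, max = 100)
  zbar_fn <- resolve_zbar(zbar)
  spectrum <- tibble::as_tibble(spectrum)
  if ("nucleus_id" %in% names(spectrum)) {
    ids <- unique(spectrum$nucleus_id)
    seeds <- derive_seeds(seed, length(ids))
    out <- purrr::imap(
      split(spectrum, factor(spectrum$nucleus_id, levels = ids)),
      function(sp, i) {
        accumulate_one(sp, zbar_fn, table, oxygen, mode,
                       if (is.null(seeds)) NULL else seeds[match(i, as.character(ids))],
                       nucleus_id = sp$nucleus_id[1])
      }
    )
    return(dplyr::bind_rows(out))
  }
  accumulate_one(spectrum, zbar_fn, table, oxygen, mode, seed, nucleus_id = 1L)
}

#' Accumulate damage for a population sharing one voxel spectrum
#'
#' Replicates a shared voxel spectrum over `n` nuclei. With
#' `fluctuate_counts = TRUE` each nucleus receives Poisson-fluctuated bin
#' counts around the shared expectation (independent traversal statistics);
#' otherwise all nuclei see the identical expected spectrum. Damage is then
#' accumulated per nucleus in the requested mode.
#'
#' @inheritParams accumulate
#' @param n Number of nuclei.
#' @param fluctuate_counts Poisson-fluctuate bin counts per nucleus.
#' @return A `damage_state` tibble with `n` rows.
#' @export
accumulate_population <- function(spectrum, n, zbar, table, oxygen,
                                  mode = c("expected", "sampled"),
                                  fluctuate_counts = FALSE, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n >= 1)
  check_number(oxygen, "oxygen", min = 0, max = 100)
  zbar_fn <- resolve_zbar(zbar)
  spectrum <- tibble::as_tibble(spectrum)
  z <- zbar_fn(spectrum$energy_eV)
  yields <- interpolate_yield(table, spectrum$energy_eV, oxygen)
  seeds <- derive_seeds(seed, 2L)
  nb <- nrow(spectrum)
  counts <- if (fluctuate_counts) {
    with_seed_maybe(seeds[1],
      matrix(stats::rpois(n * nb, rep(spectrum$count, each = n)), nrow = n))
  } else {
    matrix(rep(spectrum$count, each = n), nrow = n)
  }
  dose <- as.numeric(counts %*% z)
  y_s <- as.numeric(counts %*% (z * yields$sdsb_per_gy))
  y_c <- as.numeric(counts %*% (z * yields$cdsb_per_gy))
  if (mode == "sampled") {
    drawn <- with_seed_maybe(seeds[2], list(
      s = stats::rpois(n, y_s), c = stats::rpois(n, y_c)))
    y_s <- drawn$s; y_c <- drawn$c
  }
  tibble::tibble(nucleus_id = seq_len(n), dose_gy = dose,
                 L1_0 = y_s, L2_0 = y_c, oxygen_pct = oxygen)
}

#' Draw integer lesion counts around expected damage burdens
#'
#' Replaces the (real-valued) expected burdens `L1_0`, `L2_0` of each
#' nucleus with independent Poisson draws at those means — the sampling
#' step of the stochastic pipeline, applied after any dose rescaling so the
#' draws happen at the target fluence.
#'
#' @param state A `damage_state` tibble (expected mode).
#' @param seed Seed for the draws.
#' @return The state with integer `L1_0`, `L2_0`.
#' @export
sample_damage <- function(state, seed = NULL) {
  n <- nrow(state)
  drawn <- with_seed_maybe(seed, list(
    s = stats::rpois(n, state$L1_0), c = stats::rpois(n, state$L2_0)))
  dplyr::mutate(state, L1_0 = as.numeric(drawn$s), L2_0 = as.numeric(drawn$c))
}

#' Rescale a damage state to a target macroscopic dose
#'
#' Damage induction is linear in dose, so dose and both initial lesion
#' burdens are scaled by `target_dose / dose` (expected-value semantics).
#' This is how damage patterns computed at a simulation's natural fluence
#' are converted to prescribed macroscopic dose levels.
#'
#' @param state A `damage_state` tibble (rows rescaled independently).
#' @param target_dose_gy Target macroscopic dose, Gy (>= 0).
#' @return Rescaled `damage_state`.
#' @export
rescale_to_dose <- function(state, target_dose_gy) {
  check_number(target_dose_gy, "target_dose_gy", min = 0)
  if (any(state$dose_gy <= 0)) {
    abort_bad("cannot rescale a state with zero dose (nucleus %s)",
              state$nucleus_id[which(state$dose_gy <= 0)[1]])
  }
  ratio <- target_dose_gy / state$dose_gy
  dplyr::mutate(state,
                dose_gy = .data$dose_gy * ratio,
                L1_0 = .data$L1_0 * ratio,
                L2_0 = .data$L2_0 * ratio)
}
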