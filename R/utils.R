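# Shared constants and small helpers.

# J per keV (CODATA elementary charge x 1000)
KEV_TO_J <- 1.602176634e-16

# Common database energy range, eV
ENERGY_MIN_EV <- 50
ENERGY_MAX_EV <- 6e6

# Normoxic reference oxygen concentration, % v/v
OXYGEN_NORMOXIC <- 21

# Oxygen level standing in for fully anoxic (0%) conditions on the log axis
OXYGEN_FLOOR <- 0.001

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_bad <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)

check_number <- function(x, name, min = -Inf, max = Inf, allow_min = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    abort_bad("`%s` must be numeric and non-missing", name)
  }
  bad <- if (allow_min) x < min | x > max else x <= min | x > max
  if (any(bad)) {
    abort_bad(
      "`%s` must lie in %s%g, %g]; got %g", name,
      if (allow_min) "[" else "(", min, max, x[which(bad)[1]]
    )
  }
  invisible(x)
}

#' Derive reproducible child seeds from one master seed
#'
#' Stochastic stages (repair-time assignment, Poisson damage sampling,
#' Bernoulli survival draws) each receive their own child seed so a stage can
#' be reproduced in isolation. Derivation is itself seeded, so one master seed
#' fixes the whole pipeline.
#'
#' @param seed Master seed (single integer), or `NULL` for no seeding.
#' @param n Number of child seeds.
#' @return Integer vector of length `n` (or `NULL` if `seed` is `NULL`).
#' @export
#' @examples
#' derive_seeds(1, 3)
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(NULL)
  check_number(seed, "seed")
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}
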