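# Shared fixtures, built in code at test time.

# minimal rectangular yield grid with hand-picked values
tiny_yield_table <- function() {
  yield_table(tibble::tibble(
    energy_eV = rep(c(1e3, 1e4, 1e6), times = 2),
    oxygen_pct = rep(c(1, 21), each = 3),
    sdsb_per_cell_gy = c(30, 12, 5, 60, 24, 10),
    cdsb_per_cell_gy = c(20, 8, 3, 40, 16, 6)
  ))
}

# constant-yield table: every node Sigma_s = 25, Sigma_c = 25
flat_yield_table <- function(value = 25) {
  yield_table(tibble::tibble(
    energy_eV = rep(c(1e2, 6e6), times = 2),
    oxygen_pct = rep(c(0.001, 100), each = 2),
    sdsb_per_cell_gy = value, cdsb_per_cell_gy = value
  ))
}

const_zbar <- function(z) function(E) rep(z, length(E))

# independent nested-1D interpolation oracle (energy first, then oxygen),
# both axes on log10 scale; one query at a time
interp_oracle <- function(table, energy, oxygen, column) {
  oxygens <- sort(unique(table$oxygen_pct))
  vapply(seq_along(energy), function(i) {
    at_oxygen <- vapply(oxygens, function(o) {
      sub <- table[table$oxygen_pct == o, ]
      sub <- sub[order(sub$energy_eV), ]
      stats::approx(log10(sub$energy_eV), sub[[column]],
                    xout = log10(energy[i]))$y
    }, numeric(1))
    stats::approx(log10(oxygens), at_oxygen, xout = log10(oxygen[i]))$y
  }, numeric(1))
}

# forward-Euler reference integrator for the TLK equations, written
# independently of the package's compiled RK4 path
euler_tlk <- function(L1, L2, params, T_h, dt_h) {
  lam1 <- log(2) / params$tau1_h
  lam2 <- log(2) / params$tau2_h
  LL <- 0
  nsteps <- round(T_h / dt_h)
  for (s in seq_len(nsteps)) {
    tot <- L1 + L2
    d1 <- -lam1 * L1 - params$eta_per_h * L1 * tot
    d2 <- -lam2 * L2 - params$eta_per_h * L2 * tot
    dL <- params$beta1 * lam1 * L1 + params$beta2 * lam2 * L2 +
      params$lethal_pair_frac * params$eta_per_h * tot^2
    L1 <- L1 + dt_h * d1
    L2 <- L2 + dt_h * d2
    LL <- LL + dt_h * dL
  }
  list(L1 = L1, L2 = L2, L_lethal = LL)
}

# small, fast calibration setup shared across calibration tests
quick_calib_config <- function(n_nuclei = 16, seed = 1) {
  fixture_calibration_config(n_nuclei = n_nuclei, seed = seed, dt_h = 0.02)
}
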