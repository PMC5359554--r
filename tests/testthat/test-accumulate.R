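test_that("single-bin accumulation reproduces the hand computation", {
  tab <- flat_yield_table(25)
  sp <- electron_spectrum(tibble::tibble(energy_eV = 1e6, count = 100))
  st <- accumulate(sp, const_zbar(0.01), tab, oxygen = 21)
  expect_equal(st$dose_gy, 1)
  expect_equal(st$L1_0, 25)
  expect_equal(st$L2_0, 25)
})

test_that("an empty spectrum accumulates zero dose and damage", {
  tab <- flat_yield_table()
  st <- accumulate(electron_spectrum(tibble::tibble(energy_eV = numeric(0),
                                                    count = numeric(0))),
                   const_zbar(0.01), tab, oxygen = 21)
  expect_equal(st$dose_gy, 0)
  expect_equal(st$L1_0 + st$L2_0, 0)
})

test_that("accumulation matches a term-by-term brute-force oracle", {
  tab <- generate_yield_table()
  nuc <- nucleus_model()
  zfun <- zbar_function(
    specific_energy_model(stopping_power = fixture_stopping_power()), nuc)
  sp <- withr::with_seed(3, electron_spectrum(tibble::tibble(
    energy_eV = 10^runif(50, log10(100), log10(6e6)),
    count = runif(50, 0, 10)
  )))
  st <- accumulate(sp, zfun, tab, oxygen = 21)
  # independent per-bin summation
  D <- 0; Ys <- 0; Yc <- 0
  for (i in seq_len(nrow(sp))) {
    z <- zfun(sp$energy_eV[i])
    y <- interpolate_yield(tab, sp$energy_eV[i], 21)
    D <- D + sp$count[i] * z
    Ys <- Ys + sp$count[i] * z * y$sdsb_per_gy
    Yc <- Yc + sp$count[i] * z * y$cdsb_per_gy
  }
  expect_equal(st$dose_gy, D, tolerance = 1e-12)
  expect_equal(st$L1_0, Ys, tolerance = 1e-12)
  expect_equal(st$L2_0, Yc, tolerance = 1e-12)
})

test_that("accumulation is additive over spectra and linear in counts", {
  tab <- generate_yield_table()
  zf <- const_zbar(5e-3)
  mk <- function(seed, n) withr::with_seed(seed, tibble::tibble(
    energy_eV = 10^runif(n, 2.2, 6.5), count = runif(n)))
  a <- mk(10, 20); b <- mk(11, 15)
  st_a <- accumulate(electron_spectrum(a), zf, tab, 21)
  st_b <- accumulate(electron_spectrum(b), zf, tab, 21)
  st_ab <- accumulate(electron_spectrum(dplyr::bind_rows(a, b)), zf, tab, 21)
  expect_equal(st_ab$dose_gy, st_a$dose_gy + st_b$dose_gy, tolerance = 1e-12)
  expect_equal(st_ab$L1_0, st_a$L1_0 + st_b$L1_0, tolerance = 1e-12)
  scaled <- accumulate(electron_spectrum(dplyr::mutate(a, count = count * 3)),
                       zf, tab, 21)
  expect_equal(scaled$L2_0, 3 * st_a$L2_0, tolerance = 1e-12)
})

test_that("sampled damage is Poisson around the expected-mode means", {
  tab <- flat_yield_table(25)
  sp <- electron_spectrum(tibble::tibble(energy_eV = 1e6, count = 100))
  expected <- accumulate(sp, const_zbar(0.01), tab, 21)
  n <- 1000
  pop <- accumulate_population(sp, n, const_zbar(0.01), tab, 21,
                               mode = "sampled", seed = 5)
  expect_true(all(pop$L1_0 == round(pop$L1_0)))  # integer counts
  for (col in c("L1_0", "L2_0")) {
    mu <- expected[[col]]
    expect_lt(abs(mean(pop[[col]]) - mu), 3 * sqrt(mu / n))
  }
  # same seed reproduces the draws
  pop2 <- accumulate_population(sp, n, const_zbar(0.01), tab, 21,
                                mode = "sampled", seed = 5)
  expect_identical(pop$L1_0, pop2$L1_0)
})

test_that("per-nucleus spectra and count fluctuation are honoured", {
  tab <- flat_yield_table(25)
  sp <- tibble::tibble(nucleus_id = c(1, 1, 2),
                       energy_eV = c(1e4, 1e6, 1e6),
                       count = c(1, 2, 5))
  st <- accumulate(electron_spectrum(sp), const_zbar(0.01), tab, 21)
  expect_equal(nrow(st), 2)
  expect_equal(st$dose_gy, c(0.03, 0.05))
  # fluctuated shared spectrum: per-nucleus doses vary around the mean
  sp2 <- electron_spectrum(tibble::tibble(energy_eV = 1e6, count = 50))
  pop <- accumulate_population(sp2, 500, const_zbar(0.01), tab, 21,
                               fluctuate_counts = TRUE, seed = 9)
  expect_gt(stats::sd(pop$dose_gy), 0)
  expect_lt(abs(mean(pop$dose_gy) - 0.5), 3 * 0.01 * sqrt(50 / 500))
})

test_that("rescaling to a target dose scales damage linearly", {
  st <- tibble::tibble(nucleus_id = 1L, dose_gy = 0.89,
                       L1_0 = 20, L2_0 = 20, oxygen_pct = 21)
  re <- rescale_to_dose(st, 1)
  expect_equal(re$dose_gy, 1)
  expect_equal(re$L1_0, 20 / 0.89, tolerance = 1e-12)
  expect_equal(re$L1_0, 22.47, tolerance = 1e-3)
  expect_equal(rescale_to_dose(st, 0.89), st)
  zero <- rescale_to_dose(st, 0)
  expect_equal(zero$L1_0 + zero$L2_0 + zero$dose_gy, 0)
  st0 <- dplyr::mutate(st, dose_gy = 0)
  expect_error(rescale_to_dose(st0, 1), "zero dose")
})

test_that("spectrum summaries match a direct weighted-average oracle", {
  all_low <- tibble::tibble(energy_eV = c(1e3, 5e4), count = c(1, 2))
  expect_equal(spectrum_summary(all_low)$frac_below_100keV, 1)
  sym <- tibble::tibble(energy_eV = c(5e4, 1.5e5), count = c(3, 3))
  s <- spectrum_summary(sym)
  expect_equal(s$frac_below_100keV, 0.5)
  expect_equal(s$mean_energy_eV, 1e5)
  rnd <- withr::with_seed(21, tibble::tibble(
    energy_eV = 10^runif(40, 2, 6.7), count = runif(40)))
  s2 <- spectrum_summary(rnd)
  expect_equal(s2$mean_energy_eV,
               sum(rnd$energy_eV * rnd$count) / sum(rnd$count),
               tolerance = 1e-12)
  expect_equal(s2$frac_below_100keV,
               sum(rnd$count[rnd$energy_eV < 1e5]) / sum(rnd$count),
               tolerance = 1e-12)
  expect_error(spectrum_summary(tibble::tibble(energy_eV = 1, count = 0)[0, ]),
               "empty")
})
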