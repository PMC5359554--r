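# Population survival: heterogeneous repair half-times across nuclei,
# per-cell TLK solves, Bernoulli survival draws, and replicate summaries.

#' Distribution of fast/slow repair half-times across a population
#'
#' Cell-to-cell diversity in repair capacity is modelled by independent
#' Gaussian draws of the fast and slow repair half-times, truncated below at
#' `floor_h` (an untruncated Gaussian with mean 0.25 h and sd 0.1 h has mass
#' at non-positive half-times, which would make the repair rate ln2/tau
#' blow up).
#'
#' @param mu_fast_h,sigma_fast_h Mean and sd of the fast half-time, hours.
#' @param mu_slow_h,sigma_slow_h Mean and sd of the slow half-time, hours.
#' @param floor_h Truncation floor, hours.
#' @return A `repair_time_distribution`.
#' @export
repair_time_distribution <- function(mu_fast_h = 0.25, sigma_fast_h = 0.1,
                                     mu_slow_h = 8, sigma_slow_h = 1,
                                     floor_h = 0.01) {
  for (nm in c("mu_fast_h", "sigma_fast_h", "mu_slow_h", "sigma_slow_h", "floor_h")) {
    check_number(get(nm), nm, min = 0, allow_min = FALSE)
  }
  structure(list(mu_fast_h = mu_fast_h, sigma_fast_h = sigma_fast_h,
                 mu_slow_h = mu_slow_h, sigma_slow_h = sigma_slow_h,
                 floor_h = floor_h),
            class = "repair_time_distribution")
}

rnorm_truncated <- function(n, mu, sigma, floor) {
  x <- stats::rnorm(n, mu, sigma)
  while (any(bad <- x < floor)) {
    x[bad] <- stats::rnorm(sum(bad), mu, sigma)
  }
  x
}

#' Assign repair half-times to a population of nuclei
#'
#' Independent truncated-Gaussian draws per nucleus, reproducible under
#' `seed`.
#'
#' @param n Number of nuclei (>= 1).
#' @param dist A [repair_time_distribution].
#' @param seed Seed for the draws (`NULL` = current RNG state).
#' @return Tibble `nucleus_id, tau1_h, tau2_h`.
#' @export
#' @examples
#' assign_repair_times(5, seed = 1)
assign_repair_times <- function(n, dist = repair_time_distribution(), seed = NULL) {
  stopifnot(inherits(dist, "repair_time_distribution"), n >= 1)
  with_seed_maybe(seed, tibble::tibble(
    nucleus_id = seq_len(n),
    tau1_h = rnorm_truncated(n, dist$mu_fast_h, dist$sigma_fast_h, dist$floor_h),
    tau2_h = rnorm_truncated(n, dist$mu_slow_h, dist$sigma_slow_h, dist$floor_h)
  ))
}

#' Monte Carlo survival fraction of a nucleus population
#'
#' Each nucleus is integrated through the TLK model with its own repair
#' half-times; its survival probability `p_i = exp(-L_lethal,i(T))` is then
#' realised by one Bernoulli draw, and the survival fraction is the
#' proportion of survivors. The expectation `mean_survival_prob = mean(p_i)`
#' is reported alongside and is seed-independent.
#'
#' @param states `damage_state` tibble, one row per nucleus.
#' @param taus Tibble `tau1_h, tau2_h` per nucleus, or `NULL` to use the
#'   half-times in `params` for all nuclei.
#' @param params A [tlk_params].
#' @param T_h,dt_h Repair horizon and integration step, hours.
#' @param seed Seed for the Bernoulli survival draws.
#' @return A `survival_result`: `n_cells`, `n_survivors`, `sf`,
#'   `stderr` (binomial), `mean_survival_prob`, and a `cells` tibble with
#'   per-nucleus dose, damage, half-times, lethal damage, `p` and
#'   `survived`.
#' @export
population_survival <- function(states, taus = NULL, params = tlk_params(),
                                T_h = 24, dt_h = 0.005, seed = NULL) {
  if (nrow(states) == 0) abort_bad("empty population")
  if (!is.null(taus) && nrow(taus) != nrow(states)) {
    abort_bad("`states` and `taus` must have the same length")
  }
  finals <- tlk_final(states, params, T_h = T_h, dt_h = dt_h, taus = taus)
  p <- finals$p_survival
  n <- nrow(states)
  survived <- with_seed_maybe(seed, stats::runif(n) < p)
  sf <- mean(survived)
  cells <- tibble::tibble(
    nucleus_id = if ("nucleus_id" %in% names(states)) states$nucleus_id
                 else seq_len(n),
    dose_gy = states$dose_gy,
    L1_0 = states$L1_0, L2_0 = states$L2_0,
    tau1_h = if (is.null(taus)) params$tau1_h else taus$tau1_h,
    tau2_h = if (is.null(taus)) params$tau2_h else taus$tau2_h,
    L_lethal_T = finals$L_lethal_T,
    p = p, survived = survived
  )
  structure(
    list(n_cells = n, n_survivors = sum(survived), sf = sf,
         stderr = sqrt(sf * (1 - sf) / n),
         mean_survival_prob = mean(p),
         T_h = T_h, dt_h = dt_h, seed = seed, cells = cells),
    class = "survival_result"
  )
}

#' @export
print.survival_result <- function(x, ...) {
  cat(sprintf(
    "<survival_result> n = %d, SF = %.4f +/- %.4f (mean p = %.4f), T = %g h\n",
    x$n_cells, x$sf, x$stderr, x$mean_survival_prob, x$T_h))
  invisible(x)
}

#' @export
glance.survival_result <- function(x, ...) {
  tibble::tibble(n_cells = x$n_cells, n_survivors = x$n_survivors,
                 sf = x$sf, stderr = x$stderr,
                 mean_survival_prob = x$mean_survival_prob,
                 T_h = x$T_h, dt_h = x$dt_h)
}

#' @export
tidy.survival_result <- function(x, ...) x$cells

#' Repeat a survival simulation over independent seeds
#'
#' Runs [population_survival] once per seed and summarises the replicate
#' survival fractions as mean and standard deviation, mirroring the practice
#' of reporting Monte Carlo endpoints as mean +/- sd over repeated
#' simulations.
#'
#' @inheritParams population_survival
#' @param k Number of replicates (>= 2).
#' @param seeds Integer vector of at least `k` seeds.
#' @return A `survival_replicates` list: `replicates` tibble
#'   (`replicate, seed, sf, stderr`), `mean_sf`, `sd_sf`,
#'   `mean_survival_prob`.
#' @export
replicate_runs <- function(k, states, taus = NULL, params = tlk_params(),
                           T_h = 24, dt_h = 0.005, seeds) {
  if (k < 2) abort_bad("need at least 2 replicates")
  if (length(seeds) < k) abort_bad("need at least %d seeds, got %d", k, length(seeds))
  runs <- purrr::map(seeds[seq_len(k)], function(s) {
    population_survival(states, taus, params, T_h = T_h, dt_h = dt_h, seed = s)
  })
  reps <- tibble::tibble(
    replicate = seq_len(k),
    seed = seeds[seq_len(k)],
    sf = purrr::map_dbl(runs, "sf"),
    stderr = purrr::map_dbl(runs, "stderr")
  )
  structure(
    list(replicates = reps, mean_sf = mean(reps$sf), sd_sf = stats::sd(reps$sf),
         mean_survival_prob = runs[[1]]$mean_survival_prob),
    class = "survival_replicates"
  )
}

#' @export
print.survival_replicates <- function(x, ...) {
  cat(sprintf("<survival_replicates> k = %d, SF = %.4f +/- %.4f (mean p = %.4f)\n",
              nrow(x$replicates), x$mean_sf, x$sd_sf, x$mean_survival_prob))
  invisible(x)
}

#' @export
tidy.survival_replicates <- function(x, ...) x$replicates

#' @export
glance.survival_replicates <- function(x, ...) {
  tibble::tibble(k = nrow(x$replicates), mean_sf = x$mean_sf, sd_sf = x$sd_sf,
                 mean_survival_prob = x$mean_survival_prob)
}

#' Serialise a survival result
#'
#' Writes the scalar summary as JSON and, optionally, the per-nucleus table
#' as CSV.
#'
#' @param x A `survival_result`.
#' @param json_path Output JSON path.
#' @param cells_path Optional per-nucleus CSV path.
#' @export
write_survival_result <- function(x, json_path, cells_path = NULL) {
  stopifnot(inherits(x, "survival_result"))
  jsonlite::write_json(
    list(n_cells = x$n_cells, n_survivors = x$n_survivors, sf = x$sf,
         stderr = x$stderr, mean_survival_prob = x$mean_survival_prob,
         T_h = x$T_h, dt_h = x$dt_h, seed = x$seed),
    json_path, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(cells_path)) readr::write_csv(x$cells, cells_path)
  invisible(json_path)
}
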