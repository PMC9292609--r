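#' Define a true germination-probability surface
#'
#' The generator's ground truth is a Gaussian bell over (day, night)
#' temperature: \eqn{g(d, n) = g_{max} \exp(-q(d, n)/2)} with
#' \eqn{q = (z_d^2 - 2\rho z_d z_n + z_n^2) / (1 - \rho^2)},
#' \eqn{z_d = (d - \mu_{day})/\sigma_{day}}, \eqn{z_n = (n - \mu_{night})/\sigma_{night}}.
#' This is the simplest smooth unimodal form able to express the archetypal
#' thermal niches seen on plates: a broad/flat responder (huge sigmas), a
#' cool-restricted responder and a warm responder preferring fluctuating
#' temperatures (day optimum well above night optimum).
#'
#' @param g_max Peak germination probability in [0, 1] (0 gives a surface with
#'   no germination anywhere, useful as a degenerate test case).
#' @param mu_day,mu_night Optimum day/night temperatures, degrees C.
#' @param sigma_day,sigma_night Niche breadths, degrees C (> 0).
#' @param rho Day-night interaction in (-1, 1).
#' @return A \code{true_surface} object; call it via
#'   \code{\link{surface_probability}}.
#' @export
true_surface <- function(g_max, mu_day, mu_night, sigma_day, sigma_night,
                         rho = 0) {
  stopifnot(g_max >= 0, g_max <= 1, sigma_day > 0, sigma_night > 0,
            rho > -1, rho < 1)
  structure(
    list(g_max = g_max, mu_day = mu_day, mu_night = mu_night,
         sigma_day = sigma_day, sigma_night = sigma_night, rho = rho),
    class = "true_surface"
  )
}

#' Evaluate a true surface
#'
#' @param surface A \code{\link{true_surface}}.
#' @param day_temp,night_temp Numeric vectors of temperatures.
#' @return Germination probabilities in [0, g_max].
#' @export
surface_probability <- function(surface, day_temp, night_temp) {
  stopifnot(inherits(surface, "true_surface"))
  g <- surface
  zd <- (day_temp - g$mu_day) / g$sigma_day
  zn <- (night_temp - g$mu_night) / g$sigma_night
  q <- (zd^2 - 2 * g$rho * zd * zn + zn^2) / (1 - g$rho^2)
  g$g_max * exp(-q / 2)
}

#' Define a germination-timing model
#'
#' Per-seed germination days are lognormal with a median that slows away from
#' the thermal optimum: median = \code{median_days * (1 + slowdown * q)} where
#' q is the quadratic distance of the cell from the optimum (see
#' \code{\link{true_surface}}).
#'
#' @param median_days Median days to germination at the optimum (> 0).
#' @param log_sd Lognormal log-scale SD (> 0).
#' @param slowdown Proportional slowdown per unit of q (>= 0).
#' @return A \code{timing_model} object.
#' @export
timing_model <- function(median_days = 10, log_sd = 0.4, slowdown = 0.3) {
  stopifnot(median_days > 0, log_sd > 0, slowdown >= 0)
  structure(list(median_days = median_days, log_sd = log_sd,
                 slowdown = slowdown),
            class = "timing_model")
}

#' Simulate a complete TGP germination experiment
#'
#' For each usable design cell: every sown seed is independently viable with
#' probability \code{viability}; each viable seed germinates with probability
#' \eqn{g(day\_temp, night\_temp)} from the true surface; each germinating
#' seed's day is drawn from the lognormal timing model; cumulative counts are
#' recorded at the scoring days (a germination after the last scoring day is
#' unobserved). Fully reproducible given \code{seed}.
#'
#' @param design A \code{\link{make_half_grid}} design.
#' @param surface A \code{\link{true_surface}}.
#' @param timing A \code{\link{timing_model}}.
#' @param n_sown Seeds sown per cell.
#' @param viability Seed-lot viability in (0, 1] (recorded as metadata, as a
#'   cut test would supply it).
#' @param scoring_days Strictly increasing scoring days; the last should cover
#'   the expected germination horizon.
#' @param seed RNG seed.
#' @param species Species label for the experiment.
#' @return An \code{\link{experiment}} with attribute \code{truth} = list
#'   (\code{surface}, \code{timing}, \code{n_sown}, \code{viability}).
#' @export
simulate_experiment <- function(design, surface, timing, n_sown = 10,
                                viability = 1, scoring_days = seq(7, 70, by = 7),
                                seed = 1, species = "synthetic") {
  stopifnot(inherits(design, "tgp_design"), inherits(surface, "true_surface"),
            inherits(timing, "timing_model"))
  if (length(scoring_days) == 0L) {
    tgp_abort("scoring_days must be non-empty", "tgp_precondition_error")
  }
  if (any(diff(scoring_days) <= 0) || any(scoring_days <= 0)) {
    tgp_abort("scoring_days must be positive and strictly increasing",
              "tgp_precondition_error")
  }
  set.seed(seed)
  cells <- design$cells
  series <- lapply(seq_len(nrow(cells)), function(i) {
    d <- cells$day_temp[i]
    n <- cells$night_temp[i]
    p <- surface_probability(surface, d, n)
    zd <- (d - surface$mu_day) / surface$sigma_day
    zn <- (n - surface$mu_night) / surface$sigma_night
    q <- (zd^2 - 2 * surface$rho * zd * zn + zn^2) / (1 - surface$rho^2)
    viable <- stats::rbinom(n_sown, 1, viability)
    germinates <- viable * stats::rbinom(n_sown, 1, p)
    k <- sum(germinates)
    times <- if (k > 0) {
      stats::rlnorm(k,
                    meanlog = log(timing$median_days * (1 + timing$slowdown * q)),
                    sdlog = timing$log_sd)
    } else numeric(0)
    cum <- vapply(scoring_days, function(day) sum(times <= day), integer(1))
    suppressWarnings(
      cell_series(cells$cell_id[i], n_sown, viability, scoring_days, cum)
    )
  })
  exp <- experiment(design, series, species = species)
  attr(exp, "truth") <- list(surface = surface, timing = timing,
                             n_sown = n_sown, viability = viability)
  exp
}

# Monthly climate typical of a subtropical east-Australian seed-source site:
# warm wet summers (Jan peak) and mild winters.
default_current_climate <- function() {
  climate_series(
    data.frame(
      month = 1:12,
      tmax = c(31, 30, 28, 25, 22, 19, 19, 21, 24, 27, 29, 31),
      tmin = c(18, 18, 16, 12, 8, 6, 5, 6, 9, 12, 15, 17)
    ),
    scenario = "current", model = "worldclim-like"
  )
}

# Eight future model variants: uniform warming plus small deterministic
# per-model offsets, mimicking an end-of-century high-emissions ensemble.
default_future_models <- function(warming = 5, n_models = 8, seed = 1) {
  cur <- default_current_climate()
  set.seed(seed)
  lapply(seq_len(n_models), function(m) {
    off <- stats::rnorm(12, 0, 0.6)
    climate_series(
      data.frame(month = 1:12,
                 tmax = cur$tmax + warming + off,
                 tmin = cur$tmin + warming + off),
      scenario = "future", model = sprintf("model%02d", m)
    )
  })
}

#' Canned synthetic fixtures spanning the archetypal thermal niches
#'
#' Three complete experiments with known ground truth, mirroring the archetypal
#' plate responses: \code{flat} — a broad responder germinating nearly
#' uniformly at low probability (21-cell plate, 50 pooled seeds per cell);
#' \code{cool} — a cool-restricted responder with little diurnal preference
#' (45-cell plate, 10 seeds per cell); \code{warm} — a warm responder
#' preferring fluctuating temperatures, optimum near 30/14 degrees C (36-cell
#' plate, 10 seeds per cell). Each fixture bundles a current climate series and
#' an 8-model future ensemble (uniform +5 degrees C warming with small
#' per-model spread).
#'
#' @param seed RNG seed; generation is deterministic per seed.
#' @return Named list of three fixtures, each a list with \code{experiment},
#'   \code{climate_current}, \code{climate_future} (list of 8 series) and
#'   \code{truth}.
#' @export
make_fixture_suite <- function(seed = 1) {
  archetypes <- list(
    flat = list(
      design = make_half_grid(6, 5, 45),
      surface = true_surface(0.30, 25, 15, 1000, 1000, 0),
      n_sown = 50, viability = 0.9,
      scoring_days = c(7, 14, 28, 35, 49, 63, 70)
    ),
    cool = list(
      design = make_half_grid(9, 5, 45),
      surface = true_surface(0.95, 23, 15, 5, 4, 0.5),
      n_sown = 10, viability = 0.95,
      scoring_days = c(7, 14, 21, 35, 42, 56, 70)
    ),
    warm = list(
      design = make_half_grid(8, 5, 45),
      surface = true_surface(0.80, 30, 14, 5, 5, 0.3),
      n_sown = 10, viability = 0.9,
      scoring_days = c(3, 7, 10, 14, 17, 21, 25, 28, 32, 35, 42)
    )
  )
  timing <- timing_model()
  out <- lapply(seq_along(archetypes), function(i) {
    a <- archetypes[[i]]
    exp <- simulate_experiment(a$design, a$surface, timing,
                               n_sown = a$n_sown, viability = a$viability,
                               scoring_days = a$scoring_days,
                               seed = seed + i,
                               species = names(archetypes)[i])
    list(
      experiment = exp,
      climate_current = default_current_climate(),
      climate_future = default_future_models(seed = seed + i),
      truth = attr(exp, "truth")
    )
  })
  names(out) <- names(archetypes)
  out
}

#' Write a fixture's climate series to the climate CSV schema
#'
#' @param series_list List of \code{\link{climate_series}} (any mix of
#'   scenarios/models).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_climate_csv <- function(series_list, path) {
  if (inherits(series_list, "climate_series")) series_list <- list(series_list)
  df <- do.call(rbind, lapply(series_list, function(s) {
    data.frame(scenario = attr(s, "scenario"), model = attr(s, "model"),
               month = s$month, tmax = s$tmax, tmin = s$tmin,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
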