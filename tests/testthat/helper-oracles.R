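# Independent brute-force oracles for germination indices. These deliberately
# re-derive each quantity with plain loops from the definition, staying
# independent of the package's implementation paths.

oracle_indices <- function(days, cum, viable_n) {
  stopifnot(length(days) == length(cum))
  n_i <- diff(c(0, cum))           # per-interval counts (day 0 implicit zero)
  t_i <- days
  if (days[1] == 0) {              # day-0 observation carries no interval
    n_i <- diff(cum)
    t_i <- days[-1]
  }
  N <- cum[length(cum)]
  out <- list(final_prop = if (viable_n > 0) N / viable_n else NA_real_)
  if (N > 0) {
    tot <- 0
    for (k in seq_along(n_i)) tot <- tot + n_i[k] * t_i[k]
    out$mgt <- tot / sum(n_i)
    sp <- 0
    for (k in seq_along(n_i)) sp <- sp + n_i[k] / t_i[k]
    out$speed <- sp
    f <- n_i[n_i > 0] / N
    out$uncertainty <- -sum(f * log2(f))
    m <- round(cum) - c(0, round(cum)[-length(cum)])
    if (days[1] == 0) m <- diff(round(cum))
    Nint <- sum(m)
    out$synchrony <- if (Nint > 1) {
      sum(m * (m - 1) / 2) / (Nint * (Nint - 1) / 2)
    } else NA_real_
    if (N > 1) {
      out$var_time <- sum(n_i * (t_i - out$mgt)^2) / (sum(n_i) - 1)
    }
  }
  out$timson <- sum(100 * (if (days[1] == 0) cum[-1] else cum) / viable_n)
  out
}

# Linear-scan t50 oracle: walk the cumulative curve (with a day-0 zero anchor)
# and interpolate at the first crossing of N/2 under the requested bracketing.
oracle_t50 <- function(days, cum, variant = "coolbear") {
  if (days[1] > 0) {
    days <- c(0, days)
    cum <- c(0, cum)
  }
  N <- cum[length(cum)]
  if (N <= 0) return(NA_real_)
  half <- N / 2
  for (j in seq_along(cum)) {
    hit <- if (variant == "coolbear") cum[j] >= half else cum[j] > half
    if (hit) {
      is <- if (variant == "coolbear") which(cum < half) else
        which(cum <= half & seq_along(cum) < j)
      i <- max(is)
      return(days[i] + (half - cum[i]) * (days[j] - days[i]) / (cum[j] - cum[i]))
    }
  }
  NA_real_
}

# Random small cumulative germination series on an integer daily grid.
random_daily_series <- function(seed, max_days = 12, viable_n = 20) {
  set.seed(seed)
  T <- sample(4:max_days, 1)
  n_i <- stats::rbinom(T, 3, 0.35)
  cum <- cumsum(n_i)
  cum <- pmin(cum, viable_n)
  structure(
    list(cell_id = sprintf("rand%03d", seed), days = 0:T,
         cum_daily = c(0, cum), viable_n = viable_n),
    class = "daily_series"
  )
}

# A compact simulated binomial cell table over a half grid, for GAM tests.
sim_cells <- function(p_fun, design = make_half_grid(6, 5, 45), viable_n = 50,
                      seed = 1) {
  set.seed(seed)
  cells <- design$cells
  p <- p_fun(cells$day_temp, cells$night_temp)
  data.frame(
    cell_id = cells$cell_id,
    day_temp = cells$day_temp,
    night_temp = cells$night_temp,
    successes = stats::rbinom(nrow(cells), viable_n, p),
    viable_n = viable_n
  )
}
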