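#' Regularize an irregular cumulative series onto a daily grid
#'
#' Germination is typically scored every few days to every couple of weeks, but
#' interval-based germination indices need counts on consistent (usually daily)
#' intervals. \code{regularize_series} interpolates the cumulative record onto
#' a regular grid from day 0 to the last observed day.
#'
#' Two interpolants are available. \code{"linear"} joins observations by
#' straight lines (deterministic, used automatically when fewer than 4 scoring
#' events are available). \code{"smooth"} fits a penalized cubic regression
#' spline to the cumulative counts (basis dimension \code{min(n_events, 10)}),
#' then adds back the linear interpolant of its residuals at the observed days
#' so the curve passes exactly through every observation while staying smooth
#' between them. Either way the result is repaired to satisfy the cumulative
#' count semantics: clipped to \code{[0, final observed count]}, forced to 0 at
#' day 0 unless a day-0 observation says otherwise, and made non-decreasing by
#' a running maximum. No extrapolation occurs past the last observation, so the
#' final cumulative count is conserved exactly.
#'
#' @param series A \code{\link{cell_series}} with at least 2 scoring events.
#' @param step_days Grid spacing in days (> 0, default 1).
#' @param method \code{"auto"} (default), \code{"smooth"} or \code{"linear"}.
#' @return A \code{daily_series}: list with \code{cell_id}, \code{days} (grid),
#'   \code{cum_daily} (interpolated cumulative counts, possibly non-integer) and
#'   \code{viable_n}.
#' @export
regularize_series <- function(series, step_days = 1,
                              method = c("auto", "smooth", "linear")) {
  stopifnot(inherits(series, "cell_series"))
  method <- match.arg(method)
  if (length(series$days) < 2L) {
    tgp_abort(sprintf("cell %s: need >= 2 scoring events to regularize",
                      series$cell_id), "tgp_insufficient_data")
  }
  if (!is_scalar_number(step_days) || step_days <= 0) {
    tgp_abort("step_days must be > 0", "tgp_precondition_error")
  }
  obs_days <- series$days
  obs_cum <- as.numeric(series$cum_germinated)
  # anchor at day 0 with zero germinated unless observed otherwise
  if (obs_days[1] > 0) {
    obs_days <- c(0, obs_days)
    obs_cum <- c(0, obs_cum)
  }
  final <- obs_cum[length(obs_cum)]
  grid <- seq(0, obs_days[length(obs_days)], by = step_days)
  if (grid[length(grid)] < obs_days[length(obs_days)]) {
    grid <- c(grid, obs_days[length(obs_days)])
  }
  if (method == "auto") {
    method <- if (length(series$days) >= 4L) "smooth" else "linear"
  }
  lin <- stats::approx(obs_days, obs_cum, xout = grid, rule = 2)$y
  cum <- if (method == "linear") {
    lin
  } else {
    sm <- tryCatch(
      smooth_cumulative(obs_days, obs_cum, grid),
      error = function(e) NULL
    )
    if (is.null(sm)) {
      tgp_warn(sprintf("cell %s: smoother failed, falling back to linear",
                       series$cell_id), "tgp_smoother_fallback")
      lin
    } else sm
  }
  cum <- pmin(pmax(cum, 0), final)
  if (!(0 %in% series$days)) cum[1] <- 0
  cum <- cummax(cum)
  cum[length(cum)] <- final
  structure(
    list(cell_id = series$cell_id, days = grid, cum_daily = cum,
         viable_n = viable_n(series)),
    class = "daily_series"
  )
}

# Penalized-spline trend + exact-fit residual correction at observed days.
smooth_cumulative <- function(obs_days, obs_cum, grid) {
  k <- min(length(obs_days), 10L)
  df <- data.frame(day = obs_days, cum = obs_cum)
  fit <- mgcv::gam(cum ~ s(day, k = k, bs = "cr"), data = df, method = "REML")
  trend_grid <- as.numeric(stats::predict(fit, newdata = data.frame(day = grid)))
  resid_obs <- obs_cum - as.numeric(stats::fitted(fit))
  resid_grid <- stats::approx(obs_days, resid_obs, xout = grid, rule = 2)$y
  trend_grid + resid_grid
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("daily series for cell %s: days 0..%g, final count %g of %d viable\n",
              x$cell_id, max(x$days), x$cum_daily[length(x$cum_daily)],
              x$viable_n))
  invisible(x)
}

#' Per-interval germination counts from a daily series
#'
#' First differences of the cumulative curve: the number of new germinations in
#' each grid interval (all >= 0, telescoping to the final cumulative count).
#' These interval counts \eqn{n_i} at interval-end days \eqn{t_i} feed the
#' time-based germination indices.
#'
#' @param daily A \code{daily_series}.
#' @return Data frame \code{day} (interval end), \code{new_germinations}.
#' @export
interval_counts <- function(daily) {
  stopifnot(inherits(daily, "daily_series"))
  data.frame(
    day = daily$days[-1],
    new_germinations = diff(daily$cum_daily)
  )
}

#' Export daily series as CSV
#'
#' Schema: \code{cell_id,day,cum_daily}.
#' @param daily_list List of \code{daily_series} (or a single one).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_daily_csv <- function(daily_list, path) {
  if (inherits(daily_list, "daily_series")) daily_list <- list(daily_list)
  df <- do.call(rbind, lapply(daily_list, function(d) {
    data.frame(cell_id = d$cell_id, day = d$days, cum_daily = d$cum_daily,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
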