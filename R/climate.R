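#' Construct a 12-month climate series
#'
#' A climate series carries, for one scenario and one source model (or an
#' ensemble), the monthly mean daily maximum and minimum air temperatures
#' (tmax/tmin, degrees C) used to drive germination predictions: tmax maps to
#' the plate's day temperature and tmin to its night temperature.
#'
#' @param months Data frame with columns \code{month} (1-12, each exactly
#'   once), \code{tmax}, \code{tmin}; optional \code{se_tmax}, \code{se_tmin}.
#' @param scenario Scenario label (e.g. \code{"current"},
#'   \code{"ssp585-2081-2100"}).
#' @param model Source model id, or \code{"ensemble"}.
#' @param n_models Number of models behind an ensemble (1 otherwise).
#' @return A \code{climate_series} data frame (ordered by month) with
#'   attributes \code{scenario}, \code{model}, \code{n_models}.
#' @export
climate_series <- function(months, scenario, model = "unknown", n_models = 1L) {
  check_columns(months, c("month", "tmax", "tmin"), "climate table")
  months <- months[order(months$month), , drop = FALSE]
  if (nrow(months) != 12L || !all(months$month == 1:12)) {
    tgp_abort("climate series must have exactly months 1..12",
              "tgp_climate_error")
  }
  if (any(months$tmax < months$tmin)) {
    tgp_abort("tmax must be >= tmin in every month", "tgp_climate_error")
  }
  rownames(months) <- NULL
  structure(months, scenario = scenario, model = model,
            n_models = as.integer(n_models),
            class = c("climate_series", "data.frame"))
}

#' Read a climate CSV into per-model climate series
#'
#' Schema: \code{scenario,model,month,tmax,tmin}. Each (scenario, model) pair
#' must contribute exactly 12 monthly rows.
#'
#' @param path File path.
#' @param scale Multiplicative scale factor applied to temperatures (e.g. 0.1
#'   for datasets stored as integer tenths of a degree); default 1.
#' @return List of \code{\link{climate_series}}, one per (scenario, model).
#' @export
read_climate_csv <- function(path, scale = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("scenario", "model", "month", "tmax", "tmin"),
                basename(path))
  df$tmax <- df$tmax * scale
  df$tmin <- df$tmin * scale
  keys <- unique(df[, c("scenario", "model")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$scenario == keys$scenario[i] & df$model == keys$model[i],
              c("month", "tmax", "tmin"), drop = FALSE]
    climate_series(sub, scenario = keys$scenario[i], model = keys$model[i])
  })
}

#' Ensemble-average a set of climate series
#'
#' Averages tmax and tmin across source models for each month, attaching the
#' per-month standard error (sample SD / sqrt(m)) when two or more models are
#' supplied.
#'
#' @param series_list List of \code{\link{climate_series}} for the same
#'   scenario family.
#' @return A single \code{\link{climate_series}} with \code{model =
#'   "ensemble"} and \code{se_tmax}/\code{se_tmin} columns when m >= 2.
#' @export
ensemble_average <- function(series_list) {
  if (length(series_list) == 0L) {
    tgp_abort("ensemble_average needs at least one series", "tgp_climate_error")
  }
  stopifnot(all(vapply(series_list, inherits, logical(1), "climate_series")))
  m <- length(series_list)
  if (m == 1L) return(series_list[[1]])
  tmax <- sapply(series_list, function(s) s$tmax)
  tmin <- sapply(series_list, function(s) s$tmin)
  months <- data.frame(
    month = 1:12,
    tmax = rowMeans(tmax),
    tmin = rowMeans(tmin),
    se_tmax = apply(tmax, 1, stats::sd) / sqrt(m),
    se_tmin = apply(tmin, 1, stats::sd) / sqrt(m)
  )
  climate_series(months, scenario = attr(series_list[[1]], "scenario"),
                 model = "ensemble", n_models = m)
}

#' Predict monthly germination from a fitted surface and a climate series
#'
#' Maps monthly tmax to the surface's day temperature and tmin to its night
#' temperature and predicts the germination index for each month. When the
#' climate series carries ensemble standard errors, an uncertainty band is
#' computed by predicting at the four (tmax +/- se, tmin +/- se) envelope
#' corners and taking the min/max — an approximation that propagates the
#' temperature spread, not a confidence interval for germination.
#'
#' @param surface A \code{\link{fit_surface}} result.
#' @param climate A \code{\link{climate_series}}.
#' @param extrapolation Passed to \code{\link{predict_surface}}; default
#'   \code{"clamp"} (climate temperatures can fall outside the plate range).
#' @return Data frame with one row per month: \code{month, scenario,
#'   prediction, lo, hi, clamped}.
#' @export
predict_monthly <- function(surface, climate, extrapolation = "clamp") {
  stopifnot(inherits(surface, "fitted_surface"),
            inherits(climate, "climate_series"))
  base <- predict_surface(
    surface,
    data.frame(day_temp = climate$tmax, night_temp = climate$tmin),
    extrapolation = extrapolation
  )
  lo <- hi <- base$prediction
  if (!is.null(climate$se_tmax) && !is.null(climate$se_tmin)) {
    corners <- list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
    preds <- sapply(corners, function(sgn) {
      d <- climate$tmax + sgn[1] * climate$se_tmax
      n <- pmin(climate$tmin + sgn[2] * climate$se_tmin, d)
      predict_surface(surface, data.frame(day_temp = d, night_temp = n),
                      extrapolation = extrapolation)$prediction
    })
    all_preds <- cbind(base$prediction, preds)
    lo <- apply(all_preds, 1, min)
    hi <- apply(all_preds, 1, max)
  }
  data.frame(month = climate$month,
             scenario = attr(climate, "scenario"),
             prediction = base$prediction,
             lo = lo, hi = hi, clamped = base$clamped,
             stringsAsFactors = FALSE)
}

#' Seasonal-shift summary between two monthly prediction series
#'
#' Compares current and future monthly predictions: the peak month(s), the
#' "active" months whose prediction reaches at least half the peak, and their
#' deltas. The peak-month delta is the signed circular month difference
#' (future minus current, wrapped to -6..6). A series whose predictions are
#' (numerically) flat is flagged \code{no_seasonality} and all its months count
#' as peak months.
#'
#' @param current,future Data frames from \code{\link{predict_monthly}} with 12
#'   rows each.
#' @return List with \code{peak_current}, \code{peak_future} (month vectors),
#'   \code{peak_delta_months}, \code{active_current}, \code{active_future},
#'   \code{active_delta_count}, \code{no_seasonality} (named logical).
#' @export
seasonal_shift_report <- function(current, future) {
  pick <- function(pred) {
    p <- pred$prediction
    flat <- diff(range(p)) < 1e-9
    peak <- if (flat) pred$month else pred$month[p >= max(p) - 1e-12]
    active <- pred$month[p >= 0.5 * max(p)]
    list(peak = peak, active = active, flat = flat)
  }
  stopifnot(nrow(current) == 12L, nrow(future) == 12L)
  a <- pick(current)
  b <- pick(future)
  delta <- ((b$peak[1] - a$peak[1] + 5) %% 12) - 5
  if (a$flat && b$flat) delta <- 0
  list(
    peak_current = a$peak, peak_future = b$peak,
    peak_delta_months = delta,
    active_current = a$active, active_future = b$active,
    active_delta_count = length(b$active) - length(a$active),
    no_seasonality = c(current = a$flat, future = b$flat)
  )
}

#' Write monthly predictions to CSV
#'
#' Schema: \code{scenario,month,prediction,lo,hi,clamped}.
#' @param predictions One or a list of \code{\link{predict_monthly}} outputs.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_predictions_csv <- function(predictions, path) {
  if (is.data.frame(predictions)) predictions <- list(predictions)
  df <- do.call(rbind, predictions)
  df <- df[, c("scenario", "month", "prediction", "lo", "hi", "clamped")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
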