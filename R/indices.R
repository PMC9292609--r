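#' Registry of implemented germination indices
#'
#' Each index is a scalar summary of one cell's germination time course,
#' computed from the regularized daily series. Interval counts \eqn{n_i} are
#' the first differences of the cumulative curve, taken at interval-end days
#' \eqn{t_i}; \eqn{N} is the final cumulative germinated count and the
#' denominator of proportions is the viable-seed count
#' (\code{\link{viable_n}}). When an index is not computable for a series
#' (e.g. time-based indices with zero germination), its value is reported as
#' \code{NA} and its name listed in the index set's \code{undefined} field —
#' never silently as 0.
#'
#' Literature anchors per index: final proportion/percent (standard);
#' t50 by Coolbear-style (\eqn{N_i < N/2 \le N_j}) and Farooq-style
#' (\eqn{N_i \le N/2 < N_j}) bracketing with linear interpolation
#' \eqn{t_{50} = t_i + (N/2 - N_i)(t_j - t_i)/(N_j - N_i)};
#' mean germination time (Ellis & Roberts) \eqn{\sum n_i t_i / \sum n_i} and
#' its reciprocal mean rate; variance/SD/CV of germination time (Labouriau);
#' Maguire's germination speed \eqn{\sum n_i / t_i}; Timson's cumulative
#' index; peak day/count; Primack synchrony
#' \eqn{Z = \sum \binom{n_i}{2} / \binom{N}{2}} (computed on integerized
#' interval counts so the combinatorial form is well defined); Labouriau
#' uncertainty \eqn{U = -\sum f_i \log_2 f_i}, \eqn{f_i = n_i/N};
#' first/last germination day and spread; Czabator's mean daily germination,
#' peak value and germination value.
#'
#' @return Data frame with columns \code{name}, \code{units},
#'   \code{description}, \code{undefined_when}.
#' @export
index_registry <- function() {
  reg <- rbind(
    c("final_germination_proportion", "proportion",
      "final cumulative count / viable_n", "viable_n = 0"),
    c("final_germination_percent", "%",
      "100 x final germination proportion", "viable_n = 0"),
    c("germinated_count", "seeds", "final cumulative germinated count", "never"),
    c("t50_coolbear", "days",
      "interpolated time to 50% of final count, bracket N_i < N/2 <= N_j",
      "zero germination"),
    c("t50_farooq", "days",
      "interpolated time to 50% of final count, bracket N_i <= N/2 < N_j",
      "zero germination"),
    c("mean_germination_time", "days",
      "count-weighted mean interval-end day, sum(n_i t_i)/sum(n_i)",
      "zero germination"),
    c("mean_germination_rate", "1/days", "reciprocal of mean germination time",
      "zero germination"),
    c("variance_germination_time", "days^2",
      "count-weighted variance of germination time (n-1 denominator)",
      "fewer than 2 germinations"),
    c("sd_germination_time", "days", "square root of the variance",
      "fewer than 2 germinations"),
    c("cv_germination_time", "unitless", "sd / mean germination time",
      "fewer than 2 germinations"),
    c("germination_speed", "seeds/day", "Maguire index, sum(n_i / t_i)",
      "zero germination"),
    c("timson_index", "percent-days",
      "sum of cumulative germination percentages over grid days", "viable_n = 0"),
    c("peak_day", "days", "interval-end day with most germinations (earliest tie)",
      "zero germination"),
    c("peak_count", "seeds", "largest interval count", "zero germination"),
    c("synchrony", "proportion",
      "Z = sum C(n_i,2) / C(N,2) on integerized interval counts",
      "fewer than 2 germinations"),
    c("uncertainty", "bits", "U = -sum f_i log2 f_i, f_i = n_i / N",
      "zero germination"),
    c("first_germination_day", "days", "first grid day with cumulative count > 0",
      "zero germination"),
    c("last_germination_day", "days",
      "first grid day reaching the final cumulative count", "zero germination"),
    c("germination_spread", "days", "last minus first germination day",
      "zero germination"),
    c("mean_daily_germination", "seeds/day",
      "final count / last grid day (Czabator MDG)", "zero-length test"),
    c("peak_value_czabator", "%/day",
      "max over grid days of cumulative germination percent / day",
      "viable_n = 0"),
    c("germination_value_czabator", "%^2/day^2",
      "Czabator GV = peak value x mean daily germination percent", "viable_n = 0")
  )
  out <- as.data.frame(reg, stringsAsFactors = FALSE)
  names(out) <- c("name", "units", "description", "undefined_when")
  out
}

#' Final germination proportion of a cell
#'
#' @param series A \code{\link{cell_series}} or \code{daily_series}.
#' @return Final cumulative count divided by the viable-seed count, in [0, 1];
#'   \code{NA} if the viable count is 0.
#' @export
final_germination_proportion <- function(series) {
  if (inherits(series, "cell_series")) {
    nv <- viable_n(series)
    final <- series$cum_germinated[length(series$cum_germinated)]
  } else if (inherits(series, "daily_series")) {
    nv <- series$viable_n
    final <- series$cum_daily[length(series$cum_daily)]
  } else {
    tgp_abort("series must be a cell_series or daily_series", "tgp_domain_error")
  }
  if (nv == 0L) return(NA_real_)
  final / nv
}

#' Time to 50 percent of final germination
#'
#' Linear interpolation between the cumulative observations bracketing half the
#' final count \eqn{N}: \eqn{t_{50} = t_i + (N/2 - N_i)(t_j - t_i)/(N_j - N_i)}.
#' The \code{coolbear} variant brackets with \eqn{N_i < N/2 \le N_j}, the
#' \code{farooq} variant with \eqn{N_i \le N/2 < N_j}; they differ only when
#' \eqn{N/2} is itself attained exactly at an observation plateau.
#'
#' @param daily A \code{daily_series} (or a \code{cell_series}, whose observed
#'   points are used directly with a day-0 zero anchor).
#' @param variant \code{"coolbear"} (default) or \code{"farooq"}.
#' @return Days to 50\% of final germinated count; \code{NA} if nothing
#'   germinated.
#' @export
t50 <- function(daily, variant = c("coolbear", "farooq")) {
  variant <- match.arg(variant)
  if (inherits(daily, "cell_series")) {
    days <- daily$days
    cum <- as.numeric(daily$cum_germinated)
    if (days[1] > 0) { days <- c(0, days); cum <- c(0, cum) }
  } else if (inherits(daily, "daily_series")) {
    days <- daily$days
    cum <- daily$cum_daily
  } else {
    tgp_abort("daily must be a daily_series or cell_series", "tgp_domain_error")
  }
  N <- cum[length(cum)]
  if (N <= 0) return(NA_real_)
  half <- N / 2
  if (variant == "coolbear") {
    i <- max(which(cum < half))
    j <- min(which(cum >= half))
  } else {
    below <- which(cum <= half)
    above <- which(cum > half)
    j <- min(above)
    i <- max(below[below < j])
  }
  days[i] + (half - cum[i]) * (days[j] - days[i]) / (cum[j] - cum[i])
}

#' Compute the core germination-index battery for one cell
#'
#' @param daily A \code{daily_series} from \code{\link{regularize_series}}.
#' @return An \code{index_set}: list with \code{cell_id}, \code{values} (named
#'   numeric vector over the full \code{\link{index_registry}}) and
#'   \code{undefined} (names of indices flagged not computable, stored as
#'   \code{NA} in \code{values}).
#' @export
core_indices <- function(daily) {
  stopifnot(inherits(daily, "daily_series"))
  ic <- interval_counts(daily)
  t_i <- ic$day
  n_i <- ic$new_germinations
  N <- daily$cum_daily[length(daily$cum_daily)]
  nv <- daily$viable_n
  Tlast <- max(daily$days)
  reg <- index_registry()
  v <- stats::setNames(rep(NA_real_, nrow(reg)), reg$name)

  v["germinated_count"] <- N
  if (nv > 0L) {
    v["final_germination_proportion"] <- N / nv
    v["final_germination_percent"] <- 100 * N / nv
    cumpct <- 100 * daily$cum_daily / nv
    v["timson_index"] <- sum(cumpct[-1])
    pos_days <- daily$days > 0
    if (any(pos_days)) {
      v["peak_value_czabator"] <- max(cumpct[pos_days] / daily$days[pos_days])
      if (Tlast > 0) {
        v["germination_value_czabator"] <-
          v["peak_value_czabator"] * (100 * N / nv) / Tlast
      }
    }
  }
  if (Tlast > 0) v["mean_daily_germination"] <- N / Tlast

  if (N > 0) {
    v["t50_coolbear"] <- t50(daily, "coolbear")
    v["t50_farooq"] <- t50(daily, "farooq")
    mgt <- sum(n_i * t_i) / sum(n_i)
    v["mean_germination_time"] <- mgt
    if (mgt > 0) v["mean_germination_rate"] <- 1 / mgt
    v["germination_speed"] <- sum(n_i / t_i)
    active <- n_i > 1e-9
    v["peak_day"] <- t_i[which.max(n_i)]
    v["peak_count"] <- max(n_i)
    f_i <- n_i[active] / N
    v["uncertainty"] <- -sum(f_i * log2(f_i))
    first_idx <- min(which(daily$cum_daily > 1e-9))
    last_idx <- min(which(daily$cum_daily >= N - 1e-9))
    v["first_germination_day"] <- daily$days[first_idx]
    v["last_germination_day"] <- daily$days[last_idx]
    v["germination_spread"] <- daily$days[last_idx] - daily$days[first_idx]
    if (N > 1) {
      v["variance_germination_time"] <-
        sum(n_i * (t_i - mgt)^2) / (sum(n_i) - 1)
      v["sd_germination_time"] <- sqrt(v["variance_germination_time"])
      if (mgt > 0) v["cv_germination_time"] <- v["sd_germination_time"] / mgt
      # synchrony on integerized interval counts
      m_i <- diff(round(daily$cum_daily))
      Nint <- sum(m_i)
      if (Nint > 1) {
        v["synchrony"] <- sum(m_i * (m_i - 1) / 2) / (Nint * (Nint - 1) / 2)
      }
    }
  } else {
    if (nv > 0L) v["final_germination_proportion"] <- 0
    if (nv > 0L) v["final_germination_percent"] <- 0
  }
  v <- v[reg$name]
  structure(
    list(cell_id = daily$cell_id, values = v,
         undefined = names(v)[is.na(v)]),
    class = "index_set"
  )
}

#' @export
print.index_set <- function(x, ...) {
  cat(sprintf("index set for cell %s (%d indices, %d undefined)\n",
              x$cell_id, length(x$values), length(x$undefined)))
  print(round(x$values, 4))
  invisible(x)
}

#' Germination indices for every scored cell of an experiment
#'
#' Regularizes each cell's series and computes the full index battery.
#'
#' @param exp An \code{\link{experiment}}.
#' @param step_days,method Passed to \code{\link{regularize_series}}.
#' @return Data frame: one row per cell (with its day/night temperatures), one
#'   column per registered index; \code{NA} marks not-computable indices.
#' @export
indices_table <- function(exp, step_days = 1, method = "auto") {
  stopifnot(inherits(exp, "experiment"))
  rows <- lapply(exp$series, function(s) {
    d <- regularize_series(s, step_days = step_days, method = method)
    ix <- core_indices(d)
    cbind(data.frame(cell_id = s$cell_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(ix$values)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  cells <- exp$design$cells
  out$day_temp <- cells$day_temp[match(out$cell_id, cells$cell_id)]
  out$night_temp <- cells$night_temp[match(out$cell_id, cells$cell_id)]
  out[, c("cell_id", "day_temp", "night_temp",
          setdiff(names(out), c("cell_id", "day_temp", "night_temp")))]
}

#' Export an indices table with a units sidecar
#'
#' Writes one CSV of index values (row per cell, column per index) and a
#' sidecar metadata CSV (\code{index,units,description}) next to it.
#'
#' @param indices Data frame from \code{\link{indices_table}}.
#' @param path Output CSV path; the sidecar gets suffix \code{_units.csv}.
#' @return Invisibly, \code{path}.
#' @export
write_indices_csv <- function(indices, path) {
  utils::write.csv(indices, path, row.names = FALSE, quote = FALSE)
  reg <- index_registry()
  side <- data.frame(index = reg$name, units = reg$units,
                     description = reg$description, stringsAsFactors = FALSE)
  utils::write.csv(side, sub("\\.csv$", "_units.csv", path),
                   row.names = FALSE)
  invisible(path)
}
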