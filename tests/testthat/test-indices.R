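daily <- function(days, cum, viable_n = 20, id = "c") {
  structure(list(cell_id = id, days = days, cum_daily = cum,
                 viable_n = viable_n),
            class = "daily_series")
}

test_that("final germination proportion is count over viable seeds", {
  expect_equal(final_germination_proportion(
    cell_series("c", 10, 1, c(7, 14), c(3, 8))), 0.8)
  expect_equal(final_germination_proportion(
    cell_series("c", 10, 1, c(7, 14), c(0, 0))), 0)
  # viability-adjusted denominator: 36 of round(50 * 0.9) = 45 viable
  expect_equal(final_germination_proportion(
    cell_series("c", 50, 0.9, c(7, 14), c(10, 36))), 0.8)
})

test_that("t50 matches the hand-bracketed example and boundary case", {
  s <- cell_series("c", 20, 1, c(2, 4, 6), c(2, 5, 10))
  expect_equal(t50(s, "coolbear"), 4.0)
  # exactly half germinate on day d, none before: t50 interpolates to d
  b <- daily(0:4, c(0, 0, 0, 5, 10), viable_n = 10)
  expect_equal(t50(b, "coolbear"), 3.0)
  # zero germination is flagged undefined
  expect_true(is.na(t50(daily(0:3, rep(0, 4)))))
})

test_that("t50 agrees with a linear-scan oracle on random series", {
  for (seed in 1:25) {
    d <- random_daily_series(seed)
    if (d$cum_daily[length(d$cum_daily)] == 0) next
    for (variant in c("coolbear", "farooq")) {
      expect_equal(t50(d, variant),
                   oracle_t50(d$days, d$cum_daily, variant),
                   info = sprintf("seed %d %s", seed, variant))
    }
    # the variants agree whenever N/2 is never attained exactly
    N <- d$cum_daily[length(d$cum_daily)]
    if (!any(abs(d$cum_daily - N / 2) < 1e-12)) {
      expect_equal(t50(d, "coolbear"), t50(d, "farooq"))
    }
  }
})

test_that("core indices hit their closed forms on constructed series", {
  # 5 seeds on day 2 and 5 on day 4: MGT = 3, rate = 1/3
  d <- daily(0:4, c(0, 0, 5, 5, 10), viable_n = 10)
  ix <- core_indices(d)$values
  expect_equal(unname(ix["mean_germination_time"]), 3.0)
  expect_equal(unname(ix["mean_germination_rate"]), 1 / 3)
  expect_equal(unname(ix["final_germination_proportion"]), 1.0)
  expect_equal(unname(ix["peak_day"]), 2)

  # perfect synchrony: everything in one interval
  one <- daily(0:3, c(0, 0, 8, 8), viable_n = 10)
  ix1 <- core_indices(one)$values
  expect_equal(unname(ix1["synchrony"]), 1.0)
  expect_equal(unname(ix1["uncertainty"]), 0.0)

  # uniform germination over k intervals: uncertainty = log2(k)
  for (k in c(2, 4, 8)) {
    u <- daily(0:k, seq(0, 2 * k, by = 2), viable_n = 2 * k + 4)
    expect_equal(unname(core_indices(u)$values["uncertainty"]), log2(k))
  }
})

test_that("every core index matches its brute-force oracle on random series", {
  checked <- 0
  for (seed in 1:30) {
    d <- random_daily_series(seed)
    o <- oracle_indices(d$days, d$cum_daily, d$viable_n)
    v <- core_indices(d)$values
    expect_equal(unname(v["final_germination_proportion"]), o$final_prop)
    expect_equal(unname(v["timson_index"]), o$timson)
    if (!is.null(o$mgt)) {
      expect_equal(unname(v["mean_germination_time"]), o$mgt)
      expect_equal(unname(v["germination_speed"]), o$speed)
      expect_equal(unname(v["uncertainty"]), o$uncertainty)
      if (!is.na(o$synchrony)) {
        expect_equal(unname(v["synchrony"]), o$synchrony)
      }
      if (!is.null(o$var_time)) {
        expect_equal(unname(v["variance_germination_time"]), o$var_time)
      }
      checked <- checked + 1
    }
  }
  expect_gte(checked, 20)
})

test_that("index invariants hold across random series", {
  for (seed in 31:55) {
    d <- random_daily_series(seed)
    v <- core_indices(d)$values
    N <- d$cum_daily[length(d$cum_daily)]
    if (N == 0) next
    if (!is.na(v["synchrony"])) {
      expect_gte(unname(v["synchrony"]), 0)
      expect_lte(unname(v["synchrony"]), 1)
    }
    expect_gte(unname(v["uncertainty"]), -1e-12)
    expect_gte(unname(v["mean_germination_time"]),
               unname(v["first_germination_day"]) - 1)
    expect_lte(unname(v["mean_germination_time"]),
               unname(v["last_germination_day"]))
    expect_true(v["final_germination_proportion"] >= 0 &&
                  v["final_germination_proportion"] <= 1)
  }
})

test_that("delaying all germination lowers the speed index", {
  base <- daily(0:6, c(0, 0, 3, 6, 6, 6, 6), viable_n = 10)
  delayed <- daily(0:8, c(0, 0, 0, 0, 3, 6, 6, 6, 6), viable_n = 10)
  v0 <- core_indices(base)$values
  v1 <- core_indices(delayed)$values
  expect_lt(unname(v1["germination_speed"]), unname(v0["germination_speed"]))
})

test_that("zero germination flags time-based indices, not proportions", {
  ix <- core_indices(daily(0:5, rep(0, 6), viable_n = 10))
  expect_equal(unname(ix$values["final_germination_proportion"]), 0)
  expect_true("t50_coolbear" %in% ix$undefined)
  expect_true("mean_germination_time" %in% ix$undefined)
  expect_true(all(is.na(ix$values[ix$undefined])))
})

test_that("the registry documents at least 20 indices and matches outputs", {
  reg <- index_registry()
  expect_gte(nrow(reg), 20)
  expect_true(all(c("name", "units", "description", "undefined_when")
                  %in% names(reg)))
  d <- random_daily_series(99)
  expect_setequal(names(core_indices(d)$values), reg$name)
})

test_that("indices_table lines up cells with temperatures and exports", {
  design <- make_half_grid(3, 10, 30)
  series <- lapply(design$cells$cell_id[1:3], function(id)
    cell_series(id, 10, 1, c(3, 7, 12, 20), c(0, 2, 5, 7)))
  exp <- experiment(design, series)
  tab <- indices_table(exp, method = "linear")
  expect_equal(nrow(tab), 3)
  expect_true(all(c("day_temp", "night_temp", "t50_coolbear") %in% names(tab)))
  path <- tempfile(fileext = ".csv")
  write_indices_csv(tab, path)
  expect_true(file.exists(path))
  expect_true(file.exists(sub("\\.csv$", "_units.csv", path)))
})
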