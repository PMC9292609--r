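mk_series <- function(tmax, tmin, scenario = "future", model = "m1") {
  climate_series(data.frame(month = 1:12, tmax = tmax, tmin = tmin),
                 scenario = scenario, model = model)
}

test_that("climate series validation", {
  expect_s3_class(mk_series(rep(20, 12), rep(10, 12)), "climate_series")
  expect_error(climate_series(data.frame(month = 1:11, tmax = 20, tmin = 10),
                              "x"), class = "tgp_climate_error")
  expect_error(mk_series(rep(10, 12), rep(20, 12)), class = "tgp_climate_error")
})

test_that("ensemble averaging matches the mean and sd/sqrt(m) oracle", {
  a <- mk_series(rep(30, 12), rep(10, 12), model = "m1")
  b <- mk_series(rep(32, 12), rep(14, 12), model = "m2")
  ens <- ensemble_average(list(a, b))
  expect_equal(ens$tmax, rep(31, 12))
  expect_equal(ens$tmin, rep(12, 12))
  expect_equal(ens$se_tmax, rep(sd(c(30, 32)) / sqrt(2), 12))
  expect_equal(ens$se_tmax[1], 1.0)
  expect_equal(attr(ens, "model"), "ensemble")
  expect_equal(attr(ens, "n_models"), 2L)

  # single model: identity, no se columns
  one <- ensemble_average(list(a))
  expect_null(one$se_tmax)
  expect_equal(one$tmax, a$tmax)

  # permutation symmetry and boundedness by the per-model range
  set.seed(8)
  models <- lapply(1:5, function(i)
    mk_series(25 + rnorm(12), 8 + rnorm(12), model = paste0("m", i)))
  e1 <- ensemble_average(models)
  e2 <- ensemble_average(rev(models))
  expect_equal(e1$tmax, e2$tmax)
  allmax <- sapply(models, function(s) s$tmax)
  expect_true(all(e1$tmax >= apply(allmax, 1, min) - 1e-12))
  expect_true(all(e1$tmax <= apply(allmax, 1, max) + 1e-12))
  expect_error(ensemble_average(list()), class = "tgp_climate_error")
})

test_that("climate CSVs round-trip by (scenario, model)", {
  series <- list(mk_series(rep(30, 12), rep(10, 12), model = "m1"),
                 mk_series(rep(28, 12), rep(9, 12), model = "m2"))
  path <- tempfile(fileext = ".csv")
  write_climate_csv(series, path)
  back <- read_climate_csv(path)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$tmax, series[[1]]$tmax)
  expect_equal(attr(back[[2]], "model"), "m2")
  # scale factor (integer tenths of a degree)
  scaled <- read_climate_csv(path, scale = 0.1)
  expect_equal(scaled[[1]]$tmax, series[[1]]$tmax * 0.1)
})

test_that("ASCII-grid extraction returns the containing cell's value", {
  # constant one-cell raster
  p1 <- tempfile(fileext = ".asc")
  writeLines(c("ncols 1", "nrows 1", "xllcorner 150", "yllcorner -30",
               "cellsize 1", "NODATA_value -9999", "20"), p1)
  r1 <- read_ascii_grid(p1)
  expect_equal(extract_value(r1, -29.5, 150.5), 20)

  # 3x3 gradient raster: direct-indexing oracle
  vals <- matrix(1:9, nrow = 3, byrow = TRUE)
  r <- grid_raster(vals, xmin = 150, ymin = -33, cellsize = 1)
  # cell centers: row 1 (north, lat -30.5), col 2 -> value vals[1, 2]
  expect_equal(extract_value(r, -30.5, 151.5), vals[1, 2])
  expect_equal(extract_value(r, -32.5, 150.5), vals[3, 1])

  # validation and error paths
  expect_error(extract_value(r, 95, 150.5), class = "tgp_extent_error")
  expect_error(extract_value(r, -30.5, 140), class = "tgp_extent_error")
  vals[2, 2] <- NA
  rna <- grid_raster(vals, xmin = 150, ymin = -33, cellsize = 1)
  expect_error(extract_value(rna, -31.5, 151.5), class = "tgp_nodata_error")
})

test_that("extract_point assembles a 12-month series from raster files", {
  dir <- tempfile(); dir.create(dir)
  write_asc <- function(path, value) {
    writeLines(c("ncols 2", "nrows 2", "xllcorner 150", "yllcorner -32",
                 "cellsize 1", "NODATA_value -9999",
                 paste(rep(value, 2), collapse = " "),
                 paste(rep(value, 2), collapse = " ")), path)
  }
  tmax_paths <- file.path(dir, sprintf("tmax_%02d.asc", 1:12))
  tmin_paths <- file.path(dir, sprintf("tmin_%02d.asc", 1:12))
  for (m in 1:12) {
    write_asc(tmax_paths[m], 20 + m)
    write_asc(tmin_paths[m], 5 + m)
  }
  cs <- extract_point(tmax_paths, tmin_paths, -31.5, 150.5,
                      scenario = "current", model = "fixture")
  expect_equal(cs$tmax, 20 + 1:12)
  expect_equal(cs$tmin, 5 + 1:12)
  expect_error(extract_point(tmax_paths[1:3], tmin_paths, -31.5, 150.5),
               class = "tgp_raster_error")
})

test_that("monthly predictions track the fitted thermal niche", {
  # cool-optimum surface: germination peaks at mild temperatures
  truth <- true_surface(0.9, 20, 12, 5, 5, 0)
  design <- make_half_grid(9, 5, 45)
  cells <- data.frame(design$cells, viable_n = 300L)
  set.seed(14)
  cells$successes <- rbinom(nrow(cells), 300,
                            surface_probability(truth, cells$day_temp,
                                                cells$night_temp))
  surf <- fit_surface(model_spec("prop_germ ~ s(day_temp, night_temp, bs = 'tp')"),
                      cells)
  # warm-summer climate: January hot, July mild
  clim <- mk_series(tmax = c(32, 31, 28, 25, 22, 19, 18, 20, 23, 26, 29, 31),
                    tmin = c(19, 18, 16, 12, 9, 6, 5, 6, 9, 12, 15, 18),
                    scenario = "current")
  pred <- predict_monthly(surf, clim)
  expect_equal(nrow(pred), 12L)
  expect_true(all(pred$prediction >= 0 & pred$prediction <= 1))
  # winter (Jun-Aug) beats summer (Dec-Feb) for a cool-optimum species
  expect_gt(mean(pred$prediction[pred$month %in% 6:8]),
            mean(pred$prediction[pred$month %in% c(12, 1, 2)]))
  # purity: identical inputs give identical outputs
  expect_identical(pred, predict_monthly(surf, clim))

  # constant surface gives 12 equal predictions
  flatcells <- data.frame(design$cells, successes = 150L, viable_n = 300L)
  flatsurf <- fit_surface(model_spec("prop_germ ~ day_temp + night_temp"),
                          flatcells)
  flatpred <- predict_monthly(flatsurf, clim)
  expect_lt(diff(range(flatpred$prediction)), 1e-6)
})

test_that("ensemble uncertainty widens the prediction band", {
  fx <- make_fixture_suite(seed = 5)
  cells <- model_table(fx$cool$experiment)
  surf <- suppressWarnings(
    fit_surface(model_spec("prop_germ ~ s(day_temp, night_temp, bs = 'tp')"),
                cells))
  ens <- ensemble_average(fx$cool$climate_future)
  pred <- predict_monthly(surf, ens)
  expect_true(all(pred$lo <= pred$prediction + 1e-12))
  expect_true(all(pred$hi >= pred$prediction - 1e-12))
  expect_true(any(pred$hi - pred$lo > 0))
})

test_that("seasonal shift report detects rotations and flat series", {
  base <- data.frame(month = 1:12, scenario = "current",
                     prediction = c(0.1, 0.1, 0.2, 0.5, 0.8, 0.9,
                                    0.8, 0.5, 0.3, 0.2, 0.1, 0.1),
                     lo = 0, hi = 1, clamped = FALSE)
  same <- base; same$scenario <- "future"
  r0 <- seasonal_shift_report(base, same)
  expect_equal(r0$peak_delta_months, 0)

  rot <- base
  rot$prediction <- base$prediction[((0:11 - 2) %% 12) + 1]  # shift +2 months
  r2 <- seasonal_shift_report(base, rot)
  expect_equal(r2$peak_delta_months, 2)

  flat <- base; flat$prediction <- rep(0.4, 12)
  rf <- seasonal_shift_report(base, flat)
  expect_true(rf$no_seasonality["future"])
  expect_equal(rf$peak_future, 1:12)
})

test_that("prediction CSV twin matches the in-memory predictions", {
  pred <- data.frame(month = 1:12, scenario = "current",
                     prediction = seq(0.1, 0.9, length.out = 12),
                     lo = 0.05, hi = 0.95, clamped = FALSE)
  path <- tempfile(fileext = ".csv")
  write_predictions_csv(pred, path)
  back <- read.csv(path)
  expect_equal(back$prediction, pred$prediction)
  expect_equal(back$month, pred$month)
})
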