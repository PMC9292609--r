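test_that("the default candidate set covers the canonical formulas", {
  specs <- default_candidates()
  labels <- vapply(specs, format_model_spec, character(1))
  expect_gte(length(specs), 7)
  expect_false(anyDuplicated(labels) > 0)
  expected <- c(
    "prop_germ ~ te(day_temp, night_temp, bs = 'cr')",
    "prop_germ ~ te(day_temp, night_temp, bs = 'tp')",
    "prop_germ ~ s(day_temp, night_temp, bs = 'tp')",
    "prop_germ ~ s(day_temp, bs = 'tp') + s(night_temp, bs = 'tp')",
    "prop_germ ~ te(day_temp, night_temp, bs = 'ts')",
    "prop_germ ~ ti(day_temp, night_temp, bs = 'tp')"
  )
  expect_true(all(expected %in% labels))
})

test_that("a basis dimension is applied to every smooth when requested", {
  specs <- default_candidates(k = 4)
  for (s in specs) {
    n_smooths <- lengths(regmatches(s$rhs, gregexpr("\\b(s|te|ti)\\(", s$rhs)))
    n_k <- lengths(regmatches(s$rhs, gregexpr("k = 4", s$rhs)))
    expect_equal(n_k, n_smooths, info = s$label)
  }
})

test_that("the formula grammar parses and emits canonically", {
  txt <- "prop_germ ~ te(day_temp, night_temp, bs = 'cr', k = 4)"
  spec <- model_spec(txt)
  expect_identical(format_model_spec(spec), txt)
  expect_equal(spec$response, "prop_germ")
  expect_error(model_spec("prop_germ ~ spline[day_temp]"),
               class = "tgp_spec_error")
  expect_error(model_spec("no tilde here"), class = "tgp_spec_error")
})

test_that("a constant-probability surface is recovered nearly flat", {
  cells <- sim_cells(function(d, n) rep(0.5, length(d)),
                     design = make_half_grid(9, 5, 45), viable_n = 200,
                     seed = 3)
  surf <- fit_surface(model_spec("prop_germ ~ s(day_temp, night_temp, bs = 'tp')"),
                      cells)
  expect_true(all(abs(surf$fitted - 0.5) < 0.05))
})

test_that("saturated and empty responses pin the surface to the boundary", {
  design <- make_half_grid(6, 5, 45)
  cells <- data.frame(design$cells,
                      successes = 50L, viable_n = 50L)
  surf <- suppressWarnings(
    fit_surface(model_spec("prop_germ ~ te(day_temp, night_temp, bs = 'cr')"),
                cells))
  expect_true(all(surf$fitted > 0.98))

  cells$successes <- 0L
  surf0 <- suppressWarnings(
    fit_surface(model_spec("prop_germ ~ te(day_temp, night_temp, bs = 'cr')"),
                cells))
  expect_true(all(surf0$fitted < 0.02))
})

test_that("a monotone synthetic trend keeps its sign in the fit", {
  cells <- sim_cells(function(d, n) plogis(-3 + 0.12 * d),
                     design = make_half_grid(9, 5, 45), viable_n = 200,
                     seed = 5)
  surf <- suppressWarnings(  # expected basis-dimension reduction on 9 temps
    fit_surface(model_spec("prop_germ ~ s(day_temp, bs = 'tp') + s(night_temp, bs = 'tp')"),
                cells))
  nights <- 15
  days <- seq(15, 45, by = 5)
  p <- predict_surface(surf, data.frame(day_temp = days, night_temp = nights),
                       extrapolation = "clamp")$prediction
  expect_true(all(diff(p) > 0))
})

test_that("predictions reproduce fitted values and respect the link", {
  cells <- sim_cells(function(d, n) plogis(-8 + 0.45 * d - 0.007 * d^2),
                     viable_n = 50, seed = 9)
  surf <- fit_surface(model_spec("prop_germ ~ te(day_temp, night_temp, bs = 'tp')"),
                      cells)
  at_train <- predict_surface(surf, cells)
  expect_equal(at_train$prediction, surf$fitted, tolerance = 1e-8)
  expect_true(all(at_train$prediction >= 0 & at_train$prediction <= 1))
})

test_that("extrapolation policies differ only off the training range", {
  cells <- sim_cells(function(d, n) rep(0.4, length(d)), seed = 2)
  surf <- fit_surface(model_spec("prop_germ ~ te(day_temp, night_temp, bs = 'cr')"),
                      cells)
  pts <- data.frame(day_temp = c(20, 60), night_temp = c(10, 50))
  clamped <- predict_surface(surf, pts, "clamp")
  allowed <- predict_surface(surf, pts, "allow")
  expect_equal(clamped$prediction[1], allowed$prediction[1])
  expect_equal(clamped$clamped, c(FALSE, TRUE))
  err <- expect_error(predict_surface(surf, pts, "error"),
                      class = "tgp_range_error")
  expect_match(conditionMessage(err), "2")
})

test_that("refitting identical data is numerically stable", {
  cells <- sim_cells(function(d, n) plogis(-2 + 0.05 * d), seed = 12)
  spec <- model_spec("prop_germ ~ s(day_temp, night_temp, bs = 'tp')")
  f1 <- suppressWarnings(fit_surface(spec, cells))$fitted
  f2 <- suppressWarnings(fit_surface(spec, cells))$fitted
  expect_lt(max(abs(f1 - f2)), 1e-8)
})

test_that("an oversized basis dimension is reduced with a warning", {
  design <- make_half_grid(4, 10, 30)   # 4 distinct temps per axis
  cells <- data.frame(design$cells, successes = 5L, viable_n = 10L)
  spec <- model_spec("prop_germ ~ te(day_temp, night_temp, bs = 'cr', k = 9)")
  expect_warning(fit_surface(spec, cells), class = "tgp_k_reduced")
})

test_that("degenerate inputs are rejected up front", {
  cells <- data.frame(day_temp = c(20, 20), night_temp = c(10, 15),
                      successes = c(1, 2), viable_n = 10)
  spec <- model_spec("prop_germ ~ day_temp + night_temp")
  expect_error(fit_surface(spec, cells), class = "tgp_precondition_error")
  cells2 <- sim_cells(function(d, n) rep(0.5, length(d)), seed = 1)
  cells2$successes[1] <- cells2$viable_n[1] + 1
  expect_error(fit_surface(spec, cells2), class = "tgp_precondition_error")
})

test_that("the surface optimum sits at the true bump for clean data", {
  truth <- true_surface(0.9, 28, 12, 6, 6, 0)
  design <- make_half_grid(9, 5, 45)
  cells <- data.frame(
    design$cells,
    viable_n = 400L
  )
  p <- surface_probability(truth, cells$day_temp, cells$night_temp)
  set.seed(21)
  cells$successes <- rbinom(nrow(cells), cells$viable_n, p)
  surf <- fit_surface(model_spec("prop_germ ~ s(day_temp, night_temp, bs = 'tp')"),
                      cells)
  opt <- surface_optimum(surf, resolution = 81)
  expect_lt(abs(opt$day_opt - 28), 2.5)
  expect_lt(abs(opt$night_opt - 12), 2.5)
})
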