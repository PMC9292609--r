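#' Full-data fit metrics for a fitted surface
#'
#' Two of the three comparison metrics are computed from the model fitted to
#' all cells: the root mean square error between observed and fitted
#' proportions, and the Pearson correlation between fitted and observed values.
#'
#' @param surface A \code{\link{fit_surface}} result (any object carrying
#'   \code{observed} and \code{fitted} components works).
#' @return List \code{rmse}, \code{correlation} (NA with
#'   \code{correlation_defined = FALSE} when the observed values have zero
#'   variance).
#' @export
full_fit_metrics <- function(surface) {
  stopifnot(!is.null(surface$observed), !is.null(surface$fitted))
  obs <- surface$observed
  fit <- surface$fitted
  rmse <- sqrt(mean((obs - fit)^2))
  if (stats::sd(obs) == 0 || stats::sd(fit) == 0) {
    list(rmse = rmse, correlation = NA_real_, correlation_defined = FALSE)
  } else {
    list(rmse = rmse, correlation = stats::cor(obs, fit),
         correlation_defined = TRUE)
  }
}

#' Monte Carlo holdout resampling of a candidate model
#'
#' Repeatedly splits the cells at random into a training fraction (default
#' 90\%) and a held-out fraction (default 10\%, at least one cell), refits the
#' candidate on the training cells and measures the prediction error on the
#' held-out cells. The distribution of per-rep errors gives the mean holdout
#' error and a non-parametric 95\% interval (2.5/97.5 percentiles). The per-rep
#' error is the mean absolute error on the proportion scale by default
#' (\code{metric = "mae"}); per-rep RMSE is available via
#' \code{metric = "rmse"}. Reps whose refit fails to converge are recorded as
#' failures and excluded from the distribution.
#'
#' The split sequence is fully reproducible: per-rep substream seeds are drawn
#' once from the master \code{seed}.
#'
#' @param spec A \code{\link{model_spec}}.
#' @param cells Training table as in \code{\link{fit_surface}}.
#' @param holdout_fraction Fraction of cells held out per rep (default 0.10).
#' @param reps Number of resampling repetitions (default 100).
#' @param seed Master RNG seed.
#' @param metric Per-rep error functional: \code{"mae"} (default) or
#'   \code{"rmse"}.
#' @return An \code{mc_holdout}: list with \code{errors} (per successful rep),
#'   \code{mean_error}, \code{lower95}, \code{upper95}, \code{n_reps},
#'   \code{failures}, \code{seed}, \code{metric}.
#' @export
monte_carlo_holdout <- function(spec, cells, holdout_fraction = 0.10,
                                reps = 100, seed = 1,
                                metric = c("mae", "rmse")) {
  stopifnot(inherits(spec, "model_spec"))
  metric <- match.arg(metric)
  n <- nrow(cells)
  n_hold <- max(1L, round(holdout_fraction * n))
  if (n - n_hold < 3L) {
    tgp_abort("too few cells to hold out at this fraction",
              "tgp_precondition_error")
  }
  if (reps < 1) tgp_abort("reps must be >= 1", "tgp_precondition_error")
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, reps)
  errors <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    hold <- sample.int(n, n_hold)
    train <- cells[-hold, , drop = FALSE]
    test <- cells[hold, , drop = FALSE]
    surf <- tryCatch(
      suppressWarnings(fit_surface(spec, train)),
      error = function(e) NULL
    )
    if (is.null(surf)) next
    pred <- tryCatch(
      predict_surface(surf, test, extrapolation = "clamp")$prediction,
      error = function(e) NULL
    )
    if (is.null(pred)) next
    obs <- if (spec$family == "binomial") {
      test$successes / test$viable_n
    } else test[[spec$response]]
    errors[r] <- if (metric == "mae") {
      mean(abs(pred - obs))
    } else {
      sqrt(mean((pred - obs)^2))
    }
  }
  ok <- errors[!is.na(errors)]
  if (length(ok) == 0L) {
    tgp_abort(sprintf("all %d holdout reps failed for '%s'", reps, spec$label),
              "tgp_convergence_error")
  }
  qs <- stats::quantile(ok, c(0.025, 0.975), names = FALSE)
  structure(
    list(errors = ok, mean_error = mean(ok), lower95 = qs[1], upper95 = qs[2],
         n_reps = as.integer(reps), failures = as.integer(sum(is.na(errors))),
         seed = seed, metric = metric),
    class = "mc_holdout"
  )
}

#' Evaluate a candidate set: full-fit metrics plus holdout resampling
#'
#' @param specs List of \code{\link{model_spec}} (e.g.
#'   \code{\link{default_candidates}}).
#' @param cells Training table as in \code{\link{fit_surface}}.
#' @param holdout_fraction,reps,seed,metric Passed to
#'   \code{\link{monte_carlo_holdout}}; \code{reps = 0} skips the holdout
#'   resampling (holdout metrics NA), leaving full-fit RMSE/correlation only —
#'   useful when selecting by \code{"min_rmse"} in simulation studies.
#' @return List of \code{model_evaluation} objects (one per candidate that
#'   fitted on the full data; failed candidates are recorded with NA metrics).
#' @export
evaluate_candidates <- function(specs, cells, holdout_fraction = 0.10,
                                reps = 100, seed = 1, metric = "mae") {
  stopifnot(length(specs) >= 1L)
  lapply(specs, function(spec) {
    surf <- tryCatch(suppressWarnings(fit_surface(spec, cells)),
                     error = function(e) NULL)
    if (is.null(surf)) {
      return(structure(
        list(spec = spec, mean_error = NA_real_, lower95 = NA_real_,
             upper95 = NA_real_, rmse = NA_real_, correlation = NA_real_,
             n_reps = 0L, failures = NA_integer_, converged = FALSE),
        class = "model_evaluation"
      ))
    }
    fm <- full_fit_metrics(surf)
    if (reps == 0) {
      return(structure(
        list(spec = spec, mean_error = NA_real_, lower95 = NA_real_,
             upper95 = NA_real_, rmse = fm$rmse,
             correlation = fm$correlation, n_reps = 0L, failures = 0L,
             converged = TRUE),
        class = "model_evaluation"
      ))
    }
    mc <- monte_carlo_holdout(spec, cells, holdout_fraction, reps, seed,
                              metric = metric)
    structure(
      list(spec = spec, mean_error = mc$mean_error, lower95 = mc$lower95,
           upper95 = mc$upper95, rmse = fm$rmse,
           correlation = fm$correlation, n_reps = mc$n_reps,
           failures = mc$failures, converged = TRUE),
      class = "model_evaluation"
    )
  })
}

#' Select a model from a set of evaluations
#'
#' Default rule \code{"min_rmse"} picks the converged candidate with the lowest
#' full-fit RMSE; \code{"min_mean_error"} picks the lowest mean holdout error;
#' \code{"manual"} returns the named candidate. Ties are broken by fewer model
#' terms, then lexicographic formula label.
#'
#' @param evaluations List of \code{model_evaluation}.
#' @param rule \code{"min_rmse"} (default), \code{"min_mean_error"} or
#'   \code{"manual"}.
#' @param manual_label For \code{rule = "manual"}: the formula label to select.
#' @return The selected candidate's formula label.
#' @export
select_model <- function(evaluations,
                         rule = c("min_rmse", "min_mean_error", "manual"),
                         manual_label = NULL) {
  rule <- match.arg(rule)
  labels <- vapply(evaluations, function(e) e$spec$label, character(1))
  if (rule == "manual") {
    if (is.null(manual_label) || !(manual_label %in% labels)) {
      tgp_abort("manual selection requires a label present in the evaluations",
                "tgp_selection_error")
    }
    return(manual_label)
  }
  conv <- vapply(evaluations, function(e) isTRUE(e$converged), logical(1))
  if (!any(conv)) {
    tgp_abort("no candidate converged; nothing to select", "tgp_selection_error")
  }
  crit <- vapply(evaluations,
                 function(e) if (rule == "min_rmse") e$rmse else e$mean_error,
                 numeric(1))
  crit[!conv] <- Inf
  terms <- vapply(evaluations, function(e) e$spec$n_terms, numeric(1))
  ord <- order(crit, terms, labels)
  labels[ord[1]]
}

#' Comparison table of candidate evaluations
#'
#' One row per candidate with all five comparison metrics, sorted by mean
#' holdout error (ascending, non-converged candidates last), with the selected
#' model marked.
#'
#' @param evaluations List of \code{model_evaluation}.
#' @param rule,manual_label Passed to \code{\link{select_model}}.
#' @return Data frame \code{model, mean_error, lower95, upper95, rmse,
#'   correlation, n_reps, failures, selected}.
#' @export
comparison_table <- function(evaluations, rule = "min_rmse",
                             manual_label = NULL) {
  stopifnot(length(evaluations) >= 1L)
  sel <- select_model(evaluations, rule = rule, manual_label = manual_label)
  df <- do.call(rbind, lapply(evaluations, function(e) {
    data.frame(model = e$spec$label, mean_error = e$mean_error,
               lower95 = e$lower95, upper95 = e$upper95, rmse = e$rmse,
               correlation = e$correlation, n_reps = e$n_reps,
               failures = e$failures, stringsAsFactors = FALSE)
  }))
  df$selected <- df$model == sel
  df <- df[order(is.na(df$mean_error), df$mean_error), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build the per-cell model table from an experiment
#'
#' Collapses each scored cell to the binomial modelling row: day and night
#' temperature, final germinated count (\code{successes}) and viable-seed
#' denominator (\code{viable_n}).
#'
#' @param exp An \code{\link{experiment}}.
#' @return Data frame \code{cell_id, day_temp, night_temp, successes, viable_n}.
#' @export
model_table <- function(exp) {
  stopifnot(inherits(exp, "experiment"))
  cells <- exp$design$cells
  rows <- lapply(exp$series, function(s) {
    i <- match(s$cell_id, cells$cell_id)
    data.frame(cell_id = s$cell_id,
               day_temp = cells$day_temp[i],
               night_temp = cells$night_temp[i],
               successes = s$cum_germinated[length(s$cum_germinated)],
               viable_n = viable_n(s),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
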