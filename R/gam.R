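#' Candidate model specifications for germination surfaces
#'
#' A \code{model_spec} describes one candidate generalized additive model of a
#' germination index over day and night temperature, serialized in a canonical
#' text grammar, e.g. \code{"prop_germ ~ te(day_temp, night_temp, bs = 'cr', k = 4)"}.
#' Supported right-hand sides: a linear baseline
#' (\code{day_temp + night_temp}), marginal smooths \code{s(day_temp) + s(night_temp)},
#' an isotropic bivariate smooth \code{s(day_temp, night_temp)}, full tensor
#' products \code{te(...)} and tensor interactions \code{ti(...)}, over bases
#' \code{cr} (cubic regression spline), \code{tp} (thin plate) and \code{ts}
#' (thin plate with penalized null space).
#'
#' @param formula_text Canonical formula string (see above).
#' @param family \code{"binomial"} (logit link; the default, used for
#'   proportion responses with viable-seed denominators) or \code{"gaussian"}
#'   (for continuous indices such as t50).
#' @return A \code{model_spec}: list with \code{response}, \code{rhs},
#'   \code{family}, \code{label}, \code{n_terms}.
#' @export
model_spec <- function(formula_text, family = c("binomial", "gaussian")) {
  family <- match.arg(family)
  parts <- strsplit(formula_text, "~", fixed = TRUE)[[1]]
  if (length(parts) != 2L) {
    tgp_abort("formula must have the form 'response ~ terms'", "tgp_spec_error")
  }
  response <- trimws(parts[1])
  rhs <- trimws(parts[2])
  terms <- strsplit_top_level(rhs)
  ok <- grepl(
    "^([a-zA-Z_][a-zA-Z0-9_]*|(s|te|ti)\\([a-zA-Z0-9_, ]+(,\\s*bs\\s*=\\s*'(cr|tp|ts)')?(,\\s*k\\s*=\\s*[0-9]+)?\\))$",
    terms
  )
  if (!all(ok)) {
    tgp_abort(sprintf("unparseable model term(s): %s",
                      paste(terms[!ok], collapse = "; ")), "tgp_spec_error")
  }
  structure(
    list(response = response, rhs = rhs, family = family,
         label = paste(response, "~", rhs), n_terms = length(terms)),
    class = "model_spec"
  )
}

# split "a + b + te(x, y, bs = 'cr')" on '+' outside parentheses
strsplit_top_level <- function(rhs) {
  chars <- strsplit(rhs, "")[[1]]
  depth <- 0L
  buf <- character(0)
  cur <- ""
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == "+" && depth == 0L) {
      buf <- c(buf, trimws(cur)); cur <- ""
    } else cur <- paste0(cur, ch)
  }
  c(buf, trimws(cur))
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec [%s]: %s\n", x$family, x$label))
  invisible(x)
}

#' Serialize a model spec to its canonical formula string
#' @param spec A \code{model_spec}.
#' @return The canonical formula text (round-trips through
#'   \code{\link{model_spec}} bit-exactly).
#' @export
format_model_spec <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  spec$label
}

#' Default candidate set of germination-surface models
#'
#' The automated comparison covers the standard plausible specifications:
#' a linear day + night baseline, marginal smooths, an isotropic bivariate
#' thin-plate smooth, tensor-product smooths with cubic-regression, thin-plate
#' and penalized-null-space thin-plate marginal bases, and a pure tensor
#' interaction.
#'
#' @param k Optional basis dimension applied to every smooth term (e.g. 4 for
#'   small plates with 21 cells); \code{NULL} leaves engine defaults.
#' @param response Response name used in the canonical formulas.
#' @param family Model family for all candidates.
#' @return List of \code{\link{model_spec}} (7 candidates).
#' @export
default_candidates <- function(k = NULL, response = "prop_germ",
                               family = "binomial") {
  karg <- if (is.null(k)) "" else sprintf(", k = %d", as.integer(k))
  rhs <- c(
    "day_temp + night_temp",
    sprintf("te(day_temp, night_temp, bs = 'cr'%s)", karg),
    sprintf("te(day_temp, night_temp, bs = 'tp'%s)", karg),
    sprintf("s(day_temp, night_temp, bs = 'tp'%s)", karg),
    sprintf("s(day_temp, bs = 'tp'%s) + s(night_temp, bs = 'tp'%s)", karg, karg),
    sprintf("te(day_temp, night_temp, bs = 'ts'%s)", karg),
    sprintf("ti(day_temp, night_temp, bs = 'tp'%s)", karg)
  )
  lapply(paste(response, "~", rhs), model_spec, family = family)
}

# Cap smooth basis dimensions at what the covariates can support; returns the
# possibly modified rhs and warns when a reduction happened.
cap_basis_dim <- function(rhs, cells) {
  nd <- length(unique(cells$day_temp))
  nn <- length(unique(cells$night_temp))
  terms <- strsplit_top_level(rhs)
  capped <- vapply(terms, function(term) {
    m <- regmatches(term, regexec("^(s|te|ti)\\(([^)]*)\\)$", term))[[1]]
    if (length(m) == 0L) return(term)
    fn <- m[2]
    args <- m[3]
    bivariate <- grepl("day_temp", args) && grepl("night_temp", args)
    if (fn %in% c("te", "ti")) {
      # tensor products: k is the per-margin basis dimension (engine default 5)
      default_k <- 5L
      limit <- if (bivariate) min(nd, nn) else
        if (grepl("day_temp", args)) nd else nn
    } else if (bivariate) {
      # isotropic bivariate smooth (engine default 30)
      default_k <- 30L
      limit <- nrow(unique(cells[, c("day_temp", "night_temp")]))
    } else {
      # univariate smooth (engine default 10)
      default_k <- 10L
      limit <- if (grepl("day_temp", args)) nd else nn
    }
    km <- regmatches(term, regexec("k = ([0-9]+)", term))[[1]]
    k <- if (length(km)) as.integer(km[2]) else default_k
    if (k <= limit) return(term)
    tgp_warn(sprintf(
      "basis dimension k = %d in '%s' exceeds distinct covariate values; reduced to %d",
      k, term, limit), "tgp_k_reduced")
    if (length(km)) {
      sub("k = [0-9]+", sprintf("k = %d", limit), term)
    } else {
      sub("\\)$", sprintf(", k = %d)", limit), term)
    }
  }, character(1))
  paste(capped, collapse = " + ")
}

#' Fit a candidate germination surface to per-cell data
#'
#' Fits the penalized-likelihood GAM described by \code{spec} to a table of
#' cells. Binomial responses are modelled as per-cell
#' (\code{successes}, \code{viable_n - successes}) pairs — the seed is the unit
#' of replication, so each cell is weighted by its viable-seed count — with a
#' logit link; smoothing parameters are selected by REML. Fitting is
#' deterministic given the data and spec.
#'
#' @param spec A \code{\link{model_spec}}.
#' @param cells Data frame with columns \code{day_temp}, \code{night_temp} and,
#'   for the binomial family, \code{successes} and \code{viable_n}; for the
#'   gaussian family, a column named after \code{spec$response}.
#' @return A \code{fitted_surface}: list with \code{spec}, the fitted
#'   \code{mgcv} model, per-cell \code{fitted} values (response scale),
#'   \code{observed} responses, training \code{ranges}, and the training data.
#' @export
fit_surface <- function(spec, cells) {
  stopifnot(inherits(spec, "model_spec"))
  check_columns(cells, c("day_temp", "night_temp"), "cell table")
  if (length(unique(cells$day_temp)) < 2L ||
      length(unique(cells$night_temp)) < 2L) {
    tgp_abort("need >= 2 distinct day and night temperatures",
              "tgp_precondition_error")
  }
  rhs <- cap_basis_dim(spec$rhs, cells)
  if (spec$family == "binomial") {
    check_columns(cells, c("successes", "viable_n"), "cell table")
    if (any(cells$viable_n < 1) || any(cells$successes > cells$viable_n) ||
        any(cells$successes < 0)) {
      tgp_abort("need 0 <= successes <= viable_n and viable_n >= 1 per cell",
                "tgp_precondition_error")
    }
    f <- stats::as.formula(
      paste("cbind(successes, viable_n - successes) ~", rhs))
    fam <- stats::binomial(link = "logit")
    observed <- cells$successes / cells$viable_n
  } else {
    check_columns(cells, spec$response, "cell table")
    f <- stats::as.formula(paste(spec$response, "~", rhs))
    fam <- stats::gaussian()
    observed <- cells[[spec$response]]
  }
  g <- tryCatch(
    mgcv::gam(f, family = fam, data = cells, method = "REML"),
    error = function(e) {
      tgp_abort(sprintf("model '%s' failed to fit: %s",
                        spec$label, conditionMessage(e)),
                "tgp_convergence_error")
    }
  )
  if (!isTRUE(g$converged)) {
    tgp_abort(sprintf("model '%s' did not converge", spec$label),
              "tgp_convergence_error")
  }
  structure(
    list(spec = spec, gam = g,
         fitted = as.numeric(stats::fitted(g)),
         observed = observed,
         ranges = list(day = range(cells$day_temp),
                       night = range(cells$night_temp)),
         data = cells),
    class = "fitted_surface"
  )
}

#' @export
print.fitted_surface <- function(x, ...) {
  cat(sprintf("fitted surface: %s [%s], %d cells, day %g-%g degC, night %g-%g degC\n",
              x$spec$label, x$spec$family, nrow(x$data),
              x$ranges$day[1], x$ranges$day[2],
              x$ranges$night[1], x$ranges$night[2]))
  invisible(x)
}

#' Predict from a fitted germination surface
#'
#' @param surface A \code{fitted_surface}.
#' @param points Data frame with \code{day_temp} and \code{night_temp} columns.
#' @param extrapolation How to treat query temperatures outside the training
#'   range: \code{"clamp"} (default; clamp to the range edge and flag),
#'   \code{"allow"} (trust the spline extrapolation) or \code{"error"}.
#' @return Data frame \code{day_temp, night_temp, prediction, clamped}; for the
#'   binomial family predictions are proportions in [0, 1].
#' @export
predict_surface <- function(surface, points,
                            extrapolation = c("clamp", "allow", "error")) {
  stopifnot(inherits(surface, "fitted_surface"))
  extrapolation <- match.arg(extrapolation)
  check_columns(points, c("day_temp", "night_temp"), "prediction points")
  rd <- surface$ranges$day
  rn <- surface$ranges$night
  out_of_range <- points$day_temp < rd[1] | points$day_temp > rd[2] |
    points$night_temp < rn[1] | points$night_temp > rn[2]
  if (extrapolation == "error" && any(out_of_range)) {
    tgp_abort(sprintf("points outside training range at row(s): %s",
                      paste(which(out_of_range), collapse = ", ")),
              "tgp_range_error")
  }
  q <- points
  clamped <- rep(FALSE, nrow(points))
  if (extrapolation == "clamp") {
    q$day_temp <- pmin(pmax(q$day_temp, rd[1]), rd[2])
    q$night_temp <- pmin(pmax(q$night_temp, rn[1]), rn[2])
    clamped <- out_of_range
  }
  pred <- as.numeric(stats::predict(surface$gam, newdata = q,
                                    type = "response"))
  data.frame(day_temp = points$day_temp, night_temp = points$night_temp,
             prediction = pred, clamped = clamped)
}

#' Locate the optimum of a fitted surface on a prediction grid
#'
#' Evaluates the surface on a regular grid over the training half-plane
#' (day >= night within the training ranges) and returns the grid maximum —
#' the estimated thermal optimum and peak germination probability.
#'
#' @param surface A \code{fitted_surface}.
#' @param resolution Grid points per axis.
#' @return List \code{day_opt}, \code{night_opt}, \code{g_max}.
#' @export
surface_optimum <- function(surface, resolution = 101) {
  stopifnot(inherits(surface, "fitted_surface"))
  grid <- expand.grid(
    day_temp = seq(surface$ranges$day[1], surface$ranges$day[2],
                   length.out = resolution),
    night_temp = seq(surface$ranges$night[1], surface$ranges$night[2],
                     length.out = resolution)
  )
  grid <- grid[grid$day_temp >= grid$night_temp, , drop = FALSE]
  p <- predict_surface(surface, grid, extrapolation = "allow")
  best <- which.max(p$prediction)
  list(day_opt = p$day_temp[best], night_opt = p$night_temp[best],
       g_max = p$prediction[best])
}
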