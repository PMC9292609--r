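#' Construct a per-cell cumulative germination series
#'
#' A \code{cell_series} holds one TGP cell's scoring record: cumulative
#' germinated counts at (possibly irregular) days since sowing, together with
#' the number of seeds sown and the seed-lot viability proportion from a
#' pre-experiment cut test. The viability proportion is "factored in" by using
#' \code{round(n_sown * viability)} viable seeds as the binomial denominator
#' everywhere downstream (see \code{\link{viable_n}}).
#'
#' @param cell_id Cell identifier (must exist in the design when assembled
#'   into an \code{\link{experiment}}).
#' @param n_sown Seeds sown in the cell.
#' @param viability Seed-lot viable proportion in (0, 1].
#' @param days Numeric vector of scoring days since sowing, strictly increasing,
#'   all >= 0.
#' @param cum_germinated Integer cumulative germinated counts, non-decreasing,
#'   final value <= \code{n_sown}.
#' @return A \code{cell_series} object.
#' @export
cell_series <- function(cell_id, n_sown, viability, days, cum_germinated) {
  if (!is_scalar_number(n_sown) || n_sown < 1 || n_sown != round(n_sown)) {
    tgp_abort("n_sown must be a positive whole number", "tgp_domain_error")
  }
  if (!is_scalar_number(viability) || viability <= 0 || viability > 1) {
    tgp_abort("viability must be in (0, 1]", "tgp_domain_error")
  }
  if (length(days) != length(cum_germinated) || length(days) < 1L) {
    tgp_abort("days and cum_germinated must be equal-length, non-empty",
              "tgp_domain_error")
  }
  if (any(days < 0) || any(diff(days) <= 0)) {
    tgp_abort(sprintf("cell %s: scoring days must be >= 0 and strictly increasing",
                      cell_id), "tgp_domain_error")
  }
  if (any(cum_germinated < 0) || any(cum_germinated != round(cum_germinated))) {
    tgp_abort(sprintf("cell %s: counts must be non-negative integers", cell_id),
              "tgp_domain_error")
  }
  drops <- which(diff(cum_germinated) < 0)
  if (length(drops) > 0L) {
    tgp_abort(
      sprintf("cell %s: cumulative count decreases at day %g",
              cell_id, days[drops[1] + 1L]),
      "tgp_monotonicity_error"
    )
  }
  final <- cum_germinated[length(cum_germinated)]
  if (final > n_sown) {
    tgp_abort(sprintf("cell %s: cumulative count %d exceeds n_sown %d",
                      cell_id, final, n_sown), "tgp_overflow_error")
  }
  # Observed germination proves viability: if more seeds germinated than the
  # cut test predicted viable, trust the seeds and raise viability loudly.
  if (final > round(n_sown * viability)) {
    tgp_warn(
      sprintf("cell %s: final count %d exceeds viable_n %d; viability reset to %0.3f",
              cell_id, final, round(n_sown * viability), final / n_sown),
      "tgp_viability_reset"
    )
    viability <- final / n_sown
  }
  structure(
    list(cell_id = cell_id, n_sown = as.integer(n_sown), viability = viability,
         days = as.numeric(days), cum_germinated = as.integer(cum_germinated)),
    class = "cell_series"
  )
}

#' @export
print.cell_series <- function(x, ...) {
  cat(sprintf("cell %s: %d sown, viability %.2f, %d scorings, final count %d\n",
              x$cell_id, x$n_sown, x$viability, length(x$days),
              x$cum_germinated[length(x$cum_germinated)]))
  invisible(x)
}

#' Viable-seed denominator for a cell
#'
#' @param series A \code{cell_series}.
#' @return \code{round(n_sown * viability)} (round-half-even, R's \code{round}),
#'   the binomial denominator used by all downstream proportions.
#' @export
viable_n <- function(series) {
  stopifnot(inherits(series, "cell_series"))
  if (series$viability <= 0 || series$viability > 1) {
    tgp_abort("viability must be in (0, 1]", "tgp_domain_error")
  }
  as.integer(round(series$n_sown * series$viability))
}

#' Pool replicate containers within a cell
#'
#' When a cell holds several replicate jars or dishes sharing the same scoring
#' days (e.g. five 10-seed jars), they are combined so the cell is represented
#' by a single series with summed counts and sown seeds; viability is the
#' shared seed-lot value.
#'
#' @param series_list List of \code{cell_series} with identical \code{cell_id},
#'   scoring days and viability.
#' @return A single pooled \code{cell_series}.
#' @export
pool_replicates <- function(series_list) {
  stopifnot(length(series_list) >= 1L,
            all(vapply(series_list, inherits, logical(1), "cell_series")))
  first <- series_list[[1]]
  if (length(series_list) == 1L) return(first)
  for (s in series_list[-1]) {
    if (!identical(s$cell_id, first$cell_id)) {
      tgp_abort("replicates must share cell_id", "tgp_alignment_error")
    }
    if (length(s$days) != length(first$days) ||
        any(s$days != first$days)) {
      tgp_abort(sprintf("cell %s: replicate scoring days do not align",
                        first$cell_id), "tgp_alignment_error")
    }
  }
  cell_series(
    cell_id = first$cell_id,
    n_sown = sum(vapply(series_list, function(s) s$n_sown, integer(1))),
    viability = first$viability,
    days = first$days,
    cum_germinated = Reduce(`+`, lapply(series_list, `[[`, "cum_germinated"))
  )
}

#' Assemble an experiment from a design and per-cell series
#'
#' @param design A \code{tgp_design}.
#' @param series List of \code{cell_series}; each \code{cell_id} must be a
#'   usable design cell and appear at most once.
#' @param species Species label.
#' @param sown_date Optional sowing-date metadata (stored, not interpreted).
#' @return An \code{experiment} object.
#' @export
experiment <- function(design, series, species = "unknown", sown_date = NA) {
  stopifnot(inherits(design, "tgp_design"))
  ids <- vapply(series, function(s) s$cell_id, character(1))
  if (anyDuplicated(ids)) {
    tgp_abort(sprintf("duplicate series for cell(s): %s",
                      paste(unique(ids[duplicated(ids)]), collapse = ", ")),
              "tgp_reference_error")
  }
  unknown <- setdiff(ids, design$cells$cell_id)
  if (length(unknown) > 0L) {
    tgp_abort(sprintf("series reference unknown cell_id(s): %s",
                      paste(unknown, collapse = ", ")), "tgp_reference_error")
  }
  names(series) <- ids
  structure(list(design = design, series = series, species = species,
                 sown_date = sown_date),
            class = "experiment")
}

#' @export
print.experiment <- function(x, ...) {
  cat(sprintf("TGP experiment: %s, %d scored cells of %d usable\n",
              x$species, length(x$series), n_usable_cells(x$design)))
  invisible(x)
}

#' Read a germination scoring CSV (plus per-cell metadata) into an experiment
#'
#' Scoring CSV schema: \code{species,cell_id,day,cum_germinated}; metadata CSV
#' schema: \code{cell_id,n_sown,viability}. Headers are validated strictly and
#' all \code{cell_series} invariants are enforced (monotone cumulative counts,
#' counts within \code{n_sown}, known cell ids), with errors naming the
#' offending cell and day.
#'
#' @param scoring_path Path to the scoring CSV.
#' @param meta_path Path to the per-cell metadata CSV.
#' @param design A \code{tgp_design} the cells must belong to.
#' @param species Optional species label override; defaults to the (single)
#'   species found in the file.
#' @return An \code{\link{experiment}}.
#' @export
read_scoring_csv <- function(scoring_path, meta_path, design, species = NULL) {
  sc <- utils::read.csv(scoring_path, stringsAsFactors = FALSE)
  check_columns(sc, c("species", "cell_id", "day", "cum_germinated"),
                basename(scoring_path))
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  check_columns(meta, c("cell_id", "n_sown", "viability"), basename(meta_path))
  if (anyDuplicated(meta$cell_id)) {
    tgp_abort("metadata has duplicate cell_id rows", "tgp_schema_error")
  }
  sp <- unique(sc$species)
  if (is.null(species)) {
    if (length(sp) != 1L) {
      tgp_abort("scoring file contains multiple species; pass `species`",
                "tgp_schema_error")
    }
    species <- sp
  } else {
    sc <- sc[sc$species == species, , drop = FALSE]
    if (nrow(sc) == 0L) {
      tgp_abort(sprintf("no rows for species '%s' (file has: %s)",
                        species, paste(sp, collapse = ", ")),
                "tgp_schema_error")
    }
  }
  no_meta <- setdiff(unique(sc$cell_id), meta$cell_id)
  if (length(no_meta) > 0L) {
    tgp_abort(sprintf("no metadata for cell(s): %s",
                      paste(no_meta, collapse = ", ")), "tgp_reference_error")
  }
  series <- lapply(unique(sc$cell_id), function(id) {
    rows <- sc[sc$cell_id == id, , drop = FALSE]
    rows <- rows[order(rows$day), , drop = FALSE]
    m <- meta[meta$cell_id == id, , drop = FALSE]
    cell_series(id, m$n_sown, m$viability, rows$day, rows$cum_germinated)
  })
  experiment(design, series, species = species)
}

#' Write an experiment back to scoring + metadata CSVs
#'
#' Round-trips with \code{\link{read_scoring_csv}} modulo row/column order.
#'
#' @param exp An \code{\link{experiment}}.
#' @param scoring_path Output path for the scoring CSV.
#' @param meta_path Output path for the metadata CSV.
#' @return Invisibly, \code{scoring_path}.
#' @export
write_scoring_csv <- function(exp, scoring_path, meta_path) {
  stopifnot(inherits(exp, "experiment"))
  sc <- do.call(rbind, lapply(exp$series, function(s) {
    data.frame(species = exp$species, cell_id = s$cell_id, day = s$days,
               cum_germinated = s$cum_germinated, stringsAsFactors = FALSE)
  }))
  meta <- do.call(rbind, lapply(exp$series, function(s) {
    data.frame(cell_id = s$cell_id, n_sown = s$n_sown,
               viability = s$viability, stringsAsFactors = FALSE)
  }))
  utils::write.csv(sc, scoring_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(scoring_path)
}
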