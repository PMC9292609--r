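#' Construct a half-grid thermogradient-plate design
#'
#' A bidirectional thermogradient plate (TGP) produces a two-way gradient of
#' temperatures across a square grid of cells; the gradient direction swaps
#' every photoperiod so each cell experiences a distinct day/night temperature
#' pair. Only cells whose lit-phase (day) temperature is at least their dark-phase
#' (night) temperature are ecologically meaningful; those cells form the
#' triangular "half grid", including the constant-temperature diagonal, with
#' \code{axis_cells * (axis_cells + 1) / 2} usable cells (21 for a 6-cell axis,
#' 36 for 8, 45 for 9).
#'
#' Nominal per-cell set temperatures are linearly interpolated between
#' \code{cold_setting} and \code{warm_setting} along each axis. Rows index the
#' night-temperature gradient and columns the day-temperature gradient, both
#' 0-based with row 0 / col 0 at the coldest edge. Measured cell means (see
#' \code{\link{mean_cell_temperatures}}) can override the nominal values via
#' \code{\link{set_cell_temperatures}}.
#'
#' @param axis_cells Number of cells along each gradient axis (>= 1).
#' @param cold_setting Plate cold-edge set temperature, degrees C.
#' @param warm_setting Plate warm-edge set temperature, degrees C; must exceed
#'   \code{cold_setting}.
#' @param photoperiod_h Hours of light per diurnal cycle (metadata only).
#' @return A \code{tgp_design}: list with \code{axis_cells}, \code{cold_setting},
#'   \code{warm_setting}, \code{photoperiod_h} and \code{cells}, a data frame of
#'   usable cells with columns \code{cell_id,row,col,day_temp,night_temp}.
#' @examples
#' d <- make_half_grid(6, 5, 45)
#' nrow(d$cells) # 21
#' @export
make_half_grid <- function(axis_cells, cold_setting = 5, warm_setting = 45,
                           photoperiod_h = 12) {
  if (!is_scalar_number(axis_cells) || axis_cells < 1 ||
      axis_cells != round(axis_cells)) {
    tgp_abort("axis_cells must be a positive whole number", "tgp_invalid_design")
  }
  if (!is_scalar_number(cold_setting) || !is_scalar_number(warm_setting) ||
      cold_setting >= warm_setting) {
    tgp_abort("cold_setting must be strictly below warm_setting",
              "tgp_invalid_design")
  }
  axis_cells <- as.integer(axis_cells)
  # position fraction along an axis; a single cell sits at the midpoint
  frac <- if (axis_cells == 1L) 0.5 else
    (seq_len(axis_cells) - 1L) / (axis_cells - 1L)
  temp_at <- cold_setting + frac * (warm_setting - cold_setting)

  grid <- expand.grid(row = seq_len(axis_cells) - 1L,
                      col = seq_len(axis_cells) - 1L)
  grid$night_temp <- temp_at[grid$row + 1L]
  grid$day_temp <- temp_at[grid$col + 1L]
  usable <- grid[grid$day_temp >= grid$night_temp, , drop = FALSE]
  usable <- usable[order(usable$row, usable$col), , drop = FALSE]
  cells <- data.frame(
    cell_id = sprintf("r%02dc%02d", usable$row, usable$col),
    row = usable$row,
    col = usable$col,
    day_temp = usable$day_temp,
    night_temp = usable$night_temp,
    stringsAsFactors = FALSE
  )
  rownames(cells) <- NULL
  structure(
    list(axis_cells = axis_cells, cold_setting = cold_setting,
         warm_setting = warm_setting, photoperiod_h = photoperiod_h,
         cells = cells),
    class = "tgp_design"
  )
}

#' @export
print.tgp_design <- function(x, ...) {
  cat(sprintf(
    "TGP half-grid design: %d cells/axis, %d usable cells, %.1f-%.1f degC, %gh photoperiod\n",
    x$axis_cells, nrow(x$cells), x$cold_setting, x$warm_setting, x$photoperiod_h))
  invisible(x)
}

#' Number of usable cells in a design
#' @param design A \code{tgp_design}.
#' @return Integer count of usable (day >= night) cells.
#' @export
n_usable_cells <- function(design) {
  stopifnot(inherits(design, "tgp_design"))
  nrow(design$cells)
}

#' Average repeated surface temperature readings per cell and phase
#'
#' Plate surface temperatures are recorded repeatedly (e.g. with an infrared
#' thermometer on scoring days) during both the lit and dark phases; the final
#' cell temperatures are the arithmetic means over the experimental period.
#'
#' @param readings Data frame with columns \code{cell_id}, \code{phase}
#'   (\code{"day"} or \code{"night"}), \code{value} (degrees C) and optionally
#'   \code{day} (reading occasion).
#' @return Data frame with one row per cell: \code{cell_id, day_temp, night_temp}.
#' @export
mean_cell_temperatures <- function(readings) {
  check_columns(readings, c("cell_id", "phase", "value"), "readings table")
  if (!all(readings$phase %in% c("day", "night"))) {
    tgp_abort("phase must be 'day' or 'night'", "tgp_invalid_readings")
  }
  if (!all(is.finite(readings$value))) {
    tgp_abort("all temperature readings must be finite", "tgp_invalid_readings")
  }
  ids <- unique(readings$cell_id)
  missing_phase <- vapply(ids, function(id) {
    ph <- readings$phase[readings$cell_id == id]
    !all(c("day", "night") %in% ph)
  }, logical(1))
  if (any(missing_phase)) {
    tgp_abort(
      sprintf("cell(s) missing readings for one phase: %s",
              paste(ids[missing_phase], collapse = ", ")),
      "tgp_incomplete_readings"
    )
  }
  agg <- stats::aggregate(value ~ cell_id + phase, data = readings, FUN = mean)
  out <- data.frame(cell_id = ids, stringsAsFactors = FALSE)
  out$day_temp <- agg$value[match(paste(ids, "day"),
                                  paste(agg$cell_id, agg$phase))]
  out$night_temp <- agg$value[match(paste(ids, "night"),
                                    paste(agg$cell_id, agg$phase))]
  out
}

#' Override nominal design temperatures with measured cell means
#'
#' @param design A \code{tgp_design}.
#' @param temps Data frame \code{cell_id, day_temp, night_temp} (e.g. from
#'   \code{\link{mean_cell_temperatures}}); cells absent from \code{temps}
#'   keep their nominal temperatures.
#' @return The design with updated cell temperatures.
#' @export
set_cell_temperatures <- function(design, temps) {
  stopifnot(inherits(design, "tgp_design"))
  check_columns(temps, c("cell_id", "day_temp", "night_temp"), "temperature table")
  unknown <- setdiff(temps$cell_id, design$cells$cell_id)
  if (length(unknown) > 0L) {
    tgp_abort(sprintf("unknown cell_id(s): %s", paste(unknown, collapse = ", ")),
              "tgp_reference_error")
  }
  idx <- match(temps$cell_id, design$cells$cell_id)
  design$cells$day_temp[idx] <- temps$day_temp
  design$cells$night_temp[idx] <- temps$night_temp
  bad <- design$cells$day_temp < design$cells$night_temp
  if (any(bad)) {
    tgp_abort(
      sprintf("measured day_temp < night_temp for usable cell(s): %s",
              paste(design$cells$cell_id[bad], collapse = ", ")),
      "tgp_invalid_design"
    )
  }
  design
}

#' Minimum seed requirement for a design
#'
#' One practical appeal of the half-grid workflow is seed economy: a 36-cell
#' plate at 10 seeds per cell needs only 360 seeds in total.
#'
#' @param design A \code{tgp_design}.
#' @param seeds_per_cell Seeds sown in each usable cell (>= 1).
#' @return Total seeds required (usable cells x seeds per cell).
#' @export
min_seed_requirement <- function(design, seeds_per_cell) {
  stopifnot(inherits(design, "tgp_design"))
  if (!is_scalar_number(seeds_per_cell) || seeds_per_cell < 1 ||
      seeds_per_cell != round(seeds_per_cell)) {
    tgp_abort("seeds_per_cell must be a positive whole number",
              "tgp_precondition_error")
  }
  n_usable_cells(design) * as.integer(seeds_per_cell)
}

#' Read / write per-cell temperature tables
#'
#' CSV schema: \code{cell_id,row,col,day_temp,night_temp} (UTF-8, '.' decimal).
#'
#' @param path File path.
#' @return \code{read_cell_temps_csv}: a data frame in the schema above.
#' @export
read_cell_temps_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("cell_id", "row", "col", "day_temp", "night_temp"),
                basename(path))
  df
}

#' @rdname read_cell_temps_csv
#' @param design A \code{tgp_design} whose cells are written.
#' @export
write_cell_temps_csv <- function(design, path) {
  stopifnot(inherits(design, "tgp_design"))
  utils::write.csv(design$cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a surface-readings table
#'
#' CSV schema: \code{cell_id,phase,value,day}.
#' @param path File path.
#' @return Data frame of readings.
#' @export
read_readings_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("cell_id", "phase", "value"), basename(path))
  df
}
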