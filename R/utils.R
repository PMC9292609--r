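#' @keywords internal
#' @importFrom ggplot2 .data
"_PACKAGE"

# Classed conditions so callers can distinguish validation failures
# programmatically (tests match on class, not message wording).
tgp_abort <- function(message, class) {
  stop(structure(
    class = c(class, "tgpgerm_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

tgp_warn <- function(message, class) {
  warning(structure(
    class = c(class, "tgpgerm_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Strict CSV header check shared by all readers.
check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    tgp_abort(
      sprintf("%s is missing required column(s): %s",
              what, paste(missing, collapse = ", ")),
      "tgp_schema_error"
    )
  }
  invisible(df)
}
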