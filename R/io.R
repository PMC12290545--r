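timeline_cols <- function() {
  readr::cols(
    subject_id = readr::col_character(),
    condition = readr::col_character(),
    session_order = readr::col_integer(),
    probe_order = readr::col_integer(),
    actual_position = readr::col_integer(),
    context_index = readr::col_integer(),
    within_context_position = readr::col_integer(),
    is_boundary = readr::col_logical(),
    rated_position = readr::col_integer(),
    response_time = readr::col_double()
  )
}

encoding_cols <- function() {
  readr::cols(
    subject_id = readr::col_character(),
    condition = readr::col_character(),
    session_order = readr::col_integer(),
    serial_position = readr::col_integer(),
    context_index = readr::col_integer(),
    within_context_position = readr::col_integer(),
    is_boundary = readr::col_logical(),
    image_id = readr::col_character(),
    frame_color_hex = readr::col_character(),
    rating = readr::col_integer(),
    response_time = readr::col_double()
  )
}

#' Read and write the package's CSV schemas
#'
#' Comma-separated, header row, UTF-8, `"."` decimal. `read_timeline_csv()`
#' and `read_encoding_csv()` enforce column types; extra columns are kept as
#' guessed.
#'
#' @param path File path.
#' @param x Tibble to write.
#' @return Readers return tibbles; writers return `x` invisibly.
#' @name timelinr_io
NULL

#' @rdname timelinr_io
#' @export
read_timeline_csv <- function(path) {
  readr::read_csv(path, col_types = timeline_cols(), show_col_types = FALSE)
}

#' @rdname timelinr_io
#' @export
write_timeline_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname timelinr_io
#' @export
read_encoding_csv <- function(path) {
  readr::read_csv(path, col_types = encoding_cols(), show_col_types = FALSE)
}

#' @rdname timelinr_io
#' @export
write_encoding_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname timelinr_io
#' @export
write_chance_csv <- function(x, path) {
  stopifnot(inherits(x, "chance_curves"))
  out <- as_tibble(x)
  out$method <- attr(x, "method")
  readr::write_csv(out, path)
  invisible(x)
}

#' @rdname timelinr_io
#' @export
read_chance_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
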