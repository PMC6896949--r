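#' Read a Bayesian-skyline point series
#'
#' Consumes the smoothed point output of a skyline reconstruction as a TSV
#' with columns `time` (years before present) and `ne` (effective population
#' size), optionally `lower` and `upper` bounds. Times must be strictly
#' monotone in one direction; `ne` must be positive everywhere.
#'
#' @param path TSV file.
#' @return A `skyline_tbl`: tibble of the points, ordered as read, with an
#'   `orientation` attribute (`"increasing"` or `"decreasing"` time).
#' @export
read_skyline <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path))
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double()
  ), progress = FALSE)
  skyline_tbl(tab)
}

#' @rdname read_skyline
#' @param points Data frame with columns `time` and `ne` (optional `lower`,
#'   `upper`).
#' @export
skyline_tbl <- function(points) {
  tab <- as_tibble(points)
  if (!all(c("time", "ne") %in% names(tab))) {
    abort("Skyline table needs columns `time` and `ne`.",
          class = "invmix_validation_error")
  }
  if (any(!is.finite(tab$ne)) || any(tab$ne <= 0)) {
    abort("Skyline Ne values must be positive.",
          class = "invmix_validation_error")
  }
  orientation <- "increasing"
  if (nrow(tab) > 1) {
    d <- diff(tab$time)
    if (all(d > 0)) {
      orientation <- "increasing"
    } else if (all(d < 0)) {
      orientation <- "decreasing"
    } else {
      abort("Skyline times must be strictly monotone.",
            class = "invmix_validation_error")
    }
  }
  structure(tab, orientation = orientation,
            class = c("skyline_tbl", class(tibble())))
}
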