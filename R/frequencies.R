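#' Allele counts and frequencies per unit
#'
#' Tallies allele calls per population (or per group) and locus. Missing
#' calls are excluded from the denominators; a unit x locus combination with
#' zero scored calls is flagged with a warning and absent from the table.
#'
#' @param x A [genotype_tbl()] (normally clone-filtered).
#' @param by `"population"` or `"group"` (requires a group mapping).
#' @return Tibble `unit`, `locus`, `allele`, `count`, `freq`; frequencies
#'   sum to 1 within each `unit` x `locus`.
#' @export
allele_frequencies <- function(x, by = c("population", "group")) {
  by <- match.arg(by)
  stopifnot(inherits(x, "genotype_tbl"))
  calls <- gt_calls(x, with_group = by == "group")
  calls$unit <- calls[[by]]
  if (by == "group" && anyNA(calls$unit)) {
    abort("Group tally requested but some populations have no group label.")
  }

  scored <- calls[!is.na(calls$allele), c("unit", "locus", "allele")]
  empty <- dplyr::anti_join(
    dplyr::distinct(calls, .data$unit, .data$locus),
    dplyr::distinct(scored, .data$unit, .data$locus),
    by = c("unit", "locus")
  )
  if (nrow(empty) > 0) {
    warn(paste0(
      "No scored calls (frequency undefined) for: ",
      paste(paste(empty$unit, empty$locus, sep = "/"), collapse = ", ")
    ))
  }
  scored |>
    dplyr::count(.data$unit, .data$locus, .data$allele, name = "count") |>
    dplyr::group_by(.data$unit, .data$locus) |>
    dplyr::mutate(freq = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
}

#' Private alleles
#'
#' Alleles present (count > 0) in a focal unit and absent from every
#' reference unit, computed on a shared allele-frequency table.
#'
#' @param freqs Output of [allele_frequencies()].
#' @param focal Character vector of focal unit names.
#' @param reference Character vector of reference unit names.
#' @return Tibble `unit`, `locus`, `allele` — one row per private allele per
#'   focal unit carrying it.
#' @export
private_alleles <- function(freqs, focal, reference) {
  freqs <- as_tibble(freqs)
  stopifnot(all(c("unit", "locus", "allele", "count") %in% names(freqs)))
  missing_units <- setdiff(c(focal, reference), unique(freqs$unit))
  if (length(missing_units) > 0) {
    abort(paste0("Unit(s) absent from the frequency table: ",
                 paste(missing_units, collapse = ", ")))
  }
  loci_by_unit <- freqs |>
    dplyr::distinct(.data$unit, .data$locus) |>
    dplyr::count(.data$unit)
  if (length(unique(loci_by_unit$n)) > 1) {
    abort("Units were tallied over different locus sets.",
          class = "invmix_validation_error")
  }
  ref_alleles <- freqs |>
    dplyr::filter(.data$unit %in% reference, .data$count > 0) |>
    dplyr::distinct(.data$locus, .data$allele)
  freqs |>
    dplyr::filter(.data$unit %in% focal, .data$count > 0) |>
    dplyr::anti_join(ref_alleles, by = c("locus", "allele")) |>
    dplyr::select("unit", "locus", "allele")
}
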