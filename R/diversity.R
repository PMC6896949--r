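#' Per-unit diversity indices
#'
#' Computes, per population or per group (pooled calls) and averaged over
#' loci:
#'
#' * `ae` — effective number of alleles, \eqn{1 / \sum p^2};
#' * `shannon_i` — Shannon's information index, \eqn{-\sum p \ln p};
#' * `ho` — observed heterozygosity: the fraction of scored individuals
#'   whose allele multiset at the locus holds at least two distinct alleles
#'   (a dosage-free definition valid at any ploidy);
#' * `he` — expected heterozygosity (gene diversity), \eqn{1 - \sum p^2};
#' * `fis` — fixation index \eqn{1 - H_o / H_e}, averaged over loci with
#'   \eqn{H_e > 0} (monomorphic loci leave it undefined and are excluded
#'   from its average, with a message);
#' * `n_private` — number of alleles found in this unit only (relative to
#'   all other units at the same level), with the alleles themselves in the
#'   `private` list-column.
#'
#' @param x A [genotype_tbl()], normally clone-filtered first.
#' @param by `"population"` or `"group"`.
#' @return A tibble with one row per unit: `unit`, `n` (individuals), `ae`,
#'   `shannon_i`, `ho`, `he`, `fis`, `n_private`, `private`.
#' @export
diversity_indices <- function(x, by = c("population", "group")) {
  by <- match.arg(by)
  stopifnot(inherits(x, "genotype_tbl"))
  freqs <- suppressWarnings(allele_frequencies(x, by = by))
  calls <- gt_calls(x, with_group = by == "group")
  calls$unit <- calls[[by]]

  per_locus <- freqs |>
    dplyr::group_by(.data$unit, .data$locus) |>
    dplyr::summarise(
      ae = 1 / sum(.data$freq^2),
      shannon_i = -sum(.data$freq * log(.data$freq)),
      he = 1 - sum(.data$freq^2),
      .groups = "drop"
    )
  ho_locus <- calls |>
    dplyr::filter(!is.na(.data$allele)) |>
    dplyr::group_by(.data$unit, .data$locus, .data$individual) |>
    dplyr::summarise(het = dplyr::n_distinct(.data$allele) >= 2,
                     .groups = "drop") |>
    dplyr::group_by(.data$unit, .data$locus) |>
    dplyr::summarise(ho = mean(.data$het), .groups = "drop")
  per_locus <- dplyr::left_join(per_locus, ho_locus, by = c("unit", "locus")) |>
    dplyr::mutate(fis = dplyr::if_else(.data$he > 0, 1 - .data$ho / .data$he,
                                       NA_real_))
  n_mono <- sum(per_locus$he == 0)
  if (n_mono > 0) {
    inform(sprintf(
      "%d monomorphic unit x locus combination(s): fixation index undefined there, excluded from its average.",
      n_mono
    ))
  }

  n_tbl <- calls |>
    dplyr::distinct(.data$unit, .data$individual) |>
    dplyr::count(.data$unit, name = "n")

  present <- freqs |>
    dplyr::filter(.data$count > 0) |>
    dplyr::distinct(.data$unit, .data$locus, .data$allele)
  priv <- purrr::map(unique(per_locus$unit), function(u) {
    other <- dplyr::distinct(present[present$unit != u, ],
                             .data$locus, .data$allele)
    dplyr::anti_join(present[present$unit == u, ], other,
                     by = c("locus", "allele"))
  })
  priv_tbl <- tibble(
    unit = unique(per_locus$unit),
    n_private = vapply(priv, nrow, integer(1)),
    private = priv
  )

  per_locus |>
    dplyr::group_by(.data$unit) |>
    dplyr::summarise(
      ae = mean(.data$ae),
      shannon_i = mean(.data$shannon_i),
      ho = mean(.data$ho),
      he = mean(.data$he),
      fis = if (all(is.na(.data$fis))) NA_real_ else
        mean(.data$fis, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::left_join(n_tbl, by = "unit") |>
    dplyr::left_join(priv_tbl, by = "unit") |>
    dplyr::select("unit", "n", "ae", "shannon_i", "ho", "he", "fis",
                  "n_private", "private")
}

#' Locus-averaged Shannon index of a set of calls
#'
#' The Shannon information index \eqn{-\sum p \ln p} of the allele
#' frequencies at each locus, averaged over loci. Used directly by the
#' rarefaction simulation.
#'
#' @param calls A tibble of scored calls with columns `locus`, `allele`
#'   (rows with `NA` allele are ignored), or a [genotype_tbl()].
#' @return A single number.
#' @export
shannon_index <- function(calls) {
  calls <- as_tibble(calls)
  calls <- calls[!is.na(calls$allele), c("locus", "allele")]
  if (nrow(calls) == 0) {
    return(NA_real_)
  }
  per_locus <- calls |>
    dplyr::count(.data$locus, .data$allele) |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(
      i = { p <- .data$n / sum(.data$n); -sum(p * log(p)) },
      .groups = "drop"
    )
  mean(per_locus$i)
}
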