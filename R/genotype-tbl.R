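#' Genotype tables
#'
#' `invmix` stores codominant (microsatellite) genotypes in a long tibble of
#' class `genotype_tbl`: one row per allele call, with columns `individual`,
#' `population`, `locus` and `allele` (a positive integer fragment size).
#' A cell that was scored but failed (missing data) is kept as a single row
#' with `allele = NA`. Allele dosage in polyploids is represented by repeated
#' rows, and a cell may hold at most `ploidy` calls. An optional
#' population-to-group mapping (e.g. `source`, `non-source`, `introduced`)
#' travels with the table as an attribute.
#'
#' @param calls A data frame with columns `individual`, `population`, `locus`
#'   and `allele` (integer; `NA` marks an unscored cell). Cells absent from
#'   `calls` are completed as missing.
#' @param ploidy Maximum number of allele calls per cell (default 6,
#'   hexaploid).
#' @param groups Optional population-to-group mapping: a data frame with
#'   columns `population` and `group`, or a named character vector
#'   (names = populations). Must cover every population present.
#' @return A `genotype_tbl`: the completed, validated long tibble with
#'   attributes `ploidy`, `groups`, `loci` and `individuals`.
#' @examples
#' calls <- tibble::tibble(
#'   individual = rep(c("i1", "i2"), each = 2),
#'   population = "P1",
#'   locus      = rep(c("L1", "L2"), 2),
#'   allele     = c(131L, 135L, 131L, 131L)
#' )
#' g <- genotype_tbl(calls, ploidy = 2)
#' gt_ploidy(g)
#' @export
genotype_tbl <- function(calls, ploidy = 6L, groups = NULL) {
  calls <- as_tibble(calls)
  needed <- c("individual", "population", "locus", "allele")
  missing_cols <- setdiff(needed, names(calls))
  if (length(missing_cols) > 0) {
    abort(paste0("`calls` lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  calls <- dplyr::mutate(
    calls,
    individual = as.character(.data$individual),
    population = as.character(.data$population),
    locus      = as.character(.data$locus),
    allele     = as.integer(.data$allele)
  )
  if (any(!is.na(calls$allele) & calls$allele <= 0L)) {
    abort("Allele labels must be positive integers (0 is reserved for missing).")
  }

  ploidy <- as.integer(assert_scalar_number(ploidy, "ploidy", lower = 1))
  ind_tbl <- dplyr::distinct(calls, .data$individual, .data$population)
  if (anyDuplicated(ind_tbl$individual)) {
    dup <- ind_tbl$individual[duplicated(ind_tbl$individual)]
    abort(paste0("Individual(s) assigned to more than one population: ",
                 paste(unique(dup), collapse = ", ")))
  }
  loci <- unique(calls$locus)
  individuals <- ind_tbl$individual

  # complete individual x locus grid; absent cells become missing rows
  scored <- dplyr::filter(calls, !is.na(.data$allele))
  cell_n <- dplyr::count(scored, .data$individual, .data$locus)
  if (any(cell_n$n > ploidy)) {
    bad <- cell_n[cell_n$n > ploidy, ]
    abort(sprintf(
      "Cell %s/%s holds %d allele calls; ploidy is %d.",
      bad$individual[1], bad$locus[1], bad$n[1], ploidy
    ))
  }
  grid <- tidyr::expand_grid(individual = individuals, locus = loci)
  filled <- dplyr::anti_join(grid, cell_n, by = c("individual", "locus"))
  if (nrow(filled) > 0) {
    filled <- dplyr::left_join(filled, ind_tbl, by = "individual")
    filled$allele <- NA_integer_
    calls <- dplyr::bind_rows(scored, filled[names(scored)])
  } else {
    calls <- scored
  }
  calls <- dplyr::arrange(
    calls,
    match(.data$individual, individuals),
    match(.data$locus, loci),
    .data$allele
  )

  groups <- normalise_groups(groups, unique(ind_tbl$population))
  new_genotype_tbl(calls, ploidy = ploidy, groups = groups,
                   loci = loci, individuals = individuals)
}

new_genotype_tbl <- function(calls, ploidy, groups, loci, individuals) {
  structure(
    calls,
    ploidy = ploidy,
    groups = groups,
    loci = loci,
    individuals = individuals,
    class = c("genotype_tbl", class(tibble()))
  )
}

normalise_groups <- function(groups, populations) {
  if (is.null(groups)) {
    return(tibble(population = populations, group = NA_character_))
  }
  if (is.character(groups) && !is.null(names(groups))) {
    groups <- tibble(population = names(groups), group = unname(groups))
  }
  groups <- as_tibble(groups)
  if (!all(c("population", "group") %in% names(groups))) {
    abort("`groups` needs columns `population` and `group`.")
  }
  groups <- dplyr::distinct(groups, .data$population, .data$group)
  if (anyDuplicated(groups$population)) {
    abort("Each population may belong to exactly one group.")
  }
  uncovered <- setdiff(populations, groups$population)
  if (length(uncovered) > 0) {
    abort(paste0("Population(s) missing from the group mapping: ",
                 paste(uncovered, collapse = ", ")))
  }
  groups[groups$population %in% populations, ]
}

#' @rdname genotype_tbl
#' @param x A `genotype_tbl`.
#' @export
gt_ploidy <- function(x) attr(x, "ploidy", exact = TRUE)

#' @rdname genotype_tbl
#' @export
gt_groups <- function(x) attr(x, "groups", exact = TRUE)

#' @rdname genotype_tbl
#' @export
gt_loci <- function(x) attr(x, "loci", exact = TRUE)

#' @rdname genotype_tbl
#' @export
gt_individuals <- function(x) attr(x, "individuals", exact = TRUE)

#' Attach or replace the population-to-group mapping
#'
#' @param x A `genotype_tbl`.
#' @param groups As in [genotype_tbl()].
#' @return `x` with the new mapping.
#' @export
set_groups <- function(x, groups) {
  stopifnot(inherits(x, "genotype_tbl"))
  attr(x, "groups") <- normalise_groups(groups, unique(x$population))
  x
}

# plain-tibble view with group column joined in
gt_calls <- function(x, with_group = FALSE) {
  out <- as_tibble(x)[c("individual", "population", "locus", "allele")]
  if (with_group) {
    out <- dplyr::left_join(out, gt_groups(x), by = "population")
  }
  out
}

# rebuild after a row subset that kept whole individuals
gt_subset_individuals <- function(x, keep) {
  calls <- as_tibble(x)
  calls <- calls[calls$individual %in% keep, ]
  new_genotype_tbl(
    calls,
    ploidy = gt_ploidy(x),
    groups = gt_groups(x),
    loci = gt_loci(x),
    individuals = intersect(gt_individuals(x), keep)
  )
}

#' @export
print.genotype_tbl <- function(x, ...) {
  n_ind <- length(gt_individuals(x))
  n_loc <- length(gt_loci(x))
  n_pop <- length(unique(x$population))
  cat(sprintf(
    "# Genotype table: %d individuals x %d loci, %d population(s), ploidy %d\n",
    n_ind, n_loc, n_pop, gt_ploidy(x)
  ))
  NextMethod()
}
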