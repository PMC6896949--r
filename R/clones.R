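#' Clonal filtering and clonal diversity
#'
#' Clonally spreading plants produce repeated multilocus genotypes; repeated
#' genotypes bias frequency-based statistics and are removed before any
#' diversity analysis. Within every population, one representative (the
#' first in input order) is retained per identical multilocus genotype.
#' Under missing data, two individuals are considered the same genotype iff
#' they share at least one scored locus and agree (as allele multisets) on
#' every locus scored in both; matching is greedy against the retained
#' representatives in input order, which makes the filter idempotent.
#'
#' Clonal diversity — the number of distinct genotypes divided by the sample
#' size — is computed on the *pre*-filter matrix, per population; the group
#' value is the mean of its member populations' values.
#'
#' @param x A [genotype_tbl()].
#' @return A `clone_filter` list: `genotypes` (filtered [genotype_tbl()]),
#'   `removed` (count), `populations` (tibble `population`, `group`, `n`,
#'   `n_genotypes`, `clonal_diversity`), `groups` (tibble `group`,
#'   `n`, `clonal_diversity` = mean over member populations).
#' @examples
#' g <- sample_population(
#'   tibble::tibble(locus = "L1", allele = c(101L, 103L), freq = c(.5, .5)),
#'   10, ploidy = 2, seed = 1
#' )
#' deduplicate_clones(g)$populations
#' @export
deduplicate_clones <- function(x) {
  stopifnot(inherits(x, "genotype_tbl"))
  calls <- gt_calls(x)
  if (nrow(calls) == 0) {
    warn("Empty genotype table; nothing to filter.")
  }

  # per-cell key: sorted allele string, NA when unscored
  cells <- calls |>
    dplyr::group_by(.data$individual, .data$population, .data$locus) |>
    dplyr::summarise(
      key = if (all(is.na(.data$allele))) NA_character_ else
        paste(sort(.data$allele), collapse = "/"),
      .groups = "drop"
    )
  loci <- gt_loci(x)
  ind_order <- gt_individuals(x)

  keep <- character(0)
  pop_rows <- list()
  for (p in unique(cells$population)) {
    sub <- cells[cells$population == p, ]
    inds <- ind_order[ind_order %in% unique(sub$individual)]
    if (length(inds) == 0) {
      warn(sprintf("Population %s is empty; excluded from the report.", p))
      next
    }
    # matrix of cell keys, individuals x loci
    km <- matrix(NA_character_, length(inds), length(loci),
                 dimnames = list(inds, loci))
    km[cbind(match(sub$individual, inds), match(sub$locus, loci))] <- sub$key
    reps <- integer(0)  # indices of retained representatives
    for (i in seq_along(inds)) {
      is_clone <- FALSE
      for (r in reps) {
        shared <- !is.na(km[i, ]) & !is.na(km[r, ])
        if (any(shared) && all(km[i, shared] == km[r, shared])) {
          is_clone <- TRUE
          break
        }
      }
      if (!is_clone) reps <- c(reps, i)
    }
    pop_rows[[p]] <- tibble(
      population = p,
      n = length(inds),
      n_genotypes = length(reps),
      clonal_diversity = length(reps) / length(inds),
      retained = list(inds[reps])
    )
  }
  pop_tbl <- dplyr::bind_rows(pop_rows) |>
    dplyr::left_join(gt_groups(x), by = "population") |>
    dplyr::select("population", "group", "n", "n_genotypes",
                  "clonal_diversity", "retained")
  grp_tbl <- pop_tbl |>
    dplyr::filter(!is.na(.data$group)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = sum(.data$n),
      clonal_diversity = mean(.data$clonal_diversity),
      .groups = "drop"
    )

  retained_ids <- unlist(pop_tbl$retained, use.names = FALSE)
  out <- gt_subset_individuals(x, retained_ids)
  structure(
    list(
      genotypes = out,
      removed = length(gt_individuals(x)) - length(retained_ids),
      populations = dplyr::select(pop_tbl, -"retained"),
      groups = grp_tbl
    ),
    class = "clone_filter"
  )
}

#' @export
print.clone_filter <- function(x, ...) {
  cat(sprintf("# Clone filter: removed %d of %d individuals\n",
              x$removed, x$removed + length(gt_individuals(x$genotypes))))
  print(x$populations, ...)
  invisible(x)
}

#' @export
tidy.clone_filter <- function(x, ...) {
  x$populations
}

#' @export
glance.clone_filter <- function(x, ...) {
  tibble(
    n = x$removed + length(gt_individuals(x$genotypes)),
    n_retained = length(gt_individuals(x$genotypes)),
    removed = x$removed,
    clonal_diversity = mean(x$populations$clonal_diversity)
  )
}
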