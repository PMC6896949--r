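#' Invasion scenario parameters
#'
#' Bundles the ground-truth parameters of a simulated introduction: mixture
#' proportions of the three sources, founding sample size, generations of
#' Wright–Fisher drift, final deme sizes, and the clonal fraction injected
#' into the sampled demes.
#'
#' @param a,b Genetic contributions of sources 1 and 2 (`a + b <= 1`; source
#'   3 contributes `1 - a - b`).
#' @param n_founders Founding sample size `N`; allele draws are allocated as
#'   `a * 2N`, `b * 2N` and `(1 - a - b) * 2N` under diploid counting (the
#'   convention of the contribution formulas), regardless of the ploidy of
#'   the genotypes later sampled.
#' @param n_generations Generations of frequency-level Wright–Fisher drift at
#'   size `2N` after founding (>= 0).
#' @param deme_sizes Integer vector of final invasive population sizes.
#' @param ploidy Ploidy of the sampled genotypes (default 6).
#' @param clonal_fraction Fraction of each deme replaced by clonal copies
#'   (in `[0, 1)`).
#' @param seed Optional integer seed.
#' @return An `invasion_scenario` list.
#' @export
invasion_scenario <- function(a, b, n_founders, n_generations = 0L,
                              deme_sizes = c(50L, 50L), ploidy = 6L,
                              clonal_fraction = 0, seed = NULL) {
  assert_scalar_number(a, "a", lower = 0, upper = 1)
  assert_scalar_number(b, "b", lower = 0, upper = 1)
  if (a + b > 1 + 1e-12) abort("`a + b` must not exceed 1.")
  assert_scalar_number(n_founders, "n_founders", lower = 1)
  assert_scalar_number(n_generations, "n_generations", lower = 0)
  assert_scalar_number(clonal_fraction, "clonal_fraction", lower = 0)
  if (clonal_fraction >= 1) abort("`clonal_fraction` must be < 1.")
  if (length(deme_sizes) < 1 || any(deme_sizes < 1)) {
    abort("`deme_sizes` must all be >= 1.")
  }
  structure(
    list(a = a, b = b, c = 1 - a - b,
         n_founders = as.integer(n_founders),
         n_generations = as.integer(n_generations),
         deme_sizes = as.integer(deme_sizes),
         ploidy = as.integer(ploidy),
         clonal_fraction = clonal_fraction,
         seed = seed),
    class = "invasion_scenario"
  )
}

#' Simulate an admixed invasion
#'
#' The founder allele pool at every locus is built from
#' `round(a * 2N)` draws from source 1, `round(b * 2N)` from source 2 and
#' the remainder to `2N` from source 3 (see [founder_composition()]).
#' Founder frequencies then drift `n_generations` generations by multinomial
#' Wright–Fisher resampling at size `2N` (one shared trajectory), after
#' which each invasive deme is sampled from the final frequencies and,
#' optionally, clonal copies are injected.
#'
#' @param model A three-source [simulate_sources()] model.
#' @param scenario An [invasion_scenario()].
#' @return An `invasion_sim` list: `genotypes` (a [genotype_tbl()] of the
#'   invasive demes, group `"introduced"`), and `truth` (every generating
#'   parameter plus founder and post-drift allele frequencies).
#' @export
simulate_invasion <- function(model, scenario) {
  stopifnot(inherits(model, "source_model"), inherits(scenario, "invasion_scenario"))
  if (length(model$sources) != 3) {
    abort("`simulate_invasion()` requires exactly three sources.")
  }
  local_seed(scenario$seed)

  comp <- founder_composition(scenario$a, scenario$b, scenario$n_founders)
  two_n <- sum(comp)
  src_split <- split(model$freqs, model$freqs$source)

  loci <- unique(model$freqs$locus)
  founder <- purrr::map_dfr(loci, function(l) {
    counts <- 0
    alleles <- NULL
    for (s in seq_along(model$sources)) {
      f <- src_split[[model$sources[s]]]
      f <- f[f$locus == l, ]
      alleles <- f$allele
      if (comp[s] > 0) {
        counts <- counts + as.numeric(rmultinom(1, comp[s], f$freq))
      }
    }
    tibble(locus = l, allele = alleles, freq = counts / two_n)
  })

  final <- founder
  if (scenario$n_generations > 0) {
    final <- final |>
      dplyr::group_by(.data$locus) |>
      dplyr::group_modify(function(f, key) {
        p <- f$freq
        for (g in seq_len(scenario$n_generations)) {
          p <- as.numeric(rmultinom(1, two_n, p)) / two_n
        }
        f$freq <- p
        f
      }) |>
      dplyr::ungroup()
  }

  demes <- purrr::imap(scenario$deme_sizes, function(sz, i) {
    pop <- sprintf("I%02d", i)
    g <- sample_population(final, sz, ploidy = scenario$ploidy,
                           population = pop)
    gt_calls(g)
  })
  g <- genotype_tbl(dplyr::bind_rows(demes), ploidy = scenario$ploidy)
  if (scenario$clonal_fraction > 0) {
    g <- inject_clones(g, scenario$clonal_fraction)
  }
  g <- set_groups(g, tibble(population = unique(g$population),
                            group = "introduced"))

  structure(
    list(
      genotypes = g,
      truth = list(
        a = scenario$a, b = scenario$b, c = scenario$c,
        n_founders = scenario$n_founders,
        composition = comp,
        founder_freqs = founder,
        final_freqs = final,
        scenario = scenario,
        model_f_st = model$f_st,
        model_seed = model$seed
      )
    ),
    class = "invasion_sim"
  )
}

#' Inject clonal copies into a genotype table
#'
#' Replaces a fraction of the individuals of each population with exact
#' copies of other (retained) individuals of the same population, emulating
#' clonal (rhizome) spread. With all-distinct input genotypes the expected
#' clonal diversity (genotypes / sample size) of the result is
#' `1 - clonal_fraction`.
#'
#' @param x A [genotype_tbl()].
#' @param clonal_fraction Fraction replaced, in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return A [genotype_tbl()] with the same individuals, sizes and groups.
#' @export
inject_clones <- function(x, clonal_fraction, seed = NULL) {
  stopifnot(inherits(x, "genotype_tbl"))
  assert_scalar_number(clonal_fraction, "clonal_fraction", lower = 0)
  if (clonal_fraction >= 1) abort("`clonal_fraction` must be < 1.")
  if (clonal_fraction == 0) {
    return(x)
  }
  local_seed(seed)

  calls <- gt_calls(x)
  ind_tbl <- dplyr::distinct(calls, .data$individual, .data$population)
  by_pop <- split(ind_tbl$individual, ind_tbl$population)
  cell_key <- c("locus", "allele")

  replacements <- purrr::imap(by_pop, function(inds, pop) {
    n <- length(inds)
    n_rep <- as.integer(round_half_up(clonal_fraction * n))
    if (n_rep == 0) return(NULL)
    if (n == 1) {
      warn(sprintf("Population %s has a single individual; skipped.", pop))
      return(NULL)
    }
    replaced <- sample(inds, n_rep)
    donors <- setdiff(inds, replaced)
    tibble(individual = replaced,
           donor = sample(donors, n_rep, replace = TRUE))
  })
  repl <- dplyr::bind_rows(replacements)
  if (nrow(repl) == 0) {
    return(x)
  }
  keep <- calls[!calls$individual %in% repl$individual, ]
  copied <- calls[calls$individual %in% repl$donor, ] |>
    dplyr::rename(donor = "individual") |>
    dplyr::inner_join(repl, by = "donor", relationship = "many-to-many") |>
    dplyr::select("individual", "population", "locus", "allele")
  out <- genotype_tbl(dplyr::bind_rows(keep, copied), ploidy = gt_ploidy(x))
  set_groups(out, gt_groups(x))
}
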