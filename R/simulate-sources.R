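#' Simulate diverged source populations
#'
#' Draws locus-wise allele frequencies for three (or more) source
#' populations around a common ancestral pool, following the
#' Balding–Nichols construction: the ancestral frequency vector of each
#' locus is uniform-Dirichlet, and each source's vector is Dirichlet with
#' mean the ancestral vector and concentration `(1 - f_st) / f_st`, so the
#' expected among-source differentiation is approximately `f_st`.
#'
#' @param n_loci Number of loci.
#' @param n_alleles Alleles per locus (>= 2). Allele labels are integers
#'   `101, 103, ...` mimicking fragment sizes.
#' @param f_st Divergence parameter in (0, 1).
#' @param seed Optional integer seed (scoped; the global RNG is untouched).
#' @param sources Source population labels (length defines the number of
#'   sources; default three).
#' @return A `source_model`: list with `freqs` (tibble `source`, `locus`,
#'   `allele`, `freq`), `ancestral` (tibble `locus`, `allele`, `freq`),
#'   and the generating parameters.
#' @export
simulate_sources <- function(n_loci, n_alleles, f_st, seed = NULL,
                             sources = c("S1", "S2", "S3")) {
  assert_scalar_number(n_loci, "n_loci", lower = 1)
  assert_scalar_number(n_alleles, "n_alleles", lower = 2)
  assert_scalar_number(f_st, "f_st")
  if (f_st <= 0 || f_st >= 1) {
    abort("`f_st` must lie strictly inside (0, 1).")
  }
  local_seed(seed)

  loci <- sprintf("L%02d", seq_len(n_loci))
  alleles <- as.integer(99 + 2 * seq_len(n_alleles))
  conc <- (1 - f_st) / f_st

  ancestral <- purrr::map_dfr(loci, function(l) {
    p <- as.numeric(rdirichlet(1, rep(1, n_alleles)))
    tibble(locus = l, allele = alleles, freq = p)
  })
  freqs <- purrr::map_dfr(sources, function(s) {
    purrr::map_dfr(loci, function(l) {
      anc <- ancestral$freq[ancestral$locus == l]
      p <- as.numeric(rdirichlet(1, pmax(anc, 1e-12) * conc))
      tibble(source = s, locus = l, allele = alleles, freq = p)
    })
  })

  structure(
    list(freqs = freqs, ancestral = ancestral,
         f_st = f_st, n_loci = n_loci, n_alleles = n_alleles,
         sources = sources, seed = seed),
    class = "source_model"
  )
}

#' @export
print.source_model <- function(x, ...) {
  cat(sprintf(
    "# Source model: %d sources x %d loci x %d alleles, divergence F = %g\n",
    length(x$sources), x$n_loci, x$n_alleles, x$f_st
  ))
  invisible(x)
}

#' Sample a genotype matrix from allele frequencies
#'
#' Each individual's cell at each locus is `ploidy` independent multinomial
#' draws from that locus's allele-frequency vector; the resulting allele
#' multiset (with dosage) is retained.
#'
#' @param freqs Tibble with columns `locus`, `allele`, `freq` (one
#'   population's frequencies; use [mixture_freqs()] or subset a
#'   `source_model$freqs` by source first).
#' @param n_individuals Number of individuals to draw (> 0).
#' @param ploidy Allele copies per cell.
#' @param seed Optional integer seed.
#' @param population Population code assigned to the draws.
#' @param prefix Individual ID prefix.
#' @return A [genotype_tbl()].
#' @export
sample_population <- function(freqs, n_individuals, ploidy = 6L, seed = NULL,
                              population = "P1", prefix = population) {
  assert_scalar_number(n_individuals, "n_individuals", lower = 1)
  n_individuals <- as.integer(n_individuals)
  ploidy <- as.integer(assert_scalar_number(ploidy, "ploidy", lower = 1))
  freqs <- as_tibble(freqs)
  stopifnot(all(c("locus", "allele", "freq") %in% names(freqs)))
  local_seed(seed)

  inds <- sprintf("%s_%04d", prefix, seq_len(n_individuals))
  calls <- purrr::map_dfr(split(freqs, freqs$locus), function(f) {
    counts <- rmultinom(n_individuals, ploidy, f$freq)  # alleles x individuals
    idx <- which(counts > 0, arr.ind = TRUE)
    tibble(
      individual = rep(inds[idx[, "col"]], counts[idx]),
      population = population,
      locus = f$locus[1],
      allele = rep(f$allele[idx[, "row"]], counts[idx])
    )
  })
  genotype_tbl(calls, ploidy = ploidy)
}

#' Mixture allele frequencies of three sources
#'
#' Returns the per-locus allele frequencies of the admixed pool
#' `a * f1 + b * f2 + (1 - a - b) * f3` over the union allele support.
#'
#' @param model A [simulate_sources()] model (exactly three sources).
#' @param a,b Contributions of the first and second source (`a + b <= 1`).
#' @return Tibble `locus`, `allele`, `freq`.
#' @export
mixture_freqs <- function(model, a, b) {
  stopifnot(inherits(model, "source_model"), length(model$sources) == 3)
  assert_scalar_number(a, "a", lower = 0, upper = 1)
  assert_scalar_number(b, "b", lower = 0, upper = 1)
  if (a + b > 1 + 1e-12) {
    abort("`a + b` must not exceed 1.")
  }
  w <- setNames(c(a, b, 1 - a - b), model$sources)
  model$freqs |>
    dplyr::mutate(w = w[.data$source]) |>
    dplyr::group_by(.data$locus, .data$allele) |>
    dplyr::summarise(freq = sum(.data$freq * .data$w), .groups = "drop")
}
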