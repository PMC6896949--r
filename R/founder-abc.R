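#' Founder allele-draw composition
#'
#' Allocates the `2N` founding allele draws (diploid counting, the
#' convention of the contribution formulas) among the three sources:
#' `k1 = round(a * 2N)`, `k2 = round(b * 2N)` (half away from zero) and
#' `k3 = 2N - k1 - k2`. If rounding drives `k3` negative the largest
#' rounded component is decremented (deterministically) until the total is
#' restored.
#'
#' @param a,b Contributions of sources 1 and 2.
#' @param n_founders Founder sample size `N` (>= 1).
#' @return Integer vector `c(k1, k2, k3)` summing exactly to `2N`.
#' @examples
#' founder_composition(0.22, 0.76, 61)  # 27 93 2
#' @export
founder_composition <- function(a, b, n_founders) {
  assert_scalar_number(a, "a", lower = 0, upper = 1)
  assert_scalar_number(b, "b", lower = 0, upper = 1)
  if (a + b > 1 + 1e-12) abort("`a + b` must not exceed 1.")
  assert_scalar_number(n_founders, "n_founders", lower = 1)
  two_n <- 2L * as.integer(n_founders)
  k1 <- as.integer(round_half_up(a * two_n))
  k2 <- as.integer(round_half_up(b * two_n))
  k3 <- two_n - k1 - k2
  while (k3 < 0) {
    if (k1 >= k2) k1 <- k1 - 1L else k2 <- k2 - 1L
    k3 <- two_n - k1 - k2
  }
  c(k1, k2, k3)
}

#' Simulate one founder allele spectrum
#'
#' At each locus, draws `k_s` alleles from source `s`'s frequency vector
#' (`s = 1, 2, 3`) and returns the counts and presence of every allele in
#' the pooled founding sample.
#'
#' @param source_freqs Tibble `source`, `locus`, `allele`, `freq`, exactly
#'   three sources.
#' @param composition Integer vector `c(k1, k2, k3)` from
#'   [founder_composition()].
#' @param seed Optional integer seed.
#' @return Tibble `locus`, `allele`, `count`, `present`.
#' @export
simulate_founder_spectrum <- function(source_freqs, composition, seed = NULL) {
  prep <- prepare_spectrum(source_freqs)
  stopifnot(length(composition) == 3, all(composition >= 0))
  local_seed(seed)
  purrr::map_dfr(prep, function(loc) {
    counts <- numeric(nrow(loc$f))
    for (s in 1:3) {
      if (composition[s] > 0) {
        counts <- counts + as.numeric(rmultinom(1, composition[s], loc$f[, s]))
      }
    }
    tibble(locus = loc$locus, allele = loc$alleles,
           count = as.integer(counts), present = counts > 0)
  })
}

# per-locus list of aligned frequency matrices (alleles x 3 sources)
prepare_spectrum <- function(source_freqs) {
  source_freqs <- as_tibble(source_freqs)
  stopifnot(all(c("source", "locus", "allele", "freq") %in% names(source_freqs)))
  sources <- unique(source_freqs$source)
  if (length(sources) != 3) abort("Exactly three sources are required.")
  wide <- source_freqs |>
    dplyr::mutate(source = factor(.data$source, levels = sources)) |>
    tidyr::pivot_wider(id_cols = c("locus", "allele"),
                       names_from = "source", values_from = "freq",
                       values_fill = 0)
  lapply(split(wide, wide$locus), function(w) {
    list(locus = w$locus[1], alleles = w$allele,
         f = as.matrix(w[as.character(sources)]))
  })
}

#' Compare two allele spectra
#'
#' The accept/reject step of the founder scan: under the
#' `"exact-set"` criterion a simulation matches iff its per-locus allele
#' presence sets equal the observed ones at every locus; under
#' `"tolerant"` at most `k` presence mismatches (symmetric difference,
#' summed over loci) are allowed.
#'
#' @param simulated,observed Tibbles with columns `locus`, `allele`,
#'   `present` (or `count`).
#' @param criterion `"exact-set"` or `"tolerant"`.
#' @param k Mismatch budget for `"tolerant"`.
#' @return Logical scalar.
#' @export
is_match <- function(simulated, observed, criterion = c("exact-set", "tolerant"),
                     k = 0L) {
  criterion <- tryCatch(match.arg(criterion),
                        error = function(e) abort(paste0(
                          "Unknown match criterion: ",
                          paste(criterion, collapse = "/"))))
  sim <- spectrum_presence(simulated)
  obs <- spectrum_presence(observed)
  merged <- dplyr::full_join(sim, obs, by = c("locus", "allele"),
                             suffix = c("_sim", "_obs"))
  merged$present_sim[is.na(merged$present_sim)] <- FALSE
  merged$present_obs[is.na(merged$present_obs)] <- FALSE
  mismatches <- sum(merged$present_sim != merged$present_obs)
  if (criterion == "exact-set") mismatches == 0 else mismatches <= k
}

spectrum_presence <- function(x) {
  x <- as_tibble(x)
  if (!"present" %in% names(x)) {
    stopifnot("count" %in% names(x))
    x$present <- x$count > 0
  }
  x[x$present, c("locus", "allele", "present")]
}

#' ABC scan over the founder sample size
#'
#' For each candidate founder size `N`, simulates `n_reps` founding samples
#' (allele draws allocated by [founder_composition()] with the supplied
#' contributions), scores each against the observed invasive allele
#' spectrum, and reports the matching frequency. Too-small `N` tends to
#' miss observed alleles and too-large `N` imports source alleles absent
#' from the observed spectrum, so the matching-frequency curve is typically
#' bell-shaped; the optimum is the `N` with the highest matching frequency
#' (ties: smallest `N`).
#'
#' Observed alleles absent from all three sources can never be matched; they
#' are dropped with a message before scanning (set
#' `drop_unmatchable = FALSE` to keep them and accept zero matching).
#'
#' @inheritParams simulate_founder_spectrum
#' @param observed Observed spectrum: tibble `locus`, `allele` with
#'   `present` or `count` (e.g. pooled invasive [allele_frequencies()]).
#' @param a,b Source contributions (typically the
#'   [estimate_contributions()] estimates).
#' @param n_grid Ascending integer vector of candidate `N`.
#' @param n_reps Replicates per `N` (default 1e5).
#' @param criterion,k Match criterion, as in [is_match()].
#' @param seed Optional integer seed.
#' @return An `abc_scan` object: `grid` (tibble `n_founders`,
#'   `matching_frequency`, `n_reps`), `optimal_n`, `no_signal` flag,
#'   `criterion`, `seed`.
#' @export
abc_scan <- function(source_freqs, observed, a, b, n_grid,
                     n_reps = 1e5, criterion = c("exact-set", "tolerant"),
                     k = 0L, seed = NULL, drop_unmatchable = TRUE) {
  criterion <- match.arg(criterion)
  if (length(n_grid) == 0 || is.unsorted(n_grid, strictly = TRUE)) {
    abort("`n_grid` must be a nonempty strictly ascending vector.")
  }
  assert_scalar_number(n_reps, "n_reps", lower = 1)
  n_reps <- as.integer(n_reps)
  prep <- prepare_spectrum(source_freqs)
  obs <- spectrum_presence(observed)

  # observed alleles with zero frequency in every source are unreachable
  source_support <- purrr::map_dfr(prep, function(loc) {
    tibble(locus = loc$locus, allele = loc$alleles)[rowSums(loc$f) > 0, ]
  })
  orphan <- dplyr::anti_join(obs, source_support, by = c("locus", "allele"))
  if (nrow(orphan) > 0 && drop_unmatchable) {
    inform(sprintf(
      "Dropping %d observed allele(s) absent from all sources before scanning.",
      nrow(orphan)
    ))
    obs <- dplyr::anti_join(obs, orphan, by = c("locus", "allele"))
  }

  # per-locus observed presence over the source support
  obs_presence <- lapply(prep, function(loc) {
    loc$alleles %in% obs$allele[obs$locus == loc$locus]
  })
  # observed alleles outside the source support (kept): never matchable
  unmatched_kept <- nrow(orphan) > 0 && !drop_unmatchable

  local_seed(seed)
  grid <- purrr::map_dfr(n_grid, function(nf) {
    comp <- founder_composition(a, b, nf)
    if (unmatched_kept) {
      return(tibble(n_founders = nf, matching_frequency = 0, n_reps = n_reps))
    }
    total_mismatch <- integer(n_reps)
    for (li in seq_along(prep)) {
      f <- prep[[li]]$f
      counts <- 0
      for (s in 1:3) {
        if (comp[s] > 0) {
          counts <- counts + rmultinom(n_reps, comp[s], f[, s])
        }
      }
      if (identical(counts, 0)) {
        presence <- matrix(FALSE, nrow(f), n_reps)
      } else {
        presence <- counts > 0
      }
      total_mismatch <- total_mismatch +
        colSums(presence != obs_presence[[li]])
    }
    ok <- if (criterion == "exact-set") total_mismatch == 0L
          else total_mismatch <= k
    tibble(n_founders = nf, matching_frequency = mean(ok), n_reps = n_reps)
  })

  no_signal <- all(grid$matching_frequency == 0)
  optimal_n <- if (no_signal) NA_integer_ else
    grid$n_founders[which.max(grid$matching_frequency)]
  if (no_signal) {
    warn("Zero matches at every N; consider a tolerant criterion or more reps.")
  }
  structure(
    list(grid = grid, optimal_n = optimal_n, no_signal = no_signal,
         criterion = if (criterion == "tolerant")
           sprintf("tolerant(%d)", as.integer(k)) else criterion,
         a = a, b = b, seed = seed),
    class = "abc_scan"
  )
}

#' @export
print.abc_scan <- function(x, ...) {
  cat(sprintf(
    "# ABC founder-size scan (%s, a = %g, b = %g)\n  optimal N = %s\n",
    x$criterion, x$a, x$b,
    if (x$no_signal) "undefined (no matches)" else x$optimal_n
  ))
  print(x$grid, ...)
  invisible(x)
}

#' @export
tidy.abc_scan <- function(x, ...) x$grid

#' @export
glance.abc_scan <- function(x, ...) {
  tibble(optimal_n = x$optimal_n,
         peak_matching_frequency =
           if (x$no_signal) 0 else max(x$grid$matching_frequency),
         criterion = x$criterion, no_signal = x$no_signal)
}

#' Exact matching probability by inclusion–exclusion
#'
#' For enumerable cases (few loci, few alleles) the probability that a
#' simulated founding sample's presence set equals the observed presence
#' set exactly is, per locus and by inclusion–exclusion over subsets
#' `T` of the observed set `S`,
#' \deqn{P = \sum_{T \subseteq S} (-1)^{|S| - |T|}
#'   \prod_s \Big(\sum_{j \in T} f_{sj}\Big)^{k_s},}
#' multiplied over loci (independent draws). Used as the independent check
#' of the Monte-Carlo scan.
#'
#' @inheritParams simulate_founder_spectrum
#' @param observed Observed spectrum (tibble with `locus`, `allele`,
#'   `present`/`count`).
#' @return Exact probability (scalar).
#' @export
exact_match_probability <- function(source_freqs, composition, observed) {
  prep <- prepare_spectrum(source_freqs)
  obs <- spectrum_presence(observed)
  p_total <- 1
  for (loc in prep) {
    s_idx <- which(loc$alleles %in% obs$allele[obs$locus == loc$locus])
    if (length(s_idx) > 20) {
      abort("Observed set too large for enumeration (> 20 alleles).")
    }
    # any observed allele with zero total source frequency is unreachable
    if (any(rowSums(loc$f[s_idx, , drop = FALSE]) == 0)) {
      return(0)
    }
    p_loc <- 0
    for (m in 0:(2^length(s_idx) - 1)) {
      t_idx <- s_idx[bitwAnd(m, 2^(seq_along(s_idx) - 1)) > 0]
      q <- colSums(loc$f[t_idx, , drop = FALSE])
      term <- prod(q^composition)
      p_loc <- p_loc + (-1)^(length(s_idx) - length(t_idx)) * term
    }
    p_total <- p_total * p_loc
  }
  p_total
}
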