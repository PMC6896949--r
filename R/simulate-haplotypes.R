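#' Simulate a chloroplast haplotype alignment
#'
#' Builds `H` haplotype sequences with a known star-shaped distance matrix:
#' haplotype 1 is a random reference sequence and haplotype `i` (i >= 2)
#' carries a single private substitution at position `i - 1`, so
#' `d(H1, Hi) = 1` and `d(Hi, Hj) = 2` for distinct `i, j >= 2`. Individuals
#' are then assigned haplotypes multinomially within each population and the
#' alignment is rebuilt through the same variable-site machinery as
#' [read_alignment()], so the generator also exercises the caller.
#'
#' @param pop_freqs Tibble with columns `population`, `haplotype` (integer
#'   1..H or labels `H1..`), `freq`; frequencies sum to 1 within each
#'   population.
#' @param n_individuals Named integer vector: sample size per population.
#' @param seq_length Alignment length (>= number of haplotypes - 1).
#' @param seed Optional integer seed.
#' @return A [haplo_alignment()] object.
#' @export
simulate_haplotypes <- function(pop_freqs, n_individuals, seq_length = 500L,
                                seed = NULL) {
  pop_freqs <- as_tibble(pop_freqs)
  stopifnot(all(c("population", "haplotype", "freq") %in% names(pop_freqs)))
  hap_idx <- pop_freqs$haplotype
  if (is.character(hap_idx)) {
    hap_idx <- as.integer(sub("^H", "", hap_idx))
  }
  pop_freqs$.hap <- as.integer(hap_idx)
  n_hap <- max(pop_freqs$.hap)
  if (n_hap < 1) abort("Need at least one haplotype.")
  if (seq_length < n_hap - 1) {
    abort(sprintf(
      "seq_length (%d) too short to place %d distinct haplotypes.",
      seq_length, n_hap
    ))
  }
  bad <- pop_freqs |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(s = sum(.data$freq), .groups = "drop") |>
    dplyr::filter(abs(.data$s - 1) > 1e-9)
  if (nrow(bad) > 0) {
    abort(paste0("Haplotype frequencies do not sum to 1 in: ",
                 paste(bad$population, collapse = ", ")))
  }
  local_seed(seed)

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, seq_length, replace = TRUE)
  hap_seqs <- vapply(seq_len(n_hap), function(h) {
    s <- ref
    if (h >= 2) {
      pos <- h - 1L
      s[pos] <- bases[(match(s[pos], bases)) %% 4 + 1]  # deterministic alternate
    }
    paste(s, collapse = "")
  }, character(1))

  pops <- unique(pop_freqs$population)
  n_individuals <- n_individuals[pops]
  if (anyNA(n_individuals)) {
    abort("`n_individuals` must be named and cover every population.")
  }
  seqs <- character(0)
  pop_of <- character(0)
  for (p in pops) {
    f <- pop_freqs[pop_freqs$population == p, ]
    probs <- numeric(n_hap)
    probs[f$.hap] <- f$freq
    draws <- sample.int(n_hap, n_individuals[[p]], replace = TRUE, prob = probs)
    ids <- sprintf("%s_%03d", p, seq_along(draws))
    seqs <- c(seqs, setNames(hap_seqs[draws], ids))
    pop_of <- c(pop_of, setNames(rep(p, length(ids)), ids))
  }
  haplo_alignment(seqs, pop_of)
}
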