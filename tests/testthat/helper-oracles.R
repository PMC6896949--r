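# independent brute-force log-likelihood: explicit double loop over loci and
# alleles, no matrix algebra shared with the implementation
oracle_loglik <- function(a, b, source_freqs, invasive_counts) {
  tot <- 0
  for (i in seq_len(nrow(invasive_counts))) {
    l <- invasive_counts$locus[i]; al <- invasive_counts$allele[i]
    n <- invasive_counts$count[i]
    if (n == 0) next
    f <- vapply(unique(source_freqs$source), function(s) {
      v <- source_freqs$freq[source_freqs$source == s &
                               source_freqs$locus == l &
                               source_freqs$allele == al]
      if (length(v) == 0) 0 else v
    }, numeric(1))
    f <- unname(f)
    mix <- a * f[1] + b * f[2] + (1 - a - b) * f[3]
    if (sum(f) == 0) next  # excluded allele
    tot <- tot + n * log(mix)
  }
  tot
}

random_admix_instance <- function(seed) {
  withr::local_seed(seed)
  n_loci <- sample(1:3, 1)
  sf <- purrr::map_dfr(seq_len(n_loci), function(k) {
    n_all <- sample(2:5, 1)
    w <- matrix(stats::rgamma(3 * n_all, 1), nrow = 3)
    tibble::tibble(
      source = rep(c("S1", "S2", "S3"), each = n_all),
      locus = sprintf("L%d", k),
      allele = rep(100L + seq_len(n_all), 3),
      freq = as.numeric(t(w / rowSums(w)))
    )
  })
  counts <- sf |>
    dplyr::distinct(locus, allele) |>
    dplyr::mutate(count = stats::rpois(dplyr::n(), 5))
  list(sf = sf, counts = counts)
}

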