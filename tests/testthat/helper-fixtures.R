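# shared fixture builders (everything generated in code; no stored data)

# small genotype table from a compact description:
#   list(ind = list(population, locus = c(alleles...), ...))
toy_genotypes <- function(spec, ploidy = 6L, groups = NULL) {
  rows <- purrr::imap_dfr(spec, function(cfg, ind) {
    loci <- setdiff(names(cfg), "population")
    purrr::map_dfr(loci, function(l) {
      a <- cfg[[l]]
      tibble::tibble(
        individual = ind, population = cfg$population,
        locus = l,
        allele = if (length(a) == 0) NA_integer_ else as.integer(a)
      )
    })
  })
  genotype_tbl(rows, ploidy = ploidy, groups = groups)
}

# random genotype table over given dimensions, all cells scored
random_genotypes <- function(n_ind = 12, n_loci = 3, n_alleles = 4,
                             n_pops = 2, ploidy = 4L, seed = 1) {
  withr::local_seed(seed)
  inds <- sprintf("i%03d", seq_len(n_ind))
  pops <- sprintf("P%d", rep_len(seq_len(n_pops), n_ind))
  loci <- sprintf("L%d", seq_len(n_loci))
  alleles <- 100L + 2L * seq_len(n_alleles)
  calls <- purrr::map_dfr(seq_len(n_ind), function(i) {
    purrr::map_dfr(loci, function(l) {
      tibble::tibble(
        individual = inds[i], population = pops[i], locus = l,
        allele = sample(alleles, ploidy, replace = TRUE)
      )
    })
  })
  genotype_tbl(calls, ploidy = ploidy)
}

# three-source frequency table with fixed small support
toy_source_freqs <- function(f1, f2, f3, locus = "L1",
                             sources = c("S1", "S2", "S3")) {
  alleles <- 100L + seq_along(f1)
  tibble::tibble(
    source = rep(sources, each = length(f1)),
    locus = locus,
    allele = rep(alleles, 3),
    freq = c(f1, f2, f3)
  )
}

toy_counts <- function(counts, locus = "L1") {
  tibble::tibble(locus = locus, allele = 100L + seq_along(counts),
                 count = as.integer(counts))
}

# write an alignment fixture as FASTA and return the path
write_fasta <- function(seqs, path = withr::local_tempfile(fileext = ".fa",
                                                           .local_envir = parent.frame())) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

# independent Shannon / diversity oracle: plain base-R loops over a calls df
oracle_locus_stats <- function(calls) {
  calls <- calls[!is.na(calls$allele), ]
  out <- list()
  for (l in unique(calls$locus)) {
    a <- calls$allele[calls$locus == l]
    p <- as.numeric(table(a)) / length(a)
    ho_ind <- tapply(calls$allele[calls$locus == l],
                     calls$individual[calls$locus == l],
                     function(x) length(unique(x)) >= 2)
    out[[l]] <- c(
      ae = 1 / sum(p^2),
      shannon_i = -sum(p * log(p)),
      he = 1 - sum(p^2),
      ho = mean(ho_ind)
    )
  }
  do.call(rbind, out)
}
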