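# independent Nei FST oracle on a frequency table: (HT - HS)/HT per locus,
# unweighted means over sources, averaged over loci
oracle_fst <- function(freqs) {
  per_locus <- vapply(split(freqs, freqs$locus), function(f) {
    p <- matrix(f$freq, nrow = length(unique(f$source)), byrow = TRUE)
    hs <- mean(1 - rowSums(p^2))
    ht <- 1 - sum(colMeans(p)^2)
    (ht - hs) / ht
  }, numeric(1))
  mean(per_locus)
}

test_that("source divergence matches the requested F on average", {
  fsts <- vapply(1:50, function(s) {
    m <- simulate_sources(20, 8, f_st = 0.2, seed = s)
    oracle_fst(m$freqs)
  }, numeric(1))
  expect_gt(mean(fsts), 0.1)
  expect_lt(mean(fsts), 0.3)
})

test_that("the F -> 0 limit collapses sources onto the ancestral pool", {
  m <- simulate_sources(5, 4, f_st = 1e-6, seed = 3)
  joined <- dplyr::left_join(
    m$freqs, m$ancestral, by = c("locus", "allele"), suffix = c("", "_anc")
  )
  expect_lt(max(abs(joined$freq - joined$freq_anc)), 1e-2)
})

test_that("source model generation is deterministic under a fixed seed", {
  m1 <- simulate_sources(6, 5, 0.15, seed = 11)
  m2 <- simulate_sources(6, 5, 0.15, seed = 11)
  expect_identical(m1$freqs, m2$freqs)
  expect_error(simulate_sources(5, 1, 0.2), "n_alleles")
  expect_error(simulate_sources(5, 4, 0), "f_st")
})

test_that("per-locus frequencies in generated tables sum to one", {
  m <- simulate_sources(10, 6, 0.3, seed = 9)
  sums <- m$freqs |>
    dplyr::group_by(source, locus) |>
    dplyr::summarise(s = sum(freq), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
  mf <- mixture_freqs(m, 0.3, 0.5)
  sums2 <- tapply(mf$freq, mf$locus, sum)
  expect_true(all(abs(sums2 - 1) < 1e-9))
})

test_that("sample_population reproduces the generating frequencies", {
  freqs <- tibble::tibble(locus = "L1", allele = c(101L, 103L, 105L),
                          freq = c(0.3, 0.5, 0.2))
  g <- sample_population(freqs, 10000, ploidy = 6, seed = 4)
  tab <- allele_frequencies(g)
  f_a <- tab$freq[tab$allele == 101L]
  # 60,000 draws: exact binomial 3-sigma half-width ~ 0.006
  expect_lt(abs(f_a - 0.3), 0.02)

  mono <- sample_population(tibble::tibble(locus = "L1", allele = 101L, freq = 1),
                            20, ploidy = 6, seed = 1)
  expect_true(all(mono$allele == 101L))

  hap <- sample_population(freqs, 50, ploidy = 1, seed = 2)
  per_cell <- dplyr::count(gt_calls(hap), individual, locus)
  expect_true(all(per_cell$n == 1))
  expect_error(sample_population(freqs, 0), "n_individuals")
})

test_that("a pure-source invasion carries no private alleles of other sources", {
  m <- simulate_sources(8, 5, 0.4, seed = 21)
  sim <- simulate_invasion(m, invasion_scenario(
    a = 1, b = 0, n_founders = 30, deme_sizes = c(40, 40), seed = 5
  ))
  # alleles in the invasive demes must have nonzero frequency in source 1
  inv <- allele_frequencies(sim$genotypes, by = "group")
  s1 <- m$freqs[m$freqs$source == "S1" & m$freqs$freq > 0, ]
  extra <- dplyr::anti_join(inv[inv$count > 0, ], s1, by = c("locus", "allele"))
  expect_equal(nrow(extra), 0L)
})

test_that("with no drift and huge demes, deme frequencies approach the founder pool", {
  m <- simulate_sources(5, 4, 0.2, seed = 31)
  sim <- simulate_invasion(m, invasion_scenario(
    a = 0.5, b = 0.3, n_founders = 200, n_generations = 0,
    deme_sizes = 3000, ploidy = 6, seed = 7
  ))
  inv <- allele_frequencies(sim$genotypes, by = "population")
  joined <- dplyr::left_join(sim$truth$founder_freqs, inv,
                             by = c("locus", "allele"))
  joined$freq.y[is.na(joined$freq.y)] <- 0
  # 18,000 draws per locus: multinomial SE < 0.004 per allele
  expect_lt(max(abs(joined$freq.x - joined$freq.y)), 0.02)
})

test_that("the truth record stores the canonical scenario exactly", {
  m <- simulate_sources(9, 6, 0.2, seed = 41)
  sc <- invasion_scenario(a = 0.22, b = 0.76, n_founders = 61,
                          deme_sizes = c(30, 30), seed = 13)
  sim <- simulate_invasion(m, sc)
  expect_equal(sim$truth$a, 0.22)
  expect_equal(sim$truth$b, 0.76)
  expect_equal(sim$truth$n_founders, 61L)
  expect_equal(sim$truth$composition, c(27L, 93L, 2L))
  # reproducible bit-exactly from the recorded seeds
  sim2 <- simulate_invasion(simulate_sources(9, 6, 0.2, seed = 41), sc)
  expect_identical(gt_calls(sim$genotypes), gt_calls(sim2$genotypes))
})

test_that("drift variance grows with generations and shrinks with size", {
  freq_after <- function(n_founders, n_gen, seed) {
    m <- simulate_sources(1, 2, 0.2, seed = 100)
    sim <- simulate_invasion(m, invasion_scenario(
      a = 1, b = 0, n_founders = n_founders, n_generations = n_gen,
      deme_sizes = 1, seed = seed
    ))
    sim$truth$final_freqs$freq[1]
  }
  reps <- 200
  v_small_long <- var(vapply(1:reps, function(s) freq_after(25, 10, s), numeric(1)))
  v_small_short <- var(vapply(1:reps, function(s) freq_after(25, 1, s), numeric(1)))
  v_big_long <- var(vapply(1:reps, function(s) freq_after(400, 10, s), numeric(1)))
  expect_gt(v_small_long, v_small_short)
  expect_gt(v_small_long, v_big_long)
})

test_that("inject_clones hits the requested clonal diversity", {
  g <- random_genotypes(n_ind = 60, n_loci = 8, n_alleles = 8,
                        n_pops = 1, ploidy = 6L, seed = 50)
  expect_identical(gt_calls(inject_clones(g, 0)), gt_calls(g))

  cd <- deduplicate_clones(inject_clones(g, 0.25, seed = 1))
  expect_equal(cd$populations$clonal_diversity, 1 - 15 / 60)

  expect_error(inject_clones(g, 1), "clonal_fraction")
  single <- toy_genotypes(list(i1 = list(population = "P1", L1 = c(1, 2))),
                          ploidy = 2)
  expect_warning(inject_clones(single, 0.5, seed = 1), "single")
})

test_that("simulated haplotype alignments have the declared star distances", {
  pf <- tidyr::expand_grid(population = c("P1", "P2"), haplotype = 1:4) |>
    dplyr::mutate(freq = 0.25)
  aln <- simulate_haplotypes(pf, c(P1 = 200, P2 = 200), seq_length = 60, seed = 8)
  expect_equal(nrow(aln$haplotypes), 4L)
  d <- aln$dist
  expect_true(all(d[upper.tri(d)] %in% c(1, 2)))
  # exactly 3 pairs at distance 1 (each mutant vs the reference haplotype)
  expect_equal(sum(d[upper.tri(d)] == 1), 3)

  one <- simulate_haplotypes(
    tibble::tibble(population = "P1", haplotype = 1, freq = 1),
    c(P1 = 5), seq_length = 10, seed = 1
  )
  expect_equal(nrow(one$haplotypes), 1L)
  expect_identical(haplotype_stats(one)$populations$hd, 0)

  expect_error(
    simulate_haplotypes(pf, c(P1 = 5, P2 = 5), seq_length = 2, seed = 1),
    "too short"
  )
  a1 <- simulate_haplotypes(pf, c(P1 = 10, P2 = 10), seq_length = 30, seed = 3)
  a2 <- simulate_haplotypes(pf, c(P1 = 10, P2 = 10), seq_length = 30, seed = 3)
  expect_identical(a1$individuals, a2$individuals)
})

test_that("two equifrequent haplotypes give Hd near n/(n-1)/2", {
  pf <- tibble::tibble(population = "P1", haplotype = c(1, 2), freq = 0.5)
  n <- 2000
  aln <- simulate_haplotypes(pf, c(P1 = n), seq_length = 20, seed = 17)
  hd <- haplotype_stats(aln)$populations$hd
  expect_lt(abs(hd - n / (n - 1) * 0.5), 0.03)
})
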