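test_that("clone filter counts genotypes and removes duplicates", {
  # 10 individuals, one duplicated genotype -> 9 genotypes, diversity 0.9
  base <- random_genotypes(n_ind = 9, n_loci = 4, n_alleles = 6,
                           n_pops = 1, ploidy = 4L, seed = 7)
  calls <- gt_calls(base)
  clone <- calls[calls$individual == "i001", ]
  clone$individual <- "i_clone"
  g <- genotype_tbl(dplyr::bind_rows(calls, clone), ploidy = 4)
  cf <- deduplicate_clones(g)
  expect_equal(cf$removed, 1L)
  expect_equal(cf$populations$clonal_diversity, 0.9)
  expect_equal(cf$populations$n_genotypes, 9L)
  # first-by-input-order representative retained
  expect_true("i001" %in% gt_individuals(cf$genotypes))
  expect_false("i_clone" %in% gt_individuals(cf$genotypes))
})

test_that("clone filter is the identity on all-distinct data and idempotent", {
  g <- random_genotypes(n_ind = 20, n_loci = 5, n_alleles = 8,
                        n_pops = 2, ploidy = 6L, seed = 8)
  cf <- deduplicate_clones(g)
  expect_equal(cf$removed, 0L)
  expect_true(all(cf$populations$clonal_diversity == 1))
  cf2 <- deduplicate_clones(cf$genotypes)
  expect_equal(cf2$removed, 0L)
  expect_identical(gt_calls(cf2$genotypes), gt_calls(cf$genotypes))
})

test_that("missing-tolerant genotype identity compares shared scored loci", {
  g <- toy_genotypes(list(
    i1 = list(population = "P1", L1 = c(1, 2), L2 = c(3, 3)),
    i2 = list(population = "P1", L1 = c(1, 2), L2 = integer(0)),  # clone of i1
    i3 = list(population = "P1", L1 = c(1, 3), L2 = c(3, 3))      # distinct
  ), ploidy = 2)
  cf <- deduplicate_clones(g)
  expect_equal(cf$removed, 1L)
  expect_setequal(gt_individuals(cf$genotypes), c("i1", "i3"))
})

test_that("group clonal diversity averages its member populations", {
  g <- toy_genotypes(list(
    a1 = list(population = "P1", L1 = c(1, 1)),
    a2 = list(population = "P1", L1 = c(1, 1)),   # clone
    b1 = list(population = "P2", L1 = c(2, 2)),
    b2 = list(population = "P2", L1 = c(3, 3))
  ), ploidy = 2, groups = c(P1 = "native", P2 = "native"))
  cf <- deduplicate_clones(g)
  expect_equal(cf$groups$clonal_diversity, mean(c(0.5, 1)))
})

test_that("allele tallies match a brute-force count and groups add up", {
  g <- toy_genotypes(list(
    i1 = list(population = "P1", L1 = c(101, 101, 101, 103, 103, 103))
  ), ploidy = 6)
  f <- allele_frequencies(g)
  expect_equal(f$freq, c(0.5, 0.5))

  g2 <- random_genotypes(n_ind = 15, n_loci = 4, n_alleles = 5,
                         n_pops = 3, ploidy = 6L, seed = 12)
  g2 <- set_groups(g2, c(P1 = "A", P2 = "A", P3 = "B"))
  fp <- allele_frequencies(g2, by = "population")
  fg <- allele_frequencies(g2, by = "group")
  # group counts are the sums of member population counts
  manual <- fp |>
    dplyr::mutate(group = c(P1 = "A", P2 = "A", P3 = "B")[unit]) |>
    dplyr::group_by(unit = group, locus, allele) |>
    dplyr::summarise(count = sum(count), .groups = "drop")
  joined <- dplyr::full_join(manual, fg[c("unit", "locus", "allele", "count")],
                             by = c("unit", "locus", "allele"))
  expect_true(all(joined$count.x == joined$count.y))

  # independent tally oracle
  calls <- gt_calls(g2)
  for (k in seq_len(5)) {
    row <- fp[sample.int(nrow(fp), 1), ]
    n_direct <- sum(calls$population == row$unit & calls$locus == row$locus &
                      calls$allele == row$allele, na.rm = TRUE)
    expect_equal(row$count, n_direct)
  }
})

test_that("diversity indices match closed forms and a brute-force oracle", {
  # uniform 4-allele locus: Ae = 4, I = ln 4, He = 0.75
  g <- toy_genotypes(list(
    i1 = list(population = "P1", L1 = c(1, 2)),
    i2 = list(population = "P1", L1 = c(3, 4)),
    i3 = list(population = "P1", L1 = c(1, 2)),
    i4 = list(population = "P1", L1 = c(3, 4))
  ), ploidy = 2)
  d <- diversity_indices(g)
  expect_equal(d$ae, 4)
  expect_equal(d$shannon_i, log(4))
  expect_equal(d$he, 0.75)
  expect_equal(d$ho, 1)

  # two equifrequent alleles, all heterozygotes: He = .5, Ho = 1, F = -1
  g2 <- toy_genotypes(list(
    i1 = list(population = "P1", L1 = c(1, 2)),
    i2 = list(population = "P1", L1 = c(1, 2))
  ), ploidy = 2)
  d2 <- diversity_indices(g2)
  expect_equal(d2$he, 0.5)
  expect_equal(d2$ho, 1)
  expect_equal(d2$fis, -1)

  # random matrix against the independent per-locus oracle
  g3 <- random_genotypes(n_ind = 10, n_loci = 5, n_alleles = 6,
                         n_pops = 1, ploidy = 6L, seed = 33)
  d3 <- diversity_indices(g3)
  orc <- oracle_locus_stats(gt_calls(g3))
  expect_equal(d3$ae, mean(orc[, "ae"]), tolerance = 1e-12)
  expect_equal(d3$shannon_i, mean(orc[, "shannon_i"]), tolerance = 1e-12)
  expect_equal(d3$he, mean(orc[, "he"]), tolerance = 1e-12)
  expect_equal(d3$ho, mean(orc[, "ho"]), tolerance = 1e-12)
  fis_locus <- 1 - orc[, "ho"] / orc[, "he"]
  fis_locus <- fis_locus[orc[, "he"] > 0]
  expect_equal(d3$fis, mean(fis_locus), tolerance = 1e-12)
})

test_that("monomorphic loci drop out of the fixation-index average only", {
  g <- toy_genotypes(list(
    i1 = list(population = "P1", L1 = c(1, 1), L2 = c(1, 2)),
    i2 = list(population = "P1", L1 = c(1, 1), L2 = c(1, 1))
  ), ploidy = 2)
  expect_message(d <- diversity_indices(g), "monomorphic")
  # L1: He = 0 excluded from fis; L2: He = 0.375, Ho = 0.5
  expect_equal(d$fis, 1 - 0.5 / 0.375)
  expect_equal(d$he, mean(c(0, 0.375)))
})

test_that("statistics are invariant to individual order and allele relabeling", {
  g <- random_genotypes(n_ind = 12, n_loci = 4, n_alleles = 5,
                        n_pops = 2, ploidy = 6L, seed = 77)
  d <- diversity_indices(g)

  calls <- gt_calls(g)
  shuffled <- calls[order(rev(seq_len(nrow(calls)))), ]
  d_shuf <- diversity_indices(genotype_tbl(shuffled, ploidy = 6))
  expect_equal(d_shuf[order(d_shuf$unit), !(names(d_shuf) %in% "private")],
               d[order(d$unit), !(names(d) %in% "private")])

  relab <- calls
  relab$allele <- relab$allele * 7L + 1L  # bijective integer renaming
  d_rel <- diversity_indices(genotype_tbl(relab, ploidy = 6))
  cols <- c("ae", "shannon_i", "ho", "he", "fis", "n_private")
  expect_equal(d_rel[order(d_rel$unit), cols], d[order(d$unit), cols])
})

test_that("private alleles are detected per focal unit", {
  g <- toy_genotypes(list(
    i1 = list(population = "P1", L1 = c(1, 2)),
    i2 = list(population = "P2", L1 = c(1, 3)),
    i3 = list(population = "P3", L1 = c(1, 1))
  ), ploidy = 2)
  f <- allele_frequencies(g)
  pa <- private_alleles(f, focal = c("P1", "P2"), reference = "P3")
  expect_equal(nrow(pa), 2L)                      # alleles 2 and 3
  expect_setequal(pa$allele, c(2L, 3L))
  # allele 1 present everywhere: never private
  expect_false(1L %in% pa$allele)
  expect_error(private_alleles(f, "P1", "PX"), "absent")
})
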