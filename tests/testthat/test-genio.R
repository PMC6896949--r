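test_that("long-format TSV transcribes a toy matrix and round-trips", {
  g <- toy_genotypes(list(
    i1 = list(population = "P1", L1 = c(131, 133), L2 = c(140, 140)),
    i2 = list(population = "P1", L1 = c(131, 131), L2 = c(142, 144)),
    i3 = list(population = "P2", L1 = c(133, 135), L2 = integer(0))
  ), ploidy = 2)
  expect_length(gt_individuals(g), 3)
  expect_length(gt_loci(g), 2)
  expect_equal(sort(g$allele[g$individual == "i1" & g$locus == "L1"]),
               c(131L, 133L))
  # i3's unscored L2 cell survives as an explicit missing row
  expect_true(is.na(g$allele[g$individual == "i3" & g$locus == "L2"]))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, path)
  g2 <- read_genotypes(path, "long", ploidy = 2, quiet = TRUE)
  expect_equal(gt_calls(g2), gt_calls(g))
  expect_equal(gt_ploidy(g2), 2L)

  # and the file itself is stable under a second round trip (bit-exact)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("long-format read/write is the identity on random matrices", {
  for (seed in 1:5) {
    g <- random_genotypes(n_ind = 10, n_loci = 3, n_alleles = 5,
                          n_pops = 2, ploidy = 6L, seed = seed)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_genotypes(g, path)
    g2 <- read_genotypes(path, "long", ploidy = 6, quiet = TRUE)
    expect_equal(gt_calls(g2), gt_calls(g))
  }
})

test_that("empty matrix writes a header-only file", {
  g <- genotype_tbl(tibble::tibble(individual = character(),
                                   population = character(),
                                   locus = character(),
                                   allele = integer()), ploidy = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, path)
  expect_length(readLines(path), 1L)
})

test_that("a cell exceeding ploidy is refused", {
  calls <- tibble::tibble(
    individual = "i1", population = "P1", locus = "L1",
    allele = c(101L, 103L, 105L, 107L, 109L, 111L, 113L)
  )
  expect_error(genotype_tbl(calls, ploidy = 6), "ploidy")
})

test_that("genalex dialect parses and round-trips through the long dialect", {
  lines <- c(
    "2,3,2,2,1",
    "toy,,PA,PB",
    "Ind,Pop,SP02,,SP13,",
    "s1,PA,131,133,140,0",
    "s2,PA,131,131,142,144",
    "s3,PB,0,0,140,140"
  )
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, path)
  g <- read_genotypes(path, "genalex", ploidy = 2, quiet = TRUE)
  expect_equal(gt_loci(g), c("SP02", "SP13"))
  expect_length(gt_individuals(g), 3)
  # 0,0 cell is missing
  expect_true(is.na(g$allele[g$individual == "s3" & g$locus == "SP02"]))
  # single 0 pads a one-call cell
  expect_equal(g$allele[g$individual == "s1" & g$locus == "SP13" &
                          !is.na(g$allele)], 140L)

  out <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(g, out, "genalex")
  g2 <- read_genotypes(out, "genalex", ploidy = 2, quiet = TRUE)
  expect_equal(gt_calls(g2), gt_calls(g))
})

test_that("genalex structural errors are named", {
  bad_pop <- c("1,1,1,1", "t,,PA", "Ind,Pop,L1,", "s1,PX,1,2")
  p1 <- withr::local_tempfile(fileext = ".csv"); writeLines(bad_pop, p1)
  expect_error(read_genotypes(p1, "genalex", ploidy = 2, quiet = TRUE),
               class = "invmix_validation_error")

  bad_cols <- c("1,1,1,1", "t,,PA", "Ind,Pop,L1,,", "s1,PA,1,2,3")
  p2 <- withr::local_tempfile(fileext = ".csv"); writeLines(bad_cols, p2)
  expect_error(read_genotypes(p2, "genalex", ploidy = 2, quiet = TRUE),
               class = "invmix_format_error")

  p3 <- withr::local_tempfile(fileext = ".csv"); writeLines("only,one", p3)
  expect_error(read_genotypes(p3, "genalex", ploidy = 2, quiet = TRUE),
               class = "invmix_parse_error")
})

test_that("alignment reader detects haplotypes and variable sites", {
  # identical sequences: one haplotype, no variable sites
  a1 <- read_alignment(write_fasta(c(
    "a|P1" = "ACGTACGT", "b|P1" = "ACGTACGT",
    "c|P2" = "ACGTACGT", "d|P2" = "ACGTACGT"
  )))
  expect_equal(nrow(a1$haplotypes), 1L)
  expect_length(a1$variable_sites, 0L)

  # one SNP, two states: two haplotypes
  a2 <- read_alignment(write_fasta(c(
    "a|P1" = "ACGTACGT", "b|P1" = "ACGTACGT",
    "c|P2" = "ACCTACGT", "d|P2" = "ACCTACGT"
  )))
  expect_equal(nrow(a2$haplotypes), 2L)
  expect_equal(a2$variable_sites, 3L)
})

test_that("an indel run collapses to a single fifth-state polymorphism", {
  aln <- read_alignment(write_fasta(c(
    "a|P1" = "ACGTTTACGT",
    "b|P1" = "ACG---ACGT",
    "c|P2" = "ACG---ACGT"
  )))
  # 3 gap columns with one shared pattern -> one variable site
  expect_length(aln$variable_sites, 1L)
  expect_equal(nrow(aln$haplotypes), 2L)
  expect_equal(aln$alignment_length, 8L)  # 10 columns - 3 + 1 composite
  expect_equal(unname(aln$dist["H1", "H2"]), 1)
})

test_that("haplotype labels follow decreasing frequency with stable ties", {
  seqs <- c(x1 = "AAAA", x2 = "AATA", x3 = "AATA", x4 = "ACAA")
  aln <- haplo_alignment(seqs, c(x1 = "P1", x2 = "P1", x3 = "P1", x4 = "P2"))
  ind <- aln$individuals
  expect_equal(ind$haplotype[ind$individual == "x2"], "H1")  # n = 2
  expect_equal(ind$haplotype[ind$individual == "x1"], "H2")  # tie: first seen
  expect_equal(ind$haplotype[ind$individual == "x4"], "H3")
})

test_that("shuffling records preserves the haplotype partition", {
  withr::local_seed(42)
  base <- c("ACGTAC", "ACGTAC", "ACCTAC", "ACCTAT", "ACGTAT", "ACGTAC")
  names(base) <- sprintf("i%d", seq_along(base))
  pops <- setNames(rep(c("P1", "P2"), 3), names(base))
  a <- haplo_alignment(base, pops)
  for (k in 1:5) {
    ord <- sample(length(base))
    b <- haplo_alignment(base[ord], pops[ord])
    pa <- split(a$individuals$individual, a$individuals$haplotype)
    pb <- split(b$individuals$individual, b$individuals$haplotype)
    expect_setequal(
      unname(vapply(pa, function(v) paste(sort(v), collapse = ","), character(1))),
      unname(vapply(pb, function(v) paste(sort(v), collapse = ","), character(1)))
    )
    expect_lte(nrow(b$haplotypes), length(unique(base)))
    expect_lte(length(unique(base)), length(base))
  }
})

test_that("alignment error cases", {
  expect_error(read_alignment(write_fasta(c("a|P1" = "ACGT", "b|P1" = "ACG"))),
               class = "invmix_alignment_error")
  empty <- withr::local_tempfile(fileext = ".fa"); writeLines(character(0), empty)
  expect_error(read_alignment(empty), class = "invmix_alignment_error")
})

test_that("skyline reader validates and preserves order", {
  path <- withr::local_tempfile(fileext = ".tsv")
  n <- 100
  readr::write_tsv(tibble::tibble(time = seq(1000, 10, length.out = n),
                                  ne = exp(seq(2, 8, length.out = n))), path)
  sky <- read_skyline(path)
  expect_equal(nrow(sky), n)
  expect_equal(attr(sky, "orientation"), "decreasing")

  one <- skyline_tbl(tibble::tibble(time = 10, ne = 5))
  expect_equal(nrow(one), 1L)
  expect_error(fastest_growth_interval(one), "two")

  expect_error(skyline_tbl(tibble::tibble(time = c(2, 1), ne = c(1, 0))),
               class = "invmix_validation_error")
  expect_error(skyline_tbl(tibble::tibble(time = c(1, 3, 2), ne = c(1, 1, 1))),
               class = "invmix_validation_error")
})
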