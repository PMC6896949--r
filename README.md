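# invmix

Population-genetics inference for single-introduction invasions of clonal,
polyploid plants. Given codominant microsatellite genotypes (up to six
allele calls per locus in a hexaploid), chloroplast haplotype alignments,
and a Bayesian-skyline point series, `invmix` reconstructs the demographic
history of an invasion: how much of the sample is clonal duplication, how
diverse each population and group is, which native source populations
contributed how much genetic material, how many founding individuals could
have produced the invasive allele pool, and how fast the invasive range
expanded. A fully parameterised synthetic-data generator (three diverged
sources, admixed founders, Wright–Fisher drift, clonal copying, star-tree
haplotypes) makes every stage verifiable against known truth.

## The models at the core

**Clonal filtering.** Clonal diversity is the number of distinct multilocus
genotypes divided by sample size; repeated genotypes are removed (first
occurrence kept) before any frequency-based statistic.

**Diversity.** Per population/group, locus-averaged: effective alleles
*Ae* = 1/Σp², Shannon index *I* = −Σp ln p, expected heterozygosity
*He* = 1 − Σp², observed heterozygosity *Ho* = fraction of individuals with
≥ 2 distinct alleles at the locus (dosage-free, valid at any ploidy),
fixation index *F* = 1 − *Ho*/*He*, and private alleles. For haplotypes:
*Hd*, π, and Nei–Chesser corrected *H*<sub>S</sub>/*H*<sub>T</sub> with a
permutation test of *N*<sub>st</sub> > *G*<sub>st</sub> (distance-weighted
vs frequency-only differentiation) for phylogeographic structure.

**Three-source contributions.** With *f<sub>ij,s</sub>* the frequency of
allele *j* at locus *i* in source *s* and *n<sub>ij</sub>* the pooled
invasive allele counts,

  ln *P*(a, b) = Σ<sub>i</sub> Σ<sub>j</sub> *n<sub>ij</sub>* ln[*a·f<sub>ij,1</sub>* + *b·f<sub>ij,2</sub>* + (1 − *a* − *b*)·*f<sub>ij,3</sub>*]

is maximised by grid search over the simplex (step 0.01, deterministic
tie-breaks, one refinement pass), exploiting its concavity in (*a*, *b*).

**Founder sample size (ABC).** A founding sample of *N* individuals is
2*N* allele draws per locus, allocated round(*a*·2*N*) / round(*b*·2*N*) /
remainder across the sources. For each candidate *N*, the scan simulates
founding samples and scores how often the simulated per-locus allele
presence sets match the observed invasive spectrum exactly; the matching
frequency is bell-shaped in *N* and its mode is the estimate. An exact
inclusion–exclusion probability is available for enumerable cases.

**Growth.** *r* = ln(*N<sub>t</sub>*/*N*₀)/*t* per year, and a scan for the
fastest-growth window of a skyline series with *N*₀ the minimum effective
size immediately preceding growth.

## Worked example

A synthetic study at study-like scale — 9 loci, three sources diverged at
F = 0.2, contributions (0.22, 0.76, 0.02), 61 founders, 5 generations of
drift, 11 invasive demes of 40 with 15% clonal copies:

```r
library(invmix)
library(dplyr)

model <- simulate_sources(9, 8, f_st = 0.2, seed = 101,
                          sources = c("U-MC", "U-SI", "U-TB"))
sim <- simulate_invasion(model, invasion_scenario(
  a = 0.22, b = 0.76, n_founders = 61, n_generations = 5,
  deme_sizes = rep(40L, 11), clonal_fraction = 0.15, seed = 202))

cf <- deduplicate_clones(sim$genotypes)
glance(cf)
#> # A tibble: 1 × 4
#>       n n_retained removed clonal_diversity
#>   <int>      <int>   <int>            <dbl>
#> 1   440        374      66             0.85

counts <- allele_frequencies(cf$genotypes, "group") |>
  transmute(locus, allele, count)
fit <- estimate_contributions(model$freqs, counts)
fit
#> # Contribution estimate (grid step 0.01)
#>   U-MC: a = 0.203
#>   U-SI: b = 0.737
#>   U-TB: c = 0.060
#>   lnP = -26835.1330

founder_composition(fit$a, fit$b, 61)
#> [1] 25 90  7
```

The clone filter removed the 66 injected clonal copies exactly
(clonal diversity 0.85 = 1 − 0.15). The grid search recovers the
generating contributions up to the drift noise of a 61-founder bottleneck
(the realised contribution of a source varies binomially around its
nominal share). `founder_composition()` shows how the estimated
proportions translate into allele draws for the ABC scan; `abc_scan()`
then locates the founder sample size with the highest matching frequency,
and `autoplot()` methods plot the likelihood surface, the scan curve, the
rarefaction saturation and the skyline.

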