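#' Haplotype diversity statistics
#'
#' Per population: haplotype count `ha`, haplotype diversity
#' \eqn{Hd = n/(n-1) (1 - \sum p_k^2)} and nucleotide diversity \eqn{\pi} —
#' the mean number of differing variable sites between all pairs of sampled
#' sequences, divided by the (indel-collapsed) alignment length. Per group
#' (or over all populations when no grouping is supplied): the mean
#' within-population gene diversity `hs` and total gene diversity `ht`
#' following the Nei & Chesser small-sample-corrected estimators
#' \deqn{\hat H_S = \tilde n/(\tilde n - 1)\,(1 - \overline{\sum_k p_{ik}^2}),
#'       \qquad
#'       \hat H_T = 1 - \sum_k \bar p_k^2 + \hat H_S/(\tilde n s),}
#' with \eqn{\tilde n} the harmonic-mean sample size over the \eqn{s}
#' populations and \eqn{\bar p_k} the unweighted mean haplotype frequency.
#' Populations with a single individual have undefined `hd`/`pi` (reported
#' `NA`) and are excluded from `hs`/`ht`.
#'
#' @param aln A `haplo_aln` (from [read_alignment()], [haplo_alignment()],
#'   [haplo_table()] or [simulate_haplotypes()]).
#' @param grouping Optional population-to-group mapping (named character
#'   vector or tibble `population`, `group`). `NULL` treats all populations
#'   as one group `"all"`.
#' @return A `haplo_stats` list: `populations` (tibble `population`, `n`,
#'   `ha`, `hd`, `pi`) and `groups` (tibble `group`, `s`, `n`, `hs`, `ht`).
#' @export
haplotype_stats <- function(aln, grouping = NULL) {
  stopifnot(inherits(aln, "haplo_aln"))
  ind <- aln$individuals
  d <- aln$dist
  len <- aln$alignment_length

  pop_tbl <- ind |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(
      n = dplyr::n(),
      ha = dplyr::n_distinct(.data$haplotype),
      hd = hap_diversity(.data$haplotype),
      pi = nucleotide_diversity(.data$haplotype, d, len),
      .groups = "drop"
    )
  if (any(pop_tbl$n == 1)) {
    inform(paste0(
      "Population(s) with n = 1 (hd/pi undefined, excluded from hs/ht): ",
      paste(pop_tbl$population[pop_tbl$n == 1], collapse = ", ")
    ))
  }

  grouping <- normalise_grouping(grouping, unique(ind$population))
  ind <- dplyr::left_join(ind, grouping, by = "population")
  grp_tbl <- purrr::map_dfr(unique(grouping$group), function(g) {
    pops <- grouping$population[grouping$group == g]
    sub <- ind[ind$population %in% pops, ]
    hs_ht <- nei_hs_ht(sub, rownames(d), d, weighted = FALSE)
    tibble(group = g, s = hs_ht$s, n = nrow(sub),
           hs = hs_ht$hs, ht = hs_ht$ht)
  })

  structure(list(populations = pop_tbl, groups = grp_tbl),
            class = "haplo_stats")
}

normalise_grouping <- function(grouping, populations) {
  if (is.null(grouping)) {
    return(tibble(population = populations, group = "all"))
  }
  if (is.character(grouping) && !is.null(names(grouping))) {
    grouping <- tibble(population = names(grouping), group = unname(grouping))
  }
  grouping <- as_tibble(grouping)
  stopifnot(all(c("population", "group") %in% names(grouping)))
  grouping[grouping$population %in% populations, ]
}

hap_diversity <- function(haps) {
  n <- length(haps)
  if (n < 2) return(NA_real_)
  p <- as.numeric(table(haps)) / n
  n / (n - 1) * (1 - sum(p^2))
}

nucleotide_diversity <- function(haps, d, len) {
  n <- length(haps)
  if (n < 2) return(NA_real_)
  idx <- match(haps, rownames(d))
  tot <- 0
  for (i in seq_len(n - 1)) {
    tot <- tot + sum(d[idx[i], idx[(i + 1):n]])
  }
  tot / choose(n, 2) / len
}

# Nei & Chesser corrected HS/HT, and the distance-weighted analogues VS/VT
# used by Nst. With every off-diagonal distance equal the two collapse to
# the same value, which is the identity the permutation test relies on.
nei_hs_ht <- function(ind, hap_levels, d = NULL, weighted = FALSE) {
  counts <- table(factor(ind$population), factor(ind$haplotype, levels = hap_levels))
  counts <- counts[rowSums(counts) >= 2, , drop = FALSE]
  s <- nrow(counts)
  if (s == 0) {
    return(list(hs = NA_real_, ht = NA_real_, s = 0L))
  }
  ns <- rowSums(counts)
  p <- sweep(unclass(counts), 1, ns, "/")
  n_tilde <- 1 / mean(1 / ns)
  if (!weighted) {
    within <- 1 - rowSums(p^2)
    hs <- n_tilde / (n_tilde - 1) * mean(within)
    p_bar <- colMeans(p)
    ht <- 1 - sum(p_bar^2) + hs / (n_tilde * s)
  } else {
    within <- vapply(seq_len(s), function(i) {
      drop(p[i, , drop = FALSE] %*% d %*% t(p[i, , drop = FALSE]))
    }, numeric(1))
    hs <- n_tilde / (n_tilde - 1) * mean(within)
    p_bar <- colMeans(p)
    ht <- drop(t(p_bar) %*% d %*% p_bar) + hs / (n_tilde * s)
  }
  list(hs = hs, ht = ht, s = s)
}

#' @export
print.haplo_stats <- function(x, ...) {
  cat("# Haplotype statistics\n")
  print(x$populations, ...)
  print(x$groups, ...)
  invisible(x)
}

#' @export
tidy.haplo_stats <- function(x, ...) x$populations

#' @export
glance.haplo_stats <- function(x, ...) x$groups

#' Gst/Nst test for phylogeographic structure
#'
#' `Gst = (Ht - Hs)/Ht` measures differentiation on haplotype frequencies
#' alone; `Nst` is its analogue with gene diversities replaced by
#' distance-weighted diversities \eqn{\sum_{k,l} p_k p_l d_{kl}} (with the
#' same Nei–Chesser sample-size corrections), so it exceeds `Gst` when
#' closely related haplotypes co-occur within populations — the signature of
#' phylogeographic structure. Significance of `Nst > Gst` is assessed by
#' permuting the haplotype labels on the distance matrix `n_perm` times
#' (`Gst` is invariant under this permutation) and reporting the one-sided
#' add-one p-value \eqn{(b + 1)/(m + 1)}.
#'
#' @param aln A `haplo_aln`.
#' @param populations Optional subset of population codes to test (e.g. one
#'   group at a time). Default: all populations with n >= 2.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @return A `gst_nst` list: `gst`, `nst`, `p_value`, `n_perm`, `seed`,
#'   `degenerate` flag, plus `hs`, `ht`, `vs`, `vt`.
#' @export
gst_nst_test <- function(aln, populations = NULL, n_perm = 999L, seed = NULL) {
  stopifnot(inherits(aln, "haplo_aln"))
  assert_scalar_number(n_perm, "n_perm", lower = 1)
  ind <- aln$individuals
  if (!is.null(populations)) {
    ind <- ind[ind$population %in% populations, ]
  }
  pop_sizes <- table(ind$population)
  ind <- ind[ind$population %in% names(pop_sizes[pop_sizes >= 2]), ]
  if (dplyr::n_distinct(ind$population) < 2) {
    abort("Need at least two populations with n >= 2.")
  }
  if (dplyr::n_distinct(ind$haplotype) < 2) {
    abort("Need at least two haplotypes.")
  }
  local_seed(seed)

  hap_levels <- rownames(aln$dist)
  d <- aln$dist
  counts <- table(factor(ind$population),
                  factor(ind$haplotype, levels = hap_levels))
  counts <- unclass(counts)
  ns <- rowSums(counts)
  s <- nrow(counts)
  p_mat <- sweep(counts, 1, ns, "/")
  n_tilde <- 1 / mean(1 / ns)
  p_bar <- colMeans(p_mat)
  hs <- n_tilde / (n_tilde - 1) * mean(1 - rowSums(p_mat^2))
  ht <- 1 - sum(p_bar^2) + hs / (n_tilde * s)
  gst <- (ht - hs) / ht
  nst_of <- function(dd) {
    within <- rowSums((p_mat %*% dd) * p_mat)
    vs <- n_tilde / (n_tilde - 1) * mean(within)
    vt <- drop(t(p_bar) %*% dd %*% p_bar) + vs / (n_tilde * s)
    c(vs = vs, vt = vt, nst = (vt - vs) / vt)
  }
  v <- nst_of(d)
  nst <- v[["nst"]]

  off <- d[upper.tri(d)]
  degenerate <- length(unique(round(off, 12))) <= 1
  if (degenerate) {
    warn("All pairwise haplotype distances are equal: Nst == Gst, test degenerate.")
    p <- 1
  } else {
    obs <- nst - gst
    k <- nrow(d)
    perm_stats <- vapply(seq_len(n_perm), function(i) {
      perm <- sample.int(k)
      nst_of(d[perm, perm])[["nst"]] - gst
    }, numeric(1))
    p <- (sum(perm_stats >= obs - 1e-15) + 1) / (n_perm + 1)
  }

  structure(
    list(gst = gst, nst = nst, p_value = p,
         n_perm = as.integer(n_perm), seed = seed,
         degenerate = degenerate,
         hs = hs, ht = ht, vs = v[["vs"]], vt = v[["vt"]]),
    class = "gst_nst"
  )
}

#' @export
print.gst_nst <- function(x, ...) {
  cat(sprintf(
    "# Gst/Nst permutation test\n  Gst = %.4f, Nst = %.4f, p = %.4g (%d permutations)%s\n",
    x$gst, x$nst, x$p_value, x$n_perm,
    if (x$degenerate) " [degenerate: equal distances]" else ""
  ))
  invisible(x)
}

#' @export
tidy.gst_nst <- function(x, ...) {
  tibble(gst = x$gst, nst = x$nst, p_value = x$p_value, n_perm = x$n_perm)
}

#' @export
glance.gst_nst <- function(x, ...) {
  tibble(gst = x$gst, nst = x$nst, hs = x$hs, ht = x$ht,
         vs = x$vs, vt = x$vt, p_value = x$p_value,
         n_perm = x$n_perm, degenerate = x$degenerate)
}
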