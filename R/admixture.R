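#' Three-source admixture contribution likelihood
#'
#' The probability of the invasive allele counts under mixture proportions
#' `(a, b, 1 - a - b)` of three source populations is
#' \deqn{P = \prod_{i}\prod_{j}\left[a f_{ij,1} + b f_{ij,2} +
#'   (1 - a - b) f_{ij,3}\right]^{n_{ij}},}
#' where \eqn{f_{ij,s}} is the frequency of allele `j` at locus `i` in
#' source `s` and \eqn{n_{ij}} the count of that allele in the pooled
#' invasive group. `admix_loglik()` evaluates \eqn{\ln P} as the
#' corresponding sum. Alleles observed in the invasive group but absent
#' from all three sources would force \eqn{P = 0} identically; they are
#' excluded from the sum and reported (candidate post-introduction
#' mutations), unless a pseudo-frequency `epsilon > 0` is supplied.
#'
#' @param a,b Contributions of sources 1 and 2 (`a, b >= 0`, `a + b <= 1`).
#' @param source_freqs Tibble `source`, `locus`, `allele`, `freq` with
#'   exactly three sources (order of first appearance = source order), e.g.
#'   [allele_frequencies()] output renamed, or `source_model$freqs`.
#' @param invasive_counts Tibble `locus`, `allele`, `count`: allele counts
#'   pooled over the invasive group.
#' @param epsilon Optional pseudo-frequency substituted for the three zero
#'   source frequencies of otherwise-excluded alleles (default 0 = exclude).
#' @return `admix_loglik()`: the log-likelihood (scalar; `-Inf` if an
#'   included allele has zero mixture frequency at these weights), with the
#'   excluded alleles in attribute `"excluded"`.
#' @export
admix_loglik <- function(a, b, source_freqs, invasive_counts, epsilon = 0) {
  prep <- prepare_admix(source_freqs, invasive_counts, epsilon)
  assert_scalar_number(a, "a", lower = 0, upper = 1)
  assert_scalar_number(b, "b", lower = 0, upper = 1)
  if (a + b > 1 + 1e-12) {
    abort("`a + b` must not exceed 1.", class = "invmix_domain_error")
  }
  mix <- drop(prep$f %*% c(a, b, 1 - a - b))
  ll <- sum(prep$n * log(mix))
  if (!is.finite(ll)) {
    ll <- -Inf
    attr(ll, "zero_mixture") <- prep$key[mix <= 0 & prep$n > 0]
  }
  attr(ll, "excluded") <- prep$excluded
  ll
}

# Align the three sources and the invasive counts on the union allele
# support; returns F (alleles x 3), n, excluded tibble.
prepare_admix <- function(source_freqs, invasive_counts, epsilon = 0) {
  source_freqs <- as_tibble(source_freqs)
  invasive_counts <- as_tibble(invasive_counts)
  stopifnot(all(c("source", "locus", "allele", "freq") %in% names(source_freqs)),
            all(c("locus", "allele", "count") %in% names(invasive_counts)))
  sources <- unique(source_freqs$source)
  if (length(sources) != 3) {
    abort("Exactly three sources are required.")
  }
  wide <- source_freqs |>
    dplyr::mutate(source = factor(.data$source, levels = sources)) |>
    tidyr::pivot_wider(id_cols = c("locus", "allele"),
                       names_from = "source", values_from = "freq",
                       values_fill = 0)
  tab <- dplyr::full_join(
    wide,
    invasive_counts[invasive_counts$count > 0, ],
    by = c("locus", "allele")
  ) |>
    dplyr::mutate(dplyr::across(dplyr::everything(), ~ tidyr::replace_na(.x, 0)))
  f <- as.matrix(tab[sources])
  n <- tab$count
  orphan <- rowSums(f) == 0 & n > 0
  excluded <- tab[orphan, c("locus", "allele", "count")]
  if (epsilon > 0) {
    f[orphan, ] <- epsilon
    orphan[] <- FALSE
  }
  keep <- n > 0 & !orphan
  list(
    f = f[keep, , drop = FALSE],
    n = n[keep],
    key = paste(tab$locus, tab$allele, sep = ":")[keep],
    excluded = excluded,
    sources = sources
  )
}

#' Grid-search maximisation of the contribution likelihood
#'
#' Evaluates the log-likelihood on the simplex lattice
#' `{(a, b) : a, b in {0, step, ..., 1}, a + b <= 1}` (boundaries included)
#' and returns the maximiser, ties broken by smallest `a` then smallest `b`.
#' The objective is concave in `(a, b)` (a sum of logs of affine functions),
#' so one refinement pass at `step / 10` in a one-coarse-step window around
#' the coarse optimum (the default) locates the optimum to the fine
#' resolution.
#'
#' @inheritParams admix_loglik
#' @param step Lattice resolution in `(0, 0.5]` (default 0.01).
#' @param refine Refine once at `step / 10` around the coarse optimum.
#' @param keep_surface Retain the full `(a, b, lnP)` lattice for
#'   [likelihood_surface()] / `autoplot()`.
#' @return A `contribution_fit`: estimates `a`, `b`, `c`, `log_lik`, the
#'   source labels, `step`, excluded alleles, and optionally the surface.
#' @export
estimate_contributions <- function(source_freqs, invasive_counts, step = 0.01,
                                   refine = TRUE, keep_surface = TRUE,
                                   epsilon = 0) {
  assert_scalar_number(step, "step")
  if (step <= 0 || step > 0.5) {
    abort("`step` must lie in (0, 0.5].")
  }
  prep <- prepare_admix(source_freqs, invasive_counts, epsilon)
  if (length(prep$n) == 0) {
    abort("No usable alleles: every observed allele is absent from all sources.",
          class = "invmix_estimation_error")
  }

  coarse <- eval_lattice(prep, seq(0, 1, by = step))
  best <- lattice_argmax(coarse)
  if (all(!is.finite(coarse$lnp))) {
    abort(paste0(
      "Likelihood is -Inf on the whole lattice. Offending alleles: ",
      paste(prep$key, collapse = ", ")
    ), class = "invmix_estimation_error")
  }

  refined <- NULL
  if (refine) {
    fine_a <- seq(max(0, best$a - step), min(1, best$a + step), by = step / 10)
    fine_b <- seq(max(0, best$b - step), min(1, best$b + step), by = step / 10)
    refined <- eval_lattice(prep, a_vals = fine_a, b_vals = fine_b)
    best <- lattice_argmax(refined)
  }

  structure(
    list(
      a = best$a, b = best$b, c = 1 - best$a - best$b,
      log_lik = best$lnp,
      sources = prep$sources,
      step = step,
      refined = refine,
      excluded = prep$excluded,
      n_total = sum(prep$n),
      surface = if (keep_surface) coarse else NULL
    ),
    class = "contribution_fit"
  )
}

eval_lattice <- function(prep, a_vals, b_vals = a_vals) {
  grid <- tidyr::expand_grid(a = a_vals, b = b_vals)
  grid <- grid[grid$a + grid$b <= 1 + 1e-9, ]
  w <- rbind(grid$a, grid$b, pmax(1 - grid$a - grid$b, 0))
  mix <- prep$f %*% w                      # alleles x points
  lnp <- colSums(prep$n * log(mix))
  lnp[is.nan(lnp)] <- -Inf
  grid$lnp <- lnp
  grid
}

lattice_argmax <- function(grid) {
  m <- max(grid$lnp)
  top <- grid[grid$lnp >= m - 1e-12 * max(1, abs(m)), ]
  top <- top[order(top$a, top$b), ]
  list(a = top$a[1], b = top$b[1], lnp = top$lnp[1])
}

#' Likelihood surface of a contribution fit
#'
#' @param fit A [estimate_contributions()] result with `keep_surface = TRUE`.
#' @return Tibble `a`, `b`, `lnp` over the coarse lattice.
#' @export
likelihood_surface <- function(fit) {
  stopifnot(inherits(fit, "contribution_fit"))
  if (is.null(fit$surface)) {
    abort("Surface was not retained; rerun with `keep_surface = TRUE`.")
  }
  as_tibble(fit$surface)
}

#' @export
print.contribution_fit <- function(x, ...) {
  cat(sprintf(
    "# Contribution estimate (grid step %g)\n  %s: a = %.3f\n  %s: b = %.3f\n  %s: c = %.3f\n  lnP = %.4f\n",
    x$step, x$sources[1], x$a, x$sources[2], x$b, x$sources[3], x$c, x$log_lik
  ))
  if (nrow(x$excluded) > 0) {
    cat(sprintf(
      "  %d allele(s) absent from all sources excluded (candidate new mutations).\n",
      nrow(x$excluded)
    ))
  }
  invisible(x)
}

#' @export
tidy.contribution_fit <- function(x, ...) {
  tibble(
    source = x$sources,
    proportion = c(x$a, x$b, x$c)
  )
}

#' @export
glance.contribution_fit <- function(x, ...) {
  tibble(
    log_lik = x$log_lik, step = x$step, refined = x$refined,
    n_total = x$n_total, n_excluded = nrow(x$excluded)
  )
}
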