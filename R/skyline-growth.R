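#' Exponential growth rate
#'
#' The per-year growth rate of the exponential model,
#' \eqn{r = \ln(N_t / N_0) / t}, applied to two effective-size estimates
#' `t` years apart. Antisymmetric: swapping `n0` and `nt` flips the sign.
#'
#' @param n0 Initial effective size (> 0).
#' @param nt Final effective size (> 0).
#' @param t Elapsed years (> 0).
#' @return The growth rate per year (vectorised).
#' @examples
#' growth_rate(100, 200, 35)  # ln(2)/35 ~= 0.0198
#' @export
growth_rate <- function(n0, nt, t) {
  if (any(n0 <= 0) || any(nt <= 0) || any(t <= 0)) {
    abort("`n0`, `nt` and `t` must all be positive.",
          class = "invmix_domain_error")
  }
  log(nt / n0) / t
}

#' Fastest-growth interval of a skyline series
#'
#' Scans contiguous windows of the skyline (ordered oldest to most recent)
#' and returns the one maximising \eqn{r = \ln(N_t / N_0)/t}. Following the
#' convention that the initial size is the minimum effective size during
#' the period immediately preceding growth, the start of a window is taken
#' as whichever of the window's leading point and its immediate predecessor
#' has the smaller `ne` (ties prefer the leading point itself, keeping the
#' interval tight); the elapsed time runs from that start point to the
#' window's end. Ties in `r` go to the earliest window start and, from the
#' same start, the longest extent (the full fastest-growth segment).
#'
#' @param skyline A [skyline_tbl()] / [read_skyline()] series (>= 2 points).
#' @param window Optional window length in points; `NULL` (default) scans
#'   all contiguous windows of >= 2 points.
#' @return A `growth_estimate` tibble row: `r`, `n0`, `nt`, `t`,
#'   `start_time`, `end_time` (years before present).
#' @export
fastest_growth_interval <- function(skyline, window = NULL) {
  stopifnot(inherits(skyline, "skyline_tbl") ||
              all(c("time", "ne") %in% names(skyline)))
  tab <- as_tibble(skyline)[c("time", "ne")]
  if (nrow(tab) < 2) {
    abort("Need at least two skyline points.")
  }
  # chronological order: oldest (largest time before present) first
  tab <- tab[order(-tab$time), ]
  m <- nrow(tab)

  best <- NULL
  for (i in seq_len(m - 1)) {
    ends <- if (is.null(window)) (i + 1):m else {
      j <- i + window - 1L
      if (j > m) break
      j
    }
    for (j in ends) {
      # start candidates: leading point and its immediate predecessor
      cand <- if (i > 1) c(i, i - 1) else i
      s <- cand[which.min(tab$ne[cand])]     # tie -> leading point itself
      dt <- tab$time[s] - tab$time[j]
      if (dt <= 0) next
      r <- log(tab$ne[j] / tab$ne[s]) / dt
      tol <- 1e-12 * max(1, abs(r))
      if (is.null(best) || r > best$r + tol) {
        best <- list(r = r, s = s, i = i, j = j, dt = dt)
      } else if (r >= best$r - tol && i == best$i && j > best$j) {
        # tie at the same start: extend to the full fastest segment
        best <- list(r = r, s = s, i = i, j = j, dt = dt)
      }
    }
  }
  if (is.null(best)) {
    abort("No valid window (zero elapsed time everywhere).")
  }
  if (abs(best$r) < 1e-15) {
    warn("Series is flat: fastest growth rate is 0.")
  }
  structure(
    tibble(
      r = best$r,
      n0 = tab$ne[best$s],
      nt = tab$ne[best$j],
      t = best$dt,
      start_time = tab$time[best$s],
      end_time = tab$time[best$j]
    ),
    class = c("growth_estimate", class(tibble()))
  )
}
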