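#' Shannon-index rarefaction
#'
#' Draws individuals from a reference group without replacement along a
#' gradient of sample sizes (the study design: 2, 5, 25, 50, 100, 200, 400
#' with 10 replicates each), computes the locus-averaged Shannon index of
#' each draw, and expresses it as a proportion of the full reference
#' group's index. Sampling without replacement guarantees the proportion
#' reaches exactly 1 at the full sample size.
#'
#' @param x A [genotype_tbl()].
#' @param reference Populations forming the reference group: a group label
#'   (when a group mapping is attached) or a character vector of population
#'   codes.
#' @param sizes Sample-size gradient; sizes exceeding the group size are
#'   skipped with a warning.
#' @param reps Replicates per size (default 10).
#' @param seed Optional integer seed.
#' @param replace Sample with replacement instead (bootstrap variant;
#'   default `FALSE`).
#' @return A `saturation_tbl`: tibble `sample_size`, `replicate`,
#'   `i_sample`, `proportion_i`, with attributes `i_total` and `n_reference`.
#' @export
shannon_rarefaction <- function(x, reference, sizes = c(2, 5, 25, 50, 100, 200, 400),
                                reps = 10L, seed = NULL, replace = FALSE) {
  stopifnot(inherits(x, "genotype_tbl"))
  calls <- gt_calls(x, with_group = TRUE)
  pops <- if (all(reference %in% calls$group)) {
    unique(calls$population[calls$group %in% reference])
  } else {
    reference
  }
  sub <- calls[calls$population %in% pops & !is.na(calls$allele),
               c("individual", "locus", "allele")]
  inds <- unique(sub$individual)
  n_full <- length(inds)
  if (n_full == 0) {
    abort("Reference group contains no individuals.")
  }
  i_total <- shannon_index(sub)
  local_seed(seed)

  call_split <- split(sub[c("locus", "allele")], sub$individual)
  rows <- purrr::map_dfr(sizes, function(sz) {
    if (sz > n_full) {
      warn(sprintf("Size %d exceeds the reference group (%d); skipped.",
                   sz, n_full))
      return(NULL)
    }
    purrr::map_dfr(seq_len(reps), function(r) {
      picked <- sample(inds, sz, replace = replace)
      i_s <- shannon_index(dplyr::bind_rows(call_split[picked]))
      tibble(sample_size = as.integer(sz), replicate = r,
             i_sample = i_s, proportion_i = i_s / i_total)
    })
  })
  structure(rows, i_total = i_total, n_reference = n_full,
            class = c("saturation_tbl", class(tibble())))
}

#' Fit a saturation curve to rarefaction output
#'
#' Least-squares fit of the proportion-of-Shannon-index curve against
#' sample size. Two saturating one-parameter models are offered:
#' `"michaelis"` (the default), `proportion = x / (k + x)` with
#' half-saturation constant `k`, and `"exponential"`,
#' `proportion = 1 - exp(-lambda x)`. The replicates can be fit directly
#' (`average = "after"`, default) or averaged per size first
#' (`average = "before"`).
#'
#' @param table A [shannon_rarefaction()] result (or any tibble with
#'   `sample_size` and `proportion_i`).
#' @param model `"michaelis"` or `"exponential"`.
#' @param average `"after"` (fit raw replicates) or `"before"` (fit size
#'   means).
#' @return A `saturation_fit`: parameter estimate, residual sum of squares,
#'   the model id, and `size_at_95` — the sample size at which the fitted
#'   curve first reaches proportion 0.95 (closed form for both models).
#' @export
fit_saturation_curve <- function(table, model = c("michaelis", "exponential"),
                                 average = c("after", "before")) {
  model <- match.arg(model)
  average <- match.arg(average)
  tab <- as_tibble(table)[c("sample_size", "proportion_i")]
  if (average == "before") {
    tab <- tab |>
      dplyr::group_by(.data$sample_size) |>
      dplyr::summarise(proportion_i = mean(.data$proportion_i),
                       .groups = "drop")
  }
  if (dplyr::n_distinct(tab$sample_size) < 3) {
    abort("Need at least 3 distinct sample sizes to fit.")
  }
  if (stats::sd(tab$proportion_i) < 1e-12) {
    abort("Degenerate rarefaction table: proportions are constant.",
          class = "invmix_fit_error")
  }
  # scaleOffset makes the convergence test sound on zero-residual data
  ctrl <- stats::nls.control(maxiter = 200, scaleOffset = 1)
  fit <- switch(model,
    michaelis = nls(proportion_i ~ sample_size / (k + sample_size),
                    data = tab, control = ctrl,
                    start = list(k = stats::median(tab$sample_size))),
    exponential = nls(proportion_i ~ 1 - exp(-lambda * sample_size),
                      data = tab, control = ctrl,
                      start = list(lambda = 1 / mean(tab$sample_size)))
  )
  est <- coef(fit)[[1]]
  size95 <- switch(model,
    michaelis = 19 * est,         # 0.95 = x/(k+x)  =>  x = 19k
    exponential = -log(0.05) / est
  )
  structure(
    list(model = model, parameter = est,
         parameter_name = if (model == "michaelis") "k" else "lambda",
         rss = sum(resid(fit)^2), size_at_95 = size95,
         fit = fit, average = average),
    class = "saturation_fit"
  )
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf(
    "# Saturation fit (%s): %s = %.4g, RSS = %.4g, 95%% saturation at size %.1f\n",
    x$model, x$parameter_name, x$parameter, x$rss, x$size_at_95
  ))
  invisible(x)
}

#' @export
tidy.saturation_fit <- function(x, ...) {
  tibble(term = x$parameter_name, estimate = x$parameter)
}

#' @export
glance.saturation_fit <- function(x, ...) {
  tibble(model = x$model, rss = x$rss, size_at_95 = x$size_at_95,
         average = x$average)
}

#' Predicted saturation proportion
#'
#' @param object A `saturation_fit`.
#' @param newdata Optional tibble with `sample_size`.
#' @param ... Unused.
#' @export
predict.saturation_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    return(predict(object$fit))
  }
  x <- newdata$sample_size
  if (object$model == "michaelis") {
    x / (object$parameter + x)
  } else {
    1 - exp(-object$parameter * x)
  }
}
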