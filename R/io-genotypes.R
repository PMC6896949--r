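#' Read a codominant genotype matrix
#'
#' Two dialects are supported:
#'
#' * `"long"` — tab-separated, one row per individual x locus:
#'   `individual  population  locus  a1 ... a<ploidy>`, where each `a*` column
#'   holds an integer fragment size and `0` an unscored allele. A row of all
#'   zeros is a missing cell.
#' * `"genalex"` — the GenAlEx codominant CSV layout: row 1 holds
#'   `n_loci, n_individuals, n_populations, size_1, ..., size_k`; row 2 a
#'   title followed by a blank field and the population codes; row 3 the
#'   column header `Ind, Pop, <locus1>, <blank x (ploidy-1)>, <locus2>, ...`
#'   with `ploidy` allele columns per locus; data rows follow. `0` marks an
#'   unscored allele. Duplicated values within a cell represent dosage.
#'
#' @param path File to read.
#' @param dialect `"long"` or `"genalex"`.
#' @param ploidy Allele columns per locus (default 6).
#' @param groups Optional population-to-group mapping, as in [genotype_tbl()].
#' @param quiet Suppress the summary message.
#' @return A validated [genotype_tbl()].
#' @export
read_genotypes <- function(path, dialect = c("long", "genalex"), ploidy = 6L,
                           groups = NULL, quiet = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path))
  }
  ploidy <- as.integer(assert_scalar_number(ploidy, "ploidy", lower = 1))
  out <- switch(dialect,
    long = read_genotypes_long(path, ploidy),
    genalex = read_genotypes_genalex(path, ploidy)
  )
  g <- genotype_tbl(out, ploidy = ploidy, groups = groups)
  if (!quiet) {
    inform(sprintf(
      "Read %d individuals, %d loci, %d populations from %s (%s dialect).",
      length(gt_individuals(g)), length(gt_loci(g)),
      length(unique(g$population)), path, dialect
    ))
  }
  g
}

read_genotypes_long <- function(path, ploidy) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    individual = readr::col_character(),
    population = readr::col_character(),
    locus = readr::col_character(),
    .default = readr::col_integer()
  ), progress = FALSE)
  fixed <- c("individual", "population", "locus")
  if (!all(fixed %in% names(tab))) {
    abort(paste0("Malformed header in ", path,
                 ": expected columns individual, population, locus, a1..."),
          class = "invmix_parse_error")
  }
  acols <- setdiff(names(tab), fixed)
  if (length(acols) != ploidy) {
    abort(sprintf(
      "%s: %d allele columns found but ploidy is %d.",
      path, length(acols), ploidy
    ), class = "invmix_format_error")
  }
  long_rows_to_calls(tab, acols)
}

long_rows_to_calls <- function(tab, acols) {
  long <- tidyr::pivot_longer(tab, dplyr::all_of(acols),
                              names_to = NULL, values_to = "allele")
  long$allele[!is.na(long$allele) & long$allele == 0L] <- NA_integer_
  scored <- long[!is.na(long$allele), ]
  # genotype_tbl() completes fully-missing cells back to NA rows
  scored[c("individual", "population", "locus", "allele")]
}

read_genotypes_genalex <- function(path, ploidy) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) {
    abort(paste0(path, ": need at least 3 header lines (line ",
                 length(lines) + 1, " missing)."),
          class = "invmix_parse_error")
  }
  split_csv <- function(x) {
    # keep trailing empty fields (strsplit drops them)
    n_fields <- lengths(regmatches(x, gregexpr(",", x, fixed = TRUE))) + 1L
    f <- strsplit(x, ",", fixed = TRUE)[[1]]
    c(f, rep("", n_fields - length(f)))
  }
  l1 <- suppressWarnings(as.integer(split_csv(lines[1])))
  if (length(l1) < 3 || any(is.na(l1[1:3]))) {
    abort(paste0(path, ": malformed header at line 1 ",
                 "(expected n_loci,n_individuals,n_populations,sizes...)."),
          class = "invmix_parse_error")
  }
  n_loci <- l1[1]; n_pop <- l1[3]
  l2 <- split_csv(lines[2])
  pop_codes <- l2[-(1:2)]
  pop_codes <- pop_codes[pop_codes != ""]
  if (length(pop_codes) != n_pop) {
    abort(paste0(path, ": line 2 lists ", length(pop_codes),
                 " population codes, header says ", n_pop, "."),
          class = "invmix_parse_error")
  }
  header <- split_csv(lines[3])
  n_allele_cols <- length(header) - 2L
  if (n_allele_cols %% ploidy != 0L) {
    abort(sprintf(
      "%s: %d allele columns is not a multiple of ploidy %d.",
      path, n_allele_cols, ploidy
    ), class = "invmix_format_error")
  }
  if (n_allele_cols / ploidy != n_loci) {
    abort(sprintf(
      "%s: header declares %d loci but %d allele-column blocks found.",
      path, n_loci, n_allele_cols / ploidy
    ), class = "invmix_format_error")
  }
  loci <- header[2L + seq(1L, n_allele_cols, by = ploidy)]

  data_lines <- lines[-(1:3)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  rows <- lapply(seq_along(data_lines), function(i) {
    f <- split_csv(data_lines[i])
    if (length(f) != length(header)) {
      abort(sprintf("%s: line %d has %d fields, expected %d.",
                    path, i + 3L, length(f), length(header)),
            class = "invmix_parse_error")
    }
    f
  })
  mat <- do.call(rbind, rows)
  pops <- mat[, 2]
  unknown <- setdiff(unique(pops), pop_codes)
  if (length(unknown) > 0) {
    abort(paste0(path, ": unknown population code(s): ",
                 paste(unknown, collapse = ", ")),
          class = "invmix_validation_error")
  }
  alleles <- suppressWarnings(
    matrix(as.integer(mat[, -(1:2), drop = FALSE]), nrow = nrow(mat))
  )
  if (anyNA(alleles)) {
    abort(paste0(path, ": non-integer allele entry found."),
          class = "invmix_parse_error")
  }
  tab <- tibble(
    individual = mat[, 1],
    population = pops
  )
  wide <- as_tibble(as.data.frame(alleles))
  acols <- paste0("a", seq_len(ncol(wide)))
  names(wide) <- acols
  tab <- dplyr::bind_cols(tab, wide)
  # melt locus blocks
  out <- purrr::map_dfr(seq_along(loci), function(k) {
    block <- acols[(k - 1L) * ploidy + seq_len(ploidy)]
    sub <- tab[c("individual", "population", block)]
    sub$locus <- loci[k]
    names(sub)[3:(2 + ploidy)] <- paste0("a", seq_len(ploidy))
    sub
  })
  long_rows_to_calls(out[c("individual", "population", "locus",
                           paste0("a", seq_len(ploidy)))],
                     paste0("a", seq_len(ploidy)))
}

#' Write a genotype table
#'
#' The `"long"` dialect round-trips bit-exactly through [read_genotypes()]:
#' alleles are written in ascending order, right-padded with `0` to `ploidy`
#' columns, and a missing cell is a row of zeros.
#'
#' @param x A [genotype_tbl()].
#' @param path Output file.
#' @param dialect `"long"` (TSV) or `"genalex"` (CSV).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path, dialect = c("long", "genalex")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "genotype_tbl"))
  ploidy <- gt_ploidy(x)
  wide <- genotype_wide(x)

  if (dialect == "long") {
    readr::write_tsv(wide, path, progress = FALSE)
    return(invisible(path))
  }

  # genalex CSV
  loci <- gt_loci(x)
  inds <- gt_individuals(x)
  pops <- dplyr::distinct(gt_calls(x), .data$individual, .data$population)
  pop_order <- unique(pops$population)
  sizes <- table(factor(pops$population, levels = pop_order))
  l1 <- paste(c(length(loci), length(inds), length(pop_order),
                as.integer(sizes)), collapse = ",")
  l2 <- paste(c("invmix export", "", pop_order), collapse = ",")
  hdr <- c("Ind", "Pop",
           unlist(lapply(loci, function(l) c(l, rep("", ploidy - 1L)))))
  blocks <- lapply(loci, function(l) {
    sub <- wide[wide$locus == l, c("individual", paste0("a", seq_len(ploidy)))]
    sub[match(inds, sub$individual), -1, drop = FALSE]
  })
  body <- cbind(
    Ind = inds,
    Pop = pops$population[match(inds, pops$individual)],
    do.call(cbind, blocks)
  )
  lines <- c(l1, l2, paste(hdr, collapse = ","),
             apply(body, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

# wide view: individual population locus a1..a<ploidy>, alleles sorted, 0-padded
genotype_wide <- function(x) {
  ploidy <- gt_ploidy(x)
  calls <- gt_calls(x)
  if (nrow(calls) == 0) {
    empty <- c(list(individual = character(), population = character(),
                    locus = character()),
               setNames(rep(list(integer()), ploidy),
                        paste0("a", seq_len(ploidy))))
    return(as_tibble(empty))
  }
  wide <- calls |>
    dplyr::group_by(.data$individual, .data$population, .data$locus) |>
    dplyr::summarise(
      alleles = list(sort(.data$allele[!is.na(.data$allele)])),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      padded = purrr::map(.data$alleles, function(a) {
        if (length(a) > ploidy) {
          abort(sprintf("Cell holds %d calls at ploidy %d; refusing to write.",
                        length(a), ploidy))
        }
        c(a, rep(0L, ploidy - length(a)))
      })
    )
  amat <- do.call(rbind, wide$padded)
  colnames(amat) <- paste0("a", seq_len(ploidy))
  out <- dplyr::bind_cols(
    wide[c("individual", "population", "locus")],
    as_tibble(as.data.frame(amat))
  )
  dplyr::arrange(out,
                 match(.data$individual, gt_individuals(x)),
                 match(.data$locus, gt_loci(x)))
}
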