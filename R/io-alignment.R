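#' Haplotype alignments
#'
#' A `haplo_aln` holds an aligned set of (chloroplast) sequences with their
#' haplotype assignment. Variable sites are detected as columns with more
#' than one state after collapsing each insertion/deletion event (a maximal
#' run of adjacent columns sharing the same gap pattern) into a single
#' fifth-state column, so an indel of any length counts as one polymorphism.
#' Haplotypes are labelled `H1, H2, ...` in decreasing global frequency, ties
#' broken by first occurrence in the input. Two individuals share a label iff
#' their sequences are identical at every variable site.
#'
#' @param sequences Named character vector of aligned sequences (equal
#'   length; `-` for gaps). Names are individual IDs.
#' @param populations Population code per individual: named character vector
#'   or vector in `sequences` order.
#' @return A `haplo_aln` object: list with
#'   `individuals` (tibble: `individual`, `population`, `haplotype`),
#'   `haplotypes` (tibble: `haplotype`, `n`, `profile` over variable sites),
#'   `variable_sites` (1-based column positions, indel events at their first
#'   column), `dist` (haplotype-by-haplotype matrix of differing variable
#'   sites) and `alignment_length` (columns after indel collapsing).
#' @export
haplo_alignment <- function(sequences, populations) {
  if (length(sequences) == 0) {
    abort("Empty alignment.", class = "invmix_alignment_error")
  }
  if (is.null(names(sequences))) {
    abort("`sequences` must be named by individual.")
  }
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1) {
    abort("Ragged alignment: sequences differ in length.",
          class = "invmix_alignment_error")
  }
  if (!is.null(names(populations))) {
    populations <- populations[names(sequences)]
  }
  if (length(populations) != length(sequences)) {
    abort("`populations` must cover every sequence.")
  }

  mat <- do.call(rbind, strsplit(toupper(sequences), "", fixed = TRUE))
  collapsed <- collapse_indels(mat)
  smat <- collapsed$mat
  n_states <- apply(smat, 2, function(col) length(unique(col)))
  var_idx <- which(n_states > 1)

  if (length(var_idx) == 0) {
    profiles <- rep("", nrow(smat))
  } else {
    profiles <- apply(smat[, var_idx, drop = FALSE], 1, paste, collapse = "|")
  }
  # label by decreasing frequency, ties by first occurrence
  first_seen <- match(unique(profiles), profiles)
  freq <- table(profiles)[unique(profiles)]
  ord <- order(-as.integer(freq), first_seen)
  levels_sorted <- unique(profiles)[ord]
  hap_id <- paste0("H", match(profiles, levels_sorted))

  hap_tbl <- tibble(
    haplotype = paste0("H", seq_along(levels_sorted)),
    n = as.integer(table(factor(hap_id, levels = paste0("H", seq_along(levels_sorted))))),
    profile = levels_sorted
  )
  d <- haplotype_distances(levels_sorted)
  dimnames(d) <- list(hap_tbl$haplotype, hap_tbl$haplotype)

  structure(
    list(
      individuals = tibble(
        individual = names(sequences),
        population = as.character(populations),
        haplotype = hap_id
      ),
      haplotypes = hap_tbl,
      variable_sites = collapsed$positions[var_idx],
      dist = d,
      alignment_length = ncol(smat),
      raw_length = ncol(mat)
    ),
    class = "haplo_aln"
  )
}

# collapse runs of adjacent gap columns with identical gap pattern into one
# composite column; returns the reduced matrix and the original (1-based)
# position of each retained column
collapse_indels <- function(mat) {
  nc <- ncol(mat)
  gap <- mat == "-"
  has_gap <- which(colSums(gap) > 0)
  if (length(has_gap) == 0) {
    return(list(mat = mat, positions = seq_len(nc)))
  }
  pattern_id <- rep(NA_integer_, nc)
  pattern_id[has_gap] <- as.integer(factor(apply(
    gap[, has_gap, drop = FALSE], 2, paste, collapse = ""
  )))
  event <- integer(0)          # event id per column, 0 = not in an event
  event_id <- rep(0L, nc)
  cur <- 0L
  for (j in seq_len(nc)) {
    if (is.na(pattern_id[j]) || pattern_id[j] == 0L) next
    if (j > 1 && event_id[j - 1] > 0 &&
        identical(pattern_id[j], pattern_id[j - 1])) {
      event_id[j] <- event_id[j - 1]
    } else {
      cur <- cur + 1L
      event_id[j] <- cur
    }
  }
  keep_cols <- list()
  positions <- integer(0)
  j <- 1
  while (j <= nc) {
    if (event_id[j] == 0L) {
      keep_cols[[length(keep_cols) + 1L]] <- mat[, j]
      positions <- c(positions, j)
      j <- j + 1
    } else {
      run <- which(event_id == event_id[j])
      block <- mat[, run, drop = FALSE]
      state <- apply(block, 1, paste, collapse = "")
      # carriers of the deletion get the single fifth state "-"
      state[grepl("-", state, fixed = TRUE)] <- "-"
      keep_cols[[length(keep_cols) + 1L]] <- state
      positions <- c(positions, run[1])
      j <- max(run) + 1
    }
  }
  list(mat = do.call(cbind, keep_cols), positions = positions)
}

haplotype_distances <- function(profiles) {
  k <- length(profiles)
  d <- matrix(0, k, k)
  if (k < 2 || !nzchar(profiles[1])) {
    return(d)
  }
  split_profiles <- strsplit(profiles, "|", fixed = TRUE)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d[i, j] <- d[j, i] <- sum(split_profiles[[i]] != split_profiles[[j]])
    }
  }
  d
}

#' Read an aligned FASTA into a haplotype alignment
#'
#' Headers follow the convention `>individual|population` (a bare header
#' leaves the population `NA`; whitespace also works as separator).
#'
#' @param path FASTA file of equal-length aligned sequences.
#' @return A [haplo_alignment()] object.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    abort(paste0(path, ": empty FASTA."), class = "invmix_alignment_error")
  }
  seqs <- as.character(set)
  hdr <- names(set)
  parts <- strsplit(hdr, "[|[:space:]]+")
  ind <- vapply(parts, `[`, character(1), 1)
  pop <- vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_,
                character(1))
  names(seqs) <- ind
  haplo_alignment(seqs, setNames(pop, ind))
}

#' Build a haplotype alignment from a precomputed assignment table
#'
#' For data where haplotypes were called upstream, supply the per-individual
#' assignment plus the pairwise haplotype distance matrix (number of
#' differing variable sites) and the alignment length used for per-site
#' scaling.
#'
#' @param assignments Data frame with columns `individual`, `population`,
#'   `haplotype`.
#' @param dist Symmetric numeric matrix with dimnames equal to the haplotype
#'   labels.
#' @param alignment_length Total alignment columns (for nucleotide-diversity
#'   scaling).
#' @return A `haplo_aln` object.
#' @export
haplo_table <- function(assignments, dist, alignment_length) {
  assignments <- as_tibble(assignments)
  stopifnot(all(c("individual", "population", "haplotype") %in% names(assignments)))
  haps <- unique(assignments$haplotype)
  if (is.null(dimnames(dist)) || !all(haps %in% rownames(dist))) {
    abort("`dist` must carry dimnames covering every haplotype label.")
  }
  dist <- dist[haps, haps, drop = FALSE]
  if (!isTRUE(all.equal(dist, t(dist)))) {
    abort("`dist` must be symmetric.")
  }
  tab <- table(factor(assignments$haplotype, levels = haps))
  structure(
    list(
      individuals = assignments[c("individual", "population", "haplotype")],
      haplotypes = tibble(haplotype = haps, n = as.integer(tab),
                          profile = NA_character_),
      variable_sites = integer(0),
      dist = dist,
      alignment_length = alignment_length,
      raw_length = alignment_length
    ),
    class = "haplo_aln"
  )
}

#' @export
print.haplo_aln <- function(x, ...) {
  cat(sprintf(
    "# Haplotype alignment: %d individuals, %d haplotypes, %d variable site(s), length %d\n",
    nrow(x$individuals), nrow(x$haplotypes),
    length(x$variable_sites), x$alignment_length
  ))
  print(x$haplotypes, ...)
  invisible(x)
}

#' @export
tidy.haplo_aln <- function(x, ...) {
  x$individuals
}
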