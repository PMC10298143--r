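#' Assemble the alternative-allele-count and coverage matrices
#'
#' The two core outputs of the framework: a variants-by-cells matrix of
#' reads carrying each non-reference allele, and a positions-by-cells
#' matrix of read coverage. All three possible alternative alleles are
#' materialised (sparsely) for every position whose reference base is
#' A/C/G/T, so the row universe depends only on the reference and matrices
#' from different runs are always alignable. Positions with reference base
#' `N` have no alt rows but still appear in the coverage matrix.
#'
#' @param basecounts A `mito_basecounts` from [pileup_well()] or
#'   [pileup_droplet()].
#' @return A `mito_matrices` object: sparse `alt` (variants x cells) and
#'   `cov` (positions x cells) matrices, the `variants` row table, the
#'   `cells` table and reference metadata.
#' @export
build_matrices <- function(basecounts) {
  stopifnot(inherits(basecounts, "mito_basecounts"))
  ref <- basecounts$reference
  vars <- enumerate_variants(ref)
  cov <- Reduce(`+`, basecounts$counts)
  idx_by_base <- lapply(.base_letters, function(b) which(vars$alt == b))
  pieces <- lapply(seq_along(.base_letters), function(k) {
    basecounts$counts[[k]][vars$position[idx_by_base[[k]]], , drop = FALSE]
  })
  alt <- do.call(rbind, pieces)
  # restore position-then-alt row order
  alt <- alt[match(seq_len(nrow(vars)), unlist(idx_by_base)), , drop = FALSE]
  rownames(alt) <- vars$label
  structure(
    list(
      alt = alt, cov = cov, variants = vars,
      cells = basecounts$cells,
      reference = list(contig = ref$contig, length = ref$length),
      filters = basecounts$filters, mode = basecounts$mode
    ),
    class = "mito_matrices"
  )
}

#' @export
print.mito_matrices <- function(x, ...) {
  cat(
    "<mito_matrices> ", nrow(x$alt), " variants x ", ncol(x$alt),
    " cells (coverage: ", nrow(x$cov), " positions); contig ",
    x$reference$contig, "\n",
    sep = ""
  )
  invisible(x)
}

#' Compute per-cell alternative-allele frequencies
#'
#' AF(variant, cell) = alt count / coverage at the variant's position,
#' wherever coverage is at least `min_coverage`; entries with coverage
#' below the cutoff are *missing*, not zero. Missingness is carried as a
#' coverage matrix aligned to the variant rows, so downstream statistics
#' drop uncovered cells instead of fabricating reference-homoplasmy
#' evidence from dropout.
#'
#' @param matrices A `mito_matrices` from [build_matrices()].
#' @param min_coverage Minimum coverage for an AF value to be defined
#'   (default 1).
#' @return A `mito_af` object with sparse `af` values, the variant-row
#'   coverage `cov`, and the variant/cell tables.
#' @export
calc_allele_frequency <- function(matrices, min_coverage = 1L) {
  stopifnot(inherits(matrices, "mito_matrices"))
  if (min_coverage < 1L) abort("min_coverage must be >= 1")
  covv <- matrices$cov[matrices$variants$position, , drop = FALSE]
  rownames(covv) <- matrices$variants$label
  s <- Matrix::summary(matrices$alt)
  if (nrow(s) > 0L) {
    cv <- covv[cbind(s$i, s$j)]
    keep <- cv >= min_coverage
    af <- sparseMatrix(
      i = s$i[keep], j = s$j[keep], x = s$x[keep] / cv[keep],
      dims = dim(matrices$alt), dimnames = dimnames(matrices$alt)
    )
  } else {
    af <- sparseMatrix(
      i = integer(), j = integer(), x = double(),
      dims = dim(matrices$alt), dimnames = dimnames(matrices$alt)
    )
  }
  structure(
    list(
      af = af, cov = covv, variants = matrices$variants,
      cells = matrices$cells, min_coverage = as.integer(min_coverage),
      reference = matrices$reference
    ),
    class = "mito_af"
  )
}

#' @export
print.mito_af <- function(x, ...) {
  cat(
    "<mito_af> ", nrow(x$af), " variants x ", ncol(x$af),
    " cells; min_coverage = ", x$min_coverage, "; ",
    format(100 * Matrix::nnzero(x$cov >= x$min_coverage) / length(x$cov), digits = 3),
    "% entries observed\n",
    sep = ""
  )
  invisible(x)
}

#' Dense allele-frequency matrix with explicit missing values
#'
#' Converts the sparse AF representation to a dense numeric matrix with
#' `NA` wherever coverage is below the `min_coverage` used at
#' construction. Intended for modest variant subsets (plotting,
#' distances, classifiers), not the full row universe of a large run.
#'
#' @param af A `mito_af` object.
#' @param variants Optional character vector of variant labels (or a
#'   tibble with a `label` column) selecting rows.
#' @return A dense numeric matrix, variants x cells, with `NA` for
#'   missing entries.
#' @export
af_values <- function(af, variants = NULL) {
  stopifnot(inherits(af, "mito_af"))
  rows <- seq_len(nrow(af$af))
  if (!is.null(variants)) {
    if (is.data.frame(variants)) variants <- variants$label
    rows <- match(variants, af$variants$label)
    if (anyNA(rows)) {
      abort(paste0(
        "Unknown variant label(s): ",
        paste(head(variants[is.na(rows)], 5L), collapse = ", ")
      ))
    }
  }
  m <- as.matrix(af$af[rows, , drop = FALSE])
  m[as.matrix(af$cov[rows, , drop = FALSE]) < af$min_coverage] <- NA_real_
  m
}

#' Long-format view of allele counts and frequencies
#'
#' @param x A `mito_af` object.
#' @param ... Unused.
#' @return A tibble with one row per observed (variant, cell) entry:
#'   `label`, `position`, `ref`, `alt`, `cell_id`, `coverage`,
#'   `allele_frequency`. Entries with coverage below `min_coverage` are
#'   omitted (they are missing, not zero).
#' @method tidy mito_af
#' @export
tidy.mito_af <- function(x, ...) {
  s <- Matrix::summary(x$cov)
  keep <- s$x >= x$min_coverage
  i <- s$i[keep]
  j <- s$j[keep]
  tibble(
    label = x$variants$label[i],
    position = x$variants$position[i],
    ref = x$variants$ref[i],
    alt = x$variants$alt[i],
    cell_id = x$cells$cell_id[j],
    coverage = s$x[keep],
    allele_frequency = x$af[cbind(i, j)]
  )
}

.manifest_name <- "manifest.json"

#' Write matrices to a directory (MatrixMarket + TSV sidecars)
#'
#' Writes `alt.mtx` and `coverage.mtx` (sparse MatrixMarket), a
#' `variants.tsv` row table, a `cells.tsv` column table, and a
#' `manifest.json` recording the reference contig/length, the pileup
#' filters and the package version. The round trip through
#' [read_matrices()] is lossless, including row and column order.
#'
#' @param matrices A `mito_matrices` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_matrices <- function(matrices, dir) {
  stopifnot(inherits(matrices, "mito_matrices"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(matrices$alt, file.path(dir, "alt.mtx"))
  Matrix::writeMM(matrices$cov, file.path(dir, "coverage.mtx"))
  readr::write_tsv(matrices$variants, file.path(dir, "variants.tsv"))
  readr::write_tsv(matrices$cells, file.path(dir, "cells.tsv"))
  manifest <- list(
    format = "mitovar-matrices",
    version = as.character(packageVersion("mitovar")),
    contig = matrices$reference$contig,
    reference_length = matrices$reference$length,
    mode = matrices$mode,
    n_cells = ncol(matrices$alt),
    n_variants = nrow(matrices$alt),
    filters = list(
      min_base_quality = matrices$filters$min_base_quality,
      min_mapping_quality = matrices$filters$min_mapping_quality,
      exclude_flags = matrices$filters$exclude_flags,
      max_depth = if (is.finite(matrices$filters$max_depth)) {
        matrices$filters$max_depth
      } else {
        "unlimited"
      },
      dedup_overlaps = matrices$filters$dedup_overlaps
    )
  )
  jsonlite::write_json(manifest, file.path(dir, .manifest_name),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}

#' Read matrices written by [write_matrices()]
#'
#' @param dir Directory containing `alt.mtx`, `coverage.mtx`,
#'   `variants.tsv`, `cells.tsv` and `manifest.json`.
#' @param reference Optional `mito_reference`; when supplied, its contig
#'   length must match the manifest (guard against mixing references).
#' @return A `mito_matrices` object.
#' @export
read_matrices <- function(dir, reference = NULL) {
  needed <- c("alt.mtx", "coverage.mtx", "variants.tsv", "cells.tsv", .manifest_name)
  missing <- needed[!file.exists(file.path(dir, needed))]
  if (length(missing) > 0L) {
    abort(paste0(
      "Matrix directory ", dir, " is incomplete; missing: ",
      paste(missing, collapse = ", ")
    ))
  }
  manifest <- jsonlite::read_json(file.path(dir, .manifest_name))
  if (!identical(manifest$format, "mitovar-matrices")) {
    abort(paste0(dir, " does not look like a mitovar matrix directory."))
  }
  if (!is.null(reference) && reference$length != manifest$reference_length) {
    abort(paste0(
      "Reference length mismatch: manifest says ", manifest$reference_length,
      ", supplied reference has ", reference$length, "."
    ))
  }
  alt <- as(Matrix::readMM(file.path(dir, "alt.mtx")), "CsparseMatrix")
  cov <- as(Matrix::readMM(file.path(dir, "coverage.mtx")), "CsparseMatrix")
  variants <- readr::read_tsv(file.path(dir, "variants.tsv"),
    col_types = readr::cols(
      label = readr::col_character(), position = readr::col_integer(),
      ref = readr::col_character(), alt = readr::col_character()
    )
  )
  cells <- readr::read_tsv(file.path(dir, "cells.tsv"),
    col_types = readr::cols(cell_id = readr::col_character())
  )
  if (nrow(alt) != nrow(variants) || ncol(alt) != nrow(cells) ||
    ncol(cov) != nrow(cells) || nrow(cov) != manifest$reference_length) {
    abort(paste0("Shape mismatch between matrices, sidecars and manifest in ", dir))
  }
  dimnames(alt) <- list(variants$label, cells$cell_id)
  dimnames(cov) <- list(NULL, cells$cell_id)
  f <- manifest$filters
  filters <- pileup_filters(
    min_base_quality = f$min_base_quality,
    min_mapping_quality = f$min_mapping_quality,
    exclude_flags = unlist(f$exclude_flags),
    max_depth = if (identical(f$max_depth, "unlimited")) Inf else f$max_depth,
    dedup_overlaps = isTRUE(f$dedup_overlaps)
  )
  structure(
    list(
      alt = alt, cov = cov, variants = variants, cells = cells,
      reference = list(
        contig = manifest$contig,
        length = manifest$reference_length
      ),
      filters = filters, mode = manifest$mode
    ),
    class = "mito_matrices"
  )
}
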