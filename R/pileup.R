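.base_letters <- c("A", "C", "G", "T")

# Biostrings DNA byte codes -> base index 1..4 (A,C,G,T); everything else
# (N, IUPAC ambiguity, gap) is NA and never counted, in coverage or alt.
.code4 <- local({
  z <- rep(NA_integer_, 16L)
  z[c(1L, 2L, 4L, 8L)] <- 1:4
  z
})

#' Read and base filters applied during pileup
#'
#' @param min_base_quality Minimum Phred base quality for a base call to be
#'   counted (default 13, the samtools-family pileup default).
#' @param min_mapping_quality Minimum mapping quality for a read to be used
#'   (default 0). Reads whose mapping quality is unavailable (255) pass any
#'   threshold, as in samtools.
#' @param exclude_flags Which flagged alignments to drop. Subset of
#'   `"secondary"`, `"supplementary"`, `"duplicate"`, `"qc_fail"`,
#'   `"unmapped"`; unmapped reads are always excluded. Default: all five.
#' @param max_depth Per-position, per-cell cap on the number of reads
#'   contributing base calls (reads ordered by alignment start, then input
#'   order). Default `Inf` (unlimited).
#' @param dedup_overlaps If `TRUE`, when the two mates of a read pair
#'   overlap a position, only the base call with the higher quality is
#'   counted (ties: first mate encountered). Default `FALSE`: each passing
#'   read counts once, matching plain pileup semantics.
#' @return A `pileup_filters` object.
#' @export
pileup_filters <- function(min_base_quality = 13L,
                           min_mapping_quality = 0L,
                           exclude_flags = c(
                             "secondary", "supplementary",
                             "duplicate", "qc_fail", "unmapped"
                           ),
                           max_depth = Inf,
                           dedup_overlaps = FALSE) {
  known <- c("secondary", "supplementary", "duplicate", "qc_fail", "unmapped")
  if (length(bad <- setdiff(exclude_flags, known)) > 0L) {
    abort(paste0("Unknown exclude_flags: ", paste(bad, collapse = ", ")))
  }
  if (min_base_quality < 0 || min_mapping_quality < 0) {
    abort("Quality thresholds must be non-negative.")
  }
  if (!(is.infinite(max_depth) || (max_depth == floor(max_depth) && max_depth >= 1))) {
    abort("max_depth must be a positive integer or Inf.")
  }
  structure(
    list(
      min_base_quality = as.integer(min_base_quality),
      min_mapping_quality = as.integer(min_mapping_quality),
      exclude_flags = union(exclude_flags, "unmapped"),
      max_depth = max_depth,
      dedup_overlaps = isTRUE(dedup_overlaps)
    ),
    class = "pileup_filters"
  )
}

.param_flag <- function(filters) {
  ex <- filters$exclude_flags
  Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = if ("secondary" %in% ex) FALSE else NA,
    isSupplementaryAlignment = if ("supplementary" %in% ex) FALSE else NA,
    isDuplicate = if ("duplicate" %in% ex) FALSE else NA,
    isNotPassingQualityControls = if ("qc_fail" %in% ex) FALSE else NA
  )
}

# Resolve the reference contig against a BAM header. The FASTA record name
# is tried first; if absent, common mito aliases are accepted when their
# header length matches the FASTA length.
.resolve_contig <- function(bam_path, reference) {
  targets <- Rsamtools::scanBamHeader(bam_path)[[1L]]$targets
  if (reference$contig %in% names(targets)) {
    if (targets[[reference$contig]] != reference$length) {
      abort(paste0(
        "Contig '", reference$contig, "' length mismatch: BAM header says ",
        targets[[reference$contig]], ", FASTA says ", reference$length,
        " (", bam_path, ")"
      ))
    }
    return(reference$contig)
  }
  for (alias in c("chrM", "MT", "chrMT", "M")) {
    if (alias %in% names(targets) && targets[[alias]] == reference$length) {
      return(alias)
    }
  }
  abort(paste0(
    "Mitochondrial contig '", reference$contig, "' (", reference$length,
    " bp) not found in BAM header of ", bam_path,
    "; also tried aliases chrM/MT/chrMT/M with matching length."
  ))
}

.check_index <- function(bam_path) {
  if (!file.exists(paste0(bam_path, ".bai")) &&
    !file.exists(sub("\\.bam$", ".bai", bam_path))) {
    abort(paste0("BAM index (.bai) not found for ", bam_path))
  }
}

# Read-level validity beyond flag filtering: aligned position, a CIGAR,
# sequence and quality strings of equal nonzero width, mapping quality
# passing (NA = unavailable/255 passes any threshold).
.read_keep <- function(ch, filters) {
  sw <- Biostrings::width(ch$seq)
  qw <- Biostrings::width(ch$qual)
  !is.na(ch$pos) & !is.na(ch$cigar) & nzchar(ch$cigar) &
    sw > 0L & qw == sw &
    (is.na(ch$mapq) | ch$mapq >= filters$min_mapping_quality)
}

# Expand aligned-match CIGAR segments (M/=/X only; insertions, deletions,
# skips and clips contribute nothing) into per-base calls. Returns parallel
# vectors: read index into the input vectors, 1-based reference position,
# base index 1..4, and Phred quality. N base calls and calls below
# min_base_quality are dropped here.
.chunk_calls <- function(pos, cigar, seq, qual, filters, contig_len) {
  n <- length(pos)
  empty <- list(
    read = integer(), pos = integer(),
    base = integer(), qual = integer()
  )
  if (n == 0L) {
    return(empty)
  }
  ops <- c("M", "=", "X")
  refr <- GenomicAlignments::cigarRangesAlongReferenceSpace(cigar, pos = pos, ops = ops)
  qryr <- GenomicAlignments::cigarRangesAlongQuerySpace(cigar, ops = ops)
  nper <- S4Vectors::elementNROWS(refr)
  refu <- unlist(refr, use.names = FALSE)
  qryu <- unlist(qryr, use.names = FALSE)
  w <- IRanges::width(refu)
  if (sum(w) == 0L) {
    return(empty)
  }
  ridx <- rep(rep.int(seq_len(n), nper), w)
  off <- sequence(w) - 1L
  rpos <- rep(IRanges::start(refu), w) + off
  qpos <- rep(IRanges::start(qryu), w) + off
  qlen <- Biostrings::width(seq)
  codes <- as.integer(unlist(seq))
  quals <- unlist(as(qual, "IntegerList"), use.names = FALSE)
  qstart <- cumsum(qlen) - qlen + 1L
  gidx <- qstart[ridx] + qpos - 1L
  b4 <- .code4[codes[gidx]]
  qv <- quals[gidx]
  keep <- !is.na(b4) & qv >= filters$min_base_quality &
    rpos >= 1L & rpos <= contig_len
  list(
    read = ridx[keep], pos = rpos[keep],
    base = b4[keep], qual = qv[keep]
  )
}

# Optional slow-path post-processing of a per-cell call set:
# mate-overlap single-counting, then the per-position depth cap.
.postprocess_calls <- function(calls, filters, qname = NULL, start = NULL) {
  d <- tibble(
    read = calls$read, pos = calls$pos,
    base = calls$base, qual = calls$qual
  )
  if (filters$dedup_overlaps && !is.null(qname)) {
    d$qname <- qname[d$read]
    d <- d |>
      dplyr::arrange(.data$pos, dplyr::desc(.data$qual), .data$read) |>
      dplyr::distinct(.data$qname, .data$pos, .keep_all = TRUE)
  }
  if (is.finite(filters$max_depth)) {
    d$start <- start[d$read]
    d <- d |>
      dplyr::arrange(.data$pos, .data$start, .data$read) |>
      dplyr::group_by(.data$pos) |>
      dplyr::filter(match(.data$read, unique(.data$read)) <= filters$max_depth) |>
      dplyr::ungroup()
  }
  list(read = d$read, pos = d$pos, base = d$base, qual = d$qual)
}

.needs_slow_path <- function(filters) {
  filters$dedup_overlaps || is.finite(filters$max_depth)
}

# Tally calls of one cell into 4 dense count vectors (list A,C,G,T).
.tally_cell <- function(calls, contig_len) {
  lapply(1:4, function(b) {
    tabulate(calls$pos[calls$base == b], nbins = contig_len)
  })
}

new_mito_basecounts <- function(counts, cells, reference, filters, mode) {
  structure(
    list(
      counts = counts, cells = cells, reference = reference,
      filters = filters, mode = mode
    ),
    class = "mito_basecounts"
  )
}

#' @export
print.mito_basecounts <- function(x, ...) {
  cat(
    "<mito_basecounts> ", nrow(x$cells), " cell(s) [", x$mode, " layout], ",
    "contig ", x$reference$contig, " (", x$reference$length, " bp), ",
    format(sum(x$cells$n_bases), big.mark = ","), " counted base calls\n",
    sep = ""
  )
  invisible(x)
}

#' Pile up well-based data: one BAM file per cell or sample
#'
#' Walks each BAM over the mitochondrial contig and tallies A/C/G/T base
#' calls per position per cell. Only aligned-match base calls (CIGAR
#' `M`/`=`/`X`) are counted; insertions, deletions, reference skips, soft
#' clips and `N` base calls contribute nothing, so coverage at a position
#' always equals the sum of the four base counts there.
#'
#' @param bam_paths Character vector of coordinate-sorted, indexed BAM
#'   files; one per cell. The file stem (basename without `.bam`) becomes
#'   the cell id and the input order fixes the column order of all
#'   downstream matrices.
#' @param reference A `mito_reference` from [read_mito_reference()].
#' @param filters A [pileup_filters()] object.
#' @return A `mito_basecounts` object: per-base sparse position-by-cell
#'   count matrices plus a cell table (`cell_id`, `n_reads`, `n_bases`).
#' @seealso [pileup_droplet()] for barcoded single-BAM layouts,
#'   [build_matrices()] for the alt-count / coverage matrices.
#' @export
pileup_well <- function(bam_paths, reference, filters = pileup_filters()) {
  if (length(bam_paths) < 1L) abort("Supply at least one BAM file.")
  missing <- bam_paths[!file.exists(bam_paths)]
  if (length(missing) > 0L) {
    abort(paste0("BAM file(s) not found: ", paste(missing, collapse = ", ")))
  }
  cell_ids <- sub("\\.bam$", "", basename(bam_paths))
  if (anyDuplicated(cell_ids)) {
    abort("Duplicate BAM file stems; cell ids must be unique.")
  }
  L <- reference$length
  need_qname <- filters$dedup_overlaps
  what <- c("pos", "mapq", "cigar", "seq", "qual", if (need_qname) "qname")
  flag <- .param_flag(filters)
  ii <- vector("list", 4L)
  jj <- vector("list", 4L)
  xx <- vector("list", 4L)
  for (b in 1:4) {
    ii[[b]] <- list()
    jj[[b]] <- list()
    xx[[b]] <- list()
  }
  n_reads <- integer(length(bam_paths))
  n_bases <- integer(length(bam_paths))
  for (j in seq_along(bam_paths)) {
    bam <- bam_paths[j]
    .check_index(bam)
    contig <- .resolve_contig(bam, reference)
    which <- GenomicRanges::GRanges(contig, IRanges::IRanges(1L, L))
    param <- Rsamtools::ScanBamParam(which = which, what = what, flag = flag)
    ch <- Rsamtools::scanBam(bam, param = param)[[1L]]
    keep <- .read_keep(ch, filters)
    calls <- .chunk_calls(
      ch$pos[keep], ch$cigar[keep], ch$seq[keep], ch$qual[keep],
      filters, L
    )
    if (.needs_slow_path(filters)) {
      calls <- .postprocess_calls(
        calls, filters,
        qname = if (need_qname) ch$qname[keep],
        start = ch$pos[keep]
      )
    }
    n_reads[j] <- sum(keep)
    n_bases[j] <- length(calls$pos)
    tal <- .tally_cell(calls, L)
    for (b in 1:4) {
      nz <- which(tal[[b]] > 0L)
      if (length(nz) > 0L) {
        ii[[b]][[length(ii[[b]]) + 1L]] <- nz
        jj[[b]][[length(jj[[b]]) + 1L]] <- rep.int(j, length(nz))
        xx[[b]][[length(xx[[b]]) + 1L]] <- tal[[b]][nz]
      }
    }
  }
  counts <- lapply(1:4, function(b) {
    sparseMatrix(
      i = as.integer(unlist(ii[[b]])),
      j = as.integer(unlist(jj[[b]])),
      x = as.double(unlist(xx[[b]])),
      dims = c(L, length(bam_paths)),
      dimnames = list(NULL, cell_ids)
    )
  })
  names(counts) <- .base_letters
  cells <- tibble(cell_id = cell_ids, n_reads = n_reads, n_bases = n_bases)
  new_mito_basecounts(counts, cells, reference, filters, "well")
}

#' Pile up droplet-based data: one barcoded BAM for all cells
#'
#' Streams a barcoded BAM (e.g. 10x Genomics) and tallies base calls per
#' cell barcode. Reads lacking the barcode tag are dropped. Because far
#' more barcodes are observed than real cells, empty droplets must be
#' excluded: supply a barcode `whitelist`, a `min_reads` cutoff on the
#' per-barcode mitochondrial read count, or both (the whitelist is applied
#' first).
#'
#' @inheritParams pileup_well
#' @param bam_path A single coordinate-sorted, indexed barcoded BAM.
#' @param barcode_tag BAM tag holding the cell barcode (default `"CB"`,
#'   the 10x corrected-barcode convention; use `"CR"` for raw barcodes).
#' @param whitelist Character vector of barcodes to retain, or a path to a
#'   plain-text file with one barcode per line. Its order fixes the column
#'   order; barcodes absent from the BAM are dropped with a warning.
#' @param min_reads Minimum mitochondrial read count for a barcode to be
#'   retained. Without a whitelist, retained barcodes are ordered
#'   alphabetically.
#' @param umi_collapse If `TRUE`, reads sharing (barcode, UMI) are
#'   collapsed to one vote per position: the majority base, ties broken by
#'   higher summed base quality, then alphabetical base. Reads without the
#'   UMI tag keep one vote each. Default `FALSE` (read-level counting).
#' @param umi_tag BAM tag holding the UMI (default `"UB"`).
#' @param yield_size Number of BAM records per streaming chunk.
#' @return A `mito_basecounts` object, as for [pileup_well()].
#' @export
pileup_droplet <- function(bam_path, reference, filters = pileup_filters(),
                           barcode_tag = "CB", whitelist = NULL,
                           min_reads = NULL, umi_collapse = FALSE,
                           umi_tag = "UB", yield_size = 100000L) {
  if (length(bam_path) != 1L) abort("Droplet mode takes a single BAM file.")
  if (!file.exists(bam_path)) abort(paste0("BAM file not found: ", bam_path))
  if (is.null(whitelist) && is.null(min_reads)) {
    abort("Supply a barcode `whitelist` and/or a `min_reads` cutoff to exclude empty droplets.")
  }
  if (!is.null(whitelist) && length(whitelist) == 1L && file.exists(whitelist)) {
    whitelist <- read_barcodes(whitelist)
  }
  .check_index(bam_path)
  contig <- .resolve_contig(bam_path, reference)
  L <- reference$length
  slow <- .needs_slow_path(filters) || isTRUE(umi_collapse)
  need_qname <- filters$dedup_overlaps
  what <- c(
    "rname", "pos", "mapq", "cigar", "seq", "qual",
    if (need_qname) "qname"
  )
  tags <- c(barcode_tag, if (isTRUE(umi_collapse)) umi_tag)
  param <- Rsamtools::ScanBamParam(
    what = what, tag = tags,
    flag = .param_flag(filters)
  )
  bf <- Rsamtools::BamFile(bam_path, yieldSize = as.integer(yield_size))
  open(bf)
  on.exit(close(bf), add = TRUE)

  tag_seen <- 0L
  records_seen <- 0L
  barcodes <- character(0L) # registry: barcode -> accumulator column
  reads_n <- numeric(0L) # per-barcode read counts, registry order
  acc <- NULL # fast path: 4 sparse L x n_barcodes accumulators
  raw <- list() # slow path: per-chunk raw calls
  read_offset <- 0L
  repeat {
    ch <- Rsamtools::scanBam(bf, param = param)[[1L]]
    nrec <- length(ch$pos)
    if (nrec == 0L) break
    records_seen <- records_seen + nrec
    bar <- ch$tag[[barcode_tag]]
    if (is.null(bar)) bar <- rep(NA_character_, nrec)
    tag_seen <- tag_seen + sum(!is.na(bar))
    keep <- .read_keep(ch, filters) &
      as.character(ch$rname) == contig & !is.na(bar)
    if (!is.null(whitelist)) keep <- keep & bar %in% whitelist
    if (any(keep)) {
      barK <- bar[keep]
      new <- setdiff(unique(barK), barcodes)
      if (length(new) > 0L) {
        if (!is.null(acc)) {
          pad <- sparseMatrix(
            i = integer(), j = integer(), x = double(),
            dims = c(L, length(new))
          )
          acc <- lapply(acc, function(m) cbind(m, pad))
        }
        barcodes <- c(barcodes, new)
        reads_n <- c(reads_n, numeric(length(new)))
      }
      j_read <- match(barK, barcodes)
      reads_n <- reads_n + tabulate(j_read, nbins = length(barcodes))
      calls <- .chunk_calls(
        ch$pos[keep], ch$cigar[keep], ch$seq[keep], ch$qual[keep],
        filters, L
      )
      if (slow) {
        umi <- if (isTRUE(umi_collapse)) ch$tag[[umi_tag]] else NULL
        raw[[length(raw) + 1L]] <- tibble(
          read = calls$read + read_offset,
          bar = barK[calls$read],
          pos = calls$pos, base = calls$base, qual = calls$qual,
          umi = if (!is.null(umi)) umi[keep][calls$read] else NA_character_,
          qname = if (need_qname) ch$qname[keep][calls$read] else NA_character_,
          start = ch$pos[keep][calls$read]
        )
        read_offset <- read_offset + sum(keep)
      } else {
        jcall <- j_read[calls$read]
        chunk <- lapply(1:4, function(b) {
          sel <- calls$base == b
          sparseMatrix(
            i = calls$pos[sel], j = jcall[sel], x = 1,
            dims = c(L, length(barcodes))
          )
        })
        acc <- if (is.null(acc)) chunk else Map(`+`, acc, chunk)
      }
    }
    if (nrec < yield_size) break
  }
  if (tag_seen == 0L) {
    abort(paste0(
      "Barcode tag '", barcode_tag, "' never observed in ", records_seen,
      " records of ", bam_path,
      "; is the tag name correct (e.g. CB vs CR)?"
    ))
  }
  reads_per_bar <- tibble(bar = barcodes, n_reads = reads_n)
  retained <- reads_per_bar
  if (!is.null(min_reads)) {
    retained <- dplyr::filter(retained, .data$n_reads >= min_reads)
  }
  if (!is.null(whitelist)) {
    absent <- setdiff(whitelist, retained$bar)
    if (length(absent) > 0L) {
      warn(paste0(
        length(absent), " whitelist barcode(s) not retained (absent or below min_reads): ",
        paste(head(absent, 5L), collapse = ", "),
        if (length(absent) > 5L) ", ..."
      ))
    }
    cell_ids <- intersect(whitelist, retained$bar)
  } else {
    cell_ids <- sort(retained$bar)
  }
  if (length(cell_ids) == 0L) {
    abort("No barcodes retained after whitelist/min_reads filtering.")
  }

  if (slow) {
    d <- dplyr::bind_rows(raw) |>
      dplyr::filter(.data$bar %in% cell_ids)
    if (isTRUE(umi_collapse)) {
      with_umi <- d |>
        dplyr::filter(!is.na(.data$umi)) |>
        dplyr::summarise(
          n = dplyr::n(), sq = sum(.data$qual),
          .by = c("bar", "umi", "pos", "base")
        ) |>
        dplyr::arrange(
          .data$bar, .data$umi, .data$pos,
          dplyr::desc(.data$n), dplyr::desc(.data$sq), .data$base
        ) |>
        dplyr::distinct(.data$bar, .data$umi, .data$pos, .keep_all = TRUE)
      d <- dplyr::bind_rows(
        dplyr::filter(d, is.na(.data$umi)),
        with_umi |> dplyr::mutate(read = NA_integer_, qual = .data$sq)
      )
    }
    if (filters$dedup_overlaps) {
      d <- d |>
        dplyr::arrange(.data$pos, dplyr::desc(.data$qual), .data$read) |>
        dplyr::distinct(.data$bar, .data$qname, .data$pos, .keep_all = TRUE)
    }
    if (is.finite(filters$max_depth)) {
      d <- d |>
        dplyr::arrange(.data$bar, .data$pos, .data$start, .data$read) |>
        dplyr::group_by(.data$bar, .data$pos) |>
        dplyr::filter(dplyr::row_number() <= filters$max_depth) |>
        dplyr::ungroup()
    }
    agg_all <- dplyr::count(d, .data$bar, .data$pos, .data$base, name = "n")
    jmap <- match(agg_all$bar, cell_ids)
    counts <- lapply(1:4, function(b) {
      sel <- agg_all$base == b
      sparseMatrix(
        i = agg_all$pos[sel], j = jmap[sel], x = as.double(agg_all$n[sel]),
        dims = c(L, length(cell_ids)),
        dimnames = list(NULL, cell_ids)
      )
    })
  } else {
    sel <- match(cell_ids, barcodes)
    counts <- lapply(acc, function(m) {
      out <- m[, sel, drop = FALSE]
      dimnames(out) <- list(NULL, cell_ids)
      out
    })
  }
  names(counts) <- .base_letters
  n_bases_cell <- Reduce(`+`, lapply(counts, Matrix::colSums))
  cells <- tibble(cell_id = cell_ids) |>
    dplyr::left_join(reads_per_bar, by = c(cell_id = "bar")) |>
    dplyr::mutate(
      n_reads = as.integer(dplyr::coalesce(.data$n_reads, 0)),
      n_bases = as.integer(n_bases_cell)
    )
  new_mito_basecounts(counts, cells, reference, filters, "droplet")
}

#' Read a barcode whitelist file
#'
#' @param path Plain-text file, one barcode per line.
#' @return Character vector of barcodes.
#' @export
read_barcodes <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x)]
}

#' Aggregate read coverage across the mitochondrial genome
#'
#' Sums counted base calls over cells to give a per-position depth track
#' (the coverage profile a MitoDepth-style plot displays).
#'
#' @param basecounts A `mito_basecounts` object.
#' @return A tibble with columns `position`, `sum_depth` (total over
#'   cells) and `mean_depth` (per-cell average); the contig name is kept
#'   in the `"contig"` attribute.
#' @export
total_coverage_track <- function(basecounts) {
  stopifnot(inherits(basecounts, "mito_basecounts"))
  ncell <- nrow(basecounts$cells)
  if (ncell == 0L) abort("No cells in basecounts.")
  total <- Reduce(`+`, lapply(basecounts$counts, Matrix::rowSums))
  out <- tibble(
    position = seq_len(basecounts$reference$length),
    sum_depth = as.numeric(total),
    mean_depth = as.numeric(total) / ncell
  )
  attr(out, "contig") <- basecounts$reference$contig
  out
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal depth are merged. bedGraph is the one output using
#' 0-based half-open coordinates, per the format standard; everything else
#' in the package is 1-based.
#'
#' @param track A tibble from [total_coverage_track()].
#' @param path Output file path.
#' @param value Which depth column to write: `"sum"` or `"mean"`.
#' @param contig Contig name; defaults to the track's `"contig"` attribute.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, value = c("sum", "mean"),
                           contig = NULL) {
  value <- match.arg(value)
  contig <- contig %||% attr(track, "contig") %||% "chrM"
  v <- if (value == "sum") track$sum_depth else track$mean_depth
  r <- rle(v)
  end <- cumsum(r$lengths)
  start0 <- end - r$lengths # 0-based starts
  keep <- r$values != 0
  lines <- sprintf(
    "%s\t%d\t%d\t%g",
    contig, start0[keep], end[keep], r$values[keep]
  )
  writeLines(lines, path)
  invisible(path)
}
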