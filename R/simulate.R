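#' Configuration for a synthetic mitochondrial study
#'
#' Defines a complete simulated experiment: a random mitochondrial
#' reference, K donors with donor-exclusive germline variants (fixed,
#' AF 1) and donor-specific heteroplasmies (intermediate AF), cells per
#' donor, and reads per cell. Every downstream draw flows from the single
#' mandatory `seed`.
#'
#' @param n_donors Number of donors.
#' @param cells_per_donor Cells per donor.
#' @param reads_per_cell Poisson mean of the per-cell read count.
#' @param reference_length Length of the simulated mitochondrial contig
#'   (default 16569 bp, the human mtDNA length; minimum 1000).
#' @param read_length Read length in bp (default 100).
#' @param error_rate Independent per-base sequencing error probability
#'   (default 1e-3); errors substitute a uniformly chosen different base.
#' @param n_germline_per_donor Donor-exclusive fixed variants per donor.
#' @param n_het_per_donor Donor-specific heteroplasmies per donor.
#' @param het_mean_af Donor-level mean AF of each heteroplasmy
#'   (default 0.10).
#' @param het_dispersion Beta-distribution dispersion rho in (0, 1) of the
#'   per-cell heteroplasmy AF around the donor mean (default 0.05; the
#'   per-cell standard deviation is `sqrt(mu * (1 - mu) * rho)`).
#' @param layout `"well"` (one BAM per cell) or `"droplet"` (one barcoded
#'   BAM with CB tags).
#' @param barcode_length Cell-barcode length for droplet layout
#'   (default 12).
#' @param low_qual_frac Fraction of base calls written with Phred quality
#'   5 instead of 30, to exercise the base-quality filter (default 0).
#' @param seed Mandatory integer seed (< 2^31 - 10).
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_donors, cells_per_donor, reads_per_cell,
                       reference_length = 16569L, read_length = 100L,
                       error_rate = 1e-3,
                       n_germline_per_donor = 0L, n_het_per_donor = 0L,
                       het_mean_af = 0.10, het_dispersion = 0.05,
                       layout = c("well", "droplet"),
                       barcode_length = 12L, low_qual_frac = 0,
                       seed) {
  layout <- match.arg(layout)
  if (missing(seed)) abort("A seed is mandatory: the simulator has no implicit randomness.")
  if (seed >= 2^31 - 10) abort("seed must be below 2^31 - 10.")
  if (reference_length < 1000L) abort("reference_length must be >= 1000.")
  if (error_rate < 0 || error_rate > 1 || low_qual_frac < 0 || low_qual_frac > 1) {
    abort("Rates must lie in [0, 1].")
  }
  if (het_mean_af <= 0 || het_mean_af >= 1 || het_dispersion <= 0 || het_dispersion >= 1) {
    abort("het_mean_af and het_dispersion must lie in (0, 1).")
  }
  structure(
    list(
      n_donors = as.integer(n_donors),
      cells_per_donor = as.integer(cells_per_donor),
      reads_per_cell = reads_per_cell,
      reference_length = as.integer(reference_length),
      read_length = as.integer(read_length),
      error_rate = error_rate,
      n_germline_per_donor = as.integer(n_germline_per_donor),
      n_het_per_donor = as.integer(n_het_per_donor),
      het_mean_af = het_mean_af, het_dispersion = het_dispersion,
      layout = layout, barcode_length = as.integer(barcode_length),
      low_qual_frac = low_qual_frac,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Generate a random mitochondrial reference
#'
#' Uniform-random A/C/G/T sequence of the configured length, written (when
#' `fasta_path` is given) as a single-record FASTA named `chrM`.
#'
#' @param config A [sim_config()].
#' @param fasta_path Optional output FASTA path.
#' @return A `mito_reference`.
#' @export
make_reference <- function(config, fasta_path = NULL) {
  set.seed(config$seed)
  sq <- paste(
    sample(c("A", "C", "G", "T"), config$reference_length, replace = TRUE),
    collapse = ""
  )
  ref <- new_mito_reference("chrM", sq)
  if (!is.null(fasta_path)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(sq, "chrM")), fasta_path
    )
  }
  ref
}

#' Draw donor genotypes: germline variants and heteroplasmies
#'
#' Samples donor-exclusive variant positions (no position is reused
#' across donors or between the germline and heteroplasmy sets) with alt
#' bases uniform over the three non-reference bases.
#'
#' @param config A [sim_config()].
#' @param reference The `mito_reference` from [make_reference()].
#' @return The truth table: a tibble with `donor_id`, `label`,
#'   `position`, `ref`, `alt`, `type` (`"germline"` or
#'   `"heteroplasmy"`), `mean_af` (1 for germline) and `dispersion`
#'   (NA for germline).
#' @export
make_truth <- function(config, reference) {
  set.seed(config$seed + 1L)
  per_donor <- config$n_germline_per_donor + config$n_het_per_donor
  total <- per_donor * config$n_donors
  eligible <- which(strsplit(reference$sequence, "", fixed = TRUE)[[1L]] %in%
    c("A", "C", "G", "T"))
  if (total > length(eligible)) {
    abort(paste0(
      total, " variants requested but only ", length(eligible),
      " usable positions in the reference."
    ))
  }
  donors <- sprintf("donor%02d", seq_len(config$n_donors))
  if (total == 0L) {
    return(tibble(
      donor_id = character(), label = character(), position = integer(),
      ref = character(), alt = character(), type = character(),
      mean_af = double(), dispersion = double()
    ))
  }
  pos <- sample(eligible, total)
  ref_base <- substring(reference$sequence, pos, pos)
  alt <- vapply(ref_base, function(r) {
    sample(setdiff(c("A", "C", "G", "T"), r), 1L)
  }, character(1L), USE.NAMES = FALSE)
  type <- rep(
    rep(c("germline", "heteroplasmy"),
      times = c(config$n_germline_per_donor, config$n_het_per_donor)
    ),
    times = config$n_donors
  )
  tibble(
    donor_id = rep(donors, each = per_donor),
    label = format_variant_label(pos, ref_base, alt),
    position = as.integer(pos),
    ref = ref_base, alt = alt, type = type,
    mean_af = ifelse(type == "germline", 1, config$het_mean_af),
    dispersion = ifelse(type == "germline", NA_real_, config$het_dispersion)
  ) |>
    dplyr::arrange(.data$donor_id, .data$position)
}

# Vectorised in-place single-character substitution that tolerates
# duplicated target indices (a read carrying several variants, or several
# errors) by applying passes until no duplicates remain.
.substr_assign <- function(x, idx, at, value) {
  while (length(idx) > 0L) {
    first <- !duplicated(idx)
    xi <- x[idx[first]]
    substring(xi, at[first], at[first]) <- value[first]
    x[idx[first]] <- xi
    idx <- idx[!first]
    at <- at[!first]
    value <- value[!first]
  }
  x
}

.random_other_base <- function(current) {
  bases <- c("A", "C", "G", "T")
  vapply(current, function(b) sample(setdiff(bases, b), 1L),
    character(1L),
    USE.NAMES = FALSE
  )
}

# Generate the reads of one cell: starts, sequences with the donor's
# variants injected (germline on every covering read; heteroplasmies on a
# Bernoulli(cell_af) subset), then sequencing errors.
.cell_reads <- function(reference, donor_truth, config) {
  L <- config$reference_length
  rl <- config$read_length
  n <- rpois(1L, config$reads_per_cell)
  if (n == 0L) {
    return(tibble(
      start = integer(), seq = character(), qual = character()
    ))
  }
  start <- sample.int(L - rl + 1L, n, replace = TRUE)
  sq <- substring(reference$sequence, start, start + rl - 1L)
  if (nrow(donor_truth) > 0L) {
    idx <- integer()
    at <- integer()
    val <- character()
    for (i in seq_len(nrow(donor_truth))) {
      p <- donor_truth$position[i]
      covering <- which(start <= p & start + rl - 1L >= p)
      if (length(covering) == 0L) next
      if (donor_truth$type[i] == "heteroplasmy") {
        mu <- donor_truth$mean_af[i]
        rho <- donor_truth$dispersion[i]
        cell_af <- rbeta(1L, mu * (1 - rho) / rho, (1 - mu) * (1 - rho) / rho)
        covering <- covering[runif(length(covering)) < cell_af]
        if (length(covering) == 0L) next
      }
      idx <- c(idx, covering)
      at <- c(at, p - start[covering] + 1L)
      val <- c(val, rep(donor_truth$alt[i], length(covering)))
    }
    sq <- .substr_assign(sq, idx, at, val)
  }
  if (config$error_rate > 0) {
    n_err <- rbinom(n, rl, config$error_rate)
    which_err <- which(n_err > 0L)
    if (length(which_err) > 0L) {
      idx <- rep(which_err, n_err[which_err])
      at <- unlist(lapply(n_err[which_err], function(k) sample.int(rl, k)))
      cur <- substring(sq[idx], at, at)
      sq <- .substr_assign(sq, idx, at, .random_other_base(cur))
    }
  }
  q30 <- strrep(rawToChar(as.raw(30L + 33L)), rl)
  qual <- rep(q30, n)
  if (config$low_qual_frac > 0) {
    n_low <- rbinom(n, rl, config$low_qual_frac)
    which_low <- which(n_low > 0L)
    if (length(which_low) > 0L) {
      idx <- rep(which_low, n_low[which_low])
      at <- unlist(lapply(n_low[which_low], function(k) sample.int(rl, k)))
      qual <- .substr_assign(
        qual, idx, at,
        rep(rawToChar(as.raw(5L + 33L)), length(idx))
      )
    }
  }
  tibble(start = start, seq = sq, qual = qual)
}

.sam_header <- function(reference) {
  c(
    "@HD\tVN:1.6\tSO:coordinate",
    paste0("@SQ\tSN:", reference$contig, "\tLN:", reference$length)
  )
}

.write_bam <- function(sam_lines, bam_path) {
  sam_path <- paste0(bam_path, ".tmp.sam")
  writeLines(sam_lines, sam_path)
  dest <- sub("\\.bam$", "", bam_path)
  Rsamtools::asBam(sam_path,
    destination = dest, overwrite = TRUE,
    indexDestination = TRUE
  )
  unlink(sam_path)
  bam_path
}

.random_barcodes <- function(n, len) {
  repeat {
    bc <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1L))
    if (!anyDuplicated(bc)) {
      return(bc)
    }
  }
}

#' Simulate cells and write BAM files
#'
#' Generates reads for every cell of every donor and writes either one
#' coordinate-sorted indexed BAM per cell (well layout) or a single
#' barcoded BAM with `CB` tags (droplet layout). Base qualities are Q30
#' (optionally degraded, see [sim_config()]), mapping quality 60, simple
#' full-match alignments on the linear reference (no origin-spanning
#' reads).
#'
#' @param reference The `mito_reference` from [make_reference()].
#' @param truth The truth table from [make_truth()].
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return A list: `bam_paths` (named by cell id), `labels` tibble
#'   (`cell_id`, `donor_id`), `whitelist` (droplet only), `dir`.
#' @export
simulate_cells <- function(reference, truth, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 2L)
  donors <- sprintf("donor%02d", seq_len(config$n_donors))
  n_cells <- config$n_donors * config$cells_per_donor
  cell_donor <- rep(donors, each = config$cells_per_donor)
  if (config$layout == "well") {
    cell_ids <- sprintf(
      "%s_c%03d", cell_donor,
      rep(seq_len(config$cells_per_donor), times = config$n_donors)
    )
  } else {
    cell_ids <- .random_barcodes(n_cells, config$barcode_length)
  }
  header <- .sam_header(reference)
  rl <- config$read_length
  bam_paths <- character(0L)
  droplet_chunks <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    dt <- truth[truth$donor_id == cell_donor[i], , drop = FALSE]
    reads <- .cell_reads(reference, dt, config)
    ord <- order(reads$start)
    reads <- reads[ord, , drop = FALSE]
    if (nrow(reads) > 0L) {
      body <- sprintf(
        "%s_r%06d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
        cell_ids[i], seq_len(nrow(reads)), reference$contig,
        reads$start, rl, reads$seq, reads$qual
      )
    } else {
      body <- character(0L)
    }
    if (config$layout == "well") {
      bam <- file.path(dir, paste0(cell_ids[i], ".bam"))
      .write_bam(c(header, body), bam)
      bam_paths[cell_ids[i]] <- bam
    } else {
      droplet_chunks[[i]] <- tibble(
        start = reads$start,
        line = paste0(body, "\tCB:Z:", cell_ids[i])
      )
    }
  }
  labels <- tibble(cell_id = cell_ids, donor_id = cell_donor)
  if (config$layout == "droplet") {
    all_reads <- dplyr::bind_rows(droplet_chunks) |>
      dplyr::arrange(.data$start)
    bam <- file.path(dir, "droplet.bam")
    .write_bam(c(header, all_reads$line), bam)
    bam_paths <- c(droplet = bam)
    whitelist <- cell_ids
  } else {
    whitelist <- NULL
  }
  list(bam_paths = bam_paths, labels = labels, whitelist = whitelist, dir = dir)
}

#' Simulate a complete synthetic study
#'
#' One-call orchestration: reference FASTA, donor truth table, BAM
#' file(s), labels TSV, barcode whitelist (droplet layout) and a JSON
#' manifest, all under `dir` and fully determined by `config$seed`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return A list: `reference` (`mito_reference`), `fasta`, `truth`
#'   (tibble; also written as `truth.tsv`), `bam_paths`, `labels`
#'   (tibble; also `labels.tsv`), `whitelist_path` (droplet), `config`,
#'   `dir`.
#' @examples
#' \donttest{
#' cfg <- sim_config(
#'   n_donors = 2, cells_per_donor = 3, reads_per_cell = 50,
#'   reference_length = 1000, n_germline_per_donor = 2, seed = 7
#' )
#' study <- simulate_study(cfg, tempfile("study"))
#' study$truth
#' }
#' @export
simulate_study <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "reference.fa")
  reference <- make_reference(config, fasta)
  truth <- make_truth(config, reference)
  sim <- simulate_cells(reference, truth, config, dir)
  readr::write_tsv(truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(sim$labels, file.path(dir, "labels.tsv"))
  whitelist_path <- NULL
  if (!is.null(sim$whitelist)) {
    whitelist_path <- file.path(dir, "whitelist.txt")
    writeLines(sim$whitelist, whitelist_path)
  }
  manifest <- unclass(config)
  manifest$package_version <- as.character(packageVersion("mitovar"))
  jsonlite::write_json(manifest, file.path(dir, "sim_manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  list(
    reference = reference, fasta = fasta, truth = truth,
    bam_paths = sim$bam_paths, labels = sim$labels,
    whitelist_path = whitelist_path, config = config, dir = dir
  )
}
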