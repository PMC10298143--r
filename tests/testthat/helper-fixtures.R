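# Shared fixtures, built once per session and cached. All simulation seeds
# are fixed constants; the fixtures define the study conditions the
# statistical layer is validated against.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# Small 3-donor well-based study used by generic pipeline tests.
small_study <- function() {
  fixture("small_study", function() {
    cfg <- sim_config(
      n_donors = 3, cells_per_donor = 10, reads_per_cell = 300,
      reference_length = 1500, read_length = 100, error_rate = 1e-3,
      n_germline_per_donor = 4, n_het_per_donor = 1,
      het_mean_af = 0.10, seed = 4242
    )
    study <- simulate_study(cfg, file.path(tempdir(), "fx_small"))
    ref <- read_mito_reference(study$fasta)
    bc <- pileup_well(study$bam_paths, ref)
    m <- build_matrices(bc)
    af <- calc_allele_frequency(m)
    list(study = study, ref = ref, bc = bc, m = m, af = af)
  })
}

# Germline-recovery study: 4 donors x 50 cells, 10 donor-exclusive fixed
# variants each, ~50x per-cell coverage, sequencing error 1e-3.
germline_study <- function() {
  fixture("germline_study", function() {
    cfg <- sim_config(
      n_donors = 4, cells_per_donor = 50,
      reads_per_cell = 1500, # 50x over a 3 kb contig at 100 bp reads
      reference_length = 3000, read_length = 100, error_rate = 1e-3,
      n_germline_per_donor = 10, n_het_per_donor = 0, seed = 101
    )
    study <- simulate_study(cfg, file.path(tempdir(), "fx_germline"))
    ref <- read_mito_reference(study$fasta)
    bc <- pileup_well(study$bam_paths, ref)
    af <- calc_allele_frequency(build_matrices(bc))
    list(study = study, ref = ref, af = af)
  })
}

# Heteroplasmy-recovery study: 8 donors x 100 cells, one donor-specific
# heteroplasmy each with mean AF 0.10, ~50x per-cell coverage; droplet
# layout (single barcoded BAM). Donors also carry a few germline variants
# so the exclusion step is exercised.
het_study <- function() {
  fixture("het_study", function() {
    cfg <- sim_config(
      n_donors = 8, cells_per_donor = 100,
      reads_per_cell = 1500, reference_length = 3000, read_length = 100,
      error_rate = 1e-3, n_germline_per_donor = 3, n_het_per_donor = 1,
      het_mean_af = 0.10, layout = "droplet", seed = 202
    )
    study <- simulate_study(cfg, file.path(tempdir(), "fx_het"))
    ref <- read_mito_reference(study$fasta)
    bc <- pileup_droplet(study$bam_paths, ref,
      whitelist = study$whitelist_path
    )
    af <- calc_allele_frequency(build_matrices(bc))
    list(study = study, ref = ref, af = af)
  })
}

# Build a mito_af object directly from a dense AF matrix (NA = missing),
# for statistics-layer tests that need exact AF values. Row i maps to
# position i with ref A, alt G; coverage is `cov` where observed, 0 where
# missing.
toy_af <- function(af_dense, cell_ids = NULL, cov = 30L) {
  nv <- nrow(af_dense)
  nc <- ncol(af_dense)
  if (is.null(cell_ids)) cell_ids <- sprintf("cell%03d", seq_len(nc))
  variants <- tibble::tibble(
    label = format_variant_label(seq_len(nv), "A", "G"),
    position = seq_len(nv), ref = "A", alt = "G"
  )
  obs <- !is.na(af_dense)
  afm <- af_dense
  afm[!obs] <- 0
  covm <- matrix(0, nv, nc)
  covm[obs] <- cov
  structure(
    list(
      af = as(Matrix::Matrix(afm, sparse = TRUE), "CsparseMatrix"),
      cov = as(Matrix::Matrix(covm, sparse = TRUE), "CsparseMatrix"),
      variants = variants,
      cells = tibble::tibble(
        cell_id = cell_ids,
        n_reads = NA_integer_, n_bases = NA_integer_
      ),
      min_coverage = 1L,
      reference = list(contig = "toy", length = nv)
    ),
    class = "mito_af"
  )
}

toy_labels <- function(cell_ids, donors) {
  tibble::tibble(cell_id = cell_ids, donor_id = donors)
}

# Split a barcoded BAM into one BAM per barcode (independent route used
# by the well/droplet equivalence checks).
split_bam_by_barcode <- function(bam, barcodes, dir, tag = "CB") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vapply(barcodes, function(b) {
    out <- file.path(dir, paste0(b, ".bam"))
    rule <- local({
      bb <- b
      function(x) !is.na(x[[tag]]) & x[[tag]] == bb
    })
    Rsamtools::filterBam(
      bam, out,
      param = Rsamtools::ScanBamParam(what = "qname", tag = tag),
      filter = S4Vectors::FilterRules(list(bar = rule)),
      indexDestination = TRUE
    )
    out
  }, character(1L))
}
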