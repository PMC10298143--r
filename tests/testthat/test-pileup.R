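flat_ref <- function(L = 200L) {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chrM", strrep("A", L)), fa)
  read_mito_reference(fa)
}

q30 <- function(n) strrep("?", n) # Phred 30
rec <- function(qname, pos, seq, qual = q30(nchar(seq)), flag = 0L,
                mapq = 60L, cigar = paste0(nchar(seq), "M")) {
  tibble::tibble(
    qname = qname, flag = flag, pos = pos, mapq = mapq,
    cigar = cigar, seq = seq, qual = qual
  )
}

test_that("pileup counts match a hand-tallied example", {
  ref <- flat_ref()
  # 5 reads of length 10 covering position 100; 2 carry G there
  reads <- dplyr::bind_rows(lapply(1:5, function(i) {
    start <- 95L + i # starts 96..100, all cover position 100
    base_at_100 <- if (i <= 2) "G" else "A"
    sq <- strrep("A", 10L)
    substr(sq, 100L - start + 1L, 100L - start + 1L) <- base_at_100
    rec(paste0("r", i), start, sq)
  }))
  bam <- records_to_bam(reads, 200L, tempfile(fileext = ".bam"))
  bc <- pileup_well(bam, ref)
  expect_equal(as.numeric(bc$counts$A[100, 1]), 3)
  expect_equal(as.numeric(bc$counts$G[100, 1]), 2)
  expect_equal(as.numeric(bc$counts$C[100, 1]), 0)
  expect_equal(as.numeric(bc$counts$T[100, 1]), 0)
  expect_equal(bc$cells$n_reads, 5L)
})

test_that("flagged reads are excluded and the base-quality filter is per base", {
  ref <- flat_ref()
  dup_only <- records_to_bam(
    rec("d1", 50L, strrep("A", 10L), flag = 1024L),
    200L, tempfile(fileext = ".bam")
  )
  bc <- pileup_well(dup_only, ref)
  expect_equal(sum(sapply(bc$counts, sum)), 0)
  expect_equal(bc$cells$n_reads, 0L)

  # base 3 of 5 has quality 5 (< 13): only that call is dropped
  qual <- q30(5L)
  substr(qual, 3L, 3L) <- rawToChar(as.raw(5L + 33L))
  bam <- records_to_bam(
    rec("q1", 10L, "AAAAA", qual = qual), 200L,
    tempfile(fileext = ".bam")
  )
  bc <- pileup_well(bam, ref)
  expect_equal(as.numeric(bc$counts$A[10:14, 1]), c(1, 1, 0, 1, 1))
})

test_that("engine equals the naive CIGAR-walking oracle under varied filters", {
  ref <- flat_ref(400L)
  set.seed(7)
  settings <- list(
    list(baseq = 13, mapq = 0, excl = c(
      "secondary", "supplementary",
      "duplicate", "qc_fail", "unmapped"
    )),
    list(baseq = 0, mapq = 30, excl = c("unmapped", "secondary")),
    list(baseq = 30, mapq = 0, excl = c("unmapped", "duplicate"))
  )
  for (i in 1:4) {
    records <- rand_alignments(250L, 400L)
    bam <- records_to_bam(records, 400L, tempfile(fileext = ".bam"))
    for (s in settings) {
      f <- pileup_filters(
        min_base_quality = s$baseq, min_mapping_quality = s$mapq,
        exclude_flags = s$excl
      )
      bc <- pileup_well(bam, ref, f)
      expected <- oracle_pileup(records, 400L,
        min_baseq = s$baseq,
        min_mapq = s$mapq, exclude = s$excl
      )
      expect_equal(unname(engine_counts_matrix(bc)), unname(expected),
        ignore_attr = TRUE
      )
    }
  }
})

test_that("well-mode counts agree with Rsamtools::pileup under matched settings", {
  fx <- small_study()
  bam <- fx$study$bam_paths[[1]]
  bc <- pileup_well(bam, fx$ref)
  pp <- Rsamtools::pileup(
    bam,
    scanBamParam = Rsamtools::ScanBamParam(
      which = GenomicRanges::GRanges("chrM", IRanges::IRanges(1, fx$ref$length)),
      flag = Rsamtools::scanBamFlag(
        isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
        isSupplementaryAlignment = FALSE, isDuplicate = FALSE,
        isNotPassingQualityControls = FALSE
      )
    ),
    pileupParam = Rsamtools::PileupParam(
      max_depth = 1e6, min_base_quality = 13L, min_mapq = 0L,
      distinguish_strands = FALSE, include_deletions = FALSE,
      include_insertions = FALSE
    )
  )
  pp <- pp[pp$nucleotide %in% c("A", "C", "G", "T"), ]
  m <- matrix(0, fx$ref$length, 4L)
  m[cbind(pp$pos, match(as.character(pp$nucleotide), c("A", "C", "G", "T")))] <- pp$count
  expect_equal(unname(engine_counts_matrix(bc)), m)
})

test_that("raising quality thresholds never increases any count", {
  ref <- flat_ref(400L)
  set.seed(11)
  records <- rand_alignments(300L, 400L)
  bam <- records_to_bam(records, 400L, tempfile(fileext = ".bam"))
  prev_bq <- NULL
  for (bq in c(0, 10, 20, 35)) {
    bc <- pileup_well(bam, ref, pileup_filters(min_base_quality = bq))
    cur <- engine_counts_matrix(bc)
    if (!is.null(prev_bq)) expect_true(all(cur <= prev_bq))
    prev_bq <- cur
  }
  prev_mq <- NULL
  for (mq in c(0, 20, 40, 61)) {
    bc <- pileup_well(bam, ref, pileup_filters(min_mapping_quality = mq))
    cur <- engine_counts_matrix(bc)
    if (!is.null(prev_mq)) expect_true(all(cur <= prev_mq))
    prev_mq <- cur
  }
})

test_that("reordering input BAMs permutes columns and nothing else", {
  fx <- small_study()
  paths <- fx$study$bam_paths[1:4]
  fwd <- pileup_well(paths, fx$ref)
  rev <- pileup_well(rev(paths), fx$ref)
  expect_equal(rev$cells$cell_id, rev(fwd$cells$cell_id))
  perm <- match(fwd$cells$cell_id, rev$cells$cell_id)
  for (b in c("A", "C", "G", "T")) {
    expect_equal(as.matrix(rev$counts[[b]][, perm]), as.matrix(fwd$counts[[b]]))
  }
})

test_that("contig aliases resolve by length; mismatches and missing index error", {
  ref <- flat_ref() # FASTA record named chrM, 200 bp
  reads <- rec("a1", 20L, strrep("A", 10L))
  bam_mt <- records_to_bam(reads, 200L, tempfile(fileext = ".bam"))
  # same BAM but header contig "MT"
  bam_alias <- tempfile(fileext = ".bam")
  records_to_bam(reads, 200L, bam_alias, contig = "MT")
  bc <- pileup_well(bam_alias, ref)
  expect_equal(as.numeric(bc$counts$A[20, 1]), 1)

  fa_long <- tempfile(fileext = ".fa")
  writeLines(c(">chrM", strrep("A", 300L)), fa_long)
  ref_long <- read_mito_reference(fa_long)
  expect_error(pileup_well(bam_mt, ref_long), "length mismatch")

  no_idx <- tempfile(fileext = ".bam")
  file.copy(bam_mt, no_idx)
  expect_error(pileup_well(no_idx, ref), "index")
})

test_that("droplet mode demultiplexes, thresholds and warns as specified", {
  ref <- flat_ref()
  reads <- dplyr::bind_rows(
    dplyr::bind_rows(lapply(1:5, function(i) rec(paste0("a", i), 10L + i, strrep("A", 10L)))),
    rec("b1", 40L, strrep("A", 10L))
  )
  tags <- c(rep("CB:Z:AAAC", 5L), "CB:Z:TTTG")
  bam <- records_to_bam(reads, 200L, tempfile(fileext = ".bam"), tags = tags)

  bc <- pileup_droplet(bam, ref, min_reads = 3)
  expect_equal(bc$cells$cell_id, "AAAC")
  expect_equal(bc$cells$n_reads, 5L)

  expect_warning(
    bc2 <- pileup_droplet(bam, ref, whitelist = c("AAAC", "GGGT")),
    "GGGT"
  )
  expect_equal(bc2$cells$cell_id, "AAAC")

  expect_error(pileup_droplet(bam, ref, barcode_tag = "XX", min_reads = 1), "never observed")
  expect_error(pileup_droplet(bam, ref, min_reads = 100), "No barcodes retained")
  expect_error(pileup_droplet(bam, ref), "whitelist")
})

test_that("UMI collapse takes the majority base with stated tie-breaks", {
  ref <- flat_ref()
  q40 <- function(n) strrep(rawToChar(as.raw(40L + 33L)), n)
  reads <- dplyr::bind_rows(
    rec("u1", 10L, "G", qual = q30(1)), # UMI m1: G,G,A -> majority G
    rec("u2", 10L, "G", qual = q30(1)),
    rec("u3", 10L, "A", qual = q30(1)),
    rec("u4", 30L, "G", qual = q40(1)), # UMI m2: G(q40),T(q30) -> qual tie-break G
    rec("u5", 30L, "T", qual = q30(1)),
    rec("u6", 50L, "C", qual = q30(1)), # UMI m3: C,T equal count+qual -> alphabetical C
    rec("u7", 50L, "T", qual = q30(1)),
    rec("u8", 70L, "T", qual = q30(1)) # no UMI: individual vote
  )
  tags <- c(
    paste0("CB:Z:AAAC\tUB:Z:m", c(1, 1, 1, 2, 2, 3, 3)),
    "CB:Z:AAAC"
  )
  bam <- records_to_bam(reads, 200L, tempfile(fileext = ".bam"), tags = tags)
  bc <- pileup_droplet(bam, ref, min_reads = 1, umi_collapse = TRUE)
  expect_equal(as.numeric(bc$counts$G[10, 1]), 1)
  expect_equal(as.numeric(bc$counts$A[10, 1]), 0)
  expect_equal(as.numeric(bc$counts$G[30, 1]), 1)
  expect_equal(as.numeric(bc$counts$T[30, 1]), 0)
  expect_equal(as.numeric(bc$counts$C[50, 1]), 1)
  expect_equal(as.numeric(bc$counts$T[50, 1]), 0)
  expect_equal(as.numeric(bc$counts$T[70, 1]), 1)
  # without collapse every read votes
  bc_raw <- pileup_droplet(bam, ref, min_reads = 1)
  expect_equal(as.numeric(bc_raw$counts$G[10, 1]), 2)
  expect_equal(as.numeric(bc_raw$counts$A[10, 1]), 1)
})

test_that("mate-overlap dedup and max_depth caps behave as documented", {
  ref <- flat_ref()
  q40 <- strrep(rawToChar(as.raw(40L + 33L)), 5L)
  mates <- dplyr::bind_rows(
    rec("pair1", 20L, "GGGGG", qual = q40),
    rec("pair1", 22L, "AAAAA", qual = q30(5))
  )
  bam <- records_to_bam(mates, 200L, tempfile(fileext = ".bam"))
  plain <- pileup_well(bam, ref)
  expect_equal(as.numeric(plain$counts$G[22, 1] + plain$counts$A[22, 1]), 2)
  dedup <- pileup_well(bam, ref, pileup_filters(dedup_overlaps = TRUE))
  expect_equal(as.numeric(dedup$counts$G[22:24, 1]), rep(1, 3)) # higher-quality mate wins
  expect_equal(as.numeric(dedup$counts$A[22:24, 1]), rep(0, 3))
  expect_equal(as.numeric(dedup$counts$A[25:26, 1]), rep(1, 2)) # unshared tail kept

  five <- dplyr::bind_rows(lapply(1:5, function(i) rec(paste0("m", i), 30L, "AAAAA")))
  bam5 <- records_to_bam(five, 200L, tempfile(fileext = ".bam"))
  capped <- pileup_well(bam5, ref, pileup_filters(max_depth = 2))
  expect_equal(as.numeric(capped$counts$A[30, 1]), 2)
})

test_that("coverage track aggregates depth and exports mergeable bedGraph", {
  ref <- flat_ref()
  bam1 <- records_to_bam(rec("c1", 100L, "AAGAA"), 200L, tempfile(fileext = ".bam"))
  bc1 <- pileup_well(bam1, ref)
  tr1 <- total_coverage_track(bc1)
  expect_equal(tr1$sum_depth[100:104], rep(1, 5))
  expect_equal(tr1$mean_depth[100], 1)
  expect_equal(sum(tr1$sum_depth), 5)

  bam2 <- records_to_bam(
    dplyr::bind_rows(rec("c2", 100L, "AAAAA"), rec("c3", 100L, "AAAAA")),
    200L, tempfile(fileext = ".bam")
  )
  bc2 <- pileup_well(c(bam1, bam2), ref)
  tr2 <- total_coverage_track(bc2)
  expect_equal(tr2$sum_depth[100], 3)
  expect_equal(tr2$mean_depth[100], 1.5)

  bg <- tempfile(fileext = ".bedGraph")
  write_bedgraph(tr1, bg)
  lines <- readLines(bg)
  expect_equal(lines, "chrM\t99\t104\t1") # 0-based half-open, runs merged

  dup <- records_to_bam(
    rec("z", 10L, "AAAAA", flag = 1024L), 200L,
    tempfile(fileext = ".bam")
  )
  tr0 <- total_coverage_track(pileup_well(dup, ref))
  expect_equal(sum(tr0$sum_depth), 0)
})
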