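# Independent per-read CIGAR-walking pileup oracle plus a random-alignment
# generator. The oracle works directly on the record table the generator
# produced (never on the BAM), so engine and oracle share no code path.

.flag_bits <- c(
  secondary = 256L, supplementary = 2048L,
  duplicate = 1024L, qc_fail = 512L, unmapped = 4L
)

# Naive tally: loop over reads, walk the CIGAR, count A/C/G/T matches.
oracle_pileup <- function(records, L, min_baseq = 13, min_mapq = 0,
                          exclude = c(
                            "secondary", "supplementary", "duplicate",
                            "qc_fail", "unmapped"
                          )) {
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, bases))
  exclude <- union(exclude, "unmapped")
  for (i in seq_len(nrow(records))) {
    flag <- records$flag[i]
    if (any(bitwAnd(flag, .flag_bits[exclude]) != 0L)) next
    mapq <- records$mapq[i]
    if (mapq != 255L && mapq < min_mapq) next
    cigar <- records$cigar[i]
    if (is.na(cigar) || cigar == "*") next
    toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
    lens <- as.integer(sub("[MIDNSHP=X]$", "", toks))
    ops <- sub("^[0-9]+", "", toks)
    sq <- strsplit(records$seq[i], "", fixed = TRUE)[[1]]
    qv <- utf8ToInt(records$qual[i]) - 33L
    qi <- 1L
    ri <- records$pos[i]
    for (k in seq_along(ops)) {
      len <- lens[k]
      op <- ops[k]
      if (op %in% c("M", "=", "X")) {
        pos_v <- ri:(ri + len - 1L)
        b_v <- sq[qi:(qi + len - 1L)]
        q_v <- qv[qi:(qi + len - 1L)]
        bi <- match(b_v, bases)
        keep <- !is.na(bi) & q_v >= min_baseq & pos_v >= 1L & pos_v <= L
        if (any(keep)) {
          idx <- cbind(pos_v[keep], bi[keep])
          counts[idx] <- counts[idx] + 1L
        }
        qi <- qi + len
        ri <- ri + len
      } else if (op %in% c("I", "S")) {
        qi <- qi + len
      } else if (op %in% c("D", "N")) {
        ri <- ri + len
      }
      # H and P consume neither
    }
  }
  counts
}

# Random CIGAR over a fixed query length: optional soft clips, M blocks
# interleaved with I/D/N, occasional hard clips at the ends.
rand_cigar <- function(qlen) {
  lead_s <- if (runif(1) < 0.3 && qlen > 3L) sample.int(min(8L, qlen - 2L), 1L) else 0L
  rest <- qlen - lead_s
  trail_s <- if (runif(1) < 0.3 && rest > 2L) sample.int(min(8L, rest - 1L), 1L) else 0L
  budget <- rest - trail_s
  ops <- character()
  lens <- integer()
  while (budget > 0L) {
    ml <- sample.int(budget, 1L)
    ops <- c(ops, "M")
    lens <- c(lens, ml)
    budget <- budget - ml
    if (budget > 1L && runif(1) < 0.6) {
      op <- sample(c("I", "D", "N"), 1L)
      if (op == "I") {
        il <- sample.int(budget - 1L, 1L)
        ops <- c(ops, "I")
        lens <- c(lens, il)
        budget <- budget - il
      } else {
        ops <- c(ops, op)
        lens <- c(lens, sample.int(15L, 1L))
      }
    }
  }
  if (lead_s > 0L) {
    ops <- c("S", ops)
    lens <- c(lead_s, lens)
  }
  if (trail_s > 0L) {
    ops <- c(ops, "S")
    lens <- c(lens, trail_s)
  }
  if (runif(1) < 0.1) {
    ops <- c("H", ops)
    lens <- c(sample.int(5L, 1L), lens)
  }
  paste0(lens, ops, collapse = "")
}

.cigar_refspan <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[MIDNSHP=X]$", "", toks))
  ops <- sub("^[0-9]+", "", toks)
  sum(lens[ops %in% c("M", "D", "N", "=", "X")])
}

# Random alignment records with varied CIGARs, qualities and flags.
rand_alignments <- function(n_reads, L) {
  recs <- lapply(seq_len(n_reads), function(i) {
    qlen <- sample(30:80, 1L)
    unmapped <- runif(1) < 0.03
    cigar <- if (unmapped) "*" else rand_cigar(qlen)
    span <- if (unmapped) 1L else .cigar_refspan(cigar)
    pos <- sample.int(max(L - span, 1L), 1L)
    flag <- 0L
    if (runif(1) < 0.5) flag <- bitwOr(flag, 16L) # reverse strand
    if (runif(1) < 0.10) flag <- bitwOr(flag, 1024L) # duplicate
    if (runif(1) < 0.07) flag <- bitwOr(flag, 256L) # secondary
    if (runif(1) < 0.05) flag <- bitwOr(flag, 2048L) # supplementary
    if (runif(1) < 0.05) flag <- bitwOr(flag, 512L) # qc fail
    if (unmapped) flag <- bitwOr(flag, 4L)
    sq <- paste(
      sample(c("A", "C", "G", "T", "N"), qlen,
        replace = TRUE,
        prob = c(0.24, 0.24, 0.24, 0.24, 0.04)
      ),
      collapse = ""
    )
    qual <- intToUtf8(sample(2:40, qlen, replace = TRUE) + 33L)
    list(
      qname = sprintf("r%05d", i), flag = flag, pos = pos,
      mapq = sample(c(0:60, 255L), 1L), cigar = cigar,
      seq = sq, qual = qual
    )
  })
  dplyr::bind_rows(recs)
}

# Write a record table as a coordinate-sorted, indexed BAM.
records_to_bam <- function(records, L, bam_path, contig = "chrM",
                           tags = NULL) {
  ord <- order(records$pos)
  records <- records[ord, , drop = FALSE]
  if (!is.null(tags)) tags <- tags[ord]
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    paste0("@SQ\tSN:", contig, "\tLN:", L)
  )
  body <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
    records$qname, records$flag, contig, records$pos, records$mapq,
    records$cigar, records$seq, records$qual
  )
  if (!is.null(tags)) body <- paste0(body, "\t", tags)
  sam <- tempfile(fileext = ".sam")
  writeLines(c(header, body), sam)
  Rsamtools::asBam(sam,
    destination = sub("\\.bam$", "", bam_path),
    overwrite = TRUE, indexDestination = TRUE
  )
  unlink(sam)
  bam_path
}

engine_counts_matrix <- function(basecounts, cell = 1L) {
  sapply(c("A", "C", "G", "T"), function(b) {
    as.numeric(basecounts$counts[[b]][, cell])
  })
}
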