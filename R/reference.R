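#' Load a mitochondrial reference sequence
#'
#' Reads a (optionally bgzipped) FASTA file and returns the mitochondrial
#' contig as a `mito_reference` object: the contig name, the upper-cased
#' sequence and its length. The reference is the source of all "ref" alleles
#' downstream and defines the 1-based coordinate system used in variant
#' labels such as `3243A>G`.
#'
#' @param fasta_path Path to a FASTA file. May contain several records.
#' @param contig Name of the record to use. May be omitted when the file
#'   contains exactly one record.
#' @return A `mito_reference` object (list with `contig`, `sequence`,
#'   `length`).
#' @details Soft-masked (lower-case) bases are upper-cased, not rejected.
#'   Any character outside `A`, `C`, `G`, `T`, `N` is an error. Positions
#'   whose reference base is `N` (such as rCRS position 3107) carry no
#'   alternative-allele definition but still receive coverage values.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrM", "ACGTACGTNN"), fa)
#' ref <- read_mito_reference(fa)
#' ref$length
#' @export
read_mito_reference <- function(fasta_path, contig = NULL) {
  if (!file.exists(fasta_path)) {
    abort(paste0("FASTA file not found: ", fasta_path))
  }
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  # readDNAStringSet keeps the full description line; the contig name is the
  # first whitespace-delimited token
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (is.null(contig)) {
    if (length(seqs) != 1L) {
      abort(paste0(
        "FASTA contains ", length(seqs),
        " records; supply `contig` to select one."
      ))
    }
    contig <- names(seqs)[1L]
  } else {
    if (!contig %in% names(seqs)) {
      abort(paste0(
        "Contig '", contig, "' not found in ", fasta_path,
        " (records: ", paste(head(names(seqs), 5L), collapse = ", "), ")"
      ))
    }
  }
  sq <- toupper(as.character(seqs[[contig]]))
  bad <- setdiff(unique(strsplit(sq, "", fixed = TRUE)[[1L]]), c("A", "C", "G", "T", "N"))
  if (length(bad) > 0L) {
    abort(paste0(
      "Reference contains characters outside {A,C,G,T,N}: ",
      paste(bad, collapse = ", ")
    ))
  }
  new_mito_reference(contig, sq)
}

new_mito_reference <- function(contig, sequence) {
  structure(
    list(contig = contig, sequence = sequence, length = nchar(sequence)),
    class = "mito_reference"
  )
}

#' @export
print.mito_reference <- function(x, ...) {
  cat("<mito_reference> ", x$contig, ": ", format(x$length, big.mark = ","),
    " bp\n",
    sep = ""
  )
  invisible(x)
}

ref_base_at <- function(reference, position) {
  substring(reference$sequence, position, position)
}

#' Parse variant labels of the form "3243A>G"
#'
#' Vectorised over `label`. Labels use standard mtDNA nomenclature:
#' 1-based position, reference base, `>`, alternative base, no separators.
#'
#' @param label Character vector of labels matching `^[0-9]+[ACGT]>[ACGT]$`.
#' @param reference Optional `mito_reference`; when supplied, positions are
#'   checked against the contig length and the stated ref base must match
#'   the reference sequence.
#' @return A tibble with columns `label`, `position`, `ref`, `alt`.
#' @examples
#' parse_variant_label(c("3243A>G", "12139T>A"))
#' @export
parse_variant_label <- function(label, reference = NULL) {
  ok <- grepl("^[0-9]+[ACGT]>[ACGT]$", label)
  if (!all(ok)) {
    abort(paste0(
      "Malformed variant label(s): ",
      paste(head(label[!ok], 5L), collapse = ", "),
      " (expected e.g. '3243A>G')"
    ))
  }
  position <- as.integer(sub("^([0-9]+).*$", "\\1", label))
  ref <- sub("^[0-9]+([ACGT])>.*$", "\\1", label)
  alt <- sub("^.*>([ACGT])$", "\\1", label)
  if (any(position < 1L)) {
    abort("Variant positions are 1-based; position 0 is out of range.")
  }
  if (any(ref == alt)) {
    abort("Variant alt base must differ from the ref base.")
  }
  if (!is.null(reference)) {
    if (any(position > reference$length)) {
      abort(paste0(
        "Position out of range (reference length ", reference$length, ")."
      ))
    }
    seen <- substring(reference$sequence, position, position)
    bad <- seen != ref
    if (any(bad)) {
      abort(paste0(
        "Ref base mismatch at ", paste(head(label[bad], 5L), collapse = ", "),
        ": reference has ", paste(head(seen[bad], 5L), collapse = ", ")
      ))
    }
  }
  tibble(label = label, position = position, ref = ref, alt = alt)
}

#' Format variant coordinates as labels
#'
#' @param position 1-based integer position(s).
#' @param ref,alt Single reference / alternative bases.
#' @return Character vector of labels like `"3243A>G"`.
#' @export
format_variant_label <- function(position, ref, alt) {
  paste0(position, ref, ">", alt)
}

#' Enumerate every possible single-nucleotide variant of a reference
#'
#' For each position with reference base in `{A,C,G,T}` there are exactly
#' three alternative alleles; `N` positions contribute none. Rows are
#' ordered by position, then alt base (`A < C < G < T`). This ordering is
#' the row universe of every alt-count and allele-frequency matrix, so two
#' runs over the same reference are always row-aligned.
#'
#' @param reference A `mito_reference`.
#' @return A tibble with columns `label`, `position`, `ref`, `alt`.
#' @export
enumerate_variants <- function(reference) {
  bases <- c("A", "C", "G", "T")
  refv <- strsplit(reference$sequence, "", fixed = TRUE)[[1L]]
  pos <- rep(seq_len(reference$length), each = 4L)
  alt <- rep(bases, times = reference$length)
  ref <- refv[pos]
  keep <- ref %in% bases & alt != ref
  tibble(
    label = format_variant_label(pos[keep], ref[keep], alt[keep]),
    position = pos[keep],
    ref = ref[keep],
    alt = alt[keep]
  )
}
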