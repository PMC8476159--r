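# Alignment and pairing-map I/O.  Column indices in pairing files are
# 0-based; alignments are plain character matrices (taxa x columns).

DOUBLET_SYMBOLS <- c(0:9, LETTERS[1:6])  # lexicographic 0..F recoding

#' Read a nucleotide alignment
#'
#' FASTA (`.fa`, `.fasta`, `.fna`) or NEXUS (`.nex`, `.nexus`); the format is
#' inferred from the extension.  IUPAC ambiguity codes and gaps are passed
#' through (upper-cased).  Duplicate taxon names are rejected.
#'
#' @param path File path.
#' @return Character matrix (taxa x columns) with taxon rownames.
#' @export
read_alignment <- function(path) {
  fmt <- alignment_format(path)
  m <- if (fmt == "fasta") {
    x <- ape::read.FASTA(path)
    if (anyDuplicated(names(x))) stop("duplicate taxon names in ", path)
    toupper(as.character(as.matrix(x)))
  } else {
    x <- ape::read.nexus.data(path)
    if (anyDuplicated(names(x))) stop("duplicate taxon names in ", path)
    toupper(do.call(rbind, x))
  }
  rownames(m) <- if (is.null(rownames(m))) names(m) else rownames(m)
  m
}

alignment_format <- function(path) {
  if (grepl("\\.(nex|nexus)$", path, ignore.case = TRUE)) "nexus" else "fasta"
}

#' Write a nucleotide alignment
#'
#' Writes FASTA or NEXUS (inferred from the extension).  With
#' `recode_doublets = TRUE` (NEXUS only) each epistatic column pair is
#' exported as a single standard-character column using the lexicographic
#' doublet code 0..F (so the doublet (A,T) -- index 3 -- becomes `"3"`),
#' after the independent columns.
#'
#' @param aln `"paired_alignment"` or character matrix.
#' @param path Output path.
#' @param recode_doublets Recode pairs as 16-state standard characters
#'   (requires a `"paired_alignment"` and a NEXUS target).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, recode_doublets = FALSE) {
  fmt <- alignment_format(path)
  m <- as_char_alignment(aln)
  if (recode_doublets) {
    if (!inherits(aln, "paired_alignment"))
      stop("doublet recoding needs a paired_alignment")
    if (fmt != "nexus") stop("doublet recoding is supported for NEXUS output")
    map <- aln$map
    ind <- m[, map$independent + 1L, drop = FALSE]
    code <- NULL
    if (nrow(map$pairs)) {
      c5 <- aln_codes(m[, map$pairs[, 1L] + 1L, drop = FALSE])
      c3 <- aln_codes(m[, map$pairs[, 2L] + 1L, drop = FALSE])
      code <- matrix(DOUBLET_SYMBOLS[(c5 - 1L) * 4L + c3], nrow = nrow(m))
    }
    m <- cbind(ind, code)
    rownames(m) <- rownames(as_char_alignment(aln))
    ape::write.nexus.data(split_rows(m), path, format = "standard",
                          interleaved = FALSE)
    return(invisible(path))
  }
  if (fmt == "fasta") {
    lines <- character(2L * nrow(m))
    lines[c(TRUE, FALSE)] <- paste0(">", rownames(m))
    lines[c(FALSE, TRUE)] <- apply(m, 1L, paste0, collapse = "")
    writeLines(lines, path)
  } else {
    ape::write.nexus.data(split_rows(m), path, format = "dna",
                          interleaved = FALSE)
  }
  invisible(path)
}

split_rows <- function(m) {
  stats::setNames(lapply(seq_len(nrow(m)), function(i) m[i, ]), rownames(m))
}

#' Read and write pairing maps
#'
#' Tab-separated, two columns (5' index, 3' index), 0-based, no header.
#' On reading, all remaining columns `0..n-1` are treated as independent.
#'
#' @param path File path.
#' @param map A `"pairing_map"`.
#' @param n Total number of alignment columns (needed on read to recover the
#'   independent set).
#' @return `read_pairing_map()` returns a `"pairing_map"`.
#' @export
read_pairing_map <- function(path, n) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           colClasses = "integer")
  pairs <- as.matrix(tab[, 1:2])
  independent <- setdiff(seq_len(n) - 1L, as.vector(pairs))
  pairing_map(pairs = pairs, independent = independent)
}

#' @rdname read_pairing_map
#' @export
write_pairing_map <- function(map, path) {
  stopifnot(inherits(map, "pairing_map"))
  utils::write.table(map$pairs, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
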