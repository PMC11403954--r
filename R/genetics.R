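# Small sequence utilities shared by the simulator and the annotator.
# The genetic code is the standard nuclear code (Biostrings::GENETIC_CODE).

DNA_BASES <- c("A", "C", "G", "T")

# 61 sense codons; stop codons are never emitted inside simulated CDS
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

#' Complement / reverse-complement of DNA strings
#'
#' Thin vectorised wrappers used throughout the package; sequences are plain
#' upper-case character strings internally.
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @keywords internal
dna_complement <- function(x) chartr("ACGT", "TGCA", x)

#' @rdname dna_complement
#' @keywords internal
dna_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate codons with the standard genetic code
#'
#' @param codons character vector of 3-base strings.
#' @return character vector of single-letter amino acids ("*" for stop).
#' @keywords internal
translate_codon <- function(codons) {
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) stop("invalid codon(s): ",
                      paste(codons[is.na(aa)], collapse = ", "))
  aa
}

#' Spliced coding sequence of a gene model
#'
#' Concatenates the CDS intervals of `gene` from the contig sequence and, for
#' minus-strand genes, reverse-complements the result so the returned string
#' is the mRNA-sense coding sequence.
#'
#' @param reference named character vector of contig sequences.
#' @param gene a gene model as produced by [generate_reference_and_genes()]
#'   or [read_gene_models()].
#' @return a single character string whose length is the coding length.
#' @export
spliced_cds <- function(reference, gene) {
  contig <- reference[[gene$contig]]
  if (is.null(contig)) stop("contig not in reference: ", gene$contig)
  iv <- gene$cds_intervals
  chunks <- substring(contig, iv$start + 1L, iv$end)
  cds <- paste(chunks, collapse = "")
  if (gene$strand == "-") cds <- dna_revcomp(cds)
  cds
}

# 0-based CDS coordinate of a 0-based contig position, or NA when the
# position falls outside every CDS interval.  Minus-strand genes count from
# the rightmost interval inward.
cds_coordinate <- function(gene, pos0) {
  iv <- gene$cds_intervals
  hit <- which(pos0 >= iv$start & pos0 < iv$end)
  if (length(hit) == 0L) return(NA_integer_)
  lens <- iv$end - iv$start
  if (gene$strand == "+") {
    before <- if (hit > 1L) sum(lens[seq_len(hit - 1L)]) else 0L
    as.integer(before + (pos0 - iv$start[hit]))
  } else {
    after <- if (hit < nrow(iv)) sum(lens[seq(hit + 1L, nrow(iv))]) else 0L
    as.integer(after + (iv$end[hit] - 1L - pos0))
  }
}

# Inverse of cds_coordinate: contig position of a 0-based CDS coordinate.
contig_coordinate <- function(gene, cds_pos0) {
  iv <- gene$cds_intervals
  lens <- iv$end - iv$start
  if (gene$strand == "+") {
    cum <- cumsum(lens)
    hit <- which(cds_pos0 < cum)[1L]
    before <- if (hit > 1L) cum[hit - 1L] else 0L
    as.integer(iv$start[hit] + (cds_pos0 - before))
  } else {
    lens_rev <- rev(lens)
    cum <- cumsum(lens_rev)
    hit_rev <- which(cds_pos0 < cum)[1L]
    before <- if (hit_rev > 1L) cum[hit_rev - 1L] else 0L
    hit <- nrow(iv) - hit_rev + 1L
    as.integer(iv$end[hit] - 1L - (cds_pos0 - before))
  }
}
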