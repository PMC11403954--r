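#' Generate the synthetic reference and gene models
#'
#' Emits one contig per gene: a random flanking sequence of `flank` bp, the
#' CDS split into exons separated by short introns, and another `flank` bp
#' of right flank.  The coding sequence is drawn codon-wise from the 61
#' sense codons, so it translates without internal stop codons; minus-strand
#' genes carry the reverse complement on the contig.
#'
#' @param gene_plan data.frame with columns `gene`, `coding_length`,
#'   `strand` (see [default_gene_plan()]).
#' @param flank flanking sequence on each side of the CDS span (bp).
#'   Defaults to 50 kb, the window also used by the differentiation PCA.
#' @param intron_length length of each intron (bp).
#' @param exon_target approximate exon size used to decide the exon count.
#' @param seed optional integer; when non-NULL, `set.seed()` is called so
#'   the same plan and seed give a byte-identical reference.
#' @return list with `reference` (named character vector of contig
#'   sequences) and `genes` (named list of gene models: `name`, `contig`,
#'   `strand`, `cds_intervals` data.frame of 0-based half-open intervals,
#'   `coding_length`).
#' @export
generate_reference_and_genes <- function(gene_plan = default_gene_plan(),
                                         flank = 50000L,
                                         intron_length = 300L,
                                         exon_target = 6000L,
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(gene_plan$coding_length %% 3L != 0L))
    stop("coding_length must be divisible by 3 for every gene")
  if (anyDuplicated(gene_plan$gene)) stop("duplicate gene names in plan")
  sense <- sense_codons()
  reference <- character(0)
  genes <- list()
  for (i in seq_len(nrow(gene_plan))) {
    gname <- gene_plan$gene[i]
    len <- gene_plan$coding_length[i]
    strand <- gene_plan$strand[i]
    cds <- paste(sample(sense, len %/% 3L, replace = TRUE), collapse = "")

    n_exon <- max(1L, as.integer(ceiling(len / exon_target)))
    base_sz <- len %/% n_exon
    sizes <- rep(base_sz, n_exon)
    sizes[n_exon] <- sizes[n_exon] + (len - sum(sizes))
    ends <- cumsum(sizes)
    starts <- c(1L, ends[-n_exon] + 1L)
    chunks <- substring(cds, starts, ends)      # mRNA order, 5'->3'
    exon_seqs <- if (strand == "+") chunks else rev(dna_revcomp(chunks))

    rand_seq <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                  collapse = "")
    pieces <- character(0)
    iv_start <- integer(n_exon); iv_end <- integer(n_exon)
    cursor <- flank
    pieces <- c(pieces, rand_seq(flank))
    for (e in seq_len(n_exon)) {
      if (e > 1L) {
        pieces <- c(pieces, rand_seq(intron_length))
        cursor <- cursor + intron_length
      }
      iv_start[e] <- cursor
      w <- nchar(exon_seqs[e])
      iv_end[e] <- cursor + w
      cursor <- cursor + w
      pieces <- c(pieces, exon_seqs[e])
    }
    pieces <- c(pieces, rand_seq(flank))
    contig_name <- paste0("ctg_", gname)
    reference[contig_name] <- paste(pieces, collapse = "")
    genes[[gname]] <- list(name = gname, contig = contig_name,
                           strand = strand,
                           cds_intervals = data.frame(start = iv_start,
                                                      end = iv_end),
                           coding_length = as.integer(len))
  }
  list(reference = reference, genes = genes)
}
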