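# All on-disk coordinates follow the conventions of their formats (1-based
# for VCF/GFF3 and every TSV this package writes); internal coordinates are
# 0-based half-open throughout.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

read_tsv_strict <- function(path, required, what = "table") {
  if (!file.exists(path)) stop("missing ", what, " file: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(what, " file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  df
}

#' Read / write the reference FASTA
#'
#' @param reference named character vector of contig sequences.
#' @param path file path.
#' @return `read_fasta` returns a named character vector.
#' @export
write_fasta <- function(reference, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reference), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  setNames(as.character(x), names(x))
}

#' Write gene models as GFF3
#'
#' Emits one `gene` feature and its `CDS` features per gene, with `phase`
#' computed in translation order.
#'
#' @param genes named list of gene models.
#' @param path output path.
#' @export
write_gene_models <- function(genes, path) {
  grl <- lapply(genes, function(g) {
    iv <- g$cds_intervals
    n <- nrow(iv)
    lens <- iv$end - iv$start
    order_tx <- if (g$strand == "+") seq_len(n) else rev(seq_len(n))
    before <- c(0L, cumsum(lens[order_tx]))[seq_len(n)]
    phase_tx <- (3L - before %% 3L) %% 3L
    phase <- integer(n); phase[order_tx] <- phase_tx
    gr <- GenomicRanges::GRanges(
      seqnames = g$contig,
      ranges = IRanges::IRanges(start = c(min(iv$start) + 1L, iv$start + 1L),
                                end = c(max(iv$end), iv$end)),
      strand = g$strand)
    S4Vectors::mcols(gr)$type <- c("gene", rep("CDS", n))
    S4Vectors::mcols(gr)$ID <- c(g$name, sprintf("%s.cds%d", g$name,
                                                 seq_len(n)))
    S4Vectors::mcols(gr)$Parent <- c(NA_character_, rep(g$name, n))
    S4Vectors::mcols(gr)$gene_id <- g$name
    S4Vectors::mcols(gr)$phase <- c(NA_integer_, phase)
    gr
  })
  gr <- suppressWarnings(do.call(c, unname(grl)))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Keeps `CDS` features, grouped by `gene_id` (falling back to `Parent`),
#' converts to 0-based half-open intervals sorted ascending, and records
#' strand and coding length.  A gene whose summed CDS length is not
#' divisible by 3 triggers a warning and is flagged (`frame_ok = FALSE`).
#'
#' @param path GFF3 file with CDS features.
#' @return named list of gene models (`name`, `contig`, `strand`,
#'   `cds_intervals`, `coding_length`, `frame_ok`).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[S4Vectors::mcols(gr)$type == "CDS"]
  if (length(cds) == 0L) stop("no CDS features in ", path)
  ids <- S4Vectors::mcols(cds)$gene_id
  if (is.null(ids)) {
    par <- S4Vectors::mcols(cds)$Parent
    ids <- vapply(as.list(par), function(p) as.character(p)[1], character(1))
  }
  genes <- list()
  for (g in unique(ids)) {
    sub <- cds[ids == g]
    sub <- sort(sub)
    iv <- data.frame(start = GenomicRanges::start(sub) - 1L,
                     end = GenomicRanges::end(sub))
    iv <- iv[order(iv$start), , drop = FALSE]
    merged <- IRanges::reduce(IRanges::IRanges(iv$start + 1L, iv$end))
    iv <- data.frame(start = IRanges::start(merged) - 1L,
                     end = IRanges::end(merged))
    rownames(iv) <- NULL
    len <- sum(iv$end - iv$start)
    frame_ok <- len %% 3L == 0L
    if (!frame_ok)
      warning("CDS length of gene ", g, " is not divisible by 3")
    genes[[g]] <- list(name = g,
                       contig = as.character(GenomicRanges::seqnames(sub))[1],
                       strand = as.character(BiocGenerics::strand(sub))[1],
                       cds_intervals = iv,
                       coding_length = as.integer(len),
                       frame_ok = frame_ok)
  }
  genes
}

#' Write a genotype set as VCF 4.2
#'
#' Emits GT (allele indexes against REF,ALT), DP and AD per sample.
#'
#' @param geno a [genotype_set()].
#' @param path output path (plain text `.vcf`).
#' @param contig_lengths optional named integer vector for `##contig`
#'   header lines.
#' @export
write_vcf_genotypes <- function(geno, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=paleofix")
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), contig_lengths))
  hdr <- c(hdr,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$samples$sample_id), collapse = "\t"))
  n <- nrow(geno$sites)
  body <- character(n)
  for (s in seq_len(n)) {
    alleles <- c(geno$sites$ref[s],
                 strsplit(geno$sites$alt[s], ",", fixed = TRUE)[[1]])
    gt_idx <- vapply(geno$gt[s, ], function(g) {
      if (is.na(g)) return("./.")
      pair <- strsplit(g, "/", fixed = TRUE)[[1]]
      idx <- sort(match(pair, alleles) - 1L)
      if (anyNA(idx)) stop("genotype allele not in REF/ALT at site ", s)
      paste(idx, collapse = "/")
    }, character(1))
    ad <- geno$ad[s, ]
    ad[is.na(ad)] <- paste(rep("0", length(alleles)), collapse = ",")
    fields <- paste(gt_idx, geno$dp[s, ], ad, sep = ":")
    body[s] <- paste(c(geno$sites$contig[s], geno$sites$pos[s] + 1L, ".",
                       geno$sites$ref[s], geno$sites$alt[s], ".", "PASS",
                       ".", "GT:DP:AD", fields), collapse = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Uses `VariantAnnotation::readVcf()` and converts to the internal
#' [genotype_set()]: 1-based VCF positions become 0-based, missing GT
#' becomes a missing genotype (the site is retained), and per-sample depth
#' is taken from DP, else the sum of AD, else missing.
#'
#' @param path VCF file.
#' @param metadata sample metadata data.frame ([read_sample_metadata()]);
#'   the VCF sample columns must be a subset of its `sample_id`s.
#' @return a [genotype_set()].
#' @export
read_vcf_genotypes <- function(path, metadata) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  vcf_samples <- colnames(vcf)
  extra <- setdiff(vcf_samples, metadata$sample_id)
  if (length(extra))
    stop("VCF sample(s) absent from metadata: ", paste(extra, collapse = ", "))
  samples <- metadata[match(vcf_samples, metadata$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  alt_list <- VariantAnnotation::alt(vcf)
  alt_chr <- vapply(as.list(alt_list),
                    function(a) paste(as.character(a), collapse = ","),
                    character(1))
  sites <- data.frame(
    contig = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr) - 1L,
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = alt_chr, stringsAsFactors = FALSE)
  g <- VariantAnnotation::geno(vcf)
  gt_raw <- g$GT
  n <- nrow(sites); m <- length(vcf_samples)
  gt <- matrix(NA_character_, n, m)
  for (s in seq_len(n)) {
    alleles <- c(sites$ref[s], strsplit(sites$alt[s], ",", fixed = TRUE)[[1]])
    raw <- gt_raw[s, ]
    ok <- !is.na(raw) & raw != "./." & raw != "." & raw != ".|."
    if (any(ok)) {
      idx <- strsplit(gsub("|", "/", raw[ok], fixed = TRUE), "/", fixed = TRUE)
      gt[s, ok] <- vapply(idx, function(i) {
        b <- alleles[as.integer(i) + 1L]
        if (anyNA(b)) stop("malformed GT at record ", s)
        geno_str(b[1], b[2])
      }, character(1))
    }
  }
  if (!is.null(g$DP)) {
    dp <- matrix(as.integer(g$DP), n, m)
  } else {
    dp <- matrix(NA_integer_, n, m)
  }
  ad <- matrix(NA_character_, n, m)
  if (!is.null(g$AD)) {
    adr <- g$AD
    for (s in seq_len(n)) for (j in seq_len(m)) {
      v <- adr[s, j][[1]]
      if (!all(is.na(v))) {
        ad[s, j] <- paste(v, collapse = ",")
        if (is.na(dp[s, j])) dp[s, j] <- sum(v, na.rm = TRUE)
      }
    }
  }
  genotype_set(sites, gt, dp, ad, samples)
}

#' Read / write sample metadata
#'
#' TSV with columns `sample_id`, `species` (polar/brown/outgroup), `era`
#' (modern/ancient) and optional `taxon`.
#'
#' @param path file path.
#' @param metadata data.frame to write.
#' @return `read_sample_metadata` returns the validated data.frame.
#' @export
read_sample_metadata <- function(path) {
  df <- read_tsv_strict(path, c("sample_id", "species", "era"),
                        "sample metadata")
  if (nrow(df) == 0L) stop("empty sample metadata file: ", path)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata: column sample_id")
  bad <- setdiff(df$species, c("polar", "brown", "outgroup"))
  if (length(bad)) stop("invalid species value(s): column species: ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(df$era, c("modern", "ancient"))
  if (length(bad)) stop("invalid era value(s): column era: ",
                        paste(bad, collapse = ", "))
  if (is.null(df$taxon)) df$taxon <- NA_character_
  df
}

#' @rdname read_sample_metadata
#' @export
write_sample_metadata <- function(metadata, path) write_tsv(metadata, path)

#' Read / write ancient base counts
#'
#' TSV columns `contig`, `pos` (1-based on disk), `sample_id`, `nA`, `nC`,
#' `nG`, `nT`; internal positions are 0-based.
#'
#' @param counts data.frame as returned by [count_bases_from_reads()].
#' @param path file path.
#' @export
write_base_counts <- function(counts, path) {
  out <- counts
  out$pos <- out$pos + 1L
  write_tsv(out, path)
}

#' @rdname write_base_counts
#' @export
read_base_counts <- function(path) {
  df <- read_tsv_strict(path, c("contig", "pos", "sample_id",
                                "nA", "nC", "nG", "nT"), "base count")
  cnt <- as.matrix(df[, c("nA", "nC", "nG", "nT")])
  if (any(cnt < 0)) stop("negative counts: columns nA..nT")
  df$pos <- as.integer(df$pos) - 1L
  df
}

#' Read / write the planted truth table
#'
#' @param truth truth table ([plant_site_truth()]).
#' @param path file path.
#' @export
write_truth_table <- function(truth, path) {
  out <- truth
  out$pos <- out$pos + 1L
  write_tsv(out, path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  df <- read_tsv_strict(path, c("gene", "contig", "pos", "class",
                                "ancestral", "derived", "brown_freq"),
                        "truth table")
  df$pos <- as.integer(df$pos) - 1L
  df
}

#' Read / write simulated reads
#'
#' TSV columns `sample_id`, `contig`, `start` (1-based on disk), `seq`.
#'
#' @param reads data.frame with 0-based `start`.
#' @param path file path.
#' @export
write_reads <- function(reads, path) {
  out <- reads
  out$start <- out$start + 1L
  write_tsv(out, path)
}

#' @rdname write_reads
#' @export
read_reads <- function(path) {
  df <- read_tsv_strict(path, c("sample_id", "contig", "start", "seq"),
                        "read")
  df$start <- as.integer(df$start) - 1L
  df
}

#' Write / re-read the per-site classification report
#'
#' One row per candidate site with filter fate, polarity, origin class,
#' brown-bear derived-allele frequency, per-ancient states and the
#' asterisk-style `not_fixed_in_ancient` flag.  Column order is fixed so
#' reruns are byte-identical.
#'
#' @param report classification data.frame from [run_pipeline()].
#' @param path file path.
#' @export
write_site_report <- function(report, path) {
  out <- report
  out$pos <- out$pos + 1L
  write_tsv(out, path)
}

#' @rdname write_site_report
#' @export
read_site_report <- function(path) {
  df <- read_tsv_strict(path, c("contig", "pos", "gene", "origin_class"),
                        "site report")
  df$pos <- as.integer(df$pos) - 1L
  df
}
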