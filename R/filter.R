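#' Filtering thresholds
#'
#' @param min_depth minimum per-individual read depth for a genotype call
#'   to be used (default 4, the published rule).
#' @param min_callable_fraction minimum fraction of callable individuals
#'   required in each species group (modern polar; brown) before a site is
#'   considered for fixation calls.  The published analysis states a
#'   completeness rule only for the PCA; this guard (default 0.9) keeps
#'   "fixed" from being decided from a handful of individuals.
#' @return list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_depth = 4L, min_callable_fraction = 0.9) {
  if (min_depth < 1L) stop("min_depth must be >= 1")
  if (min_callable_fraction <= 0 || min_callable_fraction > 1)
    stop("min_callable_fraction must lie in (0, 1]")
  structure(list(min_depth = as.integer(min_depth),
                 min_callable_fraction = min_callable_fraction),
            class = "filter_thresholds")
}

#' Mask genotypes below the depth threshold
#'
#' Sets a genotype to missing wherever the sample's depth at the site is
#' below `min_depth` (or unknown); depths are left untouched, so the
#' operation is idempotent.
#'
#' @param geno a [genotype_set()].
#' @param min_depth depth threshold (default 4).
#' @return the masked [genotype_set()].
#' @export
apply_depth_mask <- function(geno, min_depth = 4L) {
  geno$gt[is.na(geno$dp) | geno$dp < min_depth] <- NA_character_
  geno
}

# per-site vector of alleles observed among non-missing genotypes
observed_alleles <- function(gt_row) {
  g <- gt_row[!is.na(gt_row)]
  if (length(g) == 0L) return(character(0))
  sort(unique(unlist(strsplit(g, "/", fixed = TRUE), use.names = FALSE)))
}

#' Allelic state from observed genotypes
#'
#' Judged on the alleles actually observed among non-missing genotypes of
#' all samples (a listed-but-unobserved VCF ALT does not make a site
#' tri-allelic).
#'
#' @param geno a depth-masked [genotype_set()].
#' @return character vector per site: `"monomorphic"`, `"biallelic"` or
#'   `"multiallelic"` (sites with no callable genotype are
#'   `"monomorphic"`).
#' @export
classify_allelic_state <- function(geno) {
  vapply(seq_len(nrow(geno$sites)), function(s) {
    k <- length(observed_alleles(geno$gt[s, ]))
    if (k > 2L) "multiallelic" else if (k == 2L) "biallelic" else "monomorphic"
  }, character(1))
}

#' Coding-effect annotation of biallelic sites
#'
#' Maps each site into the CDS of the gene on its contig (honouring
#' strand: minus-strand alleles are complemented into the codon), builds
#' the reference and alternative codon, and translates both with the
#' standard genetic code.  The substituted allele is the observed (or
#' listed) allele other than the contig reference base.
#'
#' @param sites site table (`contig`, `pos`, `ref`, `alt`).
#' @param genes named list of gene models.
#' @param reference named character vector of contig sequences.
#' @param alt_allele optional character vector overriding the substituted
#'   allele per site (defaults to the first ALT).
#' @return data.frame, one row per site: `gene`, `in_cds`, `codon_index`
#'   (0-based), `codon_position` (1-3), `ref_codon`, `alt_codon`, `ref_aa`,
#'   `alt_aa`, `is_nonsynonymous`.
#' @export
annotate_coding_effect <- function(sites, genes, reference,
                                   alt_allele = NULL) {
  gene_by_contig <- setNames(names(genes),
                             vapply(genes, `[[`, "", "contig"))
  cds_cache <- lapply(genes, function(g) spliced_cds(reference, g))
  n <- nrow(sites)
  out <- data.frame(gene = NA_character_, in_cds = FALSE,
                    codon_index = NA_integer_, codon_position = NA_integer_,
                    ref_codon = NA_character_, alt_codon = NA_character_,
                    ref_aa = NA_character_, alt_aa = NA_character_,
                    is_nonsynonymous = NA, stringsAsFactors = FALSE)
  out <- out[rep(1L, n), , drop = FALSE]
  rownames(out) <- NULL
  if (n == 0L) return(out)
  for (s in seq_len(n)) {
    gname <- unname(gene_by_contig[sites$contig[s]])
    if (is.na(gname)) next
    gene <- genes[[gname]]
    out$gene[s] <- gname
    cpos <- cds_coordinate(gene, sites$pos[s])
    if (is.na(cpos)) next
    out$in_cds[s] <- TRUE
    contig_base <- substr(reference[[gene$contig]], sites$pos[s] + 1L,
                          sites$pos[s] + 1L)
    if (contig_base != sites$ref[s])
      stop(sprintf("reference mismatch at %s:%d: VCF ref %s, sequence %s",
                   sites$contig[s], sites$pos[s] + 1L, sites$ref[s],
                   contig_base))
    alt <- if (!is.null(alt_allele)) alt_allele[s] else
      strsplit(sites$alt[s], ",", fixed = TRUE)[[1]][1]
    to_cds <- if (gene$strand == "+") identity else dna_complement
    cds <- cds_cache[[gname]]
    ci <- cpos %/% 3L
    cp <- cpos %% 3L + 1L
    ref_codon <- substr(cds, ci * 3L + 1L, ci * 3L + 3L)
    alt_codon <- ref_codon
    substr(alt_codon, cp, cp) <- to_cds(alt)
    stopifnot(substr(ref_codon, cp, cp) == to_cds(contig_base))
    out$codon_index[s] <- ci
    out$codon_position[s] <- cp
    out$ref_codon[s] <- ref_codon
    out$alt_codon[s] <- alt_codon
    out$ref_aa[s] <- translate_codon(ref_codon)
    out$alt_aa[s] <- translate_codon(alt_codon)
    out$is_nonsynonymous[s] <- out$ref_aa[s] != out$alt_aa[s]
  }
  out
}

#' Candidate-site selection with per-site filter fates
#'
#' Applies the filter cascade on a depth-masked genotype set.  Every site
#' receives exactly one primary fate, assigned in this order:
#' `multiallelic`, `monomorphic`, `noncoding`, `synonymous`,
#' `low_callable` (either species group below the callable-fraction
#' guard), `candidate`.
#'
#' For biallelic sites the annotated substitution is the observed
#' non-reference allele.
#'
#' @param geno a depth-masked [genotype_set()].
#' @param genes named list of gene models.
#' @param reference named character vector of contig sequences.
#' @param thresholds a [filter_thresholds()].
#' @return list: `fates` (data.frame `contig`, `pos`, `gene`, `fate`,
#'   annotation columns), `candidates` (integer site indexes),
#'   `annotation` (full annotation table), `state` (allelic states).
#' @export
select_candidate_sites <- function(geno, genes, reference,
                                   thresholds = filter_thresholds()) {
  state <- classify_allelic_state(geno)
  grp <- sample_groups(geno$samples)
  n <- nrow(geno$sites)
  obs_alt <- rep(NA_character_, n)
  for (s in seq_len(n)) {
    if (state[s] != "biallelic") next
    obs <- observed_alleles(geno$gt[s, ])
    alt <- setdiff(obs, geno$sites$ref[s])
    obs_alt[s] <- if (length(alt)) alt[1] else NA_character_
  }
  ann_alt <- ifelse(is.na(obs_alt),
                    vapply(strsplit(geno$sites$alt, ",", fixed = TRUE),
                           `[`, "", 1L),
                    obs_alt)
  ann <- annotate_coding_effect(geno$sites, genes, reference,
                                alt_allele = ann_alt)
  frac_callable <- function(idx) {
    if (length(idx) == 0L) return(rep(1, n))
    rowMeans(!is.na(geno$gt[, idx, drop = FALSE]))
  }
  ok_polar <- frac_callable(grp$polar) >= thresholds$min_callable_fraction
  ok_brown <- frac_callable(grp$brown) >= thresholds$min_callable_fraction
  fate <- character(n)
  for (s in seq_len(n)) {
    fate[s] <-
      if (state[s] == "multiallelic") "multiallelic"
      else if (state[s] == "monomorphic") "monomorphic"
      else if (!isTRUE(ann$in_cds[s])) "noncoding"
      else if (!isTRUE(ann$is_nonsynonymous[s])) "synonymous"
      else if (!ok_polar[s] || !ok_brown[s]) "low_callable"
      else "candidate"
  }
  fates <- cbind(data.frame(contig = geno$sites$contig,
                            pos = geno$sites$pos,
                            fate = fate, stringsAsFactors = FALSE),
                 ann)
  list(fates = fates, candidates = which(fate == "candidate"),
       annotation = ann, state = state)
}
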