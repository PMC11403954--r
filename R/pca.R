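#' Sites within a gene's region (gene body plus flanks)
#'
#' @param sites site table (`contig`, `pos`).
#' @param gene a gene model.
#' @param flank flank size in bp (default 50 kb).
#' @param contig_length optional contig length for clamping.
#' @return integer site indexes with
#'   `pos` in `[gene_start - flank, gene_end + flank)`, clamped at contig
#'   bounds.
#' @export
extract_gene_region <- function(sites, gene, flank = 50000L,
                                contig_length = NULL) {
  if (is.null(gene)) stop("unknown gene")
  lo <- max(0L, min(gene$cds_intervals$start) - flank)
  hi <- max(gene$cds_intervals$end) + flank
  if (!is.null(contig_length)) hi <- min(hi, contig_length)
  which(sites$contig == gene$contig & sites$pos >= lo & sites$pos < hi)
}

#' Dosage matrix for the differentiation PCA
#'
#' Builds a samples-by-sites matrix of alternative-allele dosages (0/1/2)
#' over the modern polar and brown bears (ancients and outgroups are
#' excluded).  Multiallelic and monomorphic columns are dropped, as are
#' columns whose completeness is below `completeness` or whose minor
#' allele frequency is below `min_maf`; remaining missing entries are
#' mean-imputed per column and columns are centered.
#'
#' @param geno a depth-masked [genotype_set()].
#' @param site_idx integer site indexes to consider.
#' @param completeness minimum fraction of non-missing samples per column
#'   (default 0.95, the published completeness rule).
#' @param min_maf minimum minor-allele frequency (default 0; stands in for
#'   the genotype-likelihood SNP test, which needs likelihoods we do not
#'   model).
#' @return list: `matrix` (centered dosages; 0 columns when nothing
#'   survives), `samples` (metadata of the rows), `kept` (site indexes of
#'   the columns), `col_means` (imputation means).
#' @export
build_dosage_matrix <- function(geno, site_idx, completeness = 0.95,
                                min_maf = 0) {
  grp <- sample_groups(geno$samples)
  rows <- c(grp$polar, grp$brown)
  samples <- geno$samples[rows, , drop = FALSE]
  keep <- integer(0)
  cols <- list()
  means <- numeric(0)
  for (s in site_idx) {
    obs <- observed_alleles(geno$gt[s, rows])
    if (length(obs) != 2L) next
    ref <- geno$sites$ref[s]
    alt <- setdiff(obs, ref)
    if (length(alt) != 1L) next            # reference allele unobserved
    g <- geno$gt[s, rows]
    dose <- vapply(g, function(x) {
      if (is.na(x)) return(NA_real_)
      sum(gt_pair(x) == alt)
    }, numeric(1))
    comp <- mean(!is.na(dose))
    if (comp < completeness) next
    m <- mean(dose, na.rm = TRUE)
    maf <- min(m / 2, 1 - m / 2)
    if (maf < min_maf) next
    dose[is.na(dose)] <- m
    keep <- c(keep, s)
    means <- c(means, m)
    cols[[length(cols) + 1L]] <- dose - m
  }
  mat <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = length(rows), ncol = 0)
  rownames(mat) <- samples$sample_id
  list(matrix = mat, samples = samples, kept = keep, col_means = means)
}

#' Principal component analysis of a centered dosage matrix
#'
#' Eigendecomposition of the sample covariance of the (already centered)
#' matrix, computed via the singular value decomposition; eigenvalues are
#' returned in descending order and sum to the total column variance.
#'
#' @param mat centered samples-by-sites numeric matrix.
#' @return list: `coordinates` (samples by PCs), `eigenvalues`.
#' @export
dosage_pca <- function(mat) {
  if (nrow(mat) < 2L || ncol(mat) < 1L)
    stop("need at least 2 samples and 1 site for a PCA")
  p <- prcomp(mat, center = FALSE, scale. = FALSE)
  list(coordinates = p$x, eigenvalues = p$sdev^2)
}

#' Polar/brown separation score on PC1
#'
#' Distance between the species centroids on PC1 divided by the pooled
#' within-species standard deviation on PC1.  A zero pooled deviation
#' (perfectly homogeneous groups) gives the cap value.  The score and its
#' threshold are this package's own quantification of "clear
#' differentiation"; the published analysis judged the PCAs visually.
#'
#' @param coordinates PCA coordinates (rows named by sample).
#' @param samples metadata for the rows (`species` column).
#' @param cap value reported for infinite separation (default 1e6).
#' @return list: `score`, `pc1_centroids`, `pooled_sd`, `capped`.
#' @export
species_separation <- function(coordinates, samples, cap = 1e6) {
  pc1 <- coordinates[, 1]
  pol <- pc1[samples$species == "polar"]
  brn <- pc1[samples$species == "brown"]
  if (length(pol) < 2L || length(brn) < 2L)
    stop("need at least two samples per species")
  num <- abs(mean(pol) - mean(brn))
  pooled_var <- ((length(pol) - 1) * var(pol) +
                   (length(brn) - 1) * var(brn)) /
    (length(pol) + length(brn) - 2)
  pooled_sd <- sqrt(pooled_var)
  capped <- pooled_sd == 0 || num / pooled_sd > cap
  list(score = if (capped) cap else num / pooled_sd,
       pc1_centroids = c(polar = mean(pol), brown = mean(brn)),
       pooled_sd = pooled_sd, capped = capped)
}

#' Per-gene differentiation PCA
#'
#' Runs [extract_gene_region()], [build_dosage_matrix()], [dosage_pca()]
#' and [species_separation()] for each gene.
#'
#' @param geno a depth-masked [genotype_set()].
#' @param genes named list of gene models.
#' @param flank,completeness,min_maf see the stage functions.
#' @param threshold separation score above which a gene is reported as
#'   differentiated (default 3).
#' @return list: `summary` data.frame (gene, n_sites, eigenvalue shares,
#'   separation, pass flag), `details` per-gene list (coordinates,
#'   eigenvalues).
#' @export
differentiation_pca <- function(geno, genes, flank = 50000L,
                                completeness = 0.95, min_maf = 0,
                                threshold = 3) {
  rows <- list(); details <- list()
  for (g in names(genes)) {
    idx <- extract_gene_region(geno$sites, genes[[g]], flank)
    dm <- build_dosage_matrix(geno, idx, completeness, min_maf)
    if (ncol(dm$matrix) == 0L) {
      rows[[g]] <- data.frame(gene = g, n_sites = 0L, pc1_var = NA_real_,
                              separation = NA_real_, differentiated = NA,
                              stringsAsFactors = FALSE)
      next
    }
    p <- dosage_pca(dm$matrix)
    sep <- species_separation(p$coordinates, dm$samples)
    tot <- sum(p$eigenvalues)
    rows[[g]] <- data.frame(
      gene = g, n_sites = ncol(dm$matrix),
      pc1_var = if (tot > 0) p$eigenvalues[1] / tot else NA_real_,
      separation = sep$score, differentiated = sep$score >= threshold,
      stringsAsFactors = FALSE)
    details[[g]] <- list(pca = p, samples = dm$samples, kept = dm$kept,
                         separation = sep)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(summary = summary, details = details)
}
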