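#' Sample metadata for a cohort specification
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns `sample_id`, `species`, `era`, `taxon`.
#' @export
make_sample_meta <- function(spec) {
  out_taxa <- c("spectacled_bear", "giant_panda")
  data.frame(
    sample_id = c(sprintf("PB_%03d", seq_len(spec$n_polar_modern)),
                  sprintf("BB_%03d", seq_len(spec$n_brown)),
                  sprintf("ANC_%02d", seq_len(spec$n_ancient)),
                  sprintf("OUT_%02d", seq_len(spec$n_outgroup))),
    species = c(rep("polar", spec$n_polar_modern),
                rep("brown", spec$n_brown),
                rep("polar", spec$n_ancient),
                rep("outgroup", spec$n_outgroup)),
    era = c(rep("modern", spec$n_polar_modern + spec$n_brown),
            rep("ancient", spec$n_ancient),
            rep("modern", spec$n_outgroup)),
    taxon = c(rep(NA_character_, spec$n_polar_modern + spec$n_brown +
                    spec$n_ancient),
              rep_len(out_taxa, spec$n_outgroup)),
    stringsAsFactors = FALSE)
}

# sorted unordered diploid genotype string, e.g. "A/G"
geno_str <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = "/"), paste(b, a, sep = "/"))
}

#' Genotype container
#'
#' Internal container for a genotype matrix: a site table plus
#' sites-by-samples matrices of genotypes (unordered base pairs like
#' `"A/G"`, `NA` = missing), read depths, and allele-depth strings.
#'
#' @param sites data.frame `contig`, `pos` (0-based), `ref`, `alt`
#'   (comma-separated alternative alleles).
#' @param gt,dp,ad matrices with one row per site, one column per sample.
#' @param samples sample metadata data.frame (see [make_sample_meta()]).
#' @return object of class `genotype_set`.
#' @export
genotype_set <- function(sites, gt, dp, ad = NULL, samples) {
  n <- nrow(sites); m <- nrow(samples)
  stopifnot(is.matrix(gt), is.matrix(dp),
            nrow(gt) == n, ncol(gt) == m,
            nrow(dp) == n, ncol(dp) == m)
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  if (is.null(ad)) ad <- matrix(NA_character_, n, m)
  colnames(gt) <- colnames(dp) <- colnames(ad) <- samples$sample_id
  structure(list(sites = sites, gt = gt, dp = dp, ad = ad,
                 samples = samples),
            class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat(sprintf("<genotype_set> %d sites x %d samples (%d polar, %d brown, %d ancient, %d outgroup)\n",
              nrow(x$sites), nrow(x$samples),
              sum(x$samples$species == "polar" & x$samples$era == "modern"),
              sum(x$samples$species == "brown"),
              sum(x$samples$era == "ancient"),
              sum(x$samples$species == "outgroup")))
  invisible(x)
}

# sample-group column indices of a genotype_set
sample_groups <- function(samples) {
  list(polar = which(samples$species == "polar" & samples$era == "modern"),
       brown = which(samples$species == "brown"),
       ancient = which(samples$era == "ancient"),
       outgroup = which(samples$species == "outgroup"))
}

#' Simulate the cohort genotype matrix
#'
#' Realises the planted truth table as diploid genotypes with per-sample
#' depths.  Modern polar bears are homozygous derived at every `fixed_*`
#' site; brown bear genotypes are binomial draws at the planted derived
#' allele frequency; outgroups are homozygous ancestral except at
#' `outgroup_conflict_bg` sites, where one outgroup carries the polar-fixed
#' allele; ancients are homozygous derived at `fixed_pre` sites and, at
#' `fixed_post` sites, the planted ancient carries the ancestral allele
#' (heterozygous by default).  Depths are Poisson per sample class;
#' ancients and outgroups are forced callable (depth >= `min_depth`) at
#' planted fixed sites so the stated per-gene fixation counts are realised
#' exactly; `low_depth_bg` sites force sub-threshold depth in 30% of the
#' modern polar bears.
#'
#' @param truth truth table from [plant_site_truth()].
#' @param spec a [cohort_spec()].
#' @param seed optional integer seed.
#' @param min_depth callability threshold used to force planted sites
#'   callable (default 4).
#' @return a [genotype_set()].
#' @export
simulate_genotypes <- function(truth, spec, seed = NULL, min_depth = 4L) {
  if (!is.null(seed)) set.seed(seed)
  meta <- make_sample_meta(spec)
  grp <- sample_groups(meta)
  n <- nrow(truth); m <- nrow(meta)
  gt <- matrix(NA_character_, n, m)
  dp <- matrix(0L, n, m)
  ad <- matrix(NA_character_, n, m)
  if (n == 0L)
    return(genotype_set(truth_site_table(truth), gt, dp, ad, meta))

  dp[, c(grp$polar, grp$brown, grp$outgroup)] <-
    rpois(n * length(c(grp$polar, grp$brown, grp$outgroup)),
          spec$depth_mean_modern)
  dp[, grp$ancient] <- rpois(n * length(grp$ancient),
                             spec$depth_mean_ancient)

  for (s in seq_len(n)) {
    anc <- truth$ancestral[s]; der <- truth$derived[s]
    ref <- truth$ref[s]; cls <- truth$class[s]
    hom <- function(a) geno_str(a, a)
    from_counts <- function(k) c(hom(anc), geno_str(anc, der), hom(der))[k + 1L]
    brown_draw <- function(f) from_counts(rbinom(length(grp$brown), 2L, f))

    if (cls %in% c("fixed_pre", "fixed_post", "fixed_denovo",
                   "outgroup_conflict_bg")) {
      gt[s, grp$polar] <- hom(der)
      gt[s, grp$brown] <- if (cls == "fixed_denovo") hom(anc) else
        brown_draw(truth$brown_freq[s])
      gt[s, grp$outgroup] <- hom(anc)
      if (cls == "outgroup_conflict_bg" && length(grp$outgroup))
        gt[s, grp$outgroup[1L]] <- geno_str(anc, der)
      dp[s, grp$outgroup] <- pmax(dp[s, grp$outgroup], min_depth)
      if (length(grp$ancient)) {
        gt[s, grp$ancient] <- hom(der)
        dp[s, grp$ancient] <- pmax(dp[s, grp$ancient], min_depth)
        if (cls == "fixed_post" && !is.na(truth$het_sample[s])) {
          hs <- grp$ancient[(truth$het_sample[s] - 1L) %% length(grp$ancient) + 1L]
          gt[s, hs] <- if (spec$post_ancient_state == "het")
            geno_str(anc, der) else hom(anc)
          dp[s, hs] <- truth$het_depth[s]
        }
      }
    } else if (cls == "segregating_polar") {
      gt[s, grp$polar] <- from_counts(rbinom(length(grp$polar), 2L, 0.3))
      if (length(grp$polar)) {
        gt[s, grp$polar[1L]] <- geno_str(anc, der)
        dp[s, grp$polar[1L]] <- max(dp[s, grp$polar[1L]], min_depth)
      }
      gt[s, grp$brown] <- brown_draw(truth$brown_freq[s])
      gt[s, grp$ancient] <- hom(anc)
      gt[s, grp$outgroup] <- hom(anc)
    } else if (cls == "no_fixed_site_background") {
      gt[s, ] <- hom(ref)
    } else if (cls == "synonymous_bg") {
      gt[s, grp$polar] <- hom(ref)
      gt[s, grp$brown] <- brown_draw(truth$brown_freq[s])
      if (length(grp$brown)) {
        gt[s, grp$brown[1L]] <- geno_str(anc, der)
        dp[s, grp$brown[1L]] <- max(dp[s, grp$brown[1L]], min_depth)
      }
      gt[s, grp$ancient] <- hom(ref)
      gt[s, grp$outgroup] <- hom(ref)
    } else if (cls == "low_depth_bg") {
      gt[s, grp$polar] <- hom(ref)
      gt[s, grp$brown] <- brown_draw(truth$brown_freq[s])
      if (length(grp$brown)) {
        gt[s, grp$brown[1L]] <- geno_str(anc, der)
        dp[s, grp$brown[1L]] <- max(dp[s, grp$brown[1L]], min_depth)
      }
      gt[s, grp$ancient] <- hom(ref)
      gt[s, grp$outgroup] <- hom(ref)
      n_low <- ceiling(0.3 * length(grp$polar))
      if (n_low > 0L)
        dp[s, grp$polar[seq_len(n_low)]] <- sample(0:(min_depth - 1L), n_low,
                                                   replace = TRUE)
    } else if (cls == "triallelic_bg") {
      gt[s, ] <- hom(ref)
      n_c1 <- min(20L, length(grp$brown)); n_c2 <- min(5L, length(grp$polar))
      if (n_c1 > 0L) {
        idx <- grp$brown[seq_len(n_c1)]
        gt[s, idx] <- geno_str(ref, truth$derived[s])
        dp[s, idx] <- pmax(dp[s, idx], min_depth)
      }
      if (n_c2 > 0L) {
        idx <- grp$polar[seq_len(n_c2)]
        gt[s, idx] <- geno_str(ref, truth$alt2[s])
        dp[s, idx] <- pmax(dp[s, idx], min_depth)
      }
    }
    # ancient dropout (default rate 0; a nonzero rate erodes the exact
    # planted pre/post counts, which is the point of setting it)
    if (length(grp$ancient) && spec$ancient_missing_rate > 0) {
      drop <- runif(length(grp$ancient)) < spec$ancient_missing_rate
      if (any(drop)) {
        gt[s, grp$ancient[drop]] <- NA_character_
        dp[s, grp$ancient[drop]] <- 0L
      }
    }
  }

  sites <- truth_site_table(truth)
  # allele-depth strings aligned to REF,ALT order
  for (s in seq_len(n)) {
    alleles <- c(sites$ref[s], strsplit(sites$alt[s], ",", fixed = TRUE)[[1]])
    ad[s, ] <- ad_strings(gt[s, ], dp[s, ], alleles,
                          het_minor = truth$het_minor_prop[s],
                          minor_allele = truth$ancestral[s])
  }
  genotype_set(sites, gt, dp, ad, meta)
}

# site table (contig, pos, ref, alt) from a truth table
truth_site_table <- function(truth) {
  alt <- character(nrow(truth))
  for (s in seq_len(nrow(truth))) {
    a <- setdiff(unique(c(truth$ancestral[s], truth$derived[s])), truth$ref[s])
    if (!is.na(truth$alt2[s])) a <- c(a, truth$alt2[s])
    alt[s] <- paste(a, collapse = ",")
  }
  data.frame(contig = truth$contig, pos = truth$pos, ref = truth$ref,
             alt = alt, stringsAsFactors = FALSE)
}

# per-sample AD strings ("dp,0", "12,8", ...) in allele order
ad_strings <- function(gts, dps, alleles, het_minor = NA, minor_allele = NA) {
  vapply(seq_along(gts), function(j) {
    if (is.na(gts[j])) return(paste(rep("0", length(alleles)), collapse = ","))
    pair <- strsplit(gts[j], "/", fixed = TRUE)[[1]]
    counts <- setNames(integer(length(alleles)), alleles)
    if (pair[1] == pair[2]) {
      counts[pair[1]] <- dps[j]
    } else if (!is.na(het_minor) && !is.na(minor_allele) &&
               minor_allele %in% pair) {
      k <- round(dps[j] * het_minor)
      counts[minor_allele] <- k
      counts[setdiff(pair, minor_allele)] <- dps[j] - k
    } else {
      counts[pair[1]] <- ceiling(dps[j] / 2)
      counts[pair[2]] <- dps[j] - counts[pair[1]]
    }
    paste(counts, collapse = ",")
  }, character(1))
}
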