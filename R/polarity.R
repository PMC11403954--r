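gt_pair <- function(g) strsplit(g, "/", fixed = TRUE)[[1]]
carries_allele <- function(g, allele) !is.na(g) && allele %in% gt_pair(g)
is_hom <- function(g) { p <- gt_pair(g); p[1] == p[2] }

#' Fixation status in present-day polar bears
#'
#' A site is fixed when every callable modern polar bear is homozygous for
#' the same allele (and at least one is callable).
#'
#' @param geno a depth-masked [genotype_set()].
#' @param site_idx integer site indexes (default: all).
#' @return data.frame per site: `is_fixed`, `fixed_allele`,
#'   `callable_polar`.
#' @export
assess_polar_fixation <- function(geno, site_idx = seq_len(nrow(geno$sites))) {
  grp <- sample_groups(geno$samples)
  res <- data.frame(is_fixed = logical(length(site_idx)),
                    fixed_allele = rep(NA_character_, length(site_idx)),
                    callable_polar = integer(length(site_idx)),
                    stringsAsFactors = FALSE)
  for (i in seq_along(site_idx)) {
    g <- geno$gt[site_idx[i], grp$polar]
    g <- g[!is.na(g)]
    res$callable_polar[i] <- length(g)
    if (length(g) == 0L) next
    hom <- vapply(g, is_hom, logical(1))
    if (all(hom) && length(unique(g)) == 1L) {
      res$is_fixed[i] <- TRUE
      res$fixed_allele[i] <- gt_pair(g[1])[1]
    }
  }
  res
}

#' Ancestral-allele determination from the two outgroups
#'
#' Follows the published rule: if the allele fixed in all polar bears is
#' found in either outgroup individual, the site is removed from further
#' consideration.  Otherwise the ancestral allele is the allele both
#' outgroups carry homozygously; both outgroups missing gives
#' `outgroup_missing`, and outgroups that are heterozygous or homozygous
#' for different alleles give `outgroup_discordant` (unless
#' `allow_single_outgroup` permits polarizing from the one callable,
#' homozygous outgroup).
#'
#' @param outgroup_gt character vector of outgroup genotypes at the site
#'   (depth-masked; `NA` = missing).
#' @param site_alleles the two alleles of the biallelic site.
#' @param fixed_allele allele fixed in modern polar bears, or `NA`.
#' @param allow_single_outgroup polarize from a single callable outgroup
#'   (default `FALSE`: both are required).
#' @return list: `ancestral`, `derived`, `removal_reason` (`NA` or one of
#'   `outgroup_carries_polar_allele`, `outgroup_missing`,
#'   `outgroup_discordant`), `outgroup_states`.
#' @export
determine_ancestral <- function(outgroup_gt, site_alleles,
                                fixed_allele = NA_character_,
                                allow_single_outgroup = FALSE) {
  called <- outgroup_gt[!is.na(outgroup_gt)]
  unpol <- function(reason) list(ancestral = NA_character_,
                                 derived = NA_character_,
                                 removal_reason = reason,
                                 outgroup_states = outgroup_gt)
  if (!is.na(fixed_allele) && length(called) &&
      any(vapply(called, carries_allele, logical(1), allele = fixed_allele)))
    return(unpol("outgroup_carries_polar_allele"))
  if (length(called) == 0L) return(unpol("outgroup_missing"))
  if (length(called) < length(outgroup_gt) && !allow_single_outgroup)
    return(unpol("outgroup_missing"))
  hom <- vapply(called, is_hom, logical(1))
  if (!all(hom)) return(unpol("outgroup_discordant"))
  anc <- unique(vapply(called, function(g) gt_pair(g)[1], character(1)))
  if (length(anc) != 1L) return(unpol("outgroup_discordant"))
  if (!anc %in% site_alleles) return(unpol("outgroup_discordant"))
  list(ancestral = anc, derived = setdiff(site_alleles, anc),
       removal_reason = NA_character_, outgroup_states = outgroup_gt)
}

#' Derived-allele frequency in brown bears
#'
#' @param brown_gt character vector of brown bear genotypes at a site
#'   (depth-masked).
#' @param derived the derived allele (`NA` gives `NA` results).
#' @return list: `brown_derived_count`, `brown_called_alleles`,
#'   `brown_derived_freq`.
#' @export
brown_derived_frequency <- function(brown_gt, derived) {
  g <- brown_gt[!is.na(brown_gt)]
  called <- 2L * length(g)
  if (is.na(derived) || called == 0L)
    return(list(brown_derived_count = NA_integer_,
                brown_called_alleles = called,
                brown_derived_freq = NA_real_))
  cnt <- sum(unlist(strsplit(g, "/", fixed = TRUE),
                    use.names = FALSE) == derived)
  list(brown_derived_count = as.integer(cnt),
       brown_called_alleles = called,
       brown_derived_freq = cnt / called)
}

#' Origin class of a candidate site
#'
#' `standing_variation`: fixed, polarized, derived allele present in brown
#' bears; `de_novo`: fixed, polarized, absent from brown bears (and, by
#' the removal rule, from the outgroups); `not_fixed`: not fixed in
#' present-day polar bears; `removed`: a removal reason fired.
#'
#' @param is_fixed,removal_reason,brown_derived_count per-site values.
#' @return character class.
#' @export
classify_origin <- function(is_fixed, removal_reason, brown_derived_count) {
  if (!is_fixed) return("not_fixed")
  if (!is.na(removal_reason)) return("removed")
  if (is.na(brown_derived_count)) return("removed")
  if (brown_derived_count > 0L) "standing_variation" else "de_novo"
}

#' Polarity and origin classification of candidate sites
#'
#' Runs [assess_polar_fixation()], [determine_ancestral()],
#' [brown_derived_frequency()] and [classify_origin()] over the candidate
#' sites of a filtered genotype set.
#'
#' @param geno a depth-masked [genotype_set()].
#' @param candidates integer site indexes (from [select_candidate_sites()]).
#' @param allow_single_outgroup see [determine_ancestral()].
#' @return data.frame, one row per candidate site.
#' @export
classify_polarity <- function(geno, candidates,
                              allow_single_outgroup = FALSE) {
  grp <- sample_groups(geno$samples)
  fix <- assess_polar_fixation(geno, candidates)
  rows <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    s <- candidates[i]
    obs <- observed_alleles(geno$gt[s, ])
    pol <- determine_ancestral(geno$gt[s, grp$outgroup], obs,
                               fixed_allele =
                                 if (fix$is_fixed[i]) fix$fixed_allele[i]
                                 else NA_character_,
                               allow_single_outgroup = allow_single_outgroup)
    bf <- brown_derived_frequency(geno$gt[s, grp$brown], pol$derived)
    origin <- classify_origin(fix$is_fixed[i], pol$removal_reason,
                              bf$brown_derived_count)
    rows[[i]] <- data.frame(
      contig = geno$sites$contig[s], pos = geno$sites$pos[s],
      is_fixed = fix$is_fixed[i], fixed_allele = fix$fixed_allele[i],
      callable_polar = fix$callable_polar[i],
      ancestral = pol$ancestral, derived = pol$derived,
      removal_reason = pol$removal_reason,
      brown_derived_count = bf$brown_derived_count,
      brown_called_alleles = bf$brown_called_alleles,
      brown_derived_freq = bf$brown_derived_freq,
      origin_class = origin, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(0), pos = integer(0),
               is_fixed = logical(0), fixed_allele = character(0),
               callable_polar = integer(0), ancestral = character(0),
               derived = character(0), removal_reason = character(0),
               brown_derived_count = integer(0),
               brown_called_alleles = integer(0),
               brown_derived_freq = numeric(0),
               origin_class = character(0))
  rownames(out) <- NULL
  out
}

#' Per-gene summary of fixation and timing
#'
#' Mirrors the published per-gene table: counts of candidate sites, fixed
#' derived sites, and their pre-/post-fixation split, with genes carrying
#' no fixed sites listed separately.
#'
#' @param classification joined classification table (with `gene`,
#'   `origin_class` and, if timing has run, `timing_class`).
#' @param genes character vector of all analysed gene names.
#' @return list: `per_gene` data.frame, `genes_without_fixed`,
#'   `genes_with_fixed`.
#' @export
summarize_by_gene <- function(classification, genes) {
  zero <- integer(length(genes))
  per_gene <- data.frame(gene = genes, n_candidates = zero, n_fixed = zero,
                         n_pre_fixed = zero, n_post_fixed = zero,
                         n_unresolved = zero, stringsAsFactors = FALSE)
  if (nrow(classification)) {
    for (i in seq_along(genes)) {
      sub <- classification[!is.na(classification$gene) &
                              classification$gene == genes[i], , drop = FALSE]
      per_gene$n_candidates[i] <- nrow(sub)
      fixed <- sub$origin_class %in% c("standing_variation", "de_novo")
      per_gene$n_fixed[i] <- sum(fixed)
      if (!is.null(sub$timing_class)) {
        per_gene$n_pre_fixed[i] <- sum(fixed &
                                         sub$timing_class == "pre_fixed",
                                       na.rm = TRUE)
        per_gene$n_post_fixed[i] <- sum(fixed &
                                          sub$timing_class == "post_fixed",
                                        na.rm = TRUE)
        per_gene$n_unresolved[i] <- sum(fixed &
                                          sub$timing_class == "unresolved",
                                        na.rm = TRUE)
      }
    }
  }
  list(per_gene = per_gene,
       genes_without_fixed = per_gene$gene[per_gene$n_fixed == 0L],
       genes_with_fixed = per_gene$gene[per_gene$n_fixed > 0L])
}
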