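#' Timing of fixation against the ancient genotypes
#'
#' For a site fixed for the derived allele in present-day polar bears, the
#' per-ancient state is `hom_derived`, `carries_ancestral` (heterozygous
#' or homozygous ancestral) or `missing` (depth-masked).  The site is
#' `pre_fixed` when no ancient carries the ancestral allele and at least
#' one is homozygous derived, `post_fixed` when at least one ancient
#' carries the ancestral allele, and `unresolved` when both are missing.
#' In the default (`strict = FALSE`) mode a single homozygous-derived
#' ancient with the other missing still counts as `pre_fixed`, flagged
#' `low_confidence`; `strict = TRUE` requires both ancients.
#'
#' @param ancient_gt character vector of ancient genotypes at the site
#'   (depth-masked).
#' @param derived,ancestral the site's derived and ancestral alleles.
#' @param strict require both ancients for a `pre_fixed` call.
#' @return list: `timing_class`, `ancient_states`, `low_confidence`.
#' @export
classify_timing <- function(ancient_gt, derived, ancestral, strict = FALSE) {
  states <- vapply(ancient_gt, function(g) {
    if (is.na(g)) return("missing")
    pair <- gt_pair(g)
    if (all(pair == derived)) "hom_derived" else "carries_ancestral"
  }, character(1))
  n_missing <- sum(states == "missing")
  cls <- if (any(states == "carries_ancestral")) "post_fixed"
  else if (n_missing == length(states)) "unresolved"
  else if (n_missing > 0L && strict) "unresolved"
  else "pre_fixed"
  list(timing_class = cls, ancient_states = unname(states),
       low_confidence = cls == "pre_fixed" && n_missing > 0L)
}

#' Time every fixed site of a classification
#'
#' @param geno a depth-masked [genotype_set()].
#' @param classification output of [classify_polarity()] (rows aligned to
#'   `candidates`).
#' @param candidates integer site indexes matching `classification`.
#' @param strict see [classify_timing()].
#' @return `classification` with columns `timing_class`,
#'   `ancient_1_state`, `ancient_2_state`, ... and `low_confidence`
#'   appended (`NA` for non-fixed rows).
#' @export
classify_timing_all <- function(geno, classification, candidates,
                                strict = FALSE) {
  grp <- sample_groups(geno$samples)
  n_anc <- length(grp$ancient)
  cl <- classification
  cl$timing_class <- rep(NA_character_, nrow(cl))
  for (a in seq_len(n_anc))
    cl[[paste0("ancient_", a, "_state")]] <- rep(NA_character_, nrow(cl))
  cl$low_confidence <- rep(NA, nrow(cl))
  fixed <- which(cl$origin_class %in% c("standing_variation", "de_novo"))
  for (i in fixed) {
    s <- candidates[i]
    tm <- classify_timing(geno$gt[s, grp$ancient], cl$derived[i],
                          cl$ancestral[i], strict = strict)
    cl$timing_class[i] <- tm$timing_class
    for (a in seq_len(n_anc))
      cl[[paste0("ancient_", a, "_state")]][i] <- tm$ancient_states[a]
    cl$low_confidence[i] <- tm$low_confidence
  }
  cl
}

#' Totals of the timing classification
#'
#' @param classification table with `origin_class`, `timing_class`, `gene`.
#' @return list: `totals` (named counts of `pre_fixed`, `post_fixed`,
#'   `unresolved`), `per_gene` split, `genes_with_post_fixed`.
#' @export
timing_summary <- function(classification) {
  fixed <- classification[classification$origin_class %in%
                            c("standing_variation", "de_novo"), ,
                          drop = FALSE]
  totals <- c(pre_fixed = sum(fixed$timing_class == "pre_fixed"),
              post_fixed = sum(fixed$timing_class == "post_fixed"),
              unresolved = sum(fixed$timing_class == "unresolved"))
  per_gene <- NULL
  genes_post <- character(0)
  if (nrow(fixed) && !is.null(fixed$gene)) {
    per_gene <- as.data.frame.matrix(
      table(fixed$gene, factor(fixed$timing_class,
                               levels = c("pre_fixed", "post_fixed",
                                          "unresolved"))))
    genes_post <- sort(unique(fixed$gene[fixed$timing_class ==
                                           "post_fixed"]))
  }
  list(totals = totals, per_gene = per_gene,
       genes_with_post_fixed = genes_post)
}
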