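TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

#' Plant the per-site truth table
#'
#' Chooses, for every entry of the class plan, a position inside the gene's
#' CDS and an allele pair satisfying the class requirements:
#'
#' * `fixed_pre`, `fixed_post`, `fixed_denovo` — the contig (reference)
#'   base is the derived allele (the reference genome is a polar bear) and
#'   the ancestral allele is chosen so the substitution is non-synonymous
#'   and stop-free.  `fixed_post` pairs are additionally transitions
#'   (C/T or G/A), the allele pairs a deamination artefact could mimic, so
#'   the heterozygote-validation stage is exercised on damage-type sites.
#' * `segregating_polar`, `low_depth_bg`, `outgroup_conflict_bg` —
#'   non-synonymous as above (`outgroup_conflict_bg` keeps the reference
#'   base as the polar-fixed allele).
#' * `synonymous_bg` — a synonymous substitution.
#' * `triallelic_bg` — two alternative alleles (no coding requirement).
#' * `no_fixed_site_background` — an alternative allele that no sample will
#'   actually carry.
#'
#' Each `fixed_post` site is assigned the ancient individual that will be
#' heterozygous, together with a target minor-base read proportion: the
#' first two TTN post-fixation sites get 0.25 and 0.29 at depth 100 (the
#' borderline worked example), all others 0.40 at depth 20.
#'
#' Positions are unique and occupy distinct codons within a gene.  A draw
#' whose codon admits no valid substitution is re-drawn; planting fails
#' after `max_retries` attempts for a site.
#'
#' @param reference,genes output of [generate_reference_and_genes()].
#' @param class_plan data.frame `gene`, `class`, `count`
#'   (see [default_class_plan()]).
#' @param seed optional integer seed.
#' @param max_retries bound on re-draws per site.
#' @return data.frame (the truth table) with one row per planted site:
#'   `gene`, `contig`, `pos` (0-based), `class`, `ref`, `ancestral`,
#'   `derived`, `alt2`, `brown_freq`, `het_sample`, `het_minor_prop`,
#'   `het_depth`.
#' @export
plant_site_truth <- function(reference, genes,
                             class_plan = default_class_plan(names(genes)),
                             seed = NULL, max_retries = 100L) {
  if (!is.null(seed)) set.seed(seed)
  bad <- setdiff(class_plan$class, SITE_CLASSES)
  if (length(bad)) stop("unknown site class(es): ", paste(bad, collapse = ", "))
  if (any(class_plan$count < 0)) stop("class counts must be >= 0")
  nonsyn_classes <- c("fixed_pre", "fixed_post", "fixed_denovo",
                      "segregating_polar", "low_depth_bg",
                      "outgroup_conflict_bg")
  ref_is_derived <- c("fixed_pre", "fixed_post", "fixed_denovo",
                      "outgroup_conflict_bg")
  rows <- list()
  used_codons <- lapply(genes, function(g) integer(0))
  for (i in seq_len(nrow(class_plan))) {
    gname <- class_plan$gene[i]
    cls <- class_plan$class[i]
    n <- class_plan$count[i]
    if (n == 0L) next
    gene <- genes[[gname]]
    if (is.null(gene)) stop("class plan names unknown gene: ", gname)
    cds <- spliced_cds(reference, gene)
    n_codons <- nchar(cds) %/% 3L
    for (k in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        ci <- sample.int(n_codons, 1L) - 1L          # 0-based codon index
        if (ci %in% used_codons[[gname]]) next
        codon <- substr(cds, ci * 3L + 1L, ci * 3L + 3L)
        ref_aa <- translate_codon(codon)
        for (cp in sample(1:3)) {                    # codon position 1..3
          ref_base <- substr(codon, cp, cp)
          alts <- setdiff(DNA_BASES, ref_base)
          if (cls == "fixed_post")                   # damage-type pairs only
            alts <- TRANSITION_PARTNER[[ref_base]]
          alts <- sample(alts, length(alts))
          pick <- NA_character_
          if (cls %in% nonsyn_classes) {
            for (a in alts) {
              alt_codon <- codon; substr(alt_codon, cp, cp) <- a
              aa <- translate_codon(alt_codon)
              if (aa != ref_aa && aa != "*") { pick <- a; break }
            }
          } else if (cls == "synonymous_bg") {
            for (a in alts) {
              alt_codon <- codon; substr(alt_codon, cp, cp) <- a
              if (translate_codon(alt_codon) == ref_aa) { pick <- a; break }
            }
          } else {                                   # triallelic / no_fixed
            pick <- alts[1L]
          }
          if (is.na(pick)) next
          cds_pos <- ci * 3L + (cp - 1L)
          pos0 <- contig_coordinate(gene, cds_pos)
          contig_ref <- substr(reference[[gene$contig]], pos0 + 1L, pos0 + 1L)
          # map alleles from CDS frame to contig frame
          to_contig <- if (gene$strand == "+") identity else dna_complement
          stopifnot(to_contig(ref_base) == contig_ref)
          alt_contig <- to_contig(pick)
          alt2 <- NA_character_
          if (cls == "triallelic_bg") {
            rest <- setdiff(DNA_BASES, c(contig_ref, alt_contig))
            alt2 <- sample(rest, 1L)
          }
          if (cls %in% ref_is_derived) {
            ancestral <- alt_contig; derived <- contig_ref
          } else {
            ancestral <- contig_ref; derived <- alt_contig
          }
          brown_freq <- switch(cls,
            fixed_pre = , fixed_post = ,
            outgroup_conflict_bg = , segregating_polar = round(runif(1, 0.1, 0.9), 3),
            fixed_denovo = 0,
            synonymous_bg = , low_depth_bg = round(runif(1, 0.2, 0.8), 3),
            no_fixed_site_background = 0,
            triallelic_bg = NA_real_)
          rows[[length(rows) + 1L]] <- data.frame(
            gene = gname, contig = gene$contig, pos = pos0, class = cls,
            ref = contig_ref, ancestral = ancestral, derived = derived,
            alt2 = alt2, brown_freq = brown_freq,
            het_sample = NA_integer_, het_minor_prop = NA_real_,
            het_depth = NA_integer_, stringsAsFactors = FALSE)
          used_codons[[gname]] <- c(used_codons[[gname]], ci)
          placed <- TRUE
          break
        }
        if (placed) break
      }
      if (!placed)
        stop(sprintf("could not place a %s site in %s after %d retries",
                     cls, gname, max_retries))
    }
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), contig = character(0), pos = integer(0),
               class = character(0), ref = character(0),
               ancestral = character(0), derived = character(0),
               alt2 = character(0), brown_freq = numeric(0),
               het_sample = integer(0), het_minor_prop = numeric(0),
               het_depth = integer(0), stringsAsFactors = FALSE)
  truth <- truth[order(truth$contig, truth$pos), , drop = FALSE]
  rownames(truth) <- NULL

  # heterozygote plan for post-fixation sites
  post <- which(truth$class == "fixed_post")
  if (length(post)) {
    truth$het_sample[post] <- rep_len(c(1L, 2L), length(post))
    truth$het_minor_prop[post] <- 0.40
    truth$het_depth[post] <- 20L
    ttn_post <- post[truth$gene[post] == "TTN"]
    special <- if (length(ttn_post) >= 2L) ttn_post[1:2] else post[seq_len(min(2L, length(post)))]
    truth$het_minor_prop[special] <- c(0.25, 0.29)[seq_along(special)]
    truth$het_depth[special] <- 100L
  }
  truth
}
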