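test_that("ancestral determination follows the outgroup rules", {
  # both outgroups homozygous A, polar fixed G -> ancestral A, derived G
  pol <- determine_ancestral(c("A/A", "A/A"), c("A", "G"),
                             fixed_allele = "G")
  expect_identical(pol$ancestral, "A")
  expect_identical(pol$derived, "G")
  expect_true(is.na(pol$removal_reason))

  # an outgroup carrying the polar-fixed allele removes the site,
  # heterozygous outgroups included (they carry both alleles)
  expect_identical(determine_ancestral(c("G/G", "A/A"), c("A", "G"),
                                       "G")$removal_reason,
                   "outgroup_carries_polar_allele")
  expect_identical(determine_ancestral(c("A/G", "A/A"), c("A", "G"),
                                       "G")$removal_reason,
                   "outgroup_carries_polar_allele")

  # both missing -> unpolarizable
  expect_identical(determine_ancestral(c(NA, NA), c("A", "G"),
                                       "G")$removal_reason,
                   "outgroup_missing")
  # one missing: both outgroups are required by default ...
  expect_identical(determine_ancestral(c("A/A", NA), c("A", "G"),
                                       "G")$removal_reason,
                   "outgroup_missing")
  # ... unless single-outgroup polarization is enabled
  pol1 <- determine_ancestral(c("A/A", NA), c("A", "G"), "G",
                              allow_single_outgroup = TRUE)
  expect_identical(pol1$ancestral, "A")
  # discordant homozygous outgroups (no polar-fixed allele involved)
  expect_identical(determine_ancestral(c("A/A", "G/G"), c("A", "G"),
                                       NA)$removal_reason,
                   "outgroup_discordant")
})

test_that("fixation assessment requires all callable polar bears", {
  geno <- make_tiny_geno()
  m <- apply_depth_mask(geno, 4L)
  fix <- assess_polar_fixation(m)
  # site 3: both callable modern polar bears hom G (A1 is ancient)
  expect_true(fix$is_fixed[3])
  expect_identical(fix$fixed_allele[3], "G")
  expect_identical(fix$callable_polar[3], 2L)
  # site 1: P2 is heterozygous -> not fixed
  expect_false(fix$is_fixed[1])
  # zero callable polar bears -> indeterminate, not fixed
  m2 <- m; m2$gt[1, 1:2] <- NA
  expect_false(assess_polar_fixation(m2)[1, "is_fixed"])
})

test_that("brown derived frequency is a direct allele count", {
  bf <- brown_derived_frequency(rep("A/A", 135), "G")
  expect_identical(bf$brown_derived_freq, 0)
  # 27 derived alleles among 270 called
  gts <- c(rep("A/G", 27), rep("A/A", 108))
  bf2 <- brown_derived_frequency(gts, "G")
  expect_identical(bf2$brown_derived_count, 27L)
  expect_identical(bf2$brown_called_alleles, 270L)
  expect_equal(bf2$brown_derived_freq, 0.10)
  expect_true(is.na(brown_derived_frequency(gts, NA)$brown_derived_freq))
})

test_that("origin classes partition the candidates on the fixture", {
  res <- get_small_result()
  cohort <- get_small_cohort()
  cl <- res$classification
  expect_identical(nrow(cl), res$counts$n_candidates)
  expect_true(all(cl$origin_class %in%
                    c("standing_variation", "de_novo", "not_fixed",
                      "removed")))
  truth <- cohort$truth
  key <- paste(cl$contig, cl$pos)
  for (cls in c("fixed_pre", "fixed_post", "segregating_polar",
                "outgroup_conflict_bg")) {
    idx <- which(truth$class == cls)
    rows <- match(paste(truth$contig[idx], truth$pos[idx]), key)
    expect_false(anyNA(rows), label = cls)
    expect_true(all(cl$origin_class[rows] == expected_outcome(cls)$origin),
                label = cls)
  }
  # conflict sites are removed for the paper's reason
  rem <- cl[cl$origin_class == "removed", ]
  expect_true(all(rem$removal_reason == "outgroup_carries_polar_allele"))
  # derived-fixed sites: polarized ancestral/derived match the plant
  fx <- cl[cl$origin_class == "standing_variation", ]
  rows <- match(paste(fx$contig, fx$pos), paste(truth$contig, truth$pos))
  expect_identical(fx$ancestral, truth$ancestral[rows])
  expect_identical(fx$derived, truth$derived[rows])
  expect_true(all(fx$brown_derived_count > 0L))
})

test_that("polarity classification is invariant under base relabeling", {
  cohort <- get_small_cohort()
  masked <- apply_depth_mask(cohort$geno, 4L)
  sel <- select_candidate_sites(masked, cohort$genes, cohort$reference)
  cl <- classify_polarity(masked, sel$candidates)
  # relabel all bases by a permutation; classes must be unchanged
  perm <- c(A = "C", C = "G", G = "T", T = "A")
  relabel <- masked
  relabel$gt[] <- ifelse(is.na(masked$gt), NA, vapply(masked$gt, function(g) {
    if (is.na(g)) return(NA_character_)
    p <- perm[strsplit(g, "/", fixed = TRUE)[[1]]]
    paste(sort(p), collapse = "/")
  }, character(1)))
  cl2 <- classify_polarity(relabel, sel$candidates)
  expect_identical(cl2$origin_class, cl$origin_class)
  expect_identical(cl2$removal_reason, cl$removal_reason)
  expect_identical(cl2$ancestral, unname(perm[cl$ancestral]))
})

test_that("per-gene summary matches the planted per-gene plan", {
  res <- get_default_result()
  per_gene <- res$gene_summary$per_gene
  expect_setequal(res$gene_summary$genes_without_fixed,
                  c("CUL7", "FCGBP", "LAMC3", "XIRP1"))
  expect_identical(length(res$gene_summary$genes_with_fixed), 7L)
  want <- data.frame(
    gene = c("ABCC6", "AIM1", "APOB", "COL5A3", "LYST", "POLR1A", "TTN"),
    pre = c(1L, 5L, 3L, 2L, 5L, 1L, 17L),
    post = c(0L, 0L, 7L, 0L, 3L, 0L, 4L))
  rows <- match(want$gene, per_gene$gene)
  expect_identical(per_gene$n_pre_fixed[rows], want$pre)
  expect_identical(per_gene$n_post_fixed[rows], want$post)
  expect_identical(per_gene$n_fixed[rows], want$pre + want$post)
  expect_identical(summarize_by_gene(res$classification[0, ],
                                     character(0))$per_gene$gene,
                   character(0))
})
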