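test_that("depth masking follows the >=4x rule and is idempotent", {
  geno <- make_tiny_geno()
  m <- apply_depth_mask(geno, 4L)
  expect_identical(unname(m$gt[1, 4]), NA_character_)   # depth 0
  expect_identical(unname(m$gt[2, 5]), NA_character_)   # depth 2 < 4
  expect_identical(unname(m$gt[2, 3]), "C/C")           # depth 4 retained
  expect_identical(m$dp, geno$dp)               # depths untouched
  expect_identical(apply_depth_mask(m, 4L)$gt, m$gt)

  all_zero <- geno
  all_zero$dp[] <- 0L
  expect_true(all(is.na(apply_depth_mask(all_zero, 4L)$gt)))
})

test_that("allelic state is judged on observed genotypes only", {
  geno <- make_tiny_geno()
  m <- apply_depth_mask(geno, 4L)
  expect_identical(classify_allelic_state(m),
                   c("biallelic", "multiallelic", "biallelic"))
  # removing the only carrier of the third allele demotes the site
  m2 <- m
  m2$gt[2, 2] <- "C/C"          # P2 carried the only A
  expect_identical(classify_allelic_state(m2)[2], "biallelic")
  # a listed ALT that nobody carries does not create a state
  m3 <- m
  m3$gt[3, ] <- "G/G"
  expect_identical(classify_allelic_state(m3)[3], "monomorphic")
})

test_that("coding-effect annotation agrees with a whole-protein oracle", {
  cohort <- get_small_cohort()
  geno <- cohort$geno
  sel <- select_candidate_sites(apply_depth_mask(geno, 4L), cohort$genes,
                                cohort$reference)
  ann <- sel$annotation
  # independent oracle: mutate the contig base, re-extract the CDS with
  # Biostrings, translate whole proteins, and compare
  ref_prot <- lapply(cohort$genes, function(g)
    strsplit(as.character(Biostrings::translate(Biostrings::DNAString(
      spliced_cds(cohort$reference, g)))), "")[[1]])
  for (s in seq_len(nrow(geno$sites))) {
    if (!isTRUE(ann$in_cds[s])) next
    if (cohort$truth$class[s] == "triallelic_bg") next  # alt ambiguous
    g <- cohort$genes[[ann$gene[s]]]
    alt <- if (cohort$truth$ref[s] == cohort$truth$derived[s])
      cohort$truth$ancestral[s] else cohort$truth$derived[s]
    mut_ref <- cohort$reference
    seq <- mut_ref[[g$contig]]
    substr(seq, geno$sites$pos[s] + 1L, geno$sites$pos[s] + 1L) <- alt
    mut_ref[[g$contig]] <- seq
    mut_prot <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(spliced_cds(mut_ref, g)),
      if.fuzzy.codon = "solve")), "")[[1]]
    diff <- which(mut_prot != ref_prot[[ann$gene[s]]])
    if (ann$is_nonsynonymous[s]) {
      expect_identical(diff, ann$codon_index[s] + 1L)
      expect_identical(ref_prot[[ann$gene[s]]][diff], ann$ref_aa[s])
      expect_identical(mut_prot[diff], ann$alt_aa[s])
    } else {
      expect_identical(diff, integer(0))
    }
  }
})

test_that("strand handling: minus-strand alleles complement into codons", {
  # G2 in the small plan is minus-strand; its planted non-synonymous sites
  # must annotate through the reverse complement
  cohort <- get_small_cohort()
  truth <- cohort$truth
  g2 <- truth[truth$gene == "G2" & truth$class == "segregating_polar", ][1, ]
  ann <- annotate_coding_effect(
    data.frame(contig = g2$contig, pos = g2$pos, ref = g2$ref,
               alt = g2$derived, stringsAsFactors = FALSE),
    cohort$genes, cohort$reference)
  expect_true(ann$is_nonsynonymous)
  cp <- ann$codon_position
  expect_identical(substr(ann$ref_codon, cp, cp),
                   paleofix:::dna_complement(g2$ref))
  expect_identical(substr(ann$alt_codon, cp, cp),
                   paleofix:::dna_complement(g2$derived))
})

test_that("a reference/ref-allele mismatch is reported with the site", {
  cohort <- get_small_cohort()
  sites <- cohort$geno$sites[1, , drop = FALSE]
  sites$ref <- setdiff(c("A", "C", "G", "T"), sites$ref)[1]
  expect_error(annotate_coding_effect(sites, cohort$genes,
                                      cohort$reference),
               "reference mismatch at")
})

test_that("every site receives exactly one fate and planted fates recover", {
  cohort <- get_small_cohort()
  masked <- apply_depth_mask(cohort$geno, 4L)
  sel <- select_candidate_sites(masked, cohort$genes, cohort$reference)
  expect_identical(nrow(sel$fates), nrow(cohort$geno$sites))
  expect_identical(sum(table(sel$fates$fate)), nrow(cohort$geno$sites))

  truth <- cohort$truth
  for (cls in c("synonymous_bg", "triallelic_bg", "no_fixed_site_background",
                "low_depth_bg")) {
    idx <- which(truth$class == cls)
    expect_true(all(sel$fates$fate[idx] == expected_outcome(cls)$fate),
                label = cls)
  }
  # candidate count derived from the truth table: fixed + segregating +
  # outgroup-conflict sites are biallelic, non-synonymous, callable
  expected_candidates <- sum(truth$class %in%
                               c("fixed_pre", "fixed_post", "fixed_denovo",
                                 "segregating_polar",
                                 "outgroup_conflict_bg"))
  expect_identical(length(sel$candidates), expected_candidates)
})
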