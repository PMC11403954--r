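test_that("reference generation is reproducible and frame-clean", {
  plan <- small_gene_plan()
  rg1 <- generate_reference_and_genes(plan, flank = 2000L, seed = 11)
  rg2 <- generate_reference_and_genes(plan, flank = 2000L, seed = 11)
  expect_identical(rg1$reference, rg2$reference)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(rg1$reference, f1); write_fasta(rg2$reference, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  for (g in rg1$genes) {
    expect_gte(min(g$cds_intervals$start), 2000L)
    expect_identical(sum(g$cds_intervals$end - g$cds_intervals$start),
                     g$coding_length)
    # independent translation oracle: standard-code translation of the
    # emitted spliced CDS has no internal stops
    cds <- spliced_cds(rg1$reference, g)
    prot <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_false(grepl("*", prot, fixed = TRUE))
  }
  expect_error(generate_reference_and_genes(
    data.frame(gene = "X", coding_length = 301L, strand = "+")),
    "divisible by 3")
})

test_that("default gene plan reproduces the published coding lengths", {
  plan <- default_gene_plan()
  expect_identical(plan$coding_length[plan$gene == "TTN"], 102861L)
  expect_identical(plan$coding_length[plan$gene == "APOB"], 13305L)
  expect_identical(nrow(plan), 11L)
  expect_true(all(plan$coding_length %% 3L == 0L))
})

test_that("plant_site_truth realises the class plan exactly", {
  cohort <- get_small_cohort()
  truth <- cohort$truth
  plan <- cohort$class_plan
  got <- table(truth$gene, truth$class)
  for (i in seq_len(nrow(plan))) {
    n <- if (plan$gene[i] %in% rownames(got) &&
             plan$class[i] %in% colnames(got))
      got[plan$gene[i], plan$class[i]] else 0L
    expect_identical(as.integer(n), as.integer(plan$count[i]),
                     label = paste(plan$gene[i], plan$class[i]))
  }
  # unique positions, distinct codons come out as distinct positions
  expect_false(anyDuplicated(truth[, c("contig", "pos")]) > 0)
  # fixed classes: reference base is the derived allele; ancestral differs
  fx <- truth[grepl("^fixed", truth$class), ]
  expect_true(all(fx$derived == fx$ref))
  expect_true(all(fx$ancestral != fx$derived))
  # planted fixed sites re-annotate as non-synonymous (annotation module)
  ann <- annotate_coding_effect(
    data.frame(contig = fx$contig, pos = fx$pos, ref = fx$ref,
               alt = fx$ancestral, stringsAsFactors = FALSE),
    cohort$genes, cohort$reference, alt_allele = fx$ancestral)
  expect_true(all(ann$in_cds))
  expect_true(all(ann$is_nonsynonymous))
  # post-fixation pairs are damage-type transitions
  post <- truth[truth$class == "fixed_post", ]
  expect_true(all(is_damage_pair(post$ancestral, post$derived)))

  expect_identical(nrow(plant_site_truth(
    cohort$reference, cohort$genes,
    data.frame(gene = "G1", class = "fixed_pre", count = 0L))), 0L)
})

test_that("default plan sums match the published totals", {
  truth <- get_default_cohort()$truth
  expect_identical(sum(truth$class == "fixed_pre"), 34L)
  expect_identical(sum(truth$class == "fixed_post"), 14L)
  expect_identical(sum(truth$class == "fixed_denovo"), 0L)
  per_gene_post <- table(truth$gene[truth$class == "fixed_post"])
  expect_identical(sort(names(per_gene_post)), c("APOB", "LYST", "TTN"))
})

test_that("simulated genotypes realise the planted pattern", {
  cohort <- get_small_cohort()
  geno <- cohort$geno
  grp <- paleofix:::sample_groups(geno$samples)
  truth <- cohort$truth
  for (s in which(grepl("^fixed", truth$class))) {
    hom_der <- paste(truth$derived[s], truth$derived[s], sep = "/")
    expect_true(all(geno$gt[s, grp$polar] == hom_der))
  }
  # de novo semantics: brown and outgroups carry zero derived alleles
  spec1 <- small_spec(seed = 99L)
  plan1 <- rbind(default_class_plan(small_gene_plan()$gene),
                 data.frame(gene = "G1", class = "fixed_denovo", count = 1L))
  cohort1 <- simulate_cohort(spec1, gene_plan = small_gene_plan(),
                             class_plan = plan1, flank = 3000L,
                             exon_target = 800L)
  s <- which(cohort1$truth$class == "fixed_denovo")
  g1 <- paleofix:::sample_groups(cohort1$geno$samples)
  der <- cohort1$truth$derived[s]
  carried <- unlist(strsplit(
    cohort1$geno$gt[s, c(g1$brown, g1$outgroup)], "/", fixed = TRUE))
  expect_false(der %in% carried)

  # ancient_missing_rate = 1 blanks every ancient genotype
  cohort2 <- simulate_cohort(small_spec(ancient_missing_rate = 1),
                             gene_plan = small_gene_plan(),
                             class_plan = default_class_plan(small_gene_plan()$gene),
                             flank = 3000L, exon_target = 800L)
  g2 <- paleofix:::sample_groups(cohort2$geno$samples)
  expect_true(all(is.na(cohort2$geno$gt[, g2$ancient])))
})

test_that("brown-bear allele frequencies are binomially consistent", {
  # fixed seed: each planted frequency is recovered within a Bonferroni
  # 99% acceptance region of its binomial sampling distribution
  cohort <- get_default_cohort()
  geno <- cohort$geno
  grp <- paleofix:::sample_groups(geno$samples)
  idx <- which(cohort$truth$class %in% c("fixed_pre", "fixed_post"))
  alpha <- 0.01 / length(idx)
  for (s in idx) {
    f <- cohort$truth$brown_freq[s]
    alleles <- unlist(strsplit(geno$gt[s, grp$brown], "/", fixed = TRUE))
    k <- sum(alleles == cohort$truth$derived[s])
    n <- length(alleles)
    expect_gte(k, qbinom(alpha / 2, n, f))
    expect_lte(k, qbinom(1 - alpha / 2, n, f))
  }
})

test_that("simulated reads carry the planted damage and proportions", {
  cohort <- get_small_cohort()
  reads <- cohort$reads
  L <- cohort$spec$read_length
  expect_true(all(nchar(reads$seq) == L))

  # base counts table equals an independent recount from the reads
  recount <- count_bases_from_reads(reads, cohort$truth[, c("contig", "pos")])
  key <- function(df) df[order(df$contig, df$pos, df$sample_id), ]
  expect_identical(key(recount), key(cohort$base_counts))

  # planted het proportions are exact
  plan <- cohort$het_plan
  for (h in seq_len(nrow(plan))) {
    bc <- cohort$base_counts[cohort$base_counts$contig == plan$contig[h] &
                               cohort$base_counts$pos == plan$pos[h] &
                               cohort$base_counts$sample_id ==
                                 plan$sample_id[h], ]
    cnt <- c(A = bc$nA, C = bc$nC, G = bc$nG, T = bc$nT)
    expect_equal(unname(cnt[plan$minor[h]] /
                          (cnt[plan$minor[h]] + cnt[plan$major[h]])),
                 plan$target_prop[h])
  }

  # zero damage rate -> zero mismatches at terminal positions (the only
  # remaining mismatches are the planted heterozygote minor alleles,
  # which sit at least 20 bp inside the read by construction)
  clean <- simulate_cohort(small_spec(damage_rate_per_ancient = c(0, 0)),
                           gene_plan = small_gene_plan(),
                           class_plan = default_class_plan(small_gene_plan()$gene),
                           flank = 3000L, exon_target = 800L)
  prof <- estimate_damage_profile(clean$reads, clean$reference)
  expect_true(all(prof$mismatches[prof$position <= 20] == 0L))
  expect_true(all(prof$mismatches[prof$position > 40] == 0L))
})

test_that("the fixture writes, round-trips and has the stated shape", {
  paths <- get_small_fixture()
  expect_true(all(file.exists(paths)))
  cohort <- get_small_cohort()

  meta <- read_sample_metadata(paths[["metadata"]])
  geno <- read_vcf_genotypes(paths[["vcf"]], meta)
  expect_identical(geno$gt, cohort$geno$gt)
  expect_identical(geno$dp, cohort$geno$dp)
  expect_identical(geno$sites, cohort$geno$sites)

  # same seed twice -> byte-identical fixture
  dir2 <- tempfile()
  write_fixture(small_cohort_new(), dir2)
  for (f in names(paths)) {
    expect_identical(unname(tools::md5sum(paths[[f]])),
                     unname(tools::md5sum(file.path(dir2, basename(paths[[f]])))),
                     label = paste("byte-identical", f))
  }
})

test_that("default fixture has 258 sample columns", {
  geno <- get_default_cohort()$geno
  expect_identical(ncol(geno$gt), 119L + 135L + 2L + 2L)
})
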