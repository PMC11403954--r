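test_that("damage profile equals a brute-force per-read recount", {
  cohort <- get_small_cohort()
  prof <- estimate_damage_profile(cohort$reads, cohort$reference)
  L <- cohort$spec$read_length
  # oracle: loop over reads one by one, comparing characters
  for (sid in unique(cohort$reads$sample_id)) {
    r <- cohort$reads[cohort$reads$sample_id == sid, ]
    ct_mm <- ct_opp <- ga_mm <- ga_opp <- integer(L)
    for (i in seq_len(nrow(r))) {
      ref <- strsplit(substr(cohort$reference[[r$contig[i]]],
                             r$start[i] + 1L, r$start[i] + L), "")[[1]]
      obs <- strsplit(r$seq[i], "")[[1]]
      isC <- ref == "C"; isG <- ref == "G"
      ct_opp <- ct_opp + isC
      ct_mm <- ct_mm + (isC & obs == "T")
      ga_opp <- ga_opp + isG
      ga_mm <- ga_mm + (isG & obs == "A")
    }
    five <- prof[prof$sample_id == sid & prof$end == "five_prime", ]
    three <- prof[prof$sample_id == sid & prof$end == "three_prime", ]
    expect_identical(five$mismatches[order(five$position)], ct_mm)
    expect_identical(five$opportunities[order(five$position)], ct_opp)
    # three-prime positions are indexed from the read's right end
    expect_identical(three$mismatches[order(three$position)], rev(ga_mm))
    expect_identical(three$opportunities[order(three$position)],
                     rev(ga_opp))
  }
  expect_identical(nrow(estimate_damage_profile(cohort$reads[0, ],
                                                cohort$reference)), 0L)
})

test_that("planted terminal rates are recovered within the 99% CI", {
  cohort <- get_small_cohort()
  prof <- estimate_damage_profile(cohort$reads, cohort$reference)
  rates <- cohort$spec$damage_rate_per_ancient
  ids <- sprintf("ANC_%02d", seq_along(rates))
  for (a in seq_along(rates)) {
    p1 <- prof[prof$sample_id == ids[a] & prof$end == "five_prime" &
                 prof$position == 1, ]
    half <- qnorm(0.995) * sqrt(rates[a] * (1 - rates[a]) /
                                  p1$opportunities)
    expect_lt(abs(p1$rate - rates[a]), half)
    # decay: position 2 rate is about half of position 1
    p2 <- prof[prof$sample_id == ids[a] & prof$end == "five_prime" &
                 prof$position == 2, ]
    expect_lt(p2$rate, p1$rate)
  }
})

test_that("minor-base proportion rule is strict at the threshold", {
  counts <- function(minor, major) c(A = major, C = 0, G = minor, T = 0)
  v <- validate_heterozygote(counts(25, 75), c("A", "G"))
  expect_equal(v$minor_base_proportion, 0.25)
  expect_identical(v$verdict, "potential_false_positive")
  expect_identical(validate_heterozygote(counts(29, 71),
                                         c("A", "G"))$verdict,
                   "potential_false_positive")
  expect_identical(validate_heterozygote(counts(50, 50),
                                         c("A", "G"))$verdict, "true_het")
  # exactly at the threshold: flagged ("more than 30%" read strictly)
  expect_identical(validate_heterozygote(counts(30, 70),
                                         c("A", "G"))$verdict,
                   "potential_false_positive")
  # verdict flips exactly at proportion > threshold, across a grid
  for (minor in 0:50) {
    verdict <- validate_heterozygote(counts(minor, 100 - minor),
                                     c("A", "G"))$verdict
    expect_identical(verdict,
                     if (minor / 100 > 0.30) "true_het"
                     else "potential_false_positive",
                     label = paste("minor =", minor))
  }
  # third-base reads are reported but excluded from the ratio
  v3 <- validate_heterozygote(c(A = 60, C = 10, G = 40, T = 0), c("A", "G"))
  expect_equal(v3$minor_base_proportion, 0.4)
  expect_identical(v3$third_base_count, 10)
  expect_error(validate_heterozygote(c(A = 0, C = 9, G = 0, T = 0),
                                     c("A", "G")), "zero read depth")
})

test_that("read-position check rescues mid-read minor alleles", {
  mk_reads <- function(offsets, base, pos = 100L, L = 60L) {
    data.frame(sample_id = "ANC_01", contig = "c1",
               start = pos - offsets,
               seq = vapply(offsets, function(o) {
                 s <- strrep("A", L); substr(s, o + 1L, o + 1L) <- base; s
               }, character(1)), stringsAsFactors = FALSE)
  }
  # all minor reads mid-read -> fraction 0 -> rescued
  pc <- minor_allele_position_check(mk_reads(c(25L, 30L, 35L), "T"),
                                    "ANC_01", "c1", 100L, "T")
  expect_equal(pc$terminal_minor_fraction, 0)
  expect_true(pc$rescued)
  # all minor reads within 2 bp of an end -> confirmed false positive
  pc2 <- minor_allele_position_check(mk_reads(c(0L, 1L, 58L, 59L), "T"),
                                     "ANC_01", "c1", 100L, "T")
  expect_equal(pc2$terminal_minor_fraction, 1)
  expect_false(pc2$rescued)
  # half terminal sits exactly at the cutoff -> rescued (inclusive)
  pc3 <- minor_allele_position_check(mk_reads(c(0L, 30L), "T"),
                                     "ANC_01", "c1", 100L, "T")
  expect_equal(pc3$terminal_minor_fraction, 0.5)
  expect_true(pc3$rescued)
  # no minor-allele reads: cannot check, verdict stands
  pc4 <- minor_allele_position_check(mk_reads(30L, "A"),
                                     "ANC_01", "c1", 100L, "T")
  expect_identical(pc4$n_minor_reads, 0L)
  expect_false(pc4$rescued)
})

test_that("ancient het validation on the fixture matches the plant", {
  res <- get_small_result()
  cohort <- get_small_cohort()
  het <- res$het_validation
  plan <- cohort$het_plan
  expect_identical(nrow(het), nrow(plan))
  rows <- match(paste(het$contig, het$pos, het$sample_id),
                paste(plan$contig, plan$pos, plan$sample_id))
  expect_false(anyNA(rows))
  expect_equal(het$minor_base_proportion, plan$target_prop[rows])
  # rescue only ever flips potential_false_positive -> true_het
  expect_true(all(het$verdict[het$proportion_verdict == "true_het"] ==
                    "true_het"))
  flagged <- het[het$proportion_verdict == "potential_false_positive", ]
  expect_true(all(flagged$is_damage_type))
  expect_true(all(flagged$terminal_minor_fraction == 0))
  expect_true(all(flagged$verdict == "true_het"))   # all rescued mid-read
  # damage-candidate report covers all planted (transition-pair) hets
  fd <- flag_damage_candidates(het)
  expect_identical(nrow(fd$table), nrow(plan))
  expect_identical(unname(fd$verdict_counts["true_het"]), nrow(plan))
})
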