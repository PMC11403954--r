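# A hand-built 3-site / 5-sample genotype set used by the io and filter
# unit tests: one clean biallelic site, one tri-allelic site, one site
# whose listed ALT nobody carries once B1 is ignored.
make_tiny_geno <- function() {
  meta <- data.frame(
    sample_id = c("P1", "P2", "B1", "A1", "O1"),
    species = c("polar", "polar", "brown", "polar", "outgroup"),
    era = c("modern", "modern", "modern", "ancient", "modern"),
    taxon = NA_character_, stringsAsFactors = FALSE)
  sites <- data.frame(contig = c("c1", "c1", "c2"),
                      pos = c(100L, 200L, 5L),
                      ref = c("A", "C", "G"),
                      alt = c("G", "T,A", "A"), stringsAsFactors = FALSE)
  gt <- matrix(c("A/A", "A/G", "G/G", NA, "A/A",
                 "C/T", "A/C", "C/C", "C/C", NA,
                 "G/G", "G/G", "A/G", "G/G", "G/G"),
               nrow = 3, byrow = TRUE)
  dp <- matrix(c(10L, 8L, 5L, 0L, 7L,
                 9L, 6L, 4L, 12L, 2L,
                 5L, 5L, 5L, 5L, 5L), nrow = 3, byrow = TRUE)
  ad <- matrix(c("10,0", "4,4", "0,5", "0,0", "7,0",
                 "5,4,0", "3,0,3", "4,0,0", "12,0,0", "0,0,0",
                 "5,0", "5,0", "2,3", "5,0", "5,0"),
               nrow = 3, byrow = TRUE)
  genotype_set(sites, gt, dp, ad, samples = meta)
}
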