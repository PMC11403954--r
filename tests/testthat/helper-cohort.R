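# Shared fixtures, built once per test run and cached.
#
# small world: 3 genes, 12 polar / 14 brown, deterministic seed.  The
# modern depth mean is raised to 20 so the 0.9 callable-fraction guard is
# never tripped by Poisson chance at these small sample sizes.
# default world: the full 119/135/2/2 cohort keyed to the published table.

small_gene_plan <- function() {
  data.frame(gene = c("G1", "G2", "TTN"),
             coding_length = c(1200L, 900L, 3000L),
             strand = c("+", "-", "+"), stringsAsFactors = FALSE)
}

small_spec <- function(seed = 42L, ...) {
  cohort_spec(n_polar_modern = 12L, n_brown = 14L,
              depth_mean_modern = 20, reads_per_ancient = 3000L,
              seed = seed, ...)
}

small_cohort_new <- function(seed = 42L, ...) {
  plan <- small_gene_plan()
  simulate_cohort(small_spec(seed = seed, ...), gene_plan = plan,
                  class_plan = default_class_plan(plan$gene),
                  flank = 3000L, exon_target = 800L)
}

.cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.cache[[key]])) .cache[[key]] <- build()
  .cache[[key]]
}

get_small_cohort <- function() cached("small_cohort", small_cohort_new)

get_small_fixture <- function() cached("small_fixture", function() {
  dir <- file.path(tempdir(), "paleofix_small_fixture")
  paths <- write_fixture(get_small_cohort(), dir)
  paths
})

fixture_config <- function(paths, outdir) {
  pipeline_config(reference = paths[["reference"]], gff = paths[["gff"]],
                  vcf = paths[["vcf"]], metadata = paths[["metadata"]],
                  base_counts = paths[["base_counts"]],
                  reads = paths[["reads"]], outdir = outdir)
}

get_small_result <- function() cached("small_result", function() {
  paths <- get_small_fixture()
  run_pipeline(fixture_config(paths, NULL), quiet = TRUE)
})

get_default_cohort <- function() cached("default_cohort",
                                        function() simulate_cohort())

get_default_fixture <- function() cached("default_fixture", function() {
  dir <- file.path(tempdir(), "paleofix_default_fixture")
  write_fixture(get_default_cohort(), dir)
})

get_default_result <- function() cached("default_result", function() {
  paths <- get_default_fixture()
  t0 <- Sys.time()
  res <- run_pipeline(fixture_config(paths, NULL), quiet = TRUE)
  attr(res, "elapsed_s") <- as.numeric(difftime(Sys.time(), t0,
                                                units = "secs"))
  res
})

# map of planted class -> expected pipeline outcome
expected_outcome <- function(class) {
  switch(class,
         fixed_pre = list(fate = "candidate", origin = "standing_variation",
                          timing = "pre_fixed"),
         fixed_post = list(fate = "candidate", origin = "standing_variation",
                           timing = "post_fixed"),
         fixed_denovo = list(fate = "candidate", origin = "de_novo",
                             timing = NULL),
         segregating_polar = list(fate = "candidate", origin = "not_fixed",
                                  timing = NA),
         outgroup_conflict_bg = list(fate = "candidate", origin = "removed",
                                     timing = NA),
         synonymous_bg = list(fate = "synonymous"),
         low_depth_bg = list(fate = "low_callable"),
         triallelic_bg = list(fate = "multiallelic"),
         no_fixed_site_background = list(fate = "monomorphic"))
}
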