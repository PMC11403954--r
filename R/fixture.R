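#' Generate a complete synthetic cohort
#'
#' Runs the whole generator under the specification's seed: reference and
#' gene models, planted truth table, genotype matrix, ancient reads with
#' terminal deamination, and the per-site base counts recounted from the
#' emitted reads.  The same spec and plans always produce a byte-identical
#' fixture.
#'
#' @param spec a [cohort_spec()].
#' @param gene_plan gene plan data.frame (see [default_gene_plan()]).
#' @param class_plan class plan data.frame (default:
#'   [default_class_plan()] over the plan's genes).
#' @param flank reference flank per side of each CDS (bp).
#' @param intron_length,exon_target reference layout knobs
#'   (see [generate_reference_and_genes()]).
#' @return object of class `paleofix_cohort`: `spec`, `reference`,
#'   `genes`, `truth`, `geno`, `reads`, `het_plan`, `base_counts`.
#' @export
simulate_cohort <- function(spec = cohort_spec(),
                            gene_plan = default_gene_plan(),
                            class_plan = NULL,
                            flank = 50000L,
                            intron_length = 300L,
                            exon_target = 6000L) {
  set.seed(spec$seed)
  rg <- generate_reference_and_genes(gene_plan, flank = flank,
                                     intron_length = intron_length,
                                     exon_target = exon_target)
  if (is.null(class_plan)) class_plan <- default_class_plan(gene_plan$gene)
  truth <- plant_site_truth(rg$reference, rg$genes, class_plan)
  geno <- simulate_genotypes(truth, spec)
  rd <- simulate_ancient_reads(truth, rg$reference, spec)
  base_counts <- count_bases_from_reads(
    rd$reads, truth[, c("contig", "pos"), drop = FALSE])
  structure(list(spec = spec, gene_plan = gene_plan,
                 class_plan = class_plan, reference = rg$reference,
                 genes = rg$genes, truth = truth, geno = geno,
                 reads = rd$reads, het_plan = rd$het_plan,
                 base_counts = base_counts),
            class = "paleofix_cohort")
}

#' @export
print.paleofix_cohort <- function(x, ...) {
  cat(sprintf("<paleofix_cohort> %d genes, %d planted sites, %d samples, %d reads\n",
              length(x$genes), nrow(x$truth), nrow(x$geno$samples),
              nrow(x$reads)))
  print(table(x$truth$class))
  invisible(x)
}

#' Write a cohort fixture to disk
#'
#' Emits `reference.fa`, `genes.gff3`, `genotypes.vcf`, `samples.tsv`,
#' `truth.tsv`, `base_counts.tsv` and `reads.tsv` under `outdir`; every
#' file round-trips through the package's readers.
#'
#' @param cohort a `paleofix_cohort` from [simulate_cohort()].
#' @param outdir output directory (created if absent).
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(reference = file.path(outdir, "reference.fa"),
             gff = file.path(outdir, "genes.gff3"),
             vcf = file.path(outdir, "genotypes.vcf"),
             metadata = file.path(outdir, "samples.tsv"),
             truth = file.path(outdir, "truth.tsv"),
             base_counts = file.path(outdir, "base_counts.tsv"),
             reads = file.path(outdir, "reads.tsv"))
  write_fasta(cohort$reference, paths["reference"])
  write_gene_models(cohort$genes, paths["gff"])
  write_vcf_genotypes(cohort$geno, paths["vcf"],
                      contig_lengths = nchar(cohort$reference))
  write_sample_metadata(cohort$geno$samples, paths["metadata"])
  write_truth_table(cohort$truth, paths["truth"])
  write_base_counts(cohort$base_counts, paths["base_counts"])
  write_reads(cohort$reads, paths["reads"])
  invisible(paths)
}
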