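#' Pipeline configuration
#'
#' Collects every path and tunable of the analysis.  Thresholds default to
#' the published rules where one is stated (minimum depth 4, heterozygote
#' minor-base threshold 0.30, PCA flank 50 kb and completeness 0.95,
#' EDH3 excluded); the remaining knobs are this package's documented
#' choices.
#'
#' @param reference,gff,vcf,metadata input paths (required at run time).
#' @param base_counts,reads optional paths enabling the damage-QC stage.
#' @param outdir output directory (`NULL`: nothing written).
#' @param exclude_genes genes dropped from the analysis (default "EDH3").
#' @param thresholds a [filter_thresholds()].
#' @param allow_single_outgroup see [determine_ancestral()].
#' @param timing_strict see [classify_timing()].
#' @param het_threshold,het_k,het_rescue_cutoff damage-QC parameters
#'   (see [validate_heterozygote()] and [minor_allele_position_check()]).
#' @param pca_flank,pca_completeness,pca_min_maf,pca_threshold PCA
#'   parameters (see [differentiation_pca()]).
#' @param seed recorded for provenance (the analysis itself is
#'   deterministic).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(reference = NULL, gff = NULL, vcf = NULL,
                            metadata = NULL, base_counts = NULL,
                            reads = NULL, outdir = NULL,
                            exclude_genes = "EDH3",
                            thresholds = filter_thresholds(),
                            allow_single_outgroup = FALSE,
                            timing_strict = FALSE,
                            het_threshold = 0.30, het_k = 5L,
                            het_rescue_cutoff = 0.5,
                            pca_flank = 50000L, pca_completeness = 0.95,
                            pca_min_maf = 0, pca_threshold = 3,
                            seed = 1L) {
  if (het_threshold < 0 || het_threshold > 0.5)
    stop("het_threshold must lie in [0, 0.5]")
  if (pca_completeness <= 0 || pca_completeness > 1)
    stop("pca_completeness must lie in (0, 1]")
  structure(list(reference = reference, gff = gff, vcf = vcf,
                 metadata = metadata, base_counts = base_counts,
                 reads = reads, outdir = outdir,
                 exclude_genes = exclude_genes, thresholds = thresholds,
                 allow_single_outgroup = allow_single_outgroup,
                 timing_strict = timing_strict,
                 het_threshold = het_threshold, het_k = as.integer(het_k),
                 het_rescue_cutoff = het_rescue_cutoff,
                 pca_flank = as.integer(pca_flank),
                 pca_completeness = pca_completeness,
                 pca_min_maf = pca_min_maf, pca_threshold = pca_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# load and depth-mask the pipeline inputs
load_pipeline_inputs <- function(config) {
  for (p in c("reference", "gff", "vcf", "metadata")) {
    if (is.null(config[[p]])) stop("pipeline config lacks input path: ", p)
    if (!file.exists(config[[p]]))
      stop("input file for '", p, "' not found: ", config[[p]])
  }
  reference <- read_fasta(config$reference)
  genes <- read_gene_models(config$gff)
  genes <- genes[setdiff(names(genes), config$exclude_genes)]
  metadata <- read_sample_metadata(config$metadata)
  geno <- read_vcf_genotypes(config$vcf, metadata)
  masked <- apply_depth_mask(geno, config$thresholds$min_depth)
  list(reference = reference, genes = genes, metadata = metadata,
       geno = geno, masked = masked)
}

config_echo <- function(config) {
  th <- config$thresholds
  c(sprintf("min_depth\t%d", th$min_depth),
    sprintf("min_callable_fraction\t%g", th$min_callable_fraction),
    sprintf("exclude_genes\t%s", paste(config$exclude_genes,
                                       collapse = ",")),
    sprintf("allow_single_outgroup\t%s", config$allow_single_outgroup),
    sprintf("timing_strict\t%s", config$timing_strict),
    sprintf("het_threshold\t%g", config$het_threshold),
    sprintf("het_terminal_window_k\t%d", config$het_k),
    sprintf("het_rescue_cutoff\t%g", config$het_rescue_cutoff),
    sprintf("pca_flank\t%d", config$pca_flank),
    sprintf("pca_completeness\t%g", config$pca_completeness),
    sprintf("pca_min_maf\t%g", config$pca_min_maf),
    sprintf("pca_separation_threshold\t%g", config$pca_threshold),
    sprintf("seed\t%d", config$seed))
}

#' Run the full pipeline
#'
#' Stages in order: input parsing and depth masking, candidate-site
#' filtering, polarity/origin classification, fixation timing,
#' ancient-heterozygote damage QC (when base counts are supplied), and the
#' per-gene differentiation PCA.  When `config$outdir` is set, every stage
#' table is written as TSV together with a plain-text summary echoing all
#' thresholds; reruns with the same config are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress INFO messages.
#' @return list of class `paleofix_result`: `fates`, `classification`,
#'   `gene_summary`, `timing`, `het_validation`, `damage_profile`,
#'   `pca`, `counts`, `config`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  info <- function(...) if (!quiet) message(sprintf(...))
  inp <- load_pipeline_inputs(config)
  info("loaded %d sites x %d samples; depth mask at >=%dx applied",
       nrow(inp$geno$sites), nrow(inp$geno$samples),
       config$thresholds$min_depth)

  sel <- select_candidate_sites(inp$masked, inp$genes, inp$reference,
                                config$thresholds)
  fate_counts <- table(sel$fates$fate)
  info("filter fates: %s",
       paste(sprintf("%s=%d", names(fate_counts), as.integer(fate_counts)),
             collapse = ", "))

  cl <- classify_polarity(inp$masked, sel$candidates,
                          config$allow_single_outgroup)
  cl$gene <- sel$fates$gene[sel$candidates]
  cl <- classify_timing_all(inp$masked, cl, sel$candidates,
                            strict = config$timing_strict)
  origin_counts <- table(factor(cl$origin_class,
                                levels = c("standing_variation", "de_novo",
                                           "not_fixed", "removed")))
  info("origin classes: %s",
       paste(sprintf("%s=%d", names(origin_counts),
                     as.integer(origin_counts)), collapse = ", "))
  tsum <- timing_summary(cl)
  info("timing: pre=%d post=%d unresolved=%d", tsum$totals["pre_fixed"],
       tsum$totals["post_fixed"], tsum$totals["unresolved"])

  gsum <- summarize_by_gene(cl, sort(names(inp$genes)))

  het <- NULL; damage <- NULL
  if (!is.null(config$base_counts)) {
    counts <- read_base_counts(config$base_counts)
    reads <- if (!is.null(config$reads)) read_reads(config$reads) else NULL
    het <- validate_ancient_heterozygotes(inp$masked, counts, reads,
                                          threshold = config$het_threshold,
                                          k = config$het_k,
                                          cutoff = config$het_rescue_cutoff)
    info("ancient heterozygous calls: %d (%d flagged by the %g rule)",
         nrow(het), sum(het$proportion_verdict == "potential_false_positive"),
         config$het_threshold)
    if (!is.null(reads))
      damage <- estimate_damage_profile(reads, inp$reference)
  }

  pca <- differentiation_pca(inp$masked, inp$genes,
                             flank = config$pca_flank,
                             completeness = config$pca_completeness,
                             min_maf = config$pca_min_maf,
                             threshold = config$pca_threshold)

  # Fig-2-style per-site table: candidates with origin, timing and the
  # asterisk flag for sites not fixed in at least one ancient individual
  report <- cl
  report$not_fixed_in_ancient <- !is.na(report$timing_class) &
    report$timing_class == "post_fixed"
  front <- c("gene", "contig", "pos")
  report <- report[, c(front, setdiff(names(report), front)), drop = FALSE]

  counts_out <- list(
    n_sites = nrow(inp$geno$sites),
    fate_counts = fate_counts,
    n_candidates = length(sel$candidates),
    origin_counts = origin_counts,
    n_fixed = sum(cl$origin_class %in% c("standing_variation", "de_novo")),
    timing_totals = tsum$totals)

  result <- structure(list(fates = sel$fates, classification = report,
                           gene_summary = gsum, timing = tsum,
                           het_validation = het, damage_profile = damage,
                           pca = pca$summary, counts = counts_out,
                           config = config),
                      class = "paleofix_result")
  if (!is.null(config$outdir)) write_pipeline_outputs(result)
  result
}

write_pipeline_outputs <- function(result) {
  outdir <- result$config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fates <- result$fates
  fates$pos <- fates$pos + 1L
  write_tsv(fates, file.path(outdir, "filter_fates.tsv"))
  write_site_report(result$classification,
                    file.path(outdir, "site_classifications.tsv"))
  write_tsv(result$gene_summary$per_gene,
            file.path(outdir, "gene_summary.tsv"))
  if (!is.null(result$het_validation)) {
    het <- result$het_validation
    het$pos <- het$pos + 1L
    write_tsv(het, file.path(outdir, "het_validation.tsv"))
  }
  if (!is.null(result$damage_profile))
    write_tsv(result$damage_profile,
              file.path(outdir, "damage_profile.tsv"))
  write_tsv(result$pca, file.path(outdir, "pca_summary.tsv"))
  writeLines(summary_lines(result), file.path(outdir, "summary.txt"))
  invisible(outdir)
}

summary_lines <- function(result) {
  cnt <- result$counts
  c("# paleofix pipeline summary",
    "## parameters",
    config_echo(result$config),
    "## counts",
    sprintf("input_sites\t%d", cnt$n_sites),
    sprintf("fate_%s\t%d", names(cnt$fate_counts),
            as.integer(cnt$fate_counts)),
    sprintf("candidates\t%d", cnt$n_candidates),
    sprintf("origin_%s\t%d", names(cnt$origin_counts),
            as.integer(cnt$origin_counts)),
    sprintf("fixed_derived_sites\t%d", cnt$n_fixed),
    sprintf("timing_%s\t%d", names(cnt$timing_totals),
            as.integer(cnt$timing_totals)),
    if (!is.null(result$het_validation))
      sprintf("ancient_het_calls\t%d", nrow(result$het_validation)),
    "## genes",
    sprintf("genes_with_fixed\t%s",
            paste(result$gene_summary$genes_with_fixed, collapse = ",")),
    sprintf("genes_without_fixed\t%s",
            paste(result$gene_summary$genes_without_fixed, collapse = ",")),
    sprintf("genes_with_post_fixed\t%s",
            paste(result$timing$genes_with_post_fixed, collapse = ",")))
}

#' @export
print.paleofix_result <- function(x, ...) {
  cat(paste(summary_lines(x), collapse = "\n"), "\n")
  invisible(x)
}
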