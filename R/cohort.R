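#' Cohort specification for the synthetic study
#'
#' Describes the simulated sampling design: 119 present-day polar bears,
#' 135 brown bears, two Late Pleistocene polar bears with terminal
#' deamination damage of roughly 20% (Poolepynten-like) and 5% (Bruno-like)
#' at the read ends, and two outgroup individuals (spectacled bear, giant
#' panda).  All values are overridable; the defaults are the stated world of
#' the default fixture.
#'
#' @param n_polar_modern number of present-day polar bears.
#' @param n_brown number of present-day brown bears.
#' @param n_ancient number of ancient polar bears.
#' @param n_outgroup number of outgroup individuals.
#' @param depth_mean_modern Poisson mean of per-site read depth for
#'   present-day and outgroup individuals.
#' @param depth_mean_ancient Poisson mean of per-site depth for ancients.
#' @param ancient_missing_rate probability that an ancient genotype is
#'   missing.  Defaults to 0: the published pre/post arithmetic implies
#'   complete ancient data at the fixed sites, and ancient Poisson depths
#'   below the 4x threshold already produce natural missingness at
#'   background sites.
#' @param damage_rate_per_ancient numeric vector, length `n_ancient`:
#'   terminal deamination probability per ancient sample.
#' @param damage_decay geometric decay of the deamination probability per
#'   position inward from the read end.
#' @param read_length simulated ancient read length (bp).
#' @param reads_per_ancient number of background reads per ancient sample;
#'   the default yields >10,000 terminal reference-C opportunities.
#' @param seq_error_rate uniform sequencing error rate in simulated reads
#'   (default 0 so damage estimates are clean).
#' @param post_ancient_state genotype of the non-fixed ancient at
#'   post-fixation sites: "het" (default) or "hom_ancestral".
#' @param seed integer seed driving every random draw of the generator.
#' @return an object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_polar_modern = 119L,
                        n_brown = 135L,
                        n_ancient = 2L,
                        n_outgroup = 2L,
                        depth_mean_modern = 10,
                        depth_mean_ancient = 8,
                        ancient_missing_rate = 0,
                        damage_rate_per_ancient = c(0.20, 0.05),
                        damage_decay = 0.5,
                        read_length = 60L,
                        reads_per_ancient = 44000L,
                        seq_error_rate = 0,
                        post_ancient_state = c("het", "hom_ancestral"),
                        seed = 20240916L) {
  post_ancient_state <- match.arg(post_ancient_state)
  counts <- c(n_polar_modern = n_polar_modern, n_brown = n_brown,
              n_ancient = n_ancient, n_outgroup = n_outgroup)
  if (any(counts < 0)) stop("sample counts must be >= 0")
  probs <- c(ancient_missing_rate = ancient_missing_rate,
             seq_error_rate = seq_error_rate,
             damage_rate_per_ancient)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (length(damage_rate_per_ancient) != n_ancient)
    stop("damage_rate_per_ancient must have length n_ancient")
  if (damage_decay < 0 || damage_decay > 1)
    stop("damage_decay must lie in [0, 1]")
  spec <- list(n_polar_modern = as.integer(n_polar_modern),
               n_brown = as.integer(n_brown),
               n_ancient = as.integer(n_ancient),
               n_outgroup = as.integer(n_outgroup),
               depth_mean_modern = depth_mean_modern,
               depth_mean_ancient = depth_mean_ancient,
               ancient_missing_rate = ancient_missing_rate,
               damage_rate_per_ancient = damage_rate_per_ancient,
               damage_decay = damage_decay,
               read_length = as.integer(read_length),
               reads_per_ancient = as.integer(reads_per_ancient),
               seq_error_rate = seq_error_rate,
               post_ancient_state = post_ancient_state,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  spec
}

#' Default gene plan
#'
#' The eleven candidate genes with their coding lengths and (arbitrary but
#' fixed) strands.  Lengths for the seven genes carrying fixed derived
#' alleles are the published coding lengths (e.g. TTN 102,861 bp); the four
#' genes without fixed sites have invented lengths of realistic magnitude,
#' all divisible by 3.
#'
#' @return data.frame with columns `gene`, `coding_length`, `strand`.
#' @export
default_gene_plan <- function() {
  data.frame(
    gene = c("ABCC6", "AIM1", "APOB", "COL5A3", "CUL7", "FCGBP",
             "LAMC3", "LYST", "POLR1A", "TTN", "XIRP1"),
    coding_length = c(4551L, 5484L, 13305L, 5256L, 5070L, 7980L,
                      4590L, 11403L, 5172L, 102861L, 5430L),
    strand = c("+", "-", "+", "-", "+", "-", "+", "-", "+", "+", "-"),
    stringsAsFactors = FALSE
  )
}

# site classes the generator can plant
SITE_CLASSES <- c("fixed_pre", "fixed_post", "fixed_denovo",
                  "segregating_polar", "no_fixed_site_background",
                  "synonymous_bg", "low_depth_bg", "triallelic_bg",
                  "outgroup_conflict_bg")

#' Default per-gene site-class plan
#'
#' Plants the published per-gene counts of derived alleles fixed before /
#' after the age of the Late Pleistocene individuals (ABCC6 1/0, AIM1 5/0,
#' APOB 3/7, COL5A3 2/0, LYST 5/3, POLR1A 1/0, TTN 17/4; CUL7, FCGBP, LAMC3
#' and XIRP1 contribute none), zero de novo sites, and one background site
#' of every other class in every gene.
#'
#' @param genes character vector of gene names (default: the default plan).
#' @return data.frame with columns `gene`, `class`, `count`.
#' @export
default_class_plan <- function(genes = default_gene_plan()$gene) {
  pre <- c(ABCC6 = 1L, AIM1 = 5L, APOB = 3L, COL5A3 = 2L, LYST = 5L,
           POLR1A = 1L, TTN = 17L)
  post <- c(APOB = 7L, LYST = 3L, TTN = 4L)
  bg <- c("segregating_polar", "no_fixed_site_background", "synonymous_bg",
          "low_depth_bg", "triallelic_bg", "outgroup_conflict_bg")
  rows <- list()
  for (g in genes) {
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g,
      class = c("fixed_pre", "fixed_post", "fixed_denovo", bg),
      count = c(if (g %in% names(pre)) pre[[g]] else 0L,
                if (g %in% names(post)) post[[g]] else 0L,
                0L, rep(1L, length(bg))),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat(sprintf("  samples: %d modern polar, %d brown, %d ancient, %d outgroup\n",
              x$n_polar_modern, x$n_brown, x$n_ancient, x$n_outgroup))
  cat(sprintf("  depth: modern ~Pois(%g), ancient ~Pois(%g); seed %d\n",
              x$depth_mean_modern, x$depth_mean_ancient, x$seed))
  cat(sprintf("  damage: %s at read ends, decay %g, reads %d x %d bp\n",
              paste(x$damage_rate_per_ancient, collapse = "/"),
              x$damage_decay, x$reads_per_ancient, x$read_length))
  invisible(x)
}
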