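---
title: "paleofix: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{paleofix: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the pipeline answers

Present-day polar bears are fixed for derived alleles at a number of
non-synonymous sites in a small panel of candidate genes with strong
selection signals (cardiovascular function, lipid metabolism,
pigmentation). Two ancient polar bear genomes — one older than roughly
130 thousand years, one older than roughly 70 — make it possible to ask
not only *where those alleles came from* (standing variation in the
ancestral polar/brown gene pool vs de novo mutation on the polar lineage)
but *when they reached fixation* relative to those individuals.
`paleofix` turns that reasoning into a reproducible pipeline over called
genotypes, plus the QC the ancient data demand.

## Procedure

1. **Depth masking.** A genotype is used only where the individual has at
   least `min_depth` (default 4) reads at the site. This is applied to
   every sample — modern, ancient and outgroup alike; the original
   analysis states the rule for genotype calling and we read it as
   applying to outgroups as well (the text is ambiguous on that point).
2. **Candidate filter.** A site enters classification iff it is biallelic
   *as observed* among non-missing genotypes (a listed but unobserved VCF
   ALT does not count; tri-allelic sites are excluded), lies in a
   candidate gene's CDS, is non-synonymous under the standard genetic
   code, and each species group (modern polar; brown) has at least
   `min_callable_fraction` (default 0.9) callable individuals. Every site
   receives exactly one fate, assigned in the documented cascade order
   (`multiallelic`, `monomorphic`, `noncoding`, `synonymous`,
   `low_callable`, `candidate`), so fates always sum to the input count.
3. **Polarization.** The ancestral allele is the allele both outgroups
   carry homozygously. If the allele fixed in all polar bears is found in
   either outgroup individual the site is *removed* — this single rule
   also disposes of sites fixed for the ancestral allele, because there
   the outgroups necessarily carry the polar-fixed allele.
4. **Origin.** Fixed + polarized sites are `standing_variation` when the
   derived allele is present among called brown bear alleles, `de_novo`
   when absent (the removal rule already guarantees the outgroups lack
   it). Non-fixed candidates are `not_fixed`.
5. **Timing.** Per ancient individual the state is `hom_derived`,
   `carries_ancestral` (heterozygous or homozygous ancestral — the report
   keeps the per-individual state so either reading can be audited) or
   `missing`. Any `carries_ancestral` ⇒ `post_fixed`; otherwise
   `pre_fixed`, or `unresolved` when no ancient is callable.
6. **Heterozygote validation.** For each ancient heterozygous call, the
   minor-base proportion is the read count of the less-supported genotype
   allele over the combined count of both genotype alleles (reads showing
   a third base are reported but excluded from the ratio — the source
   analysis does not define the denominator, so we fix one and expose the
   excluded reads). A call stands only when the proportion is strictly
   greater than `het_threshold` (0.30). Flagged calls whose allele pair
   is a deamination signature (C/T or G/A) get a read-position check: the
   fraction of minor-allele reads with the variant within `het_k` (5) bp
   of a read end; at most `het_rescue_cutoff` (0.5, inclusive) rescues
   the call to a true heterozygote. Rescue never demotes a call.
7. **Damage profile.** An exact mismatch-count ratio per read position:
   C→T mismatches over reference-C opportunities from the 5′ end, G→A
   from the 3′ end. Reads are taken to align exactly (the fixture
   guarantees it; there are no indels in this model).
8. **Differentiation PCA.** Per gene ± `pca_flank` (50 kb): dosage matrix
   over modern polar + brown bears (0/1/2 copies of the observed
   non-reference allele), columns below `pca_completeness` (0.95)
   dropped, missing entries mean-imputed, columns centered, SVD-based
   PCA. The separation score is the distance between species centroids
   on PC1 over the pooled within-species standard deviation; the score
   and its threshold (3) are this package's own quantification — the
   original judgement was visual. This dosage PCA deliberately replaces a
   genotype-likelihood PCA: at the fixture's depths hard calls are
   reliable, and without genotype likelihoods the likelihood-ratio SNP
   test has no meaning, so it is replaced by an optional minor-allele
   frequency filter (`pca_min_maf`, default 0).

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `min_depth` | 4 | reads | the published per-individual callability rule |
| `min_callable_fraction` | 0.9 | fraction | our guard: "fixed" is never decided from a handful of individuals; the source states a completeness rule only for the PCA |
| `exclude_genes` | EDH3 | — | excluded upstream for potential admixture; the gene list is data, not code |
| `allow_single_outgroup` | FALSE | — | both outgroups were used originally; degrading to one is opt-in |
| `timing_strict` | FALSE | — | one homozygous-derived ancient with the other missing counts as `pre_fixed` flagged low-confidence; the published pre+post arithmetic implies no unresolved category existed, but the artifact must still expose missingness handling |
| `het_threshold` | 0.30 | proportion | "more than 30%" read strictly (`>`); a site at exactly 0.30 is flagged — noted because the worked 0.29 case sits adjacent to the boundary |
| `het_k` | 5 | bp | terminal window of the read-position check (codifies a manual visualisation) |
| `het_rescue_cutoff` | 0.5 | fraction | inclusive rescue bound |
| `pca_flank` | 50000 | bp | published region definition |
| `pca_completeness` | 0.95 | fraction | published completeness rule |
| `pca_threshold` | 3 | sd units | our invention, labelled as such in output |

## What the generator emulates — and what it does not

`cohort_spec()` defaults *are* the stated world: 119 modern polar bears,
135 brown bears, two ancient polar bears with terminal deamination rates
0.20 and 0.05, two outgroups; per-gene planted site classes reproduce the
published per-gene table (pre/post = ABCC6 1/0, AIM1 5/0, APOB 3/7,
COL5A3 2/0, LYST 5/3, POLR1A 1/0, TTN 17/4; CUL7, FCGBP, LAMC3, XIRP1
contribute none; 0 de novo sites), with one background site per gene of
each distractor class (segregating, monomorphic-with-listed-ALT,
synonymous, low-depth, tri-allelic, outgroup-conflict). Coding lengths of
the seven genes with fixed sites are the published ones (TTN 102,861 bp);
the four without are invented at realistic magnitude. Where the sources
state no value we chose once:

* modern/outgroup depth ~ Poisson(10), ancient ~ Poisson(8) — mid-range
  shotgun coverage where a 4× rule bites occasionally but not often;
* brown-bear derived frequencies at fixed sites ~ Uniform(0.1, 0.9),
  matching the spread of the published allele-frequency figure and
  keeping the probability of a spurious all-ancestral brown sample below
  1e-12 at n = 135;
* reads: 60 bp, single-end, uniform coverage, sequencing error 0 by
  default so damage estimates are clean; damage decays geometrically
  inward (constant 0.5/position) — only the end rates are published;
* at post-fixation sites the non-fixed ancient is heterozygous by default
  (homozygous-ancestral is a config option); the heterozygous sites *are*
  the 14 post-fixation sites by default, the two borderline ones (minor
  proportions 0.25 and 0.29, read depth 100) planted in TTN; all planted
  ancient heterozygotes use transition allele pairs so the damage-type
  screen is exercised on every one of them.

Deliberate idealisations, hence what a green test does *not* establish:
no recombination or linkage structure, no coalescent demography, no
indels, no mapping or base-quality error, reads align exactly where they
were drawn, and ancients/outgroups are forced callable (depth ≥ 4) at
planted fixed sites — the published arithmetic (34 + 14 = 48 with no
unresolved sites) presupposes complete ancient and outgroup data there,
and the generator states that world rather than sampling around it. For
the same reason `ancient_missing_rate` defaults to 0 and, when set,
applies uniformly to every site: a nonzero rate *should* erode the exact
pre/post counts, and the package does not hide that. Recovery of the
planted truth on this fixture validates the pipeline's logic, not its
robustness to alignment artefacts or reference bias.

Two smaller consistency choices in the read simulator: a sample's
background reads never overlap its own planted heterozygous sites, and
het-site reads carry no deamination — together these make the planted
minor-base proportions exact in the emitted base counts (the clean reads
dilute the terminal damage estimate by under 1% relative, well inside the
99% binomial acceptance band the tests use). Minor-allele reads place the
variant at least 20 bp from either read end, so the position check sees
an unambiguous mid-read signal.

## Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open; every on-disk format uses
  its own convention (1-based VCF/GFF3/TSV). Depth precedence when
  reading VCFs is DP, else the sum of AD, else missing.
* Genotypes are unordered allele pairs; phase is never used.
* Allelic state is judged on observed genotypes after depth masking, so
  masking can demote a site from tri-allelic to biallelic — the fate
  cascade is therefore defined on the *masked* matrix, once.
* A heterozygous outgroup carries both alleles: if one is the polar-fixed
  allele the removal rule fires (the conservative reading of "found in
  either of these individuals"); otherwise it cannot define a homozygous
  ancestral state and the site is reported `outgroup_discordant`.
  Discordant homozygous outgroups are likewise unpolarizable and reported
  separately — the sources are silent on both cases.
* PCA eigenvalues come from the SVD of the centered matrix and are
  checked against a dense eigendecomposition of the explicit covariance
  to 1e-8; a perfectly separated PC1 with zero within-species variance
  reports the documented cap (1e6) rather than infinity.
* Sites with zero callable genotypes are monomorphic by definition of the
  observed-allele rule and never reach fixation assessment; an empty VCF
  produces a zero-candidate report and a clean exit.
* The generator re-draws a planted site when its codon admits no valid
  substitution and fails loudly after a bounded number of retries.

## Known limitations

* The dosage PCA is a simplification of a genotype-likelihood PCA and
  will behave differently at very low coverage, where hard calls are
  biased toward homozygotes.
* Timing rests on two ancient individuals; the report deliberately keeps
  per-individual states and a `low_confidence` flag rather than implying
  population-level certainty.
* The damage model is terminal deamination only; library-preparation
  specifics (single- vs double-stranded, UDG treatment) are out of scope,
  as is base-quality rescaling of mapped reads.
* Coding-effect annotation assumes one CDS model per gene and no
  overlapping transcripts.
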