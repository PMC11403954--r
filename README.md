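# paleofix

Polar bears carry a set of candidate genes (APOB, LYST, TTN, ...) in which
derived alleles are fixed in all present-day individuals. Three questions
follow for anyone studying the genomics of their Arctic adaptation:

1. **Which non-synonymous sites are actually fixed** for the derived allele
   in present-day polar bears, once per-individual read depth, biallelic
   state and coding effect are controlled?
2. **Where did each fixed allele come from** — standing variation still
   segregating in brown bears, or a de novo mutation on the polar bear
   lineage (absent from brown bears and from the outgroups used to polarize
   ancestral state: spectacled bear and giant panda)?
3. **When did fixation happen** relative to two Late Pleistocene polar bear
   genomes (older than ~130 kya and ~70 kya): a site where both ancient
   individuals are homozygous derived was fixed *before* their age
   (`pre_fixed`); a site where at least one ancient still carries the
   ancestral allele was fixed *after* (`post_fixed`).

`paleofix` implements this pipeline for genotype matrices (VCF + GFF3 +
FASTA + sample metadata), together with the two QC layers such an analysis
needs when ancient genomes are involved:

* a **damage-aware heterozygote validation** — post-mortem cytosine
  deamination inflates C→T (and, on the complement, G→A) calls at read
  ends, so every ancient heterozygous call is screened by its minor-base
  read proportion (strictly >30% to stand) and, for damage-type allele
  pairs, by where in the read the minor alleles sit;
* a **per-gene dosage PCA** (gene ± 50 kb, ≥95% completeness) checking that
  polar and brown bears remain differentiated at each locus.

Because the original ~250 genomes cannot ship with a package, `paleofix`
includes a first-class **synthetic cohort generator**: a reference with
realistic gene models, 119 modern polar bears, 135 brown bears, 2 ancient
polar bears with terminal deamination (~20% and ~5% at the read ends,
decaying inward) and 2 outgroups, with per-gene site classes planted from a
truth table so that every stage of the pipeline is verifiable exactly.

## Model in brief

For a biallelic, non-synonymous site with alleles $\{a, d\}$:

* ancestral $a$ = the allele both outgroup individuals carry homozygously;
  a site whose polar-fixed allele appears in either outgroup is removed;
* fixed ⟺ every callable (depth ≥ 4) modern polar bear is homozygous $d$;
* origin: `standing_variation` if the brown-bear derived count $k_d > 0$
  over $2n$ called alleles, `de_novo` if $k_d = 0$;
* timing from the two ancient genotypes as above;
* heterozygote screen: minor proportion $p = \min(k_1,k_2)/(k_1+k_2)$ over
  the two genotype alleles' read counts, flagged when $p \le 0.30$, rescued
  when the flagged site's minor-allele reads sit mid-read
  (terminal fraction within 5 bp of an end ≤ 0.5);
* damage profile: $\hat r(i) = \frac{\#\{C\to T \text{ at } 5' \text{ position } i\}}{\#\{\text{reference C at } i\}}$,
  and symmetrically G→A from the 3' end.

## Worked example

```r
library(paleofix)

cohort <- simulate_cohort(cohort_spec(seed = 20240916L))  # the default
fx <- write_fixture(cohort, "fixture")

res <- run_pipeline(pipeline_config(
  reference = fx[["reference"]], gff = fx[["gff"]], vcf = fx[["vcf"]],
  metadata = fx[["metadata"]], base_counts = fx[["base_counts"]],
  reads = fx[["reads"]], outdir = "out"))
```

The run logs (INFO) narrate every count:

```
loaded 114 sites x 258 samples; depth mask at >=4x applied
filter fates: candidate=70, low_callable=11, monomorphic=11, multiallelic=11, synonymous=11
origin classes: standing_variation=48, de_novo=0, not_fixed=11, removed=11
timing: pre=34 post=14 unresolved=0
ancient heterozygous calls: 14 (2 flagged by the 0.3 rule)
```

So on the default fixture: 48 sites fixed for the derived allele in all
present-day polar bears, all from standing variation (0 de novo), 34 fixed
before the age of the ancient individuals and 14 after, and 14 ancient
heterozygous calls of which 2 (minor proportions 0.25 and 0.29, both in
TTN) are flagged by the strict 30% rule and then rescued because their
minor alleles sit mid-read. The per-gene table:

```r
res$gene_summary$per_gene[res$gene_summary$per_gene$n_fixed > 0,
                          c("gene", "n_pre_fixed", "n_post_fixed")]
#>      gene n_pre_fixed n_post_fixed
#> 1   ABCC6           1            0
#> 2    AIM1           5            0
#> 3    APOB           3            7
#> 4  COL5A3           2            0
#> 8    LYST           5            3
#> 9  POLR1A           1            0
#> 10    TTN          17            4
```

and the re-estimated terminal damage rates:

```r
subset(res$damage_profile, end == "five_prime" & position == 1)
#>     sample_id        end position mismatches opportunities       rate
#> 1      ANC_01 five_prime        1       2248         11147 0.20166861
#> 121    ANC_02 five_prime        1        539         11148 0.04834948
```

recovering the planted 20% / 5% terminal deamination.

All outputs are also written as TSVs under `out/` (`filter_fates.tsv`,
`site_classifications.tsv`, `gene_summary.tsv`, `het_validation.tsv`,
`damage_profile.tsv`, `pca_summary.tsv`, `summary.txt` with every
threshold echoed).

## Command line

```sh
Rscript inst/cli/paleofix simulate --out fixture --seed 20240916
Rscript inst/cli/paleofix run --fixture fixture --out out
# or stage by stage:
Rscript inst/cli/paleofix filter   --fixture fixture --out out
Rscript inst/cli/paleofix classify --fixture fixture --out out
Rscript inst/cli/paleofix time     --fixture fixture --out out
Rscript inst/cli/paleofix damage   --fixture fixture --out out
Rscript inst/cli/paleofix pca      --fixture fixture --out out
```

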