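# dlahap

Case–control association analysis of canine MHC class II (DLA)
haplotypes, from raw sequence-based typing to graded-control statistics.

Pedigree dog breeds carry very few MHC haplotypes, which makes them
powerful natural models for immune-mediated disease: a single risk
haplotype can be tracked through a breed with a few hundred dogs.
`dlahap` implements the complete analysis such a study needs, for the
three tightly linked class II loci **DLA-DRB1, DLA-DQA1, DLA-DQB1**:

1. **Sequence-based typing (SBT).** Each locus is Sanger-sequenced in a
   single direction (reverse for DRB1/DQA1, forward for DQB1);
   heterozygous sites appear as IUPAC ambiguity codes. The unordered
   allele pair `{a, b}` at a locus is recovered as the set of reference
   library pairs whose *superposition* (position-wise IUPAC union)
   equals the consensus exactly.
2. **Haplotype phasing.** A deterministic homozygote-seeded (Clark-style)
   algorithm: dogs homozygous at all three loci reveal haplotypes
   directly; single-locus heterozygotes have a forced phase; remaining
   dogs are resolved against the accumulated pool, iterated to a fixed
   point, with a parsimony fallback that admits at most one novel
   haplotype per dog.
3. **Association statistics.** For a 2×2 table with exposed/unexposed
   cases *a, b* and controls *c, d*:
   odds ratio `OR = ad/bc`; Yates-corrected chi-squared
   `χ² = n(|ad−bc| − n/2)² / ((a+b)(c+d)(a+c)(b+d))` with its 1-df
   upper-tail p; and the **Cornfield 95% CI**, obtained by inverting the
   continuity-corrected Cornfield chi-square statistic by bisection.
   Chromosome-level (2n) tables for haplotype/allele frequencies,
   dog-level tables for genotype-dose (0/1/2 copies) analyses,
   relatedness-graded control strata, and declarative subgroup filters
   (diagnostic grade, age) are all first-class.
4. **Synthetic cohorts.** A seeded generator with an 11-haplotype breed
   pool, Hardy–Weinberg founders, Mendelian transmission, a logistic-odds
   dose penetrance model and proband-based ascertainment, so every stage
   is testable without external data.

## Worked example

The bundled `example_cohort()` is a fully phased 212-dog single-breed
myositis cohort (29 cases; 93 first-degree, 44 second-degree and 46
unrelated controls):

```r
library(dlahap)
ec <- example_cohort()
t <- haplotype_table(ec, risk_haplotype())   # chromosome-level 2x2
t
#> 2x2 (chromosome unit)
#>           exposed unexposed
#>  cases         35        23
#>  controls     162       204
assoc_stats(t)[, c("or", "ci_low", "ci_high", "chi2_yates", "p_value")]
#>     or ci_low ci_high chi2_yates p_value
#> 1 1.92   1.05     3.5       4.58  0.0324
gradient_profile(ec, risk_haplotype())
#>         stratum n_dogs two_n n_carrier_chromosomes freq_pct n_homozygous hom_pct
#> 1         cases     29    58                    35     60.3           10    34.5
#> 2  first_degree     93   186                    96     51.6           25    26.9
#> 3 second_degree     44    88                    41     46.6            8    18.2
#> 4     unrelated     46    92                    25     27.2            4     8.7
```

Case chromosomes carry the risk haplotype at 60.3% versus 44.3% in all
controls (OR 1.92, p 0.032); the frequency falls monotonically with
decreasing relatedness to an affected dog — the signature of a
low-penetrance risk haplotype segregating in affected pedigrees. Against
unrelated controls only, the same call with
`controls = cohort_filter(status = "control", relatedness = "unrelated")`
gives OR 4.08 (95% CI 1.92–8.74). Dog-level dosage via
`dose_association()` shows one copy raises disease odds about fivefold
and two copies fifteenfold.

A full synthetic pipeline run:

```r
cfg <- sim_config(seed = 1)
sim <- simulate_cohort(cfg)                    # 212 dogs with truth records
lib <- toy_allele_library()
typed <- type_reads(emit_reads(sim$cohort, lib), lib)
co <- as_cohort(merge(sim$cohort[, 1:6], typed$genotypes, by = "id"))
ph <- phase_cohort(co)
haplotype_association(phased_cohort(co, ph), cfg$risk)
```

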