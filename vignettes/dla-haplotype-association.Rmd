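---
title: "Typing, phasing and association for DLA class II haplotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing, phasing and association for DLA class II haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlahap)
```

## The problem

Dog breeds are closed populations with very limited MHC diversity: a
typical breed segregates on the order of ten three-locus DLA class II
haplotypes (DRB1–DQA1–DQB1), inherited as a single tightly linked block.
Immune-mediated diseases concentrated in one breed can therefore be
interrogated with modest cohorts: type every dog at the three loci,
reconstruct haplotypes, and compare carriage between affected dogs and
unaffected controls stratified by how closely they are related to an
affected dog ("graded controls"). `dlahap` implements that pipeline end
to end. This vignette is the package's account of the underlying
methods, the choices that were genuinely open, and what the test suite
does and does not establish.

## Sequence-based typing

Exon 2 of each locus is amplified and Sanger-sequenced in **one
direction only** — the reverse strand for DRB1 and DQA1, the forward
strand for DQB1 — so the raw observation per dog and locus is a single
base-called consensus in which heterozygous positions carry IUPAC
two-base ambiguity codes. Formally, the consensus of an allele pair
$\{a,b\}$ is the position-wise IUPAC union `superpose(a, b)`; typing is
the inverse problem: find all unordered library pairs whose
superposition equals the read **exactly**.

Decisions embedded here:

* **No mismatch tolerance and no base-call error model.** The upstream
  assay curates polymorphic positions manually; modelling sequencing
  error would add parameters the data cannot constrain. A read that
  matches no pair is a first-class outcome (`no_match`: novel allele or
  sequencing error), not an exception.
* **Codes covering three or four bases** (`N`, `V`, …) are accepted in
  input but make a read `unresolvable_multibase`: a diploid
  superposition can only produce one- or two-base codes, so such a read
  cannot be explained by any allele pair.
* **Genuine SBT ambiguity** (several pairs with identical superposition)
  is reported, not silently broken. An optional tie-break by the product
  of user-supplied prior allele frequencies exists but is off by
  default: silent auto-resolution would fabricate data.
* Orientation is normalised by IUPAC-aware reverse complement
  (R↔Y, K↔M, S and W self-complementary) before matching, so the
  library is always queried in its own frame.

The reference library is a FASTA with headers in the published DLA
nomenclature (`DLA-DRB1*02001`). All alleles at a locus must share one
sequence length — the library's own exon-2 alignment frame is
authoritative; the standard amplicon sizes (303, 345, 300 bp) are
documented defaults, not hard constraints, because a library may cover a
different window.

## Homozygote-seeded phasing

With no recombination inside the block, each dog's two chromosomes carry
one haplotype each, and a genotype heterozygous at $h$ loci is
consistent with $2^{h-1}$ unordered haplotype pairs. The phasing
procedure is the classic field heuristic made deterministic:

1. **Seeds.** Every $h=0$ dog directly exhibits one haplotype (two
   copies). These enter the pool tagged `seed_full_homozygote`.
2. **Forced phases.** Every $h=1$ dog splits deterministically: each
   allele at the heterozygous locus joins the shared homozygous
   background (`seed_partial_homozygote`).
3. **Pool resolution.** Each $h\ge2$ dog's candidate pairs are compared
   with the pool. Exactly one pair with both members pooled → phased
   (`inferred`); several → `ambiguous` (all pairs listed, optionally
   ranked by pool support); none → a parsimony fallback phases the dog
   if exactly one pair has exactly one pooled member, admitting the
   single novel partner into the pool. Two novel haplotypes in one dog
   is never accepted (`unresolved`) — the conservative Clark rule.

Because the original procedure is manual and order-dependent, the
implementation processes **strata, not dogs**: all seeds first, then all
forced phases, then the pool-resolution pass iterated to a fixed point,
with final statuses assigned against the final pool and any inferred
haplotype left carried by no phased dog pruned. Permuting subject order
provably cannot change the result (asserted property), and adding a
homozygous dog can only grow the phased set.

Dogs missing a genotype at any locus are excluded from phasing (and
flagged); they still contribute to single-locus allele analyses at their
typed loci. Ambiguously phased dogs are excluded from haplotype-level
tables by default; a sensitivity option weights each consistent pair
equally (cells then need not be integers).

## Association statistics

Two counting units are kept explicit and never mixed:

* **chromosome-level (2n)** — haplotype and allele frequencies and their
  odds ratios; every phased dog contributes exactly two chromosomes, so
  for any group $a + b = 2\times$ (phased dogs);
* **dog-level** — carrier/genotype-dose analyses classifying dogs by 0,
  1 or 2 copies of a target haplotype, with odds ratios for the
  heterozygous and homozygous classes against the zero-copy baseline
  (baseline OR fixed at 1).

For a table $(a,b,c,d)$ the package computes the cross-product odds
ratio, the Yates continuity-corrected chi-squared
$n\,(|ad-bc|-n/2)^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))$ — with the
correction floored so the statistic is zero when $|ad-bc|\le n/2$ — and
its 1-df upper-tail p-value.

**Cornfield confidence interval.** The 95% bounds are the two odds-ratio
values $\psi$ at which the continuity-corrected Cornfield statistic
equals $\chi^2_{1,0.95}$. For candidate $\psi$, the exposed-case cell is
fitted to the table's margins by solving the quadratic
$x(m_0-n_1+x) = \psi\,(m_1-x)(n_1-x)$ inside its admissible interval;
the statistic is $(|a-x|-\tfrac12)^2/V(x)$ with
$V = (1/x + 1/(m_1{-}x) + 1/(n_1{-}x) + 1/(m_0{-}n_1{+}x))^{-1}$.
Numerical choices: bisection on $\log\psi$, tolerance $10^{-6}$, at most
200 iterations per bound, initial bracket by doubling steps away from
the point estimate. Non-convergence raises an error carrying the last
bracket. Two boundary rules: any zero cell triggers the
Haldane–Anscombe adjustment (+0.5 to all four cells, applied to the
point OR and CI, reported via a flag, raw table retained); if after
adjustment the corrected statistic never reaches the critical value on
one side, that bound is reported as 0 or ∞ rather than an error. The
continuity-corrected variant was chosen because it reproduces the
intervals printed by the classic epidemiological packages
(Epi Info lineage) to within about 1% on reference tables.

No multiple-testing adjustment is applied (none is standard in this
design); result tables carry `n_tested` so users can apply their own.
P-values are reported at full precision; the two-significant-figure
convention of published tables is left to formatting.

Subgroup analyses are declarative `cohort_filter()`s — diagnostic-grade
sets, relatedness sets, and a **strict** `age > threshold` comparison
(a dog aged exactly the threshold is excluded; missing age never
passes). The graded-control gradient (`gradient_profile()`) reports
chromosome and homozygote frequencies across
cases → first-degree → second-degree → unrelated, with a monotonicity
flag; under exchangeable strata a strictly decreasing profile has null
probability about 1/24, which the suite checks empirically.

## The synthetic cohort generator

The generator's defaults are the study conditions the analysis assumes,
not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| haplotype pool | 11 haplotypes at the control-stratum frequencies of the bundled cohort (risk haplotype at 162/366 ≈ 44%) | the breed spectrum the pipeline must cope with |
| `or_het`, `or_hom` | 5, 15 | the dose effect sizes of the motivating design |
| `f0` | 0.01 | baseline penetrance; gives a population prevalence of a few percent under the default pool, realistic for a breed-predisposed complex disease, and makes ascertainment feasible. The true penetrance is not estimable from published data — this is a simulation parameter, not an estimate |
| group sizes | 29 / 93 / 44 / 46 | cases, first-degree, second-degree, unrelated |
| grade mix | 13:4:12 | definite : probable : possible among cases |
| litter size | 6 | typical for a medium breed |
| onset ages | log-normal, median ≈ 2.9 y, truncated to [0.5, 8] y | matches the reported onset range descriptively |
| control ages | uniform on [0.58, 13.83] y | matches the reported control range descriptively |

Founders are drawn under within-breed Hardy–Weinberg on haplotypes; the
disease model multiplies baseline odds $f_0/(1-f_0)$ by `or_het` or
`or_hom` (a logistic-odds dose model, chosen over a liability-threshold
model because it directly parameterises the dose odds ratios the
analysis estimates). Ascertainment is proband-based: families (two
founders, one litter, one half-sib litter from re-mating the sire) are
simulated until affected offspring fill the case quota; unaffected full
sibs and parents fill the first-degree group, unaffected half-sibs the
second-degree group, and independent unaffected founders the unrelated
group — so "unaffected relative" strata are genuinely conditioned on
being unaffected. All randomness flows through R's RNG; a single seed
makes cohorts and emitted read files byte-identical.

What the generator deliberately does **not** emulate: inbreeding (real
breeds violate Hardy–Weinberg toward homozygote excess, which would make
phasing *easier*), genotyping error, recombination within the block, or
population structure beyond one breed. Passing tests therefore show the
pipeline is correct under its stated model, not that real cohorts are
free of typing error or cryptic structure.

## Fixtures and what the tests establish

`example_cohort()` is a fully phased 212-dog cohort whose per-stratum
haplotype chromosome counts match the classic single-breed myositis
layout; `example_dose_cohort()` carries the corresponding dog-level
genotype-dose layout (24/18/4 controls). The two are separate because
the two layouts imply 25 versus 26 risk chromosomes among the unrelated
controls and cannot coexist in one cohort; each fixture is internally
consistent and drives the statistics computed from it. The toy allele
library uses synthetic 24-bp frames generated under a fixed seed and
verified to give pairwise-distinct superpositions within each locus, so
typing on it is exactly invertible — real exon-2 libraries can contain
genuinely ambiguous pairs, which the typing layer reports rather than
resolves.

Problem sizes used by the suite (the package's own choices): phasing is
checked against an exhaustive pool-scan oracle on 500 random cohorts of
up to 15 dogs and 6 haplotypes; dose-OR confidence coverage on 100
seeded case-control simulations of 2,000 dogs; the full
simulate → reads → type → phase → associate round trip on a 212-dog
cohort; truth recovery on a 500-dog cohort; smaller replicate counts
(40–60 runs) for the distributional sanity checks of the generator.

## Known limitations

* Phasing trusts the pool: a rare haplotype carried only by
  multi-heterozygous dogs can be mis-phased in principle if an
  alternative pooled pair explains the genotype; the ambiguity status
  and the parsimony conservatism bound, but do not eliminate, this risk.
* The Cornfield interval is one of several published variants; bounds
  from software using the uncorrected statistic differ at the second
  decimal.
* The typing layer performs no alignment: reads must be in the library's
  exon frame and length. Chromatogram parsing and novel-allele discovery
  are out of scope.
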