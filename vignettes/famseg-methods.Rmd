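---
title: "Methods: family-based rare-variant prioritisation in famseg"
author: "famseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based rare-variant prioritisation in famseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famseg)
```

## The analysis problem

Highly multiplex families — families with three or more diagnosed autistic
members — concentrate inherited risk variants that single-proband designs
dilute. `famseg` implements a within-family prioritisation strategy for
such cohorts that combines two complementary phenotype definitions:

* **clinical diagnosis**, which is specific but misses undiagnosed
  relatives, especially in older generations; and
* **autistic-trait subgroups**, standard-deviation bands on Autism Spectrum
  Quotient (AQ)-type questionnaire totals, which capture elevated traits in
  members who never sought a diagnosis.

Each family is analysed independently: a rare damaging variant in a
constrained gene is prioritised when its carriers inside the family match
one of the phenotype patterns below. Cross-family aggregation then asks
which genes are implicated by which approach, how candidate genes
distribute over trait bands and evidence tiers, and whether diagnosed
members are enriched for carrying variants in robustly implicated (Tier-1)
genes.

## Trait subgroups

Raw questionnaire totals are standardised against per-instrument normative
means and SDs and banded:

| band | z-range |
|---|---|
| NAP (narrow autistic phenotype)  | z ≥ 3 |
| MAP (medium)                     | 2 ≤ z < 3 |
| BAP (broad)                      | 1 ≤ z < 2 |
| AVERAGE                          | z < 1 |

Bands are **closed at the lower edge and open at the top**: a score exactly
at `mean + 2·sd` is MAP. The band definitions alone do not dictate a
boundary convention; a consistent half-open convention avoids assigning one
score to two bands, and `assign_trait_group()` applies it uniformly.

Normative means and SDs are *configuration, not constants*
(`read_instrument_norms()`): published norms differ by instrument (adult,
adolescent and child AQ, Q-CHAT for toddlers) and revision, so the package
refuses to guess them. All four instruments are mapped onto the same
z-band logic; how toddler Q-CHAT scores should relate to adult-derived
bands is genuinely unclear, and treating the norms as user input makes
that choice explicit rather than hidden.

## Variant- and gene-level filters

`filter_config()` holds every threshold. Defaults:

* **Frequency**: gnomAD non-Finnish European MAF < 1% (strict `<`) for
  inherited variants. A variant *absent* from gnomAD passes: prioritised
  variant tables routinely contain ultra-rare variants with no reference
  frequency, so absence must not disqualify
  (`missing_maf_is_rare = TRUE`).
* **Damage**: stop gain/loss and frameshift indels always qualify.
  Missense qualifies with SIFT = D **and** PolyPhen-2 HDIV ∈ {D, P}; the
  "at least possibly damaging" reading of PolyPhen is deliberate, because
  published prioritised sets include D/P calls. Splicing variants qualify
  only in the de novo filter (where the published criteria list splice
  junctions) unless `splicing_in_inherited = TRUE`.
* **Read support**: ≥ 10 reads per call; heterozygous calls need ≥ 33%
  alternate reads. Missing depth fails closed.
* **Constraint**: pLI ≥ 0.9 **or** LOEUF < 0.37 (first decile). The two
  sources describing this gene set join the metrics with "and" while
  clearly describing a union-style set; the permissive union is the
  default and `constraint_mode = "intersection"` is available. The pLI
  comparison is `≥` (the de novo criteria print "greater than or equal
  to", the inherited text "greater than"; one convention is adopted for
  both and is configurable).

## Segregation rules

At each eligible site, `carrier_set()` splits a family into carriers
(het or hom-alt calls passing read support — hom-alt genotypes count as
carriers under a dominant-model reading), non-carriers (passing hom-ref),
and *raw carriers* (any non-missing het/hom-alt call).

* **Diagnosis rule** (`diagnosis_segregation()`): at least two *diagnosed*
  carriers, and no *non-autistic* carrier. Suspected-diagnosis members
  are first-class: they neither count toward the two required carriers nor
  veto — the enrichment analysis likewise separates members who suspected
  they were undiagnosed autistic. Unknown-diagnosis members also neither
  count nor veto.
* **Trait rule** (`trait_segregation()`): a level-L variant must be
  carried by at least two members in band L or above and by nobody below.
  Equivalently the assigned level is the *minimum* band over carriers
  (provided it is at least BAP and two scored, read-support-passing
  carriers exist); any AVERAGE carrier kills the variant. Unscored members
  neither count nor veto.

The "absent in ..." vetoes inspect **raw** carriers by default
(`veto_on_raw_genotype = TRUE`): a non-autistic member whose carrier
genotype merely fails the read-support thresholds still argues against
dominant segregation. Whether the original analysis vetoed on raw or
filtered genotypes is not stated; the stricter reading was chosen and the
flag preserves the alternative.

Both rules are verified in the test suite against a brute-force oracle
that enumerates every carrier subset of small families and applies the
English rules literally.

`summarise_genes()` collapses prioritised variants to distinct genes and
classifies each as trait-only, diagnosis-only, or both (at least one
trait-labelled and one diagnosis-labelled variant anywhere in the cohort);
a gene hit in several families is a single summary row listing all
families, and Venn counts are over distinct genes.

## Trio de novo filter

`scan_trios()` applies five criteria to every (trio, site) pair, however
the genotypes were called upstream (the published pipeline used VarScan2's
trio mode, whose own parameters are strictly looser than these criteria,
so re-applying them to jointly genotyped sites reproduces the filter):

1. read depth **> 20** in child, father and mother (strict);
2. child alternate reads ≥ 8;
3. heterozygous de novo status: child alternate fraction > 40% with the
   genotype call het when available, and the variant absent in *each*
   parent (per-parent alternate fraction < 5% — "absent in parents" is
   read per parent, not pooled);
4. NFE frequency ≤ 1% or absent (note `≤`, as printed for the de novo
   criteria, versus the inherited `<`);
5. disruptive class: damaging missense (SIFT D, PolyPhen D/P), frameshift
   indel, stop gain/loss, or splicing;

plus a gene gate of pLI ≥ 0.9 (a gene missing from the constraint table
fails). The decision is symmetric in the parents and anti-monotone in
parental alternate fraction; the child-side pass region is exhaustively
enumerated in the tests (for depth d it is `alt ≥ max(8, ⌊0.4·d⌋ + 1)`).

## Evidence tiers

`assign_tier()` classifies genes by named source lists with precedence
1 > 2 > 3: Tier 1 collects robust autism / severe neurodevelopmental
sources (SFARI S/1–3, SPARK, the large exome-study gene sets, DDG2P
monoallelic, DBDGD); Tier 2 suggestive autism / ID / epilepsy / ADHD
sources; Tier 3 brain-expressed and synaptic gene sets. Matching is
verbatim on uppercased symbols — HGNC alias resolution is a documented
extension point, not silently attempted. Real database snapshots are not
bundled (licensing and versioning); the package ships small fixture
subsets sufficient to tier its bundled prioritisation table, and
`read_tier_sources()` accepts full downloads.

## Carrier enrichment

`chi_square_2x2()` computes the Pearson statistic from the closed form
`N(ad − bc)² / ((a+b)(c+d)(a+c)(b+d))` with 1 df and an upper-tail
p-value. **No continuity correction is applied by default**: on the
reference carrier table (50/24 diagnosed, 11/23 non-autistic) the
uncorrected statistic is 11.75 while Yates gives ≈ 10.4, and the package's
tests pin the uncorrected behaviour (with the correction available behind
a flag). Suspected- and unknown-diagnosis members are excluded from the
table entirely, which is why N = 108 rather than 112 in the carrier-status
replay. The p-value comes from the χ² upper tail; a Fisher-exact fallback
for sparse tables is a documented extension, not implemented.

## Bundled prioritisation table and its replay

`table1_variants()` ships the cross-family table of prioritised variants
used by the tabulation functions. Two transcription conventions are
recorded in its `notes` column: one row's trait/diagnosis label is
printed ambiguously ("N /Diagnosis") and is stored as diagnosis-only,
consistent with the published Venn counts; and the de novo TAF4 variant
observed in two families is stored as two rows of the same site. The
published prose also counts "eight" diagnosis-only Tier-1 genes while
enumerating nine; the table yields nine and the package reports nine.

`table1_replay()` inverts the filters: for every family in the table it
builds a minimal pedigree (a suspected, unscored founder who transmits
each inherited variant — so genotypes stay Mendelian-consistent without
vetoing either rule — plus scored children covering every
diagnosis-by-band role) and genotype evidence such that running the real
`prioritise_cohort()` and `scan_trios()` reproduces every row's label
row-for-row. This keeps the acceptance-level checks anchored to the
actual filter code rather than to the transcription.

## The synthetic cohort generator

`simulate_cohort()` exists because the underlying genomes are under
controlled access: every pipeline stage must be testable from nothing.
Its default configuration *is* the study shape, chosen once from the
cohort description: 21 families, 112 members, 76 diagnosed, 4 suspected
(three female), 50 females, exactly ten families with ≥ 4 diagnosed
members, and one reduced family ("10") with an unrecruited father and
only two diagnosed members — the one family that legitimately fails the
highly-multiplex flag.

Design choices:

* **Plants are sampled, not painted.** A planted diagnosis- or
  trait-segregating variant is placed on an eligible founder and
  transmitted with honest 50%-per-meiosis Mendelian sampling, rejected
  and redrawn until the carrier pattern satisfies the rule (≥ 2 diagnosed
  carriers and no non-autistic carrier; or min carrier band = L with ≥ 2
  carriers). A bounded retry count turns impossible requests (e.g. a
  diagnosis plant in a family with one diagnosed member) into a clear
  error rather than a silent phenotype-painted variant.
* **Planted evidence passes its gates by construction.** Depths are
  Poisson(λ = 30) and alternate reads Binomial(depth, 0.5) for hets;
  for planted carriers the draw is repeated until the read-support (or
  de novo depth/fraction) gates pass. This is what makes
  "precision = recall = 1 on noise-free runs" an exact property rather
  than a high-probability one.
* **Noise is honest.** Background variants descend from random founders
  under the same transmission model; a configurable fraction receives a
  qualifying annotation, the rest fail one randomly chosen gate (common
  frequency, benign predictions, unconstrained gene, synonymous class).
  An optional genotype-error rate flips het/hom-ref calls at noise sites,
  generating Mendelian violations whose expected count the tests verify
  against the generator's own error model.
* **Trait scores** are drawn on the z-scale (diagnosed ≈ N(3.1, 0.8),
  suspected ≈ N(2.5, 0.8), other relatives ≈ N(0.9, 1.0) — elevated
  relative to the general population, as expected in multiplex families)
  and mapped through per-instrument norms, truncated to the instrument
  range.
* **Determinism**: all randomness flows from the single seed; identical
  seeds give byte-identical bundles (PED, traits CSV, VCF with GT:DP:AD,
  annotation/constraint TSVs, tier lists, truth table). Analysis stages
  contain no randomness at all.

What the generator does **not** emulate — and therefore what passing
tests do not show about real data: read-level artefacts (no FASTQ/BAM),
linkage disequilibrium and recombination structure, realistic site
frequency spectra (only a rare/common dichotomy), population
stratification, assortative mating, and phenotype measurement error
beyond the Gaussian score model. Recovery results on synthetic cohorts
certify the *filter logic*, not calling quality on real genomes.

## Numerical and engineering choices

* Coordinates are 1-based VCF convention throughout; annotation joins to
  genotypes by exact `(chrom, pos, ref, alt)` match after multiallelic
  decomposition, with unmatched genotype sites dropped and counted. No
  left-alignment or liftover is attempted.
* Multiallelic VCF records decompose into one biallelic site per
  alternate allele; a genotype's class at a site counts copies of the
  focal allele only, and any `.` allele makes the call missing. How the
  original analysis handled multiallelic sites is unstated; decomposition
  is this package's convention.
* Missing evidence always fails closed (depth, alternate counts,
  predictor calls, constraint scores).
* Report rows sort deterministically by (tier, gene, family, position);
  trio enumeration sorts by (family, child); both are invariant under
  input permutation.
* The test suite runs the study-shaped simulation (21 families,
  112 members, ~30 planted variants) plus several 4–10-family toy
  configurations; the whole suite completes in well under a minute, and
  the brute-force segregation oracle enumerates all carrier subsets of
  families up to six members.

## Limitations

The package prioritises dominant-model sharing only: no compound
heterozygotes, no recessive model, no phasing, IBD or linkage
computation, and no mosaic/somatic modelling on the de novo side.
Deleteriousness predictions are consumed, never computed. Tier
assignment has no within-tier evidence weighting. The enrichment test is
a single pre-specified 2×2 χ²; there is no multiple-testing machinery.
These are scope boundaries, not oversights — each matches the published
analysis this package operationalises.
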