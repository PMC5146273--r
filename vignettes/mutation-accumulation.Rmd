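---
title: "Calling de novo mutations in mutation-accumulation pedigrees"
author: "mutacc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling de novo mutations in mutation-accumulation pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutacc)
```

## Scope and model

`mutacc` quantifies de novo mutations in mutation-accumulation (MA)
pedigrees from per-genome, per-position base-count matrices ("genome
matrices": total coverage plus counts of A, C, G, T, deletion and N).
Everything upstream of the matrix — read trimming, alignment, duplicate
removal, repeat annotation — is out of scope; masks are consumed as BED,
annotation as GFF3, references as FASTA.

The genotype model is deliberately simple and threshold-based rather
than likelihood-based: in a selfing diploid MA design the only genotypes
of interest are homozygous reference, heterozygous, and homozygous
mutant, and at ≥20× coverage their mutant-allele-frequency distributions
are well separated. The classification intervals are

* `[0, 0.1)` homozygous reference,
* `[0.1, 0.3)` putative sequencing error (rejected),
* `[0.3, 0.8)` heterozygous (accepted),
* `[0.8, 0.9]` undefined (rejected),
* `(0.9, 1]` homozygous mutant (accepted),

with coverage `< 20` overriding to low-coverage and masked regions
excluded entirely. The printed forms of these thresholds use touching
ranges; we fix the measure-zero boundaries as left-closed/right-open for
the two interior intervals, `[0.8, 0.9]` closed, and homozygous strictly
above 0.9, which preserves the strict readings "> 0.9" and "< 0.1".
These boundaries never matter for real data but must be pinned down for
exact tests. A position where *two* distinct non-reference alleles each
reach frequency 0.1 is classified undefined: the design has no
multi-allelic genotype, and refusing to call is the conservative choice.

The 0.3 heterozygous cutoff is not arbitrary: at 2% per-base error and
41× coverage, error-driven allele frequencies pile up below ~0.2 while
true heterozygous frequencies are approximately binomial around 0.5, and
the histogram between the two modes has its minimum near 0.3. The
spike-in harness (below) reproduces exactly this separation, and
`evaluate_caller()` returns the frequency vectors so the histogram can
be drawn.

## Cohort filtering and accessibility

A candidate call is accepted as a novel mutation only against a
background cohort of sibling genomes of the same genotype (typically
nine): no background may show the same variant, and at least six must
show homozygous wild-type calls. Rejection reasons are evaluated in a
fixed order — shared variant, then (i) more than one undefined
background, (ii) a different mutation in any background, (iii) more than
three backgrounds under 20×, (iv) fewer than six homozygous wild-type
backgrounds — so audit labels are reproducible. Sequencing-error-class
background calls count neither as wild-type evidence nor as mutations.
For second- and third-generation focal genomes the parental genome is
excluded from the background list (the pedigree is represented by a
parent pointer per genome); `call_genome()` simply takes the
post-exclusion list and refuses cohorts smaller than six.

*Accessible sites* — the rate denominator — are the positions at which a
mutation could have been seen in the focal genome: unmasked, ≥20×
covered, and not classified undefined. Whether background-cohort
criteria should also gate accessibility is ambiguous in a
threshold-based design; we default to focal-only accessibility (the
scale-free reading) and treat the cohort rules purely as acceptance
filters. The accessible fraction of a simulated 41× genome is then the
Poisson tail `P(cov ≥ 20) ≈ 0.9998` minus the masked fraction, which the
test suite checks in closed form. Real genomes have far lower accessible
fractions (~75%) because repeats and unmappable regions dominate; the
simulator does not emulate mappability, only the masking mechanism.

Normalization follows

```
n = ((total genome / accessible genome) × accepted mutations) / treated generations
```

and `per_site_rate(n, genome_size)` divides by the full genome length.
Fold changes are reported raw and at a one-decimal display precision
(integral displays drop the decimal, matching how such ratios are
conventionally printed). For two-group contrasts `compare_groups()`
builds the 2×2 table `[[mutations, accessible − mutations]]` per group —
a convention, since a sites-versus-mutations contrast can be pooled in
more than one way — so its Fisher p-values should be read as indicative.

## Deletions

The matrix has a deletion column but no insertion channel, so only
deletions (1–4 bp in practice) are callable. They pass through the same
frequency thresholds; adjacent accepted single-base deletion calls with
equal zygosity are merged into one multi-base record, which is this
package's convention (nothing in a count matrix marks event boundaries).
VCF output uses the standard left-anchored representation.

## The synthetic-data generator

The generator exists so that the caller's error rates are measurable
against known truth, and its defaults are the study conditions used
throughout the tests:

* **Genome**: 1 Mb, one chromosome, base composition A = T = 0.3,
  C = G = 0.2 (matching the motif background). Annotation is placed by
  labelling 500 bp slots to hit the target proportions exactly (defaults
  gene 0.45, TE 0.20, the remainder intergenic — the coarse composition
  of a compact plant genome), merging adjacent same-label slots into
  multi-kb elements; one TE is always placed across a gene end so the
  TE-precedence fraction rule is exercised. Genes carry single-interval
  CDS models (multiple-of-3 length, random strand). A 2.5% mask stands
  in for low-complexity regions (the masked share of the genome the
  design assumes).
* **Methylome**: every cytosine on both strands gets a CG/CHG/CHH
  context from its own-strand downstream bases and a Bernoulli
  methylation state (defaults CG 0.45, CHG 0.25, CHH 0.05, chosen so the
  pooled methylated fraction is ~15–16%, the genome background a
  replicate-threshold calling scheme yields).
* **Sequencing**: coverage Poisson(λ = 41); every read-base emits the
  genotype allele (heterozygous sites emit the mutant with probability
  0.5) and is corrupted with probability ε = 0.02 to one of the three
  other bases uniformly, with optional sub-rates (default 0) into the
  deletion and N columns. The 2% figure is a per-read-base symmetric
  substitution rate; read-simulator error profiles (insert sizes,
  quality decay, alignment loss) are deliberately not modelled, because
  the caller only consumes counts — this is the one simplification that
  makes the harness desk-scale.
* **Spikes**: 31 homozygous + 59 heterozygous mutations (a one-tenth
  scaling of a 900-spike genome-wide design with 308:592 zygosity).
* **UV-B-like process**: a binomial share (default 0.88) of mutations
  are G:C→A:T transitions placed at cytosines with weight
  `TC(C/T)-context weight × methylated multiplier` (defaults 20 and 2.1;
  2.1 is the odds ratio that turns a 15% methylated background into a
  27% methylated share among mutations); the remaining mutations are
  uniform over the other five classes.
* **Inheritance**: `simulate_selfing()` segregates pre-split
  heterozygous mutations 1:2:1 (absent:het:hom) per progeny and
  transmits post-split mutations heterozygous to the sequenced progeny
  (the progeny descends from the affected gamete lineage; sector sizes
  are not modelled). One progeny per parent is the default, matching the
  single-seed-descent sequencing design that the 2:1 expectation
  conditions on. `simulate_reciprocal_cross()` transmits homozygous
  parental mutations always and heterozygous ones with probability 0.5,
  all heterozygous in the F1, tagged by parent of origin.

Everything is deterministic given the configuration and one integer
seed; generators restore the caller's RNG state.

What passing spike-in tests shows — and what it does not: the harness
demonstrates that the thresholds and cohort rules recover essentially
all accessible spiked mutations (pooled false-negative rate under 2% at
41×/2% across ten seeds, zero false positives) and that with no
sequencing error at 60× recovery is exact. At 41× a heterozygous site
can drift binomially below the 0.3 cutoff even with ε = 0, which is why
the exact round-trip condition is stated at 60×. None of this
demonstrates robustness to alignment artefacts, mapping bias, or index
hopping, which live upstream of the matrix.

## Spectra, contexts and motifs

Substitutions collapse to six strand-symmetric classes through the
complement (G→A and C→T are one class). Contexts are ±3 bp 7-mers
oriented to the pyrimidine strand, so purine-reference records are
reverse-complemented and all members of a class share a frame. Motif
columns are scored by relative entropy against the non-uniform
background A = T = 0.3, C = G = 0.2:

\[ D_j = \sum_b f_{b,j} \log_2 (f_{b,j} / p_b), \qquad
   h_{b,j} = f_{b,j} D_j , \]

with `0·log 0 ≡ 0`. This is the standard non-uniform-background logo
definition; the formula is stated here precisely so scores are
reproducible without any particular logo software. No small-sample
correction is applied. Following the usual display convention the
mutated column's drawn height is capped at 1 bit; stored scores are
never altered. Deletions are excluded from spectrum denominators.

Genomic fractions use gene models *including* UTRs/introns, with TEs
(and TE-genes) taking precedence over overlapping gene models; coding
effects use CDS only, strand-aware, with stop gain/loss counted as
non-synonymous and deletions excluded from the synonymous tally.

## Methylation

`call_methylation()` is a literal implementation of the replicate rules:
replicates under 10 reads are ignored; methylated means ≥10% methylation
(inclusive) in at least two qualifying replicates; fewer than two
qualifying replicates means not analysed. `methylation_overlap()`
contrasts the methylated share among mutated cytosines (G:C→A:T records
only; a G>A record is looked up at its own position on the minus strand,
i.e. the mutated strand's cytosine — the convention when both strands of
a CG site are analysable) against all analysable cytosines, per context
and pooled ("CNN"), with a Yates-corrected χ² on the 2×2 table. Contexts
with no testable mutation are reported untestable rather than given a
p-value; with few testable positions (as happens for CHH in small
control sets) the test is fragile and the absolute counts are always
reported alongside.

## Germline timing

Under selfing, a heterozygous mutation that arose before the separation
of male and female cell lineages is carried by 3/4 of progeny, 2/3 of
carriers heterozygous — hence the 2:1 expectation. Writing `q` for the
post-split fraction *among transmitted (observed) mutations*, the
carrier mixture gives `R = (2 + q)/(1 − q)` and the estimator
`q̂ = (R − 2)/(R + 1)`, clipped to [0, 1] and flagged when `R < 2`.
Note the estimand: among *parental* mutations the relation would be
`R = 2(1 + q)/(1 − q)`, because pre-split mutations are only carried by
3/4 of progeny; `q̂` deliberately estimates the observed-set fraction,
which is what the recovery tests check. Ratios are computed on
normalized per-haploid-genome counts when those are supplied, raw counts
otherwise, and both are worth reporting. `q̂` carries no analytic
confidence interval; if one is needed, bootstrap over genomes.

`cross_analysis()` asserts that every F1 mutation is heterozygous (a
homozygous record flags the genome as a selfing contaminant and removes
it from the group statistics), attributes each genome's
irradiated-parent mutations to that parent, and compares the two cross
directions by t-test.

## Numerical conventions and degenerate inputs

* Ties for the top non-reference allele report the lexicographically
  smallest allele (deletion last); any second allele at ≥0.1 makes the
  position undefined.
* Zero coverage is a no-data signal (`NA` allele and frequency); it is
  low-coverage for accessibility purposes.
* Fisher tables with an empty margin return p = 1 with a warning; the
  Yates χ² refuses empty margins. The Yates correction term is floored
  at zero.
* Display rounding is half-even at the stated precision, and raw values
  are always carried.
* Contexts within 3 bp of a contig end are skipped with a warning;
  cytosines within 2 bp of an end have no resolvable context and are
  omitted from the methylome.
* Identical configuration + seed gives byte-identical output for every
  generator and the whole pipeline; derived seeds keep child streams
  independent of evaluation order.

## Problem sizes used in the tests

The validation suite runs the full caller on a 1 Mb genome with 90
spikes at 41×/2% over ten seeds, the oracle-equivalence property on
400-position cohorts against a literal brute-force reimplementation over
100 random cohorts, segregation at 10⁵ mutations, and process-parameter
recovery at n = 5000 (binomial CI) — sizes chosen so the whole suite
stays in the minutes range on one CPU while keeping every statistical
check well-powered.

## Known limitations

Insertions are not callable (no matrix channel); multi-base deletion
boundaries are a run-merging convention; accessibility of real genomes
is dominated by mappability, which is not emulated; the contingency
layout behind two-group Fisher tests is a documented convention; somatic
mosaicism and sector-size inheritance are not modelled.
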