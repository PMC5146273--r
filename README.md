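# mutacc

De novo mutation calling and rate estimation for mutation-accumulation
experiments, with a built-in spike-in simulation harness.

## The problem

Mutation-accumulation (MA) pedigrees — lines propagated by single-seed
descent so that new mutations drift to fixation with minimal selection —
are the standard design for measuring per-generation mutation rates and
for asking how a treatment (here, chronic UV-B exposure) or a repair
deficiency changes the rate, the substitution spectrum, the sequence
context, and the developmental timing of new mutations.

`mutacc` implements the analysis layer of such an experiment, starting
from the **genome matrix**: a per-position table of total read coverage
and counts of the six observable alleles (A, C, G, T, deletion, N) for
each re-sequenced genome. It is aimed at users who already have
per-position pileup counts (or want to simulate them) and need a
transparent, fully testable caller and downstream characterization.

## The method

**Classification.** At every position the mutant allele is the
highest-count non-reference allele and its frequency `f` (count /
coverage) is classified by fixed thresholds:

| frequency    | classification                       |
|--------------|--------------------------------------|
| `f > 0.9`    | homozygous mutation, accepted        |
| `0.8–0.9`    | undefined, not accepted              |
| `0.3–0.8`    | heterozygous mutation, accepted      |
| `0.1–0.3`    | putative sequencing error, rejected  |
| `f < 0.1`    | reference allele                     |

Positions covered by fewer than 20 reads are low-coverage; masked
(low-complexity / tandem-repeat) regions are excluded outright.

**Cohort filtering.** A candidate is a *novel* mutation only if none of
the (typically nine) background genomes of the same genotype shows the
same variant and at least six show a homozygous wild-type call, with
rejection rules for: >1 undefined background, any background carrying a
different mutation there, >3 insufficiently covered backgrounds, and <6
homozygous wild-type backgrounds. For later generations the parental
genome is excluded from the background list.

**Normalization.** Accepted counts are normalized over *accessible
sites* (unmasked, ≥20×, classifiable):

```
n = ((total genome / accessible genome) × accepted mutations) / treated generations
```

and `n / genome size` gives the per-site per-generation rate.

**Characterization.** Substitutions collapse into the six
strand-symmetric classes (G:C→A:T first), ±3 bp contexts are extracted
on the pyrimidine strand and scored as relative-entropy (bit) logos
against the background A = T = 0.3, C = G = 0.2; genomic fractions use
TE-over-gene precedence; cytosine methylation is called from replicate
profiles (≥10 reads, ≥10% methylation in ≥2 replicates) and contrasted
between mutated and genomic cytosines per CG/CHG/CHH context with a
Yates-corrected χ²; germline timing is inferred from the
heterozygous:homozygous ratio `R` (2:1 expected for purely pre-split
mutations under selfing; the post-split fraction is `(R−2)/(R+1)`), and
reciprocal-cross F1 genomes attribute mutations to the irradiated
parent.

**Validation harness.** A synthetic-data generator builds an annotated
reference (genes with CDS models, transposons, mask, context-stratified
methylome), spikes homozygous/heterozygous mutations or a UV-B-like
process (configurable G:C→A:T fraction, TC(C/T) context weight,
methylated-cytosine multiplier), and simulates genome matrices with
Poisson coverage and per-read-base errors, so false-negative and
false-positive rates of the caller are measurable against known truth.

## Worked example

```r
library(mutacc)

cfg <- sim_config(genome_size = 1e5, n_hom = 5, n_het = 10)
rep <- run_validation_experiment(cfg, seed = 42)
unlist(rep$evaluation[c("n_truth", "n_truth_accessible", "fn", "fp")])
#>            n_truth n_truth_accessible                 fn                 fp
#>                 15                 15                  0                  0

n <- normalize_count(cfg$genome_size, rep$n_accessible, nrow(rep$calls), 1)
rep$n_accessible                       # 97487 accessible sites (97.5%)
round(n, 2)                            # 15.39 mutations / haploid genome / generation
signif(per_site_rate(n, cfg$genome_size), 3)   # 0.000154 per site
```

All 15 spiked mutations fell at accessible sites and all were recovered
with no false positives at 41× coverage and a 2% per-read-base error
rate; the normalized count reproduces the spike load (15 true mutations
over 97.5% accessible sites → 15.39 after accessibility correction).

The UV-B-like process and its signature:

```r
ref <- generate_reference(sim_config(genome_size = 1e5), seed = 1)
tr  <- simulate_uvb_process(ref, 2000, seed = 2)
head(spectrum_table(tr), 3)
#>     class count proportion
#> 1 G:C>A:T  1771     0.8855
#> 2 A:T>G:C    57     0.0285
#> 3 A:T>T:A    45     0.0225

round(motif_scores(tr$context[tr$ref %in% c("C", "G")])$score, 2)
#> 0.01 0.00 0.62 2.32 0.35 0.00 0.00
```

88.6% of simulated mutations are G:C→A:T (the configured 0.88), and the
motif columns show strong information at offsets −1 and +1 around the
mutated cytosine (the TC(C/T) preference) and none beyond — the expected
dipyrimidine signature.

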