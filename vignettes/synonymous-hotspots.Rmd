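---
title: "Models and methods: synonymous mutation signatures and hotspot detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: synonymous mutation signatures and hotspot detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Synonymous single-nucleotide variants leave the protein sequence unchanged,
yet recurrent synonymous changes in tumors can act as drivers — through
splicing, mRNA stability, or the exchange of a translationally optimal codon
for a non-optimal one. `synsig` implements the full analysis chain for such
catalogs: per-mutation codon and sequence-context annotation, cohort-level
substitution and amino-acid spectra, hotspot detection at amino-acid
resolution against a context-stratified Poisson background, and three-way
comparisons (conservation, amino-acid usage, protein-domain overlap) between
hotspot, non-hotspot and neutral-cohort mutations. A seeded simulator
generates every input the pipeline consumes, so each stage can be validated
end to end without external downloads.

```{r setup, message = FALSE}
library(synsig)
library(dplyr)
```

## Annotation model

Each variant is a row (`sample_id`, `cancer_type`, `gene_id`, `cds_pos`,
`ref`, `alt`) joined to its gene's coding sequence. From the 1-based CDS
coordinate the annotation derives the amino-acid position
(`ceil(cds_pos / 3)`), the position within the codon (1, 2 or 3), the
reference and alternate codons, synonymy under the standard genetic code,
and the ordered substitution pattern (one of 12, e.g. `C>T`).

Every substitution is then assigned to one of six **sequence-context
subtypes**: transitions and transversions at A:T reference sites (`ATts`,
`ATtv`), and at G:C sites additionally split by CpG context (`C_GCts`,
`C_GCtv` inside CpG; `NC_GCts`, `NC_GCtv` outside). Two deliberate choices:

* **CpG means CpG dinucleotide, not annotated CpG island.** A site is "CpG"
  when its reference base is a C followed by G or a G preceded by C on the
  coding strand. The classifier must work per site from the CDS alone;
  genomic island annotation would require flanking sequence the inputs do
  not carry. A missing neighbour at a CDS end counts as non-CpG on that
  side, and context is always read from the *reference* sequence
  (pre-mutation).
* **Stop-codon synonymous exchanges (e.g. TAA↔TAG) are excluded**
  everywhere: the analyses are defined over amino acids, and stop codons
  encode none.

Degeneracy facts used throughout (and asserted in tests): exactly two amino
acids (Met, Trp) are single-codon and can never mutate synonymously; 18 are
degenerate; Leu, Ser, Arg have six codons each. An exhaustive scan of the
61 sense codons confirms that synonymous changes occur at the third codon
position, except the Leu T↔C and Arg C↔A exchanges at position one — a
structural property of the code that the annotation layer must reproduce
exactly.

**Optimal codons.** Whether a synonymous change converts an optimal codon
to a non-optimal one matters for translation efficiency. The packaged
default set (`inst/extdata/optimal_codons.tsv`, editable) takes the
highest-frequency human codon per amino acid, and the top two for Leu and
Ser; under it Arg has one optimal codon and Leu and Ser two each, matching
the usage asymmetry of the six-fold families. Any table can be substituted
via `codon_table(optimal = ...)`; entries are validated against the code.

## Spectra

`pattern_spectrum()` reports, per group (cancer type by default), the
proportion of mutations of each of the 12 ordered substitutions. The
`"All"` row is the **unweighted mean of per-group proportions**, not the
pooled proportion — large cohorts would otherwise dominate the cohort-level
signature. Within a cancer type, mutations are pooled (samples are not
re-weighted). The codon-position split (`by_codon_pos = TRUE`) refines the
same proportions over positions 1 and 3; a synonymous change at position 2
is impossible and is treated as a hard error rather than silently dropped.

`aa_spectrum()` and `degeneracy_spectrum()` give proportions over the 18
degenerate amino acids and over the 2/3/4/6-fold degeneracy classes;
`degeneracy_correlation()` is the Pearson correlation (and its square)
between per-amino-acid mutation percentage and codon count.
`one_sample_ttest()` compares a vector of per-cancer proportions against a
fixed reference value (typically the neutral cohort's mean for the same
pattern); it errors on zero variance, where the t statistic is undefined.
`per_sample_load()` divides mutations by *observed* samples — a sample with
zero mutations never appears in a mutation table and cannot enter the
denominator, which is documented behaviour rather than a bug.

## The hotspot model

A hotspot is an amino-acid position whose synonymous mutation count exceeds
what the gene, the cancer type and the sequence-context composition of the
cohort predict. The background needs a denominator: the **synonymous
opportunity** of a position, the number of (site, alternate-base) pairs in
its codon whose substitution is synonymous, classified by subtype
(`synonymous_opportunities()`; each count is between 0 and 9).

For gene $g$, cancer type $c$ and subtype $s$, let $N_{gcs}$ be the
observed synonymous mutation total and $o_{ps}$ the opportunity of position
$p$. The expected count at $p$ is

$$\lambda_{ps} = N_{gcs} \cdot \frac{o_{ps}}{\sum_{p'} o_{p's}},$$

i.e. the observed per-stratum mass redistributed proportionally to
opportunity. This is the minimal model consistent with a background
"characterized by genes, cancer types and mutation subtypes"; summing
$\lambda$ over positions returns $N_{gcs}$ exactly, which the tests assert
to machine precision. Per tested position, each subtype with non-zero
opportunity contributes an upper-tail Poisson p-value
$P(X \ge k \mid \lambda_{ps})$; subtypes with zero opportunity are *left
out* of the combination rather than entered as $p = 1$, because structural
impossibility is non-information that would only dilute the statistic.
The per-subtype p-values are combined with Fisher's method
($-2\sum\ln p \sim \chi^2_{2m}$), floored at $10^{-300}$ before the log to
keep the statistic finite, and adjusted by Benjamini–Hochberg across all
tested positions in the run (pooled over genes and cancer types by
default; `pool = "per_cancer"` adjusts within cancer type). Only positions
observed at least `min_count = 2` times in a stratum are tested — a
hotspot is by definition recurrent. An optional pathogenicity-label table
(a stand-in for an external variant-effect classifier) gates *reporting*
after the statistics: labelled-benign positions keep their p and q values
but are not reported.

### Calibration behaviour, measured

The recovery harness (`hotspot_recovery()`, 25 seeded replicates, 50 genes,
a single cancer type with 120 samples at 100 synonymous mutations each,
eight 20-fold planted hotspots) recovers planted positions expecting at
least 8 hits with sensitivity well above 0.8 (0.985 at the default seed of
the acceptance script). On matched null cohorts (`hotspot_null_rate()`,
~5,000 mutations, no planted hotspots) the caller reports at least one
borderline hotspot (q between ~0.02 and 0.05, 3–5 recurrences) in roughly
a quarter to half of replicates, depending on seeds. This inflation is
structural, not an estimation artefact: a parametric bootstrap that draws
counts directly from the fitted background Poissons — the model exactly
true, no estimation error — and pushes them through the same procedure
shows the same rate. The cause is the interaction of the recurrence gate
with the FDR pool: ~27,500 positions are screened down to the ~550 that
reach two observations, the survivors are by construction small-p, yet the
BH denominator counts only them. Raising `min_count`, lowering `alpha`, or
adjusting over all screened positions would each restore conservatism at a
direct cost in sensitivity near the detection boundary (6–7 observed
hits); we keep the recurrence-gated design because hotspot nomination is a
screening step whose output is expected to be filtered further (here, by
the pathogenicity gate), and we document the measured false-positive
behaviour rather than hide it. Users wanting strict control should treat
reported q-values near `alpha` with caution or raise `min_count`.

## Comparative analyses

`build_control_sets()` fixes the three comparison sets around a call set:
**hotspot** (tumor mutations at reported gene/amino-acid positions),
**non-hotspot** (remaining tumor mutations in hotspot-containing genes)
and **neutral** (neutral-cohort mutations in those genes). Membership is by
cohort — a neutral-cohort mutation at a hotspot position stays in the
neutral set — and the first two sets partition the tumor mutations of
hotspot-containing genes exactly.

Conservation is compared with a **one-tailed unpaired t-test** in the
direction "hotspots more conserved", Welch (unequal-variance) form by
default with the pooled form behind `var_equal = TRUE` — the safe default
when nothing guarantees equal variances between a handful of hotspot sites
and hundreds of background sites. Scores are taken at each mutation's own
nucleotide site (not averaged over the codon), and one observation enters
per distinct mutated site regardless of recurrence, so that a single
heavily recurrent hotspot cannot masquerade as many independent
conservation measurements. Sites missing from the score track are dropped
with a logged count; an entirely unscored set is an error.

`domain_overlap()` maps mutations to closed amino-acid intervals; a
mutation under overlapping intervals of the same accession counts once per
accession. It reports per-set accession sets, the seven Venn-region counts,
and — for accessions hit by all three sets — each set's share of that
domain's mutations (shares sum to one per domain).

## The simulator

The generator's role is to produce inputs with exactly the statistical
structure the analysis assumes, plus a ground-truth manifest for recovery
tests. Defaults (all in `simulate_config()`):

* **Genes**: 50 coding sequences, lengths uniform over multiples of 3 in
  300–3,000 nt at GC 0.5; ATG start, clean interior, trailing stop.
  Interior codons are drawn from the 61 sense codons with probabilities
  proportional to per-base probabilities at the target GC, so realized GC
  tracks the request to within a few hundredths.
* **Cohorts**: per-sample mutation counts Poisson (mean 100 for tumor
  samples, 50 for the neutral cohort); each mutation is drawn over the
  genes' synonymous opportunities with probability proportional to a
  per-subtype weight. The tumor weights lean strongly toward G:C
  transitions (strongest in CpG context), the neutral weights toward A:T
  transitions — the qualitative tumor-vs-population contrast the analyses
  are meant to detect. With these weights the realized tumor spectrum has
  `C>T` as its modal pattern, and the neutral cohort's `T>C` proportion
  exceeds the tumor's by a wide margin (~30% vs ~7%); the `C>T`-over-`G>A`
  ordering inside the tumor cohort is itself structural, because the code
  makes every NNC→NNT change synonymous but not every NNG→NNA.
* **Hotspots**: planted at codons that have a G:C-transition opportunity
  (the dominant context of real calls), with every synonymous opportunity
  in the codon up-weighted 20-fold. The manifest records each hotspot's
  analytic expected hit count, so recovery tests can restrict to hotspots
  that carry enough signal to be fair targets (≥ 8 expected hits).
* **Scores**: every CDS site gets a Normal(0, 1) rejected-substitution
  score; the three sites of each planted hotspot codon are shifted by
  +2 — a two-standard-deviation conservation excess.
* **Domains**: non-overlapping intervals per gene, accessions drawn from a
  small shared pool so the same accession recurs across genes and the
  three-way domain intersection is non-trivial.
* **Pathogenicity**: planted hotspots labelled `TRUE`, with optional flip
  noise.

Determinism: every artifact draws from its own RNG stream keyed by
(master seed, artifact name) via `withr::with_seed` (Mersenne–Twister), so
adding or reconfiguring one artifact never perturbs another, and a written
study is byte-identical across runs.

What the simulator does *not* emulate — and what passing tests therefore do
not show about real catalogs: trinucleotide-signature structure beyond the
six subtypes, regional mutation-rate covariates (replication timing,
expression, chromatin), strand asymmetry, sample-level heterogeneity of
signature composition, and selection on non-hotspot sites. The background
model is exactly correctly specified for generated data; on real data it is
an approximation, and its residual miscalibration would add to the
screening effect discussed above.

## Numerical and degenerate-input choices

* Poisson tails via the exact distribution function (`ppois` upper tail),
  verified against term-by-term series summation at 1e-12.
* Fisher's statistic floored at `p_floor = 1e-300`; a literal zero p-value
  is an error at the combination layer so the caller's floor is explicit.
* `poisson_tail(0, lambda) = 1` by definition; a position can never be
  penalized for mutations it does not have.
* Zero-variance inputs error (one-sample t, degeneracy correlation) rather
  than returning NaN.
* Empty mutation groups are reported as missing proportions, not zeros.
* Validation is front-loaded: malformed rows, reference-base mismatches,
  out-of-range coordinates, duplicate score sites and out-of-bounds domain
  intervals all fail with messages naming the offending line or site.

## Problem sizes used by the packaged checks

The test suite and the acceptance script exercise the pipeline at sizes
chosen to make every property measurable in minutes on one core: 25
replicates of the 50-gene recovery and null configurations (~12,000 and
~5,000 mutations per replicate), a 20-gene configuration for the
conservation harness, and the generator defaults (three cancer types,
40 samples each) for the cohort-bias contrast. These sizes are the
package's validation conditions; nothing in the method depends on them.
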