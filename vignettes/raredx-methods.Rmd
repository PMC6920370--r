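---
title: "Methods: segregation filtering, label-error search, and hidden-locus scanning in raredx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segregation filtering, label-error search, and hidden-locus scanning in raredx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis problem

`raredx` targets the small-cohort rare-disease setting: a few dozen
families, each with a distinct suspected-Mendelian disorder, jointly
genotyped by whole-genome sequencing. Under the *rare disease, rare
variant* hypothesis, the causative variant of one family is (i)
consistent with some inheritance model given that family's affection
labels, (ii) absent from every sequenced member of the other families,
(iii) rare in reference populations, and (iv) protein-damaging. Each of
these is a deterministic predicate, so the pipeline is a cascade of
set-shrinking filters rather than an association test. The package adds
two recoveries for when the plain cascade fails: a search over
affection-label reassignments (clinical labels are fallible) and a
variant-density scan that finds causal events invisible to SNV calling
(repeat expansions) through the linkage block that co-segregates with
them.

# Segregation predicates

All genotypes are reduced at ingest to biallelic alt-allele dosages
`0/1/2/NA` per sample; multiallelic records are split per alt allele,
with a sample's other alt alleles treated as missing in each split
record. The per-model predicates over a family with labels *L*:

* **dominant** — every sequenced affected carries (`g >= 1`), no
  sequenced unaffected carries. No affected parent is demanded, so a
  founder mutation segregating in a multiplex sibship still qualifies.
* **recessive homozygous** — every sequenced affected is `g = 2`, no
  sequenced unaffected is `g = 2`, and every sequenced parent of an
  affected carries (parents of a true recessive case are obligate
  carriers; this cheaply removes genotyping artifacts).
* **compound heterozygous** — pairs `(a, b)` in one gene with every
  sequenced affected het for both; where an affected has both parents
  sequenced, the pair must be trans-compatible (one variant
  transmissible from each parent; a father het for both and a
  non-carrier mother is cis and excluded). Without any parental
  genotypes, pairs are reported flagged `phaseUnknown` rather than
  discarded — phase certainty should gate interpretation, not
  discovery.
* **X-linked recessive** — affected males carry (hemizygotes may be
  coded `0/1` or `1/1` by diploid callers; both count), affected
  females are `g = 2`, unaffected males carry nothing, unaffected
  females are not `g = 2`.
* **de novo** — over affecteds with both parents sequenced: the child
  carries, both parents are `g = 0`, and additionally *no* sequenced
  unaffected anywhere in the family carries. The extra clause uses
  extended relatives as controls; it is stricter than minimal trio
  logic and is a deliberate design choice, not a claim about how such
  filters are usually built.

**Missing-call policy.** WGS at ~30x has dropout, so a missing call
never violates a predicate; but a variant whose support among affecteds
is entirely missing fails (no positive evidence). This single rule is
applied uniformly across models.

**Unknown affection** is unconstrained everywhere: filters reason only
over diagnosed members.

**Cross-family exclusion** removes any variant observed (`g >= 1`, not
merely missing) in a sequenced subject outside the target family, and
runs before the model predicates.

# The misclassification-tolerant search

Affection labels carry a `firm`/`soft` confidence flag (PED column 7;
everyone defaults to soft, since both self-reports and clinician records
have been wrong in this setting). For `maxFlips = k`, the search
enumerates all label assignments flipping `0..k` soft sequenced
members, in ascending flip count and lexicographic order within a
count, re-runs the full cascade under each, and reports each surviving
candidate once, at the minimal flip count at which it first appears,
with every flip set producing it at that count. Ranking is
(minimal flips, number of distinct flip sets, genomic coordinate) — a
candidate needing fewer and less ambiguous label corrections ranks
higher. The annotation-side filters (frequency/database, predictor
vote) do not depend on labels, so they are applied once up front; only
segregation is recomputed per assignment. A guard refuses searches
whose assignment count exceeds `10^5`. An assignment can void a model's
precondition (e.g. flipping away every affected with sequenced
parents); such models contribute nothing under that assignment rather
than erroring.

# Annotation filters

* **Functional classes**: frameshift / non-frameshift indel (length
  difference mod 3 against coding sequence), missense / nonsense /
  synonymous by codon translation against a minimal gene model,
  splicing for the two intronic bases flanking any coding exon boundary
  (the canonical dinucleotide), noncoding otherwise. A variant
  overlapping several genes yields one record per gene.
* **Frequency rule**: remove when any clause `(k, t)` of
  `(1, 0.05), (2, 0.03), (3, 0.025), (4, 0.02)` is met by `>= k`
  populations with frequency `>= t`. "Population" defaults to the five
  1000 Genomes super-populations; the finer 26-population grid would
  make the multi-population clauses strictly more aggressive, and the
  coarse grid is the conservative reading. Both the clause list and the
  population set are parameters.
* **Database policy**: the default removes on the frequency rule or an
  ESP-recorded frequency over the single-population threshold; *bare*
  dbSNP membership does not remove, because known pathogenic alleles
  are in dbSNP. A `strict` policy (any dbSNP membership removes) is
  provided; whether one should use it depends on how one's annotation
  source was built, and the package deliberately asserts neither as
  canonical.
* **Predictor consensus**: "damaging overwhelms" is read as a strict
  majority of non-missing calls among the eight tools; ties and
  all-missing are not deleterious (conservative for missense).
  Truncating classes bypass the vote — the predictors only score
  non-silent coding SNVs. Non-frameshift indels are deleterious when
  any tool says so, since most tools abstain on indels.

Stage order is fixed to segregation → database/frequency → prediction
so the trace mirrors the cascade's narrative; a `frequency_first`
switch exists because the filters commute as set intersections (a
property asserted by a test), changing only cost and trace shape.

# The variant-density scan

The scan consumes variants that already passed dominant-model
segregation and the database stage for one family — *co-segregating,
rare* variants — and is genotype-agnostic from there. Chromosome-level
enrichment is a one-sided binomial test of the per-chromosome count
against expectation proportional to chromosome length, BH-adjusted
across chromosomes, flagged at `q < 0.05`. On a flagged chromosome, a
sliding window (1 Mb window, 0.5 Mb step) is counted; the peak window
is the maximal count (ties to the smallest start); the *enriched run*
is the maximal contiguous stretch of windows containing the peak with
count at least half the peak; the *peak center* is the median position
of variants inside the peak window, rounded to 1 kb — the median is
robust when the peak window clips the edge of a cluster, where the
window midpoint is not. The candidate interval is peak center ± 1 Mb
(the half-width is a parameter), and candidate genes are all genes
overlapping it, ranked by midpoint distance to the center. The run,
center and interval definitions are explicit conventions of this
package: they formalize a procedure that in practice is often done by
eye on a density plot.

# De novo CNV calls

A child segment is *inherited* from a parent when some same-state
parental segment reaches reciprocal overlap
`min(ov/len_child, ov/len_parent) >= 0.5`, de novo otherwise. The 0.5
default is the field's customary reciprocal-overlap convention for
calling two segments "the same event" and is exposed as a parameter.
Only loss-vs-loss and gain-vs-gain overlaps count. Significance testing
of segments from read depth is upstream and out of scope; segments
arrive pre-called.

# The synthetic cohort generator

`simulateCohort()` makes the cascade's assumptions *true by
construction* and records the ground truth:

* **Shape**: 16 families, 79 sequenced members — one ten-member
  four-generation family (six affected, four unaffected sequenced),
  three three-generation families with eight sequenced, nine quartets,
  three trios. These template shapes mirror the pedigree variety the
  analysis must cope with (multiplex, extended, nuclear).
* **Decoys**: 20,000 variant sites placed proportional to chromosome
  length on a GRCh37-style genome. Each site draws a base frequency
  from a 50/50 mixture of a common component (`U(0.02, 0.25)`) and a
  rare tail (exponential, mean 0.004, capped at 0.02), then
  per-super-population frequencies as correlated log-normal
  perturbations of it — so the multi-population frequency rule has
  non-trivial behavior. Founders draw genotypes at Hardy–Weinberg from
  the EAS frequency (an East-Asian study population); non-founders
  receive one uniformly chosen allele per parent (gene dropping), each
  site independent. X sites transmit accordingly; male hemizygotes are
  coded as homozygous diploid calls.
* **Planting**: exactly one causal event per cohort, in a family whose
  template supports the scenario, absent from all other families.
  Causal SNVs are annotated rare (empty frequency map) and
  protein-altering; missense causals get predictor calls damaging with
  probability 0.9 per tool, so the consensus vote is genuinely
  exercised rather than bypassed.
* **Linkage-block scenario**: ~100 rare variants on one founder
  haplotype spanning 16 Mb, transmitted without recombination,
  het in exactly the affected members; the hidden locus (the
  repeat-expansion stand-in) is offset up to ±2 Mb from the block
  center and is *not* represented as a variant record. Half the block
  variants are placed `N(locus, 1 Mb)`, half uniformly over the block:
  the mixture gives both the block-wide spread of a real shared
  haplotype and a density mode at the locus, which a pure uniform
  placement lacks — under uniform placement no windowed estimator
  could localize the locus to ±1 Mb better than chance, because the
  variant positions would carry no information about where inside the
  block the locus sits.
* **Noise**: 1% missing calls; genotype errors at 0.1% are *allele
  dropouts* (het → hom-ref, hom-alt → het). After joint calling and
  QC, dropout is the residual error mode that matters for segregation
  logic; symmetric false-positive hets at that rate would contradict
  the generator's own premise that cross-family exclusion is sound,
  i.e. would simulate a different (and pathological) cohort rather
  than a noisier version of this one. False-positive calls are
  therefore out of the generator's scope and listed under limitations.
* **Label noise** is applied to the emitted PED only; the manifest
  keeps truth labels and the flip list.
* **Determinism**: one master seed; per-family and per-stage substreams
  are derived arithmetically from it, so outputs are byte-identical
  across runs of the same seed.

What the generator does **not** emulate: linkage disequilibrium among
decoys (each site drops independently), recombination inside the
planted block, population demography/relatedness across families,
sequence-context effects, false-positive genotype calls, and read-level
evidence. Passing tests on these cohorts therefore demonstrate the
*logic* of the cascade under the stated assumptions — not robustness to
violations of those assumptions in real callsets.

# Numerical and degenerate-input choices

* Dosage comparisons are exact small-integer comparisons; no floating
  tolerances enter the predicates.
* Binomial p-values come from `stats::binom.test` (exact tails), BH
  from `stats::p.adjust`.
* Window-scan ties go to the smallest window start; the final window is
  anchored to the chromosome end so the tail is always covered.
* Zero variants: the enrichment test warns and returns an empty table;
  `windowScan` requires at least one position.
* Empty flip budget (`maxFlips = 0`) reduces the search exactly to the
  plain cascade (asserted by a test).
* PED parsing repairs unknown sex of referenced parents from their
  role, rejects duplicate ids, undefined parents, cyclic parent
  relations, and families with no affected member.
* Annotation tables: duplicate keys — last row wins with a warning;
  malformed numerics fail with the line number; unlisted variants are
  treated as novel (kept by the frequency stage, never deleterious
  unless classified).

# Problem sizes

The shipped checks run cohorts at the full default scale (16 families /
79 samples / 20,000 decoys): 50 seeded cohorts per SNV inheritance
mode for planted-variant recovery, 20 per injected-flip count for the
relabeling search, 20 for the linkage-block localization, 20 for de
novo CNV recovery, plus 1,000 small random cohorts for the
filter-vs-oracle equivalence and the full 8^5 frequency grid. These
sizes keep the whole battery to a few minutes on one CPU while leaving
the per-check sampling error well below the asserted margins.

# Known limitations

* Compound-het trans-phasing uses parental carriage only; it does not
  exploit population phasing or read-backed phase.
* The density scan assumes a single enriched locus per chromosome; two
  hidden loci on one chromosome would merge or shadow.
* The predictor vote treats the eight tools as exchangeable; real tools
  are correlated, and the 0.9/0.1 call model understates that
  correlation.
* `checkMendelian` flags impossible dosage combinations only; it cannot
  see allele-origin errors that stay dosage-consistent.
* The CNV module classifies inheritance of pre-called segments; it does
  not call segments and has no notion of calling uncertainty.
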