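---
title: "Methods: field-deployable metabarcoding with de novo reference augmentation"
author: "fieldamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: field-deployable metabarcoding with de novo reference augmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldamp)
```

## The problem

Community metabarcoding of environmental DNA (eDNA) identifies taxa by
matching amplicon reads against a reference database. In remote tropical
systems this breaks down for a mundane reason: the locally dominant
species — often undescribed, endemic, or simply never sequenced — are the
ones missing from public references. Reads from those species either fail
the identity threshold or, worse, are confidently assigned to a related
but extralimital species that happens to be deposited.

`fieldamp` implements a two-step answer designed for field deployment with
isothermal amplification (RPA) and a portable long-read sequencer:

1. **Barcode arm.** Swab single specimens, amplify a ~600 bp rRNA
   fragment, build a polished consensus barcode per specimen from noisy
   long reads, and label it with the field identification.
2. **eDNA arm.** Amplify a shorter (~250 bp) marker nested inside the
   barcoding amplicon from water samples, and assign reads by best hit
   against the public database *augmented with the local barcodes*.

Because the short marker is nested inside the long one, every local
barcode covers every eDNA read — a structural guarantee that the combined
database can resolve whatever the assay amplifies locally.

## Pipeline and operating point

Reads are pooled across dual-indexed samples, so the pipeline runs:
demultiplex → quality/length filter → dereplicate → assign → tabulate →
noise floor → negative-control filter → summaries. Defaults (all in
`run_config()`):

| Parameter | Default | Why |
|---|---|---|
| mean Phred cutoff | > 12 (strict) | removes junk reads while keeping noisy-but-usable long reads |
| eDNA length window | [172, 212] bp, closed | primer-trimmed insert length ± indel slack |
| barcode length window | [520, 580] bp, closed | same for the long marker |
| identity thresholds | 95% and 99% | permissive vs stringent assignment, reported side by side |
| noise floor | counts ≤ 5 zeroed per sample | index cross-talk and trace contamination |
| index edit tolerance | 2 per 20-base index | conservative demultiplexing of noisy reads |
| primer edit tolerance | 3 | IUPAC-aware primer location before trimming |

"Mean Phred" is the quality of the *mean error probability*,
`-10·log10(mean(10^(-q/10)))`, not the arithmetic mean of scores. This is
the semantics of standard read-quality tooling and is stricter on
mixed-quality reads; a read of qualities {10, 30} has mean Phred 12.97,
not 20.

Filtering precedes dereplication: identical sequences can carry different
qualities, so collapsing first would entangle the two filters. After
dereplication each unique sequence is assigned once and counts are
re-expanded by its size.

The order *noise floor, then control removal* is deliberate: a taxon that
appears in the negative control at or below the floor is treated as the
same cross-talk the floor removes everywhere else, and does not trigger
removal of that taxon from all samples. Reversing the order changes
results (the test suite demonstrates the difference on a toy table).

## Alignment and best-hit assignment

Assignment re-implements the direct best-hit approach as a k-mer prescreen
(shared distinct 11-mers, both orientations) followed by local alignment
of the top candidates. Scoring is the conventional nucleotide scheme:
match +2, mismatch −3, gap of length L costs 5 + 2L. Percent identity is
`100 · matches / alignment columns` with gap columns in the denominator;
IUPAC-compatible pairs count as matches so degenerate reference bases
never penalise a read. The aligner is compiled (Gotoh's algorithm) with a
deterministic traceback (diagonal, then gap-in-subject, then
gap-in-query); tests verify score agreement with independent full-matrix
implementations.

"Best hit" is formalised as a total order — maximal score, then higher
identity, then provenance `local` before `base`, then accession ascending —
because file-order tie-breaking in alignment tools is irreproducible. A
hit must also cover at least 0.8 of the query length, a guard against
spurious short local matches that identity thresholds alone would not
catch. The single best hit is then tested against each identity threshold
independently; failing the threshold leaves the query unassigned at that
threshold, never re-assigned to a lower-scoring hit.

## Consensus barcoding

Specimens with fewer than 3 reads are refused (low-coverage consensus is
unreliable). Otherwise:

1. **Cluster.** Greedy centroid clustering by length-descending order at
   90% identity, both orientations. The membership statistic is *gap-free*
   identity (matches over non-gap aligned columns): indel-rich long reads
   would otherwise hover at the threshold even when genuinely
   conspecific, while templates tens of percent apart remain separated
   under either statistic. The 90% threshold will merge congeneric
   templates at 95–99% identity — a documented limitation for mixed
   swabs, acceptable for single-specimen material.
2. **Draft.** The medoid read (minimal summed edit distance to ≤ 30
   sampled cluster mates, banded at 25% of read length).
3. **Polish.** Up to 3 rounds: globally align every read to the draft,
   stack columns, majority-vote over {A, C, G, T, deletion} (bases beat
   deletions on ties, then alphabetical), accept an insertion where more
   than half the reads carry one (most common string, ties
   lexicographic). Stop when a round changes nothing.
4. **End trim.** Strip terminal columns supported by an aligned base in
   fewer than half the reads — an algorithmic surrogate for the manual
   removal of divergent consensus ends; the visual curation it replaces
   has no published algorithmic definition.

At 5% per-base error and 30× coverage the consensus is ≥ 99.5% identical
to the template (tested over 20 seeds), comfortably below the 1%
species-level divergence that matters at the 99% assignment threshold.

## Reference databases

The internal "simple" FASTA dialect is
`accession|kingdom|phylum|class|order|family|genus|species binomial`; a
tolerant parser also ingests MIDORI2-style headers (semicolon-delimited
`rank_Name_taxid` tokens), degrading unparseable fields to `UNKNOWN` with
a warning rather than failing — header grammars drift between releases
and the artifact must run offline. Augmentation adds local barcodes with
accessions prefixed `LOCAL_`; species labels come from field
identification, not sequence inference. A barcode identical in sequence
and species to an existing record is skipped, making augmentation
idempotent; whether the original workflow collapsed such duplicates is
not stated, so the skip rule is this package's choice. Every hit carries
provenance, so base-vs-combined comparisons are always traceable.

## Accuracy evaluation

With no per-read truth in the field, a detection is "correct" when the
assigned species (or genus) is on the locality checklist of visually
confirmed taxa. Databases are compared by the risk ratio of
correct-assignment proportions,

RR = (x₁/n₁) / (x₂/n₂),  CI = exp( ln RR ± z · √(1/x₁ − 1/n₁ + 1/x₂ − 1/n₂) ),

the log-normal Wald interval. The interval method reproduces the
published species-level CI to both printed decimals from counts
reconstructed off the printed percentages (round half away from zero);
sensitivity of the endpoints to ±0.05% miscounts is below printed
precision (tested). No p-value is computed: the published test is
unnamed, and the interval carries the same information. Non-target
"bycatch" reads (mammals, fish) are reported in class-share denominators
but never in amphibian correctness denominators.

## Replication statistics

Richness per indexed sample is the count of detected taxa; per-site
richness is the union over that site's field × RPA replicates. The
percentage increase from replication is `100·(site mean − sample
mean)/sample mean`, reported rounded to integer. The split of the gain
between field and RPA replication is not defined in detail anywhere we
could follow, so the package uses a transparent two-term decomposition:
per site, the field gain is the richness of the union of each field
replicate's *first* RPA replicate minus the mean single-sample richness;
the RPA gain is the remainder up to the full site union; both are
normalised to percentages of the total gain. This is a defined stand-in,
not a claim of reproducing the published 56/44 split.

## The synthetic world

The simulator exists so every stage is testable offline, and its defaults
are a stated world, not knobs:

* **Community.** Taxa descend from a random ancestor along a random
  bifurcating tree. The tree carries half the target divergence and each
  genus gets a private stem of a quarter, so the mean between-genus
  distance is ≈ `divergence` (default 0.10) while no two genera sit
  closer than about half of it. About a third of taxa get a congeneric
  sister at ~`divergence/4` — close enough that species- and genus-level
  assignment genuinely differ. Primer binding sites (28 bases at both
  ends of both markers) are conserved across all taxa including bycatch,
  which is what makes a universal assay possible at all.
* **Abundances** are log-normal (σ = 1.5) — a handful of taxa dominate
  reads, as in real communities. Terrestrial taxa are down-weighted by
  0.05 in water samples, reproducing in kind the aquatic/terrestrial
  detectability asymmetry.
* **Reads** are `index_f + primer + marker + primer site + revcomp(index_r)`
  with i.i.d. per-base substitution/insertion/deletion errors and quality
  strings; ~half are emitted reverse-complemented. The default error
  model totals 1% (substitution-dominated), the raw-read accuracy of
  current flow cells under accurate basecalling; at this rate roughly
  half of eDNA reads clear the 99% identity cutoff, matching the
  workflow's published behaviour in kind.
* **Controls and contamination.** The negative control receives 0.5% of
  a sample's read budget from arbitrary taxa.
* **Reference gaps** in the end-to-end run are clade-wise: whole genera
  (ranked by abundance) are missing from the base database, because
  public-database gaps hit unsequenced clades, not random species; each
  missing taxon still has a non-local congeneric "relative" deposited —
  the decoys that produce confident wrong-species assignments.

What the generator does **not** emulate: homopolymer-biased errors,
chimeras, signal-level artefacts, PCR/RPA amplification bias beyond the
fixed detectability factor, and intraspecific haplotype variation. A
green test therefore establishes algorithmic correctness and the
direction of the database-augmentation effect, not platform-calibrated
absolute error rates.

## Primer elongation

Isothermal amplification wants primers of ~25–30 bases, so existing
shorter primers are elongated across a curated alignment: columns with
strictly more than 50% gaps are removed first (a column at exactly 50% is
retained); per-column IUPAC consensus covers bases at frequency ≥ 0.05
(the visual screening this formalises had no numeric threshold; 5%
ignores rare variants without inflating degeneracy); all extensions
within the inclusive length range [25, 30] are enumerated and ranked by
fewest degenerate positions, then highest mean conservation, then
greatest length, then leftmost start — a total order, so candidate lists
are reproducible. Thermodynamic screening is out of scope; a crude
reverse-complement self-overlap check (≥ 8 bases) only warns.

## Numerical and degenerate-input choices

* Edit distances are banded at the caller's tolerance; the sentinel
  `cap + 1` means "greater than cap", and results are exact below it.
* Demultiplexing searches the first/last `20 + tol + 5` bases; ties
  between samples on summed index distance are left ambiguous, never
  assigned. Tolerances are per index (the per-index vs joint question is
  undocumented in the tools this mirrors; per-index with summed
  tie-breaking is this package's documented choice).
* Sequences are uppercased at ingestion; `N` participates in
  dereplication as a literal character; FASTQ must be Phred+33 and other
  encodings are rejected, not guessed.
* A risk ratio with a zero-correct base group is an error at the
  operation level; the report layer applies an explicit continuity count
  of 1 and flags zero-read groups as `NA` rather than fabricating a
  ratio.
* All randomness flows from explicit integer seeds; rerunning any stage
  with the same inputs and seed is byte-identical.

## Known limitations

Single-specimen clustering cannot phase mixed swabs or heteroplasmy; the
checklist definition of correctness inherits the checklist's blind spots
(a wrong assignment to a different checklist species is invisible);
detection attribution is a stand-in; and the simulator's i.i.d. error
model understates homopolymer error structure, so consensus accuracy on
real data depends on basecaller quality in ways the tests cannot see.
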