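# fieldamp

Field-deployable amplicon metabarcoding with de novo reference
augmentation.

## What problem this solves

eDNA metabarcoding assigns amplicon reads to taxa by matching them
against a reference database — and quietly fails where it is needed most,
in remote assemblages whose dominant species were never sequenced. Reads
from unreferenced species either drop below the identity threshold or are
confidently assigned to a related but extralimital species that *is*
deposited.

`fieldamp` implements a two-step workflow built for that situation:
single-specimen barcoding of local taxa produces polished consensus
sequences from noisy long reads, these are folded into a MIDORI2-style
reference database, and eDNA reads from the same system are then assigned
against the augmented database. The eDNA marker (~250 bp) is nested
inside the barcoding amplicon (~600 bp), so every local barcode covers
every eDNA read. The package covers the full pipeline: dual-index
demultiplexing by bounded edit distance, quality/length filtering (mean
Phred > 12; 172–212 bp / 520–580 bp windows), exact dereplication,
best-hit assignment at 95% and 99% identity, a per-sample noise floor
(counts ≤ 5 → 0), negative-control taxon removal, replicate-aware
detection statistics, degenerate primer elongation for isothermal (RPA)
chemistry, and a seeded Nanopore-like read simulator so everything runs
and is testable offline.

## The core statistic

Two databases (base vs augmented) are compared on the proportion of reads
correctly assigned — "correct" meaning the assigned taxon is on the
locality checklist of independently confirmed species. The comparison is
a risk ratio with a log-normal Wald interval:

    RR = (x1/n1) / (x2/n2)
    CI = exp( ln RR ± z · sqrt(1/x1 − 1/n1 + 1/x2 − 1/n2) )

```r
library(fieldamp)
rr <- risk_ratio(49552, 53225, 5867, 48091)
# RR = 7.63 (95% CI 7.45–7.82)
```

A species-level risk ratio far above the genus-level one is the signature
of reference-database failure: reads land in the right genus but the
wrong (extralimital) species until local barcodes are added.

## Worked example

An end-to-end simulated deployment — 9 local taxa (one third of them, as
whole genera, missing from the base database), 4 sites with 2 field × 2
RPA replicates, 9 barcoding swabs, 40 reads per indexed sample:

```r
run <- run_all(run_config(rng_seed = 7), n_taxa = 9, n_sites = 4,
               field_reps = 2, rpa_reps = 2, n_specimens = 9,
               reads_per_sample = 40)
print(run)
```

```
Two-step metabarcoding run
  simulated                1000
  demultiplexed             998  (per sample 38.4 +/- 7.8, 0-40)
  consensus_barcodes          9
  edna_filtered             640

Accuracy (combined vs base database):
 database    rank threshold n_target_reads pct_correct n_species_detected
     base species        95            381    56.16798                  5
 combined species        95            382   100.00000                  7
     base   genus        95            381   100.00000                  5
 combined   genus        95            382   100.00000                  7
     base species        99             94   100.00000                  5
 combined species        99            159   100.00000                  7

Risk ratios (combined / base):
    rank threshold       rr   ci_low  ci_high
 species        95 1.780374 1.629251 1.945514
   genus        95 1.000000 1.000000 1.000000

Detection: 2.38 species per indexed sample, 3.00 per site (+26%)
```

Reading it: with the base database, reads from the unreferenced genera
are confidently assigned to non-local congeners — only 56% of
species-level assignments are correct, although the genus level looks
flawless. Adding the nine locally built consensus barcodes lifts
species-level accuracy to 100%, detects two more checklist species, and
at the stringent 99% cutoff rescues the reads (94 → 159) that previously
had no sufficiently close reference. Site-level detections exceed
per-sample detections because field and RPA replicates each contribute
species the others miss.

## Command line

A thin CLI over the package functions is installed as `exec/fieldamp`:

```sh
fieldamp simulate  --n-taxa 12 --reads-per-sample 60 --seed 1 --out-dir sim/
fieldamp demux     --sheet sim/sample_sheet.tsv --reads sim/pooled_reads.fastq \
                   --primers sim/primers.json --out-dir demux/
fieldamp filter    --reads demux/S01_F1_R1.fastq --marker edna --out filt.fastq
fieldamp derep     --reads filt.fastq --out uniques.fasta
fieldamp consensus --reads demux/SPEC01.fastq --id SPEC01 --out barcode.fasta
fieldamp build-db  --base base.fasta --barcodes barcodes.tsv --out combined.fasta
fieldamp assign    --db combined.fasta --queries uniques.fasta --out hits.tsv
fieldamp run       --config run.json --out-dir run/
```

## Acceptance script

`scripts/acceptance.R` recomputes the workflow's headline accuracy
statistics — the four published risk ratios of correct assignment
(species/genus × 95%/99% cutoffs) and the species-level 95% confidence
interval — from their printed inputs (group totals and correct
proportions), using `risk_ratio()` on counts reconstructed by rounding.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/fieldamp-methods.Rmd`) documents the
models and their assumptions, every tunable parameter with its default
and rationale, what the synthetic world does and does not emulate,
numerical tie-breaking choices, and known limitations.
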