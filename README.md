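# nanobar

Species identification from noisy long-read barcode amplicons.

Portable nanopore sequencers put DNA barcoding (16S, CO1) within reach of
field work, but their reads — especially early-chemistry 2D reads — carry
per-base error rates of 15–20%, concentrated in miscounted homopolymer runs.
No single read can place a specimen at the few-percent divergence separating
related species. `nanobar` implements the consensus workflow that can:

1. **draft** — de novo consensus of the 2D-pass reads by partial-order
   alignment (POA);
2. **retrieve** — best hit for the draft from a local barcode reference
   database (k-mer prefilter + semi-global alignment);
3. **realign** — all working reads against the retrieved reference
   (affine-gap, free reference end gaps, both orientations tried);
4. **vote** — per reference position, call the most frequent aligned
   nucleotide (the frequency consensus);
5. **re-search** — identify the species with the polished consensus.

The reference retrieved in step 2 only supplies a coordinate frame: at
moderate coverage the reads outvote every position where it differs from the
sequenced molecule, so even a congeneric reference yields the correct final
sequence, while low-coverage homopolymer dropouts are bridged by the
reference base. The package also ships the supporting analytics: a
calibrated 2D-read simulator (per-base mismatch/insertion/deletion plus a
run-granularity homopolymer error channel, pass/fail tiers, channel
metadata, full ground truth), pooled error decomposition against a trusted
reference, homopolymer coverage-dip quantification, and per-channel
run-yield normalisation with half-up rounding.

## Worked example

Simulate a 532-bp barcode sequenced at 300 reads under the early-chemistry
error model (8% mismatch, 4% insertion, 5% deletion, homopolymer
coefficient 0.05), build a database of the true sequence plus five decoys at
90% identity, and run the pipeline:

```r
library(nanobar)
set.seed(42)
template <- seq_record("toad_16S_barcode",
                       paste(sample(c("A","C","G","T"), 532, TRUE), collapse = ""))
reads <- simulate_run(template, minion_profile("R7.4"), run_config(300, seed = 7))
db <- c(list(template), make_decoys(template, n = 5, divergence = 0.10, seed = 8))

res <- run_pipeline(sim_records(reads), db)
res$consensus
#> <consensus:pileup> 532 bp, min called-base frequency 0.697
res$report$draft_best_hit$identity_pct
#> [1] 99.25373
res$report$final_best_hit$identity_pct
#> [1] 100
```

Reading the numbers: of the 300 simulated reads, the 76 2D-pass-tier reads
form the working set (the pipeline falls back to all reads only when fewer
than 20 pass reads exist). The POA draft already retrieves the right
database record, but at 99.25% identity — its residual errors sit in
homopolymer runs. After realignment and majority voting the final consensus
is 100% identical to the truth, and the weakest position in the pileup was
still called by 69.7% of its coverage, comfortably above the majority
threshold.

The same alignments feed the error decomposition:

```r
dec <- decompose_errors(attr(res$consensus, "alignments"))
dec
#> <error decomposition> 76 reads, 40399 aligned ref bases
#>   mismatch 8.34%  insertion 3.59%  deletion 4.34%  mean 16.27%
```

The mismatch component recovers its generative 8%; the indel components sit
below theirs because an optimal aligner merges adjacent insertion–deletion
pairs into mismatch columns — an effect inherent to any alignment-based
error measurement (see the methods vignette).

A thin command-line wrapper covers the same ground from a shell:

```sh
Rscript inst/cli/nanobar.R simulate --template t.fasta --profile R7.4 \
        --n 900 --seed 1 --out reads.fastq --truth truth.tsv
Rscript inst/cli/nanobar.R run --reads reads.fastq --db db.fasta --out outdir
Rscript inst/cli/nanobar.R stats --counts counts.tsv
```

`run` writes `consensus.fasta`, `draft.fasta`, `freq_matrix.tsv` (the
per-position count/frequency table), `coverage.tsv`, both hit tables and a
machine-readable `report.json`; reruns are byte-identical.

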