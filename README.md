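# pretrna

Genome-wide pre-tRNA architecture analysis and tRNA-seq 3'-end
classification, for researchers studying RNA polymerase III transcript
processing — in particular how La-family proteins handle the uridylate-
ended 3'-trailers of nascent pre-tRNAs.

## What it computes

**Architecture.** For every annotated tRNA gene, in transcript
orientation, the package measures the 3'-trailer length — the number of
nucleotides between the discriminator base N73 (the 3'-most nucleotide of
the mature tRNA, which later receives the post-transcriptional CCA) and
the first genomic run of at least *k* consecutive Ts (the Pol III
terminator; default *k* = 4, trailers > 20 nt excluded):

    trailer(gene) = min { d >= 0 : flank[d .. d+k-1] = T^k }

Mature lengths (+1 to N73, introns excluded), per-species means +/- SD,
trailer histograms and modes, one-way ANOVA / Tukey HSD across species,
5'-leader position frequency matrices over N-W..N-1 (optionally split by
N73), and a leader/trailer Watson-Crick pairing-avoidance table
(observed vs independence frequency of N-1 = complement(N73)) complete
the picture.

**Read classification.** Raw small-RNA reads are "fished" by exact match
against unique 36-nt 3'-end baits per isoacceptor and binned by what
follows the bait: `CCA` (mature tRNA) or `T^n` (uridylate-tailed
precursor, bins U1..U10). Counts are CPM-normalised (sum = 1e6 per
replicate), IP/input enrichment is reported as log2(fold + 1) after
summing the premature bins, cumulative tail tables use log10(1 + CPM of
tails >= L), tail presence is scored at CPM > log10(2), and Pearson
correlations against gene copy number or trailer length are provided.

**Conservation.** Protein multiple sequence alignments are annotated
per-cell against a reference row as identical / conserved / none / gap,
using five side-chain groups: {D,E,N,Q}, {K,R,H}, {F,W,Y}, {V,I,L,M},
{S,T}.

**Synthetic data.** A seeded generator emits genomes (FASTA + BED12 +
ground-truth TSV) and read sets (FASTQ + truth) with every drawn quantity
exported, so the entire pipeline is testable offline.

## Worked example

```r
library(pretrna)
prof <- species_profile(n_genes = 500)          # Tetrahymena-like defaults
sim <- simulate_genome(prof, seed = 7)
catalog <- extract_genes(sim$genome, sim$annotations)
calls <- scan_terminators(catalog, min_run = 4, max_trailer = 20)
summarize_species(calls, catalog, include_undetermined = TRUE)
#> synthetic: 500 genes (500 determined), 500 trailers analyzed
#>   trailer 1.55 +/- 2.10 nt (mode 0), mature 73.9 +/- 3.0 nt

logo <- leader_logo(catalog)
logo$frequencies["A", "N-1"]
#> [1] 0.728
```

The trailer mean recovers the generating geometric distribution (mean
1.5 nt, modal length 0 — terminators typically abut the discriminator in
this architecture), and roughly three quarters of leaders end in adenine.
The pairing-avoidance table from the same catalog shows the N-1
complement of N73 at frequencies of 0.000-0.240 against independence
expectations of 0.082-0.728 — the generated leaders avoid pairing with
the discriminator:

```r
pairing_avoidance(catalog)[, c("discriminator", "n_genes",
                               "wc_complement_frequency", "expected_frequency")]
```

For file-based runs the same analyses are exposed as subcommands of the
bundled CLI (`inst/cli/pretrna`):

```sh
pretrna simulate --out sim --seed 3
pretrna architecture --genome sim/genome.fa --annotations sim/genes.bed \
    --min-run 4 --max-trailer 20 --window 10 --out results_arch
pretrna tails --catalog catalog.tsv --manifest sim/replicates.tsv --out results_tails
```

Every run writes a `run_manifest.json` with parameters and MD5 checksums;
identical inputs and configuration produce byte-identical outputs.

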