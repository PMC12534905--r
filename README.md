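# magderep

Dereplication of metagenome-assembled genome (MAG) bins across samples,
with bin merging for clusters that lack a high-quality member.

## The problem

Sample-wise assembly and binning of shotgun metagenomes recovers the same
genomes again and again across samples. Dereplication clusters these
near-identical bins at a strain-level average nucleotide identity (ANI,
conventionally 99%) and keeps one genome per cluster. The classical
approach selects a single representative and discards the rest — throwing
away pure but incomplete bins whose contigs cover genomic regions the
representative misses.

`magderep` instead:

1. filters input bins by total length (≥ 200 kb) and purity
   (> 95%, i.e. contamination < 5%);
2. builds an ANI graph (internal FracMinHash containment sketches, or a
   pre-computed skani-style edge list), keeps edges with ANI ≥ cutoff
   (default 99%), and finds single-linkage connected components by
   depth-first search;
3. enumerates **all maximal cliques** inside each component
   (Bron–Kerbosch with pivoting) — a bin may belong to several genome
   clusters — and attaches leftover bins to cliques containing a
   neighbour, so every above-cutoff pair ends up co-clustered;
4. per cluster, selects the member with the highest quality score

   *Q* = completeness − 5 × contamination

   among members with completeness > 90 and contamination < 5. If no such
   member exists, all member bins are **merged** and deduplicated by k-mer
   containment (or handed to an external assembler), the merged candidate
   is scored, and the best of {members, merged} wins (merged loses exact
   ties);
5. removes residual redundancy greedily (recomputed pairwise ANI; the
   lower-quality bin of the worst offending pair is dropped until no pair
   is ≥ cutoff) and applies the final completeness floor (≥ 50 by
   default).

ANI between two sketches *A*, *B* is estimated from the containment
*C* = |A ∩ B| / min(|A|, |B|) as ANI = 100 · *C*^(1/k) (k = 21,
scaled = 200), which stays calibrated when the two bins differ widely in
completeness.

## Worked example

The built-in generator creates a fully labelled world — 3 species at ~90%
between-species identity, 4 samples, every bin a random contig subset of
its genome with a little admixed foreign sequence:

```r
library(magderep)
ds  <- simulate_dataset(n_species = 3, samples = 4, seed = 1)
cfg <- derep_config(
  quality_provider = truth_quality_provider(ds$truth$strain_genomes),
  verbose = TRUE)
res <- run_pipeline(ds$bins, ds$qualities, cfg)
```

```
input bins: 12
after length filter (>= 200000 bp): 12
after purity filter (> 95%): 12
ANI graph: 12 nodes, 18 edges at >= 99%
clusters: 3
per-cluster decisions: 3 (of which merged: 0)
after redundancy removal: 3
after completeness filter (>= 50%): 3
```

The 12 sample-wise bins collapse to exactly one bin per species; each
retained bin lists its cluster's members:

```
s01__sp03_st01  comp=100.00 cont=0.32 score=98.39 members=s01__sp03_st01,...,s04__sp03_st01
s02__sp01_st01  comp=100.00 cont=0.04 score=99.81 members=s01__sp01_st01,...,s04__sp01_st01
s02__sp02_st01  comp=100.00 cont=0.23 score=98.87 members=s01__sp02_st01,...,s04__sp02_st01
```

`write_output(res, "out/")` writes one FASTA per retained bin plus
`dereplication_report.tsv` (bin, source = input|merged, cluster,
completeness, contamination, quality score, member bins).

## Command line

```sh
exec/magderep simulate    --out data --n-species 3 --samples 4 --seed 1
exec/magderep dereplicate --bins data/bins --quality data/quality_report.tsv \
                          --out results -p 95 -c 50 --ani 99
exec/magderep ani         --bins data/bins --out ani.tsv
exec/magderep cluster     --bins data/bins --out clusters.tsv
```

`-p` purity threshold, `-c` completeness floor, `--ani` cutoff,
`--no-reassembly` to disable merging, `--ani-edges` to supply a
skani-style edge list, `--assembler-cmd` / `--quality-cmd` to plug in an
external assembler / quality estimator via `{input}`/`{output}` command
templates.

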