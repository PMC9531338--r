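# rkmviz

Rare k-mer vetting and visualization of sequence alignments in repetitive
genomic regions.

## The problem

Near-identical copies of a genomic repeat — transposons, segmental
duplications, tandem arrays — are the hardest part of assembling and
curating complete (telomere-to-telomere) genomes. A read or contig that
truly derives from one copy will align almost equally well to the others,
and the aligner's mapping quality is useless for telling them apart: every
candidate gets MAPQ at its ceiling. Accepting the wrong alignment at this
point produces a mis-assembly.

What *does* separate the copies are their few copy-specific differences.
Rather than calling SNPs or structural variants, `rkmviz` uses **rare
k-mers** as markers: length-*k* subsequences occurring at most *R* times in
the whole target genome (*R* = 1 gives "unique k-mers"). Sequence shared by
all copies of a repeat is by definition not rare, so the rare k-mers inside
a repeat copy sit exactly on its private differences. A correct alignment
preserves them; an alignment between two *different* copies contradicts
them.

## The score

For an alignment `A` of a query to target interval `[tstart, tend)`:

- `e` — the number of rare k-mers whose window lies fully inside the target
  interval (the markers the alignment is *expected* to reproduce);
- `m` — how many of them actually match the query sequence at the position
  the alignment's CIGAR projects them to (reverse-complement-aware on minus
  strand);
- the k-mer-based mapping quality

  ```
  KMAPQ = round(60 * m / e),   KMAPQ in [0, 60]
  ```

  An alignment of a contig onto its true source copy scores `m = e`, so
  KMAPQ = 60; a false positive onto a sibling copy misses the markers and
  collapses toward 0. Intervals with `e = 0` carry no markers at all; such
  alignments are flagged *uninformative* and are never silently removed.

When a PAF record has no `cg:Z` CIGAR, matches are found instead by
anchored chaining: rare k-mers occurring exactly once on each side are
paired by canonical code and the longest strand-consistent monotone chain
is kept.

## Worked example

A simulated interspersed repeat in the package's own generator: two 2.8 kb
copies at 1% pairwise divergence inside a 20 kb genome, and a contig
sampled from copy 1. The truth PAF aligns the contig to *both* copies with
MAPQ 60 — the situation in which the aligner cannot adjudicate.

```r
library(rkmviz)

cfg    <- repeat_sim_config(seed = 11)
sim    <- simulate_repeat_genome(cfg)
contig <- extract_contig(sim$genome, sim$truth, cfg)
paf    <- emit_truth_paf(sim$genome, sim$truth, contig)

idx    <- build_rare_index(sim$genome, kmer_params(k = 21, max_count = 1))
idx
#> rare_kmer_index: k = 21 R = 1 | 1 sequences | 15448 distinct rare k-mers | 15448 indexed positions

scored <- score_alignments(paf, sim$genome, contig, idx)
scored
#> scored_alignments: 2 records (k = 21 , R = 1 )
#> contig1 -> ref1:3600-6400 (+)  MAPQ=60  m=515 e=515 KMAPQ=60 [cigar]
#> contig1 -> ref1:13600-16400 (+)  MAPQ=60  m=0 e=515 KMAPQ=0 [cigar]

fl <- filter_alignments(scored, min_mapq = 0, min_kmapq = 30)
length(fl$kept); length(fl$removed)
#> 1 kept, 1 removed
```

Both records enter with MAPQ 60, yet the copy-1 alignment reproduces all
515 expected rare k-mers (KMAPQ 60) while the copy-2 alignment reproduces
none (KMAPQ 0): a textbook false positive, removed at `min_kmapq = 30`.

Draw the two profiles (grey alignment areas, one red line per matching
rare k-mer pair):

```r
render_pair(scored, "contig1", "ref1", render_options("pair"),
            file = "profile.svg")
```

## Command line

The same pipeline as subcommands (script installed at
`system.file("cli", "rkmviz", package = "rkmviz")`):

```sh
rkmviz simulate --out sim --seed 11
rkmviz index    --target sim.ref.fa --k 21 --R 1
rkmviz score    --paf sim.truth.paf --target sim.ref.fa \
                --query sim.contig.fa --rki sim.ref.fa.rki
rkmviz filter   --rkm sim.truth.rkm --min-kmapq 30
rkmviz draw     --rkm sim.truth.rkm --mode pair --ids contig1,ref1 \
                --out profile.svg
```

`score` writes the `.rkm` intermediate file (alignment areas, k-mer
positions, k-mer matches) together with two byte-offset indexes
(`.rkm.qidx`, `.rkm.tidx`) so all records of a given query or target id can
be retrieved by seeking rather than scanning (`rkm_lookup()`). File layouts
are documented in `FORMAT.md`.

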