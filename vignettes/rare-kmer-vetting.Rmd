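---
title: "Vetting repeat alignments with rare k-mers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vetting repeat alignments with rare k-mers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rkmviz)
```

## The model

Let the target genome be a set of sequences and fix a window length $k$
and a rarity threshold $R$. A k-mer is **rare** when its canonical count —
the k-mer and its reverse complement counted as one key — over the whole
target genome is at most $R$. With $R = 1$ these are the genome's unique
k-mers. Sequence shared verbatim by two or more repeat copies cannot be
rare, so within a repeat the rare k-mers cluster on each copy's private
substitutions and indels: they are copy-specific markers that stand in for
explicit SNP/SV calls, which are costly to obtain and unnecessary for this
decision.

An alignment $A$ of a query to target interval $[t_s, t_e)$ is vetted as
follows.

* **Expected markers** $e$: the number of rare k-mers whose window lies
  fully inside $[t_s, t_e)$ (half-open, full-window semantics).
* **Matched markers** $m$: for each such window, its position is projected
  onto the query through the alignment CIGAR. The match counts iff the
  whole window is co-linear — all $k$ positions mapped, with no indel
  inside the window — and the query subsequence equals the target window
  (its reverse complement on a minus-strand record). This is a strict,
  base-exact notion of "the marker agrees"; a tolerance for indels inside
  the window was deliberately rejected because it would dilute exactly the
  signal being measured.
* **Score**:
  $$\mathrm{KMAPQ} = \mathrm{round}\!\left(60\,\frac{m}{e}\right) \in [0, 60]$$
  with half-up integer rounding (platform-stable). The 0–60 range mirrors
  the familiar mapping-quality scale: a perfect copy-specific alignment
  ($m = e$) scores 60, an alignment contradicting every marker scores 0.
  KMAPQ is a bounded descriptive ratio, not a probabilistic (log-odds)
  quality; that simplicity is intentional, since its purpose is to make an
  adjudication visible, not to calibrate error rates.

When $e = 0$ the interval carries no markers — the repeat is locally
perfect and *cannot* be adjudicated by this method. Such alignments score
0 but are flagged **uninformative** and are exempt from the KMAPQ
threshold in filtering: they are kept and labeled, never silently removed.
They remain subject to the MAPQ threshold, which does not depend on
markers.

Filtering keeps an alignment iff `mapq >= min_mapq` and
`kmapq >= min_kmapq` (uninformative records exempt from the latter). The
aligner's MAPQ and KMAPQ are deliberately orthogonal: in the repeat
scenario all candidates arrive with MAPQ 60, and KMAPQ is the axis that
separates them.

## Matching without a CIGAR

PAF records may lack the `cg:Z` tag. Two match paths are therefore
provided and recorded per record:

* **cigar** — the projection path above; exact, used whenever `cg` is
  present.
* **anchored** — candidates are rare target k-mers occurring exactly once
  in the target interval whose canonical code occurs exactly once among
  the query interval's windows; the match set is the longest strictly
  monotone chain of candidates (increasing query and target position on
  `+`; increasing target with decreasing query position on `-`), ties
  broken toward the smaller target position. This is the classical
  anchor-chaining formulation (longest increasing subsequence,
  $O(n \log n)$), restricted to one-to-one anchors so no spurious
  repeat-internal pairing can enter the chain.

The anchored path can only miss matches relative to the cigar path (both
require identical sequence), so $m \le e$ holds on both.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| $k$ | 21 | bp | standard marker size for genome-scale uniqueness; odd, so no k-mer is its own reverse complement |
| $R$ (`max_count`) | 1 | occurrences | unique k-mers, the strongest markers; raise to tolerate residual duplication in the reference |
| `min_mapq` | 0 | MAPQ | alignments usually arrive pre-thresholded; MAPQ is uninformative inside repeats |
| `min_kmapq` | 0 (30 in examples) | KMAPQ | 30 = "half the expected markers agree"; in the simulated regime scores are strongly bimodal (60 vs 0), so any mid-range threshold behaves identically |

$k$ is configurable in 2–26. The upper bound keeps the canonical 2-bit
integer codes below $4^{26} = 2^{52}$, exactly representable in double
precision, which is what R natively offers for integer-valued arithmetic
at this width. Rarity is computed over the **target genome only**: rarity
is a genome property, and the query (a read or contig) need not be a
genome at all. Windows containing `N` are excluded rather than treated as
wildcards. All coordinates are 0-based half-open (the PAF convention);
minus-strand records follow the minimap2 dialect, with `qstart`/`qend` on
the original query and the CIGAR stated over the reverse-complemented
query against the forward target.

## The simulator and what it does (not) emulate

`simulate_repeat_genome()` builds the canonical hard case: an i.i.d.
uniform A/C/G/T background genome (20 kb by default) with $n \ge 2$
instances of one random ancestral repeat (2.8 kb by default, the scale of
an interspersed-repeat copy) planted at evenly spaced, non-overlapping
coordinates. Each copy is mutated independently from the ancestor at rate
`divergence`/2 substitutions per bp (so the *pairwise* divergence between
copies matches the configured value, 1% by default), plus optional
single-base indels at `indel_rate`/2 per copy, split evenly between
insertions and deletions. Every edit is recorded, and
`emit_truth_paf()` constructs — by composition of the two copies' edit
lists over the shared ancestor, not by running an aligner — one exact PAF
record aligning the extracted contig to every copy's homologous interval,
with a valid CIGAR, an `NM` recomputed from the edits, and MAPQ pinned at
60 on all records to reproduce the premise that the aligner's score
cannot separate the copies. Keeping truth generation constructive makes
every test hermetic; a recipe using real minimap2 output is simply to
replace the truth PAF with `minimap2 -c` output and rerun the same
pipeline.

What the simulator does **not** emulate: sequencing-error profiles
(HiFi/ONT error models), higher-order repeat structure of tandem arrays,
compositional bias and low-complexity sequence, and genome-scale k-mer
collision statistics. Consequences for interpreting green tests: on real
data rare k-mers are sparser and dirtier — reference errors create false
markers, read errors destroy true matches — so real KMAPQ distributions
are less bimodal than the simulated 60-vs-0 separation. The tests
demonstrate correctness of the machinery and the discriminating power of
the markers under the stated regime, not a performance guarantee on any
particular genome.

At $k = 21$ a spurious collision between a background window and a copy
window has probability about $n^2 4^{-21}$ per pair and is negligible at
the simulated sizes; the discrimination experiment tolerates any that
occur by requiring success in at least 95 of 100 seeded trials rather
than all of them.

## Numerical and format choices

* Canonical codes are exact doubles; counting uses sort + run-length
  encoding, and membership tests use binary search on the sorted code
  table (`findInterval`), so equality is exact — no hashing, no floating
  error.
* `round(60 m / e)` uses half-up rounding (`floor(x + 0.5)`), documented
  because R's `round()` half-to-even would make scores depend on parity.
* The `.rkm` intermediate format stores k-mer *positions and integer
  codes*, never k-mer strings, keeping it compact at large $e$; its two
  sidecar indexes map sequence ids to the **byte offsets** of their
  A-lines. Offsets rather than line numbers let `rkm_lookup()` `seek()`
  directly to a block in constant time, and they survive file copies. The
  format is plain TSV for inspectability (`FORMAT.md`); gzip is accepted
  transparently on whole-file reads, while seeking lookup requires the
  uncompressed file.
* SVG output is produced by deterministic string assembly (fixed canvas of
  1200 units width, 80 per lane, coordinates printed at two decimals, no
  timestamps), so identical inputs give byte-identical documents —
  figures are diffable and testable. Minus-strand alignment areas are
  drawn with crossed edges, joining each query end to its homologous
  target end. The zoom `region` option rescales one track and clips/drops
  elements; corner clipping is a simple clamp, not a proportional
  re-projection of the opposite edge, which is adequate for a static
  overview figure.
* Degenerate inputs: empty PAF files round-trip to empty outputs; `e = 0`
  is the uninformative flag, not an error; `k` longer than every sequence
  yields an empty count map with a warning; duplicate FASTA ids, malformed
  PAF lines and CIGAR/interval mismatches are hard errors naming the
  offending record.

## Problem sizes

The test suite and the acceptance script run entirely on simulated data
chosen to exercise every code path at desk scale: 2 kb genomes for the
naive-oracle equivalence checks, 100-record fixtures for the format and
lookup checks, and 100 seeded trials of the 20 kb / 2-copy / 2.8 kb / 1%
discrimination experiment. The method itself is linear in genome length
for indexing and in $e$ per alignment for scoring, and nothing in the
implementation assumes these sizes; they are simply sufficient for the
properties being demonstrated.

## Known limitations

* Rarity is recomputed per target FASTA; there is no incremental or
  disk-backed counting for gigabase genomes, and no probabilistic k-mer
  sketches.
* KMAPQ has no error model: 60 means "all markers agree", not "the
  alignment is correct with probability $1 - 10^{-6}$".
* The anchored path requires one-to-one anchor occurrences and can
  under-count matches in heavily nested repeats; the per-record `method`
  field makes the path auditable.
* The interactive operations of a desktop viewer (continuous zoom, drag,
  tabular inspection) are intentionally out of scope; the `region`
  parameter and the TSV report are their scriptable equivalents.
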