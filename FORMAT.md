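# File formats

All files are plain tab-separated text. Coordinates are 0-based, half-open.
Every k-mer is stored as its canonical integer code (the 2-bit-per-base
encoding, A=0 C=1 G=2 T=3, of the lexicographic minimum of the k-mer and
its reverse complement), never as the k-mer string.

## `.rki` — rare k-mer index sidecar

```
#rki k=<k> R=<R>
#len<TAB><seq_id><TAB><length>        (one per target sequence)
<seq_id><TAB><position><TAB><code>    (rows sorted by seq_id, position)
```

`position` is the 0-based start of a rare k-mer occurrence; `code` its
canonical integer code. The `#len` lines record sequence lengths so
interval queries can be bounds-checked after reload.

## `.rkm` — scored-alignment file

```
#rkm<TAB>k=<k><TAB>R=<R><TAB>producer=rkmviz/<version><TAB>target=<fasta name>
A<TAB>qname qlen qstart qend strand tname tlen tstart tend nmatch alen mapq
     m e kmapq uninformative method [tags...]
K<TAB>qpos<TAB>tpos<TAB>code          (exactly m per preceding A-line)
```

One block per scored alignment, in input PAF order. A-line columns 2–13
are the 12 mandatory PAF fields; `m` = matched rare k-mers, `e` = expected
(rare k-mers fully inside the target interval), `kmapq` in 0–60,
`uninformative` is 1 when `e = 0`, `method` is `cigar` or `anchored`.
Everything from column 19 on is the record's verbatim PAF tag string
(itself tab-separated). K-lines give each match's query start (original
strand), target start and canonical code.

Gzip-compressed `.rkm` files are accepted transparently by `read_rkm()`.

## `.rkm.qidx` / `.rkm.tidx` — byte-offset indexes

```
<seq_id><TAB><byte_offset>
```

One row per A-line, keyed by the record's query id (`.qidx`) or target id
(`.tidx`), in file order; offsets are strictly increasing per key. Offsets
(not line numbers) are stored so `rkm_lookup()` can `seek()` straight to a
block; they remain valid after the file is copied. Lookup requires the
uncompressed `.rkm`.

## Filtered PAF

`write_filtered_paf()` emits standard PAF with two tags appended to each
record: `km:i:<kmapq>` and `ke:i:<e>`. Removed records go to a sibling
`<name>.removed.paf`.
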