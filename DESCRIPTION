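Package: rkmviz
Title: Rare k-mer Vetting and Visualization of Alignments in Repetitive Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects false-positive alignments between near-identical repeat
    copies by profiling rare k-mer matches over PAF alignments. Builds a
    genome-wide canonical rare k-mer index, projects k-mer windows through
    alignment CIGAR strings, scores each alignment with a k-mer-based mapping
    quality (KMAPQ), filters alignments on MAPQ/KMAPQ, writes an indexed
    intermediate format for constant-time retrieval by sequence id, and
    renders alignment and k-mer-match figures as deterministic SVG. Includes
    a repeat-genome simulator with ground-truth alignments for end-to-end
    validation of the false-positive detection workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
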