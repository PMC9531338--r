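# The method's core: the rare k-mer matching profile of each alignment,
# the KMAPQ score derived from it, and the MAPQ/KMAPQ filter.
#
# Matching is anchored on target-rare k-mers: rarity is a property of the
# whole target genome, so every rare k-mer window fully inside the aligned
# target interval is *expected* to match the query if the alignment pairs
# the true repeat copy. KMAPQ scales the fraction that actually match to
# the familiar 0-60 mapping-quality range.

.empty_matches <- function() {
  data.frame(qpos = integer(0), tpos = integer(0), code = numeric(0))
}

#' Expected rare k-mer matches of an alignment
#'
#' The number of rare k-mers whose window lies fully inside the aligned
#' target interval `[tstart, tend)` — the KMAPQ denominator.
#'
#' @param a One PAF record.
#' @param index A [build_rare_index()] built on the target genome.
#' @return Integer count `e`.
#' @export
expected_matches <- function(a, index) {
  length(rare_in_interval(index, a$tname, a$tstart, a$tend))
}

#' Rare k-mer matches via CIGAR projection
#'
#' For each rare target k-mer window inside the aligned interval, the window
#' is projected onto the query through the CIGAR; a match is emitted iff the
#' whole window is co-linear (no indel inside it) and the query window's
#' sequence equals the target window (reverse-complement equality on minus
#' strand). Matches are sorted by target position.
#'
#' @param a One PAF record with a `cg:Z` CIGAR.
#' @param qseq Query sequence string (original strand, as in the FASTA).
#' @param tseq Target sequence string.
#' @param index Rare k-mer index of the target genome.
#' @return data.frame of matches: `qpos` (original-strand query start),
#'   `tpos` (target start), `code` (canonical k-mer code).
#' @export
find_matches_cigar <- function(a, qseq, tseq, index) {
  k <- index$k
  p <- rare_in_interval(index, a$tname, a$tstart, a$tend)
  if (!length(p)) return(.empty_matches())
  qpos <- .project_target_window(a, p, k)
  keep <- !is.na(qpos)
  p <- p[keep]; qpos <- qpos[keep]
  if (!length(p)) return(.empty_matches())
  qwin <- substring(qseq, qpos + 1L, qpos + k)
  twin <- substring(tseq, p + 1L, p + k)
  ok <- if (a$strand == "+") qwin == twin else qwin == revcomp(twin)
  mp <- match(p, index$positions[[a$tname]])
  out <- data.frame(qpos = qpos[ok], tpos = p[ok],
                    code = index$codes[[a$tname]][mp][ok])
  rownames(out) <- NULL
  out
}

# longest strictly increasing subsequence (patience algorithm); returns the
# indices of one optimal chain, preferring earlier elements on ties
.lis_strict <- function(x) {
  n <- length(x)
  if (!n) return(integer(0))
  tails <- numeric(0)
  tails_idx <- integer(0)
  prev <- integer(n)
  for (i in seq_len(n)) {
    j <- findInterval(x[i] - 0.5, tails)  # tails strictly below x[i]
    prev[i] <- if (j > 0L) tails_idx[j] else 0L
    tails[j + 1L] <- x[i]
    tails_idx[j + 1L] <- i
    if (length(tails) > j + 1L) {
      tails <- tails[seq_len(j + 1L)]
      tails_idx <- tails_idx[seq_len(j + 1L)]
    }
  }
  chain <- integer(length(tails))
  at <- tails_idx[length(tails_idx)]
  for (pos in rev(seq_along(chain))) {
    chain[pos] <- at
    at <- prev[at]
  }
  chain
}

#' Rare k-mer matches without a CIGAR (anchored chaining)
#'
#' Fallback for PAF records lacking a `cg:Z` tag. Candidate pairs are rare
#' target k-mers occurring exactly once in the target interval whose
#' canonical code also occurs exactly once among the query interval's
#' windows. The final matches are the longest strictly monotone chain of
#' candidates: increasing qpos and tpos on `+`, increasing tpos with
#' decreasing qpos on `-` (ties broken toward smaller tpos).
#'
#' @inheritParams find_matches_cigar
#' @param a One PAF record (CIGAR not required).
#' @return data.frame of matches as in [find_matches_cigar()].
#' @export
find_matches_anchored <- function(a, qseq, tseq, index) {
  k <- index$k
  p <- rare_in_interval(index, a$tname, a$tstart, a$tend)
  if (!length(p)) return(.empty_matches())
  mp <- match(p, index$positions[[a$tname]])
  tcode <- index$codes[[a$tname]][mp]
  dupc <- unique(tcode[duplicated(tcode)])
  keep <- !(tcode %in% dupc)
  p <- p[keep]; tcode <- tcode[keep]
  if (!length(p)) return(.empty_matches())
  qint <- substr(qseq, a$qstart + 1L, a$qend)
  qc <- canonical_codes(qint, k)
  if (!length(qc)) return(.empty_matches())
  qp_all <- a$qstart + seq_along(qc) - 1L
  qkeep <- !is.na(qc)
  qc <- qc[qkeep]; qp_all <- qp_all[qkeep]
  qdup <- unique(qc[duplicated(qc)])
  qkeep <- !(qc %in% qdup)
  qc <- qc[qkeep]; qp_all <- qp_all[qkeep]
  hit <- match(tcode, qc)
  sel <- !is.na(hit)
  if (!any(sel)) return(.empty_matches())
  cand <- data.frame(qpos = qp_all[hit[sel]], tpos = p[sel],
                     code = tcode[sel])
  cand <- cand[order(cand$tpos), , drop = FALSE]
  key <- if (a$strand == "+") cand$qpos else -cand$qpos
  chain <- .lis_strict(key)
  out <- cand[chain, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' k-mer-based mapping quality (KMAPQ)
#'
#' `round(60 * m / e)` clipped to `[0, 60]` with half-up rounding; an
#' alignment whose target interval contains no rare k-mers (`e = 0`) scores
#' 0 and is flagged uninformative by [score_alignments()].
#'
#' @param m Matched rare k-mer count.
#' @param e Expected rare k-mer count.
#' @return Integer score in `[0, 60]` (vectorized).
#' @export
kmapq <- function(m, e) {
  stopifnot(all(m >= 0), all(e >= 0))
  s <- ifelse(e > 0, floor(60 * m / e + 0.5), 0)
  as.integer(pmin(60, pmax(0, s)))
}

#' Score PAF alignments by rare k-mer matching
#'
#' Computes, for every record, the match list (CIGAR projection when a
#' `cg:Z` tag is present, anchored chaining otherwise), the expected count
#' `e`, the matched count `m`, and the KMAPQ score. Input order is
#' preserved.
#'
#' @param paf PAF data.frame from [read_paf()].
#' @param target_genome Named character vector of target sequences.
#' @param query_seqs Named character vector of query sequences.
#' @param index Rare k-mer index built on `target_genome`.
#' @return List of class `scored_alignments`; each element (class
#'   `scored_aln`) holds `aln` (the PAF record as a list), `matches`, `m`,
#'   `e`, `kmapq`, `uninformative` (e = 0), and `method` ("cigar" or
#'   "anchored").
#' @export
score_alignments <- function(paf, target_genome, query_seqs, index) {
  res <- vector("list", nrow(paf))
  for (i in seq_len(nrow(paf))) {
    a <- paf[i, ]
    if (!(a$qname %in% names(query_seqs))) {
      stop("no query sequence for id: ", a$qname)
    }
    if (!(a$tname %in% names(target_genome))) {
      stop("no target sequence for id: ", a$tname)
    }
    qseq <- query_seqs[[a$qname]]
    tseq <- target_genome[[a$tname]]
    e <- expected_matches(a, index)
    if (!is.na(a$cg) && nzchar(a$cg)) {
      matches <- find_matches_cigar(a, qseq, tseq, index)
      method <- "cigar"
    } else {
      matches <- find_matches_anchored(a, qseq, tseq, index)
      method <- "anchored"
    }
    m <- nrow(matches)
    if (method == "cigar" && m > e) {
      stop("internal consistency error: m > e for record ",
           a$qname, " vs ", a$tname)
    }
    res[[i]] <- structure(
      list(aln = as.list(a), matches = matches, m = m, e = e,
           kmapq = kmapq(m, e), uninformative = (e == 0L), method = method),
      class = "scored_aln")
  }
  structure(res, class = "scored_alignments",
            k = index$k, R = index$max_count)
}

#' @export
print.scored_aln <- function(x, ...) {
  cat(sprintf("%s -> %s:%d-%d (%s)  MAPQ=%d  m=%d e=%d KMAPQ=%d%s [%s]\n",
              x$aln$qname, x$aln$tname, x$aln$tstart, x$aln$tend,
              x$aln$strand, x$aln$mapq, x$m, x$e, x$kmapq,
              if (x$uninformative) " (uninformative)" else "", x$method))
  invisible(x)
}

#' @export
print.scored_alignments <- function(x, ...) {
  cat("scored_alignments:", length(x), "records (k =", attr(x, "k"),
      ", R =", attr(x, "R"), ")\n")
  for (s in x) print(s)
  invisible(x)
}

#' Filter scored alignments by MAPQ and KMAPQ
#'
#' A record is kept iff `mapq >= min_mapq` and `kmapq >= min_kmapq`.
#' Uninformative records (`e = 0`: the aligned interval carries no rare
#' k-mer markers, so the alignment cannot be adjudicated) are exempt from
#' the KMAPQ threshold — they are kept and labeled, never silently removed.
#'
#' @param scored A `scored_alignments` list.
#' @param min_mapq MAPQ threshold in `[0, 255]`.
#' @param min_kmapq KMAPQ threshold in `[0, 60]`.
#' @return List with elements `kept` and `removed`, both
#'   `scored_alignments`.
#' @export
filter_alignments <- function(scored, min_mapq = 0L, min_kmapq = 0L) {
  stopifnot(min_mapq >= 0, min_mapq <= 255, min_kmapq >= 0, min_kmapq <= 60)
  keep <- vapply(scored, function(s) {
    s$aln$mapq >= min_mapq && (s$uninformative || s$kmapq >= min_kmapq)
  }, logical(1))
  k <- attr(scored, "k"); R <- attr(scored, "R")
  list(kept = structure(scored[keep], class = "scored_alignments",
                        k = k, R = R),
       removed = structure(scored[!keep], class = "scored_alignments",
                           k = k, R = R))
}

# scored records back to a PAF data.frame, optionally appending km/ke tags
.scored_to_paf <- function(scored, add_tags = FALSE) {
  if (!length(scored)) return(.paf_empty())
  rows <- lapply(scored, function(s) {
    a <- s$aln
    if (add_tags) {
      extra <- sprintf("km:i:%d\tke:i:%d", s$kmapq, s$e)
      a$tags <- if (nzchar(a$tags)) paste(a$tags, extra, sep = "\t") else extra
    }
    as.data.frame(a, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write filtered alignments back to PAF
#'
#' Kept records go to `path` with two appended tags, `km:i:<kmapq>` and
#' `ke:i:<e>`; removed records go to a sibling `<path minus .paf>.removed.paf`.
#'
#' @param kept,removed `scored_alignments` from [filter_alignments()].
#' @param path Output PAF path for kept records.
#' @return Character vector of the two paths, invisibly.
#' @export
write_filtered_paf <- function(kept, removed, path) {
  removed_path <- sub("\\.paf$", "", path)
  removed_path <- paste0(removed_path, ".removed.paf")
  write_paf(.scored_to_paf(kept, add_tags = TRUE), path)
  write_paf(.scored_to_paf(removed, add_tags = TRUE), removed_path)
  invisible(c(path, removed_path))
}
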