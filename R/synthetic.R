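# Repeat-genome simulator with exact ground truth. Emulates the situation
# the method targets: a genome carrying near-identical copies of one
# ancestral repeat that differ only by sparse substitutions (and optionally
# single-base indels), a contig sampled from one copy, and truth alignments
# of that contig to EVERY copy — so false-positive alignments (contig vs a
# non-source copy) exist by construction with full provenance.

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Repeat-simulation configuration
#'
#' `divergence` and `indel_rate` are pairwise rates between copies; each
#' copy is mutated from the shared ancestor at half that rate so the
#' expected pairwise difference matches the configured value.
#'
#' @param seed RNG seed; the whole simulation is reproducible from it.
#' @param genome_length Total genome length in bp.
#' @param n_copies Number of repeat copies planted (>= 2).
#' @param copy_length Ancestral repeat length in bp (default 2800, the scale
#'   of an interspersed-repeat copy).
#' @param divergence Substitutions per bp between copies, in `[0, 1)`.
#' @param indel_rate Single-base indels per bp between copies, in `[0, 1)`.
#' @param contig `list(source_copy=, offset=, length=, strand=)`: the query
#'   contig sampled from one copy (copy-local 0-based offset; strand
#'   `"+"`/`"-"`). `length = NULL` means the full copy.
#' @return An object of class `repeat_sim_config`.
#' @export
repeat_sim_config <- function(seed = 1L, genome_length = 20000L,
                              n_copies = 2L, copy_length = 2800L,
                              divergence = 0.01, indel_rate = 0,
                              contig = list(source_copy = 1L, offset = 0L,
                                            length = NULL, strand = "+")) {
  if (n_copies < 2L) stop("n_copies must be >= 2")
  if (divergence < 0 || divergence >= 1 || indel_rate < 0 || indel_rate >= 1) {
    stop("divergence and indel_rate must be in [0, 1)")
  }
  if (is.null(contig$length)) contig$length <- copy_length
  stopifnot(contig$strand %in% c("+", "-"))
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 n_copies = as.integer(n_copies),
                 copy_length = as.integer(copy_length),
                 divergence = divergence, indel_rate = indel_rate,
                 contig = contig),
            class = "repeat_sim_config")
}

# sample one copy's edit list against the ancestor: per-position exclusive
# events (substitution, deletion, insertion-before) at half the pairwise rate
.sample_edits <- function(anc, divergence, indel_rate) {
  L <- nchar(anc)
  ref <- strsplit(anc, "", fixed = TRUE)[[1L]]
  u <- stats::runif(L)
  p_sub <- divergence / 2
  p_del <- indel_rate / 4
  p_ins <- indel_rate / 4
  type <- rep(NA_character_, L)
  type[u < p_sub] <- "sub"
  type[u >= p_sub & u < p_sub + p_del] <- "del"
  type[u >= p_sub + p_del & u < p_sub + p_del + p_ins] <- "ins"
  idx <- which(!is.na(type))
  alt <- rep(NA_character_, length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    if (type[i] == "sub") {
      alt[j] <- sample(setdiff(c("A", "C", "G", "T"), ref[i]), 1L)
    } else if (type[i] == "ins") {
      alt[j] <- sample(c("A", "C", "G", "T"), 1L)
    }
  }
  data.frame(pos = idx - 1L, type = type[idx],
             ref = ifelse(type[idx] == "ins", NA_character_, ref[idx]),
             alt = alt, stringsAsFactors = FALSE)
}

# apply an edit list (ancestor coordinates) to the ancestral sequence
.apply_edits <- function(anc, edits) {
  out <- as.list(strsplit(anc, "", fixed = TRUE)[[1L]])
  for (i in seq_len(nrow(edits))) {
    p <- edits$pos[i] + 1L
    switch(edits$type[i],
           sub = { out[[p]] <- edits$alt[i] },
           del = { out[[p]] <- "" },
           ins = { out[[p]] <- paste0(edits$alt[i], out[[p]]) })
  }
  paste(unlist(out), collapse = "")
}

#' Simulate a genome with near-identical repeat copies
#'
#' A random i.i.d. background of `genome_length` bp with `n_copies` mutated
#' instances of one random ancestral repeat planted at recorded, evenly
#' spaced non-overlapping coordinates. Fully reproducible from
#' `config$seed`.
#'
#' @param config A [repeat_sim_config()] object.
#' @return List with `genome` (named character vector, one sequence `ref1`)
#'   and `truth` (class `repeat_truth`: ancestor, copy coordinates,
#'   per-copy edit lists, copy sequences, config).
#' @export
simulate_repeat_genome <- function(config) {
  stopifnot(inherits(config, "repeat_sim_config"))
  set.seed(config$seed)
  anc <- .random_dna(config$copy_length)
  edits <- vector("list", config$n_copies)
  copy_seq <- character(config$n_copies)
  for (i in seq_len(config$n_copies)) {
    edits[[i]] <- .sample_edits(anc, config$divergence, config$indel_rate)
    copy_seq[i] <- .apply_edits(anc, edits[[i]])
  }
  background <- .random_dna(config$genome_length)
  slot <- config$genome_length %/% config$n_copies
  len <- nchar(copy_seq)
  if (any(len > slot)) {
    stop("copies cannot be placed without overlap: copy length ",
         max(len), " exceeds slot width ", slot)
  }
  start <- (seq_len(config$n_copies) - 1L) * slot + (slot - len) %/% 2L
  pieces <- character(0)
  at <- 0L  # 0-based cursor on the background
  for (i in seq_len(config$n_copies)) {
    pieces <- c(pieces, substr(background, at + 1L, start[i]), copy_seq[i])
    at <- start[i] + len[i]
  }
  pieces <- c(pieces, substr(background, at + 1L, config$genome_length))
  genome <- c(ref1 = paste(pieces, collapse = ""))
  truth <- structure(
    list(ancestor = anc,
         copies = data.frame(copy = seq_len(config$n_copies),
                             start = start, end = start + len),
         edits = edits, copy_seq = copy_seq, config = config),
    class = "repeat_truth")
  list(genome = genome, truth = truth)
}

#' Extract the query contig from its source copy
#'
#' @param genome Named character vector from [simulate_repeat_genome()].
#' @param truth The matching `repeat_truth`.
#' @param config The simulation config (its `contig` field defines source
#'   copy, copy-local offset, length and strand).
#' @return Named character vector with one sequence `contig1` (reverse-
#'   complemented when strand is `"-"`); provenance attached as attribute
#'   `"provenance"`.
#' @export
extract_contig <- function(genome, truth, config) {
  ct <- config$contig
  src <- ct$source_copy
  cstart <- truth$copies$start[src]
  clen <- truth$copies$end[src] - cstart
  if (ct$offset < 0L || ct$offset + ct$length > clen) {
    stop("contig interval [", ct$offset, ", ", ct$offset + ct$length,
         ") outside source copy of length ", clen)
  }
  seq <- substr(genome[[1L]], cstart + ct$offset + 1L,
                cstart + ct$offset + ct$length)
  if (ct$strand == "-") seq <- revcomp(seq)
  out <- c(contig1 = seq)
  attr(out, "provenance") <- list(source_copy = src, offset = ct$offset,
                                  length = ct$length, strand = ct$strand)
  out
}

# op stream (one op per alignment column) between the contig's source copy
# (query, A) and copy B (target) over the shared ancestor; used to build
# truth CIGARs. Per ancestor position: A-insertions are I columns,
# B-insertions D columns; the base is M when present in both, D when
# deleted in A only, I when deleted in B only.
.pair_op_stream <- function(edA, edB, anc_chars) {
  L <- length(anc_chars)
  assign_edits <- function(ed) {
    sub <- del <- ins <- rep(FALSE, L)
    alt <- anc_chars
    for (i in seq_len(nrow(ed))) {
      p <- ed$pos[i] + 1L
      switch(ed$type[i],
             sub = { sub[p] <- TRUE; alt[p] <- ed$alt[i] },
             del = { del[p] <- TRUE },
             ins = { ins[p] <- TRUE })
    }
    list(sub = sub, del = del, ins = ins, alt = alt)
  }
  A <- assign_edits(edA)
  B <- assign_edits(edB)
  # up to 3 columns per ancestor position: A-ins, B-ins, base
  op <- matrix(NA_character_, nrow = 3L, ncol = L)
  mism <- matrix(FALSE, nrow = 3L, ncol = L)
  op[1L, A$ins] <- "I"
  op[2L, B$ins] <- "D"
  both <- !A$del & !B$del
  op[3L, both] <- "M"
  op[3L, A$del & !B$del] <- "D"
  op[3L, !A$del & B$del] <- "I"
  mism[1L, A$ins] <- TRUE            # inserted bases count toward NM
  mism[2L, B$ins] <- TRUE
  mism[3L, both] <- A$alt[both] != B$alt[both]
  keep <- !is.na(op)
  data.frame(op = op[keep], mism = mism[keep] | op[keep] != "M")
}

#' Construct ground-truth PAF alignments of the contig to every copy
#'
#' Builds, by construction rather than by running an aligner, one PAF record
#' aligning the contig to the homologous interval of each repeat copy, with
#' an exact `cg:Z` CIGAR and `NM:i` computed from the planted edit lists.
#' MAPQ is set to 60 on all records, mirroring the ambiguous-repeat
#' situation in which the aligner's score cannot separate the copies.
#'
#' @param genome,truth From [simulate_repeat_genome()].
#' @param contig From [extract_contig()] (provenance attribute required).
#' @return PAF data.frame (see [read_paf()]) with one record per copy.
#' @export
emit_truth_paf <- function(genome, truth, contig) {
  prov <- attr(contig, "provenance")
  if (is.null(prov)) stop("contig lacks provenance; use extract_contig()")
  src <- prov$source_copy
  qlen <- nchar(contig[[1L]])
  anc_chars <- strsplit(truth$ancestor, "", fixed = TRUE)[[1L]]
  n_copies <- nrow(truth$copies)
  rows <- vector("list", n_copies)
  for (ci in seq_len(n_copies)) {
    if (ci == src) {
      stream <- data.frame(op = rep("M", qlen), mism = FALSE)
      tstart_local <- prov$offset
    } else {
      full <- .pair_op_stream(truth$edits[[src]], truth$edits[[ci]], anc_chars)
      qcons <- full$op %in% c("M", "I")
      tcons <- full$op %in% c("M", "D")
      cumq <- cumsum(qcons)
      sel <- which(cumq >= prov$offset + 1L & cumq <= prov$offset + prov$length)
      # trim trailing target-only columns (they lie outside the query span)
      while (length(sel) && !qcons[sel[length(sel)]]) {
        sel <- sel[-length(sel)]
      }
      stream <- full[sel, , drop = FALSE]
      tstart_local <- sum(tcons[seq_len(if (length(sel)) sel[1L] - 1L else 0L)])
    }
    op <- stream$op
    tlen_local <- sum(op %in% c("M", "D"))
    r <- rle(op)
    cg <- paste0(r$lengths, r$values, collapse = "")
    nm <- sum(stream$mism)
    tstart <- truth$copies$start[ci] + tstart_local
    rows[[ci]] <- data.frame(
      qname = names(contig)[1L], qlen = qlen, qstart = 0L, qend = qlen,
      strand = prov$strand, tname = names(genome)[1L],
      tlen = nchar(genome[[1L]]), tstart = tstart,
      tend = tstart + tlen_local,
      nmatch = sum(op == "M" & !stream$mism), alen = nrow(stream),
      mapq = 60L,
      tags = sprintf("NM:i:%d\tcg:Z:%s", nm, cg),
      cg = cg, nm = nm, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  for (i in seq_len(nrow(out))) {
    .validate_paf_record(out[i, ], where = " (truth PAF)")
  }
  out
}
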