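# Independent oracles and fixture builders: naive string-based k-mer
# scanning, per-position CIGAR walking, and random input generators. These
# deliberately avoid the package's vectorized/encoded code paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

o_rc <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

o_canon <- function(w) {
  r <- o_rc(w)
  if (r < w) r else w
}

o_windows <- function(s, k) {
  n <- nchar(s) - k + 1L
  if (n < 1L) character(0) else substring(s, 1:n, k:nchar(s))
}

# naive dictionary scan: named integer vector canonical k-mer -> count
o_kmer_counts <- function(genome, k) {
  wins <- unlist(lapply(genome, o_windows, k = k), use.names = FALSE)
  wins <- wins[!grepl("N", wins, fixed = TRUE)]
  if (!length(wins)) return(stats::setNames(integer(0), character(0)))
  canon <- vapply(wins, o_canon, "", USE.NAMES = FALSE)
  tab <- table(canon)
  stats::setNames(as.integer(tab), names(tab))
}

# naive rare positions: 0-based starts whose canonical count <= R, per seq
o_rare_positions <- function(genome, k, R) {
  cnt <- o_kmer_counts(genome, k)
  lapply(genome, function(s) {
    w <- o_windows(s, k)
    keep <- vapply(w, function(x) {
      if (grepl("N", x, fixed = TRUE)) return(FALSE)
      cnt[[o_canon(x)]] <= R
    }, logical(1), USE.NAMES = FALSE)
    which(keep) - 1L
  })
}

o_random_dna <- function(n, p_n = 0) {
  letters <- c("A", "C", "G", "T")
  x <- sample(letters, n, replace = TRUE)
  if (p_n > 0) x[runif(n) < p_n] <- "N"
  paste(x, collapse = "")
}

o_parse_cigar <- function(cg) {
  toks <- regmatches(cg, gregexpr("[0-9]+[A-Z=]", cg))[[1L]]
  list(op = sub("^[0-9]+", "", toks),
       len = as.integer(sub(".$", "", toks)))
}

# per-position CIGAR walk: target image of query position qp, or NA
o_project <- function(a, qp) {
  cig <- o_parse_cigar(a$cg)
  w <- if (a$strand == "+") qp else a$qlen - 1L - qp
  q <- if (a$strand == "+") a$qstart else a$qlen - a$qend
  t <- a$tstart
  for (i in seq_along(cig$op)) {
    op <- cig$op[i]
    l <- cig$len[i]
    if (op %in% c("M", "=", "X")) {
      if (w >= q && w < q + l) return(t + (w - q))
      q <- q + l
      t <- t + l
    } else if (op == "I") {
      if (w >= q && w < q + l) return(NA_integer_)
      q <- q + l
    } else {
      t <- t + l
    }
  }
  NA_integer_
}

# construct a one-row PAF data.frame in the read_paf() column layout
t_aln <- function(qname = "q1", qlen, qstart = 0L, qend = qlen,
                  strand = "+", tname = "t1", tlen, tstart, tend,
                  nmatch = NULL, alen = NULL, mapq = 60L,
                  cg = NA_character_, nm = NA_integer_) {
  tags <- if (!is.na(cg)) paste0("cg:Z:", cg) else ""
  data.frame(qname = qname, qlen = as.integer(qlen),
             qstart = as.integer(qstart), qend = as.integer(qend),
             strand = strand, tname = tname, tlen = as.integer(tlen),
             tstart = as.integer(tstart), tend = as.integer(tend),
             nmatch = as.integer(nmatch %||% (qend - qstart)),
             alen = as.integer(alen %||% (qend - qstart)),
             mapq = as.integer(mapq), tags = tags, cg = cg,
             nm = as.integer(nm), stringsAsFactors = FALSE)
}

# random valid CIGAR (alternating aligned blocks and indels) plus a
# consistent query/target sequence pair; strand-aware
o_random_alignment <- function(tlen_extra = 30L, strand = "+",
                               n_blocks = NULL, max_block = 30L) {
  n_blocks <- n_blocks %||% sample(1:5, 1)
  ops <- character(0)
  lens <- integer(0)
  for (b in seq_len(n_blocks)) {
    ops <- c(ops, "M")
    lens <- c(lens, sample(2:max_block, 1))
    if (b < n_blocks) {
      ops <- c(ops, sample(c("I", "D"), 1))
      lens <- c(lens, sample(1:4, 1))
    }
  }
  tspan <- sum(lens[ops %in% c("M", "D")])
  qspan <- sum(lens[ops %in% c("M", "I")])
  tstart <- sample(0:tlen_extra, 1)
  tlen <- tstart + tspan + sample(0:tlen_extra, 1)
  tseq <- o_random_dna(tlen)
  # walk the CIGAR to build the aligned (RC-frame) query
  qchars <- character(0)
  t <- tstart
  for (i in seq_along(ops)) {
    if (ops[i] == "M") {
      qchars <- c(qchars, substring(tseq, t + 1L, t + lens[i]))
      t <- t + lens[i]
    } else if (ops[i] == "I") {
      qchars <- c(qchars, o_random_dna(lens[i]))
    } else {
      t <- t + lens[i]
    }
  }
  qaln <- paste(qchars, collapse = "")
  lead <- sample(0:10, 1)
  trail <- sample(0:10, 1)
  qfwd <- paste0(o_random_dna(lead), qaln, o_random_dna(trail))
  qlen <- nchar(qfwd)
  # on '-', the stored query is the reverse complement of the walk frame
  qseq <- if (strand == "+") qfwd else o_rc(qfwd)
  qstart <- if (strand == "+") lead else trail
  a <- t_aln(qlen = qlen, qstart = qstart, qend = qstart + qspan,
             strand = strand, tlen = tlen, tstart = tstart,
             tend = tstart + tspan, alen = sum(lens),
             cg = paste0(lens, ops, collapse = ""))
  list(a = a, qseq = qseq, tseq = tseq)
}

# scored fixture: nq query slices of a random genome, n alignments with
# all-M CIGARs cycling over the queries
t_scored_fixture <- function(n = 100L, nq = 10L, seed = 42L,
                             glen = 5000L, qlen = 200L, k = 11L) {
  set.seed(seed)
  genome <- c(t1 = o_random_dna(glen))
  queries <- character(nq)
  names(queries) <- paste0("q", seq_len(nq))
  starts <- (seq_len(nq) - 1L) * 40L
  for (i in seq_len(nq)) {
    queries[i] <- substring(genome[[1L]], starts[i] + 1L, starts[i] + qlen)
  }
  rows <- lapply(seq_len(n), function(i) {
    qi <- ((i - 1L) %% nq) + 1L
    t_aln(qname = names(queries)[qi], qlen = qlen, tlen = glen,
          tstart = starts[qi], tend = starts[qi] + qlen,
          cg = paste0(qlen, "M"))
  })
  paf <- do.call(rbind, rows)
  idx <- build_rare_index(genome, kmer_params(k = k, max_count = 1L))
  list(scored = score_alignments(paf, genome, queries, idx),
       paf = paf, genome = genome, queries = queries, idx = idx)
}

# one simulated discrimination trial; returns the scored pair of records
t_discrimination_trial <- function(seed, divergence = 0.01,
                                   copy_length = 2800L,
                                   genome_length = 20000L) {
  cfg <- repeat_sim_config(seed = seed, genome_length = genome_length,
                           copy_length = copy_length,
                           divergence = divergence)
  sim <- simulate_repeat_genome(cfg)
  contig <- extract_contig(sim$genome, sim$truth, cfg)
  paf <- emit_truth_paf(sim$genome, sim$truth, contig)
  idx <- build_rare_index(sim$genome, kmer_params())
  score_alignments(paf, sim$genome, contig, idx)
}
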