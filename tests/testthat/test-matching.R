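# fixture: random genome (all windows rare at k=21), query = exact slice
.slice_fixture <- function(seed = 3L, glen = 500L, offset = 200L,
                           slice_len = 100L, k = 21L) {
  set.seed(seed)
  genome <- c(t1 = o_random_dna(glen))
  qseq <- substring(genome[[1L]], offset + 1L, offset + slice_len)
  a <- t_aln(qlen = slice_len, qend = slice_len, tlen = glen,
             tstart = offset, tend = offset + slice_len,
             cg = paste0(slice_len, "M"))
  idx <- build_rare_index(genome, kmer_params(k, 1L))
  list(genome = genome, qseq = qseq, a = a, idx = idx, k = k)
}

test_that("expected_matches counts rare windows inside the target interval", {
  idx <- structure(list(k = 4L, max_count = 1L, seq_lengths = c(t1 = 100L),
                        positions = list(t1 = c(2L, 10L, 50L)),
                        codes = list(t1 = c(1, 2, 3)),
                        genome_total_rare = 3L),
                   class = "rare_kmer_index")
  expect_identical(expected_matches(t_aln(qlen = 14L, tlen = 100L,
                                          tstart = 0L, tend = 14L), idx), 2L)
  expect_identical(expected_matches(t_aln(qlen = 5L, tlen = 100L,
                                          tstart = 60L, tend = 80L), idx), 0L)
  expect_identical(expected_matches(t_aln(qlen = 100L, tlen = 100L,
                                          tstart = 0L, tend = 100L), idx), 3L)
  expect_error(expected_matches(t_aln(qlen = 5L, tname = "zz", tlen = 10L,
                                      tstart = 0L, tend = 5L), idx),
               "unknown sequence id")
})

test_that("a perfect copy matches every rare window; a SNP removes k of them", {
  fx <- .slice_fixture()
  m0 <- find_matches_cigar(fx$a, fx$qseq, fx$genome[[1L]], fx$idx)
  expect_identical(nrow(m0), 100L - 21L + 1L)  # 80 windows, all rare
  expect_identical(m0$tpos, fx$a$tstart + m0$qpos)
  expect_identical(nrow(m0), expected_matches(fx$a, fx$idx))

  # substitute the base at slice offset 50 in the query
  q2 <- fx$qseq
  old <- substring(q2, 51L, 51L)
  substr(q2, 51L, 51L) <- setdiff(c("A", "C", "G", "T"), old)[1L]
  m1 <- find_matches_cigar(fx$a, q2, fx$genome[[1L]], fx$idx)
  expect_identical(nrow(m1), 80L - 21L)  # every window covering the SNP fails
  # brute force: windows not overlapping offset 50 still match
  covered <- 30:50
  expect_identical(m1$qpos, setdiff(m0$qpos, covered))
})

test_that("a markerless repeat region yields no matches and e = 0", {
  polyA <- paste(rep("A", 100), collapse = "")
  genome <- c(t1 = paste0(polyA, polyA))  # poly-A: nothing is rare
  idx <- build_rare_index(genome, kmer_params(21, 1))
  a <- t_aln(qlen = 100L, tlen = 200L, tstart = 0L, tend = 100L, cg = "100M")
  expect_identical(expected_matches(a, idx), 0L)
  expect_identical(nrow(find_matches_cigar(a, polyA, genome[[1L]], idx)), 0L)
})

test_that("cigar matching agrees with per-position brute force on random alignments", {
  set.seed(77)
  for (i in 1:25) {
    strand <- sample(c("+", "-"), 1)
    al <- o_random_alignment(strand = strand, max_block = 40L)
    k <- 6L
    idx <- build_rare_index(c(t1 = al$tseq), kmer_params(k, 1L))
    got <- find_matches_cigar(al$a, al$qseq, al$tseq, idx)
    # oracle: project every rare window position by position, compare strings
    want_q <- integer(0); want_t <- integer(0)
    qrange <- al$a$qstart:(al$a$qend - 1L)
    timg <- vapply(qrange, function(qp) o_project(al$a, qp), integer(1))
    for (p in rare_in_interval(idx, "t1", al$a$tstart, al$a$tend)) {
      # inverse of the per-position walk: query positions mapping onto tp
      qof <- function(tp) {
        h <- qrange[!is.na(timg) & timg == tp]
        if (length(h) == 1L) h else NA_integer_
      }
      qps <- vapply(p:(p + k - 1L), qof, integer(1))
      consec <- !anyNA(qps) &&
        all(diff(qps) == (if (al$a$strand == "+") 1L else -1L))
      if (!consec) next
      qpos <- min(qps)
      qwin <- substring(al$qseq, qpos + 1L, qpos + k)
      twin <- substring(al$tseq, p + 1L, p + k)
      hit <- if (al$a$strand == "+") qwin == twin else qwin == o_rc(twin)
      if (hit) { want_q <- c(want_q, qpos); want_t <- c(want_t, p) }
    }
    expect_identical(got$tpos, want_t)
    expect_identical(got$qpos, want_q)
  }
})

test_that("anchored matching keeps the longest monotone chain", {
  # query assembled from three target windows in non-monotone order:
  # candidates {(0,10), (8,2), (16,20)} -> chain {(0,10), (16,20)}
  set.seed(9)
  k <- 8L
  tseq <- o_random_dna(60L)
  win <- function(p) substring(tseq, p + 1L, p + k)
  qseq <- paste0(win(10L), win(2L), win(20L))
  genome <- c(t1 = tseq)
  idx <- build_rare_index(genome, kmer_params(k, 1L))
  a <- t_aln(qlen = 24L, tlen = 60L, tstart = 0L, tend = 30L,
             alen = 30L)  # no CIGAR
  got <- find_matches_anchored(a, qseq, tseq, idx)
  # brute-force oracle: enumerate all candidate subsets, keep the longest
  # strictly monotone one (ties toward smaller tpos)
  cand <- data.frame(qpos = c(0L, 8L, 16L), tpos = c(10L, 2L, 20L))
  best <- NULL
  for (mask in seq_len(2^nrow(cand)) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(nrow(cand)) - 1L)) > 0L)
    sub <- cand[sel, , drop = FALSE]
    sub <- sub[order(sub$tpos), , drop = FALSE]
    if (nrow(sub) > 1L &&
        (any(diff(sub$qpos) <= 0L) || any(diff(sub$tpos) <= 0L))) next
    if (is.null(best) || nrow(sub) > nrow(best)) best <- sub
  }
  expect_identical(got$qpos, best$qpos)
  expect_identical(got$tpos, best$tpos)
  expect_identical(nrow(got), 2L)

  # zero candidates: unrelated random query shares no 21-mers
  set.seed(10)
  g2 <- c(t1 = o_random_dna(300L))
  idx2 <- build_rare_index(g2, kmer_params(21, 1))
  a2 <- t_aln(qlen = 100L, tlen = 300L, tstart = 0L, tend = 300L, alen = 300L)
  expect_identical(nrow(find_matches_anchored(a2, o_random_dna(100L),
                                              g2[[1L]], idx2)), 0L)

  # already-collinear candidates are all retained: exact slice, no CIGAR
  q3 <- substring(g2[[1L]], 101L, 200L)
  a3 <- t_aln(qlen = 100L, tlen = 300L, tstart = 100L, tend = 200L,
              alen = 100L)
  m3 <- find_matches_anchored(a3, q3, g2[[1L]], idx2)
  expect_identical(nrow(m3), expected_matches(a3, idx2))
})

test_that("kmapq is the half-up-rounded scaled match fraction", {
  expect_identical(kmapq(73, 73), 60L)
  expect_identical(kmapq(0, 50), 0L)
  expect_identical(kmapq(3, 4), 45L)
  expect_identical(kmapq(1, 2), 30L)
  expect_identical(kmapq(1, 3), 20L)
  expect_identical(kmapq(0, 0), 0L)  # uninformative
  expect_identical(kmapq(c(3, 0), c(4, 0)), c(45L, 0L))
})

test_that("score_alignments preserves order and flags uninformative records", {
  fx <- .slice_fixture()
  queries <- c(q1 = fx$qseq)
  scored <- score_alignments(fx$a[0, ], fx$genome, queries, fx$idx)
  expect_length(scored, 0L)

  paf <- rbind(fx$a, fx$a)
  paf$tstart[2L] <- 100L; paf$tend[2L] <- 200L
  scored <- score_alignments(paf, fx$genome, queries, fx$idx)
  expect_length(scored, 2L)
  expect_identical(scored[[1L]]$aln$tstart, fx$a$tstart)
  expect_identical(scored[[1L]]$kmapq, 60L)  # self-slice: m = e
  expect_identical(scored[[1L]]$m, scored[[1L]]$e)
  expect_false(scored[[1L]]$uninformative)

  expect_error(score_alignments(fx$a, fx$genome, c(zz = "ACGT"), fx$idx),
               "no query sequence for id: q1")
})

test_that("filtering keeps by MAPQ and KMAPQ and never drops uninformative silently", {
  fx <- .slice_fixture()
  polyA <- paste(rep("A", 100), collapse = "")
  genome <- c(t1 = paste0(substring(fx$genome[[1L]], 1, 300),
                          polyA, polyA))
  idx <- build_rare_index(genome, kmer_params(21, 1))
  paf <- rbind(
    fx$a,                                               # true copy, KMAPQ 60
    t_aln(qname = "q2", qlen = 100L, tlen = 500L,       # shuffled, KMAPQ 0
          tstart = 0L, tend = 100L, cg = "100M"),
    t_aln(qname = "qa", qlen = 100L, tlen = 500L,       # poly-A, e = 0
          tstart = 310L, tend = 410L, cg = "100M"))
  set.seed(4)
  queries <- c(q1 = substring(genome[[1L]], 201L, 300L),
               q2 = o_random_dna(100L), qa = polyA)
  scored <- score_alignments(paf, genome, queries, idx)
  expect_true(scored[[3L]]$uninformative)

  all_kept <- filter_alignments(scored, 0, 0)
  expect_length(all_kept$kept, 3L)
  expect_length(all_kept$removed, 0L)

  fl <- filter_alignments(scored, 0, 30)
  expect_length(fl$kept, 2L)
  # the high-MAPQ record unsupported by rare k-mers is removed
  expect_identical(fl$removed[[1L]]$aln$qname, "q2")
  expect_identical(fl$removed[[1L]]$aln$mapq, 60L)
  expect_identical(fl$removed[[1L]]$kmapq, 0L)
  # uninformative record survives the KMAPQ threshold, labeled
  kept_names <- vapply(fl$kept, function(s) s$aln$qname, "")
  expect_true("qa" %in% kept_names)
  expect_true(fl$kept[[which(kept_names == "qa")]]$uninformative)
})

test_that("m and kmapq are invariant under reverse-complementing the query", {
  set.seed(15)
  glen <- 400L
  genome <- c(t1 = o_random_dna(glen))
  # alignment with an indel so the CIGAR is direction-sensitive
  tseq <- genome[[1L]]
  qfwd <- paste0(substring(tseq, 101L, 150L), substring(tseq, 154L, 203L))
  a_plus <- t_aln(qlen = 100L, tlen = glen, tstart = 100L, tend = 203L,
                  cg = "50M3D50M", alen = 103L)
  idx <- build_rare_index(genome, kmer_params(11, 1))
  s_plus <- find_matches_cigar(a_plus, qfwd, tseq, idx)

  a_minus <- a_plus
  a_minus$strand <- "-"
  a_minus$cg <- "50M3D50M"  # run order is symmetric here
  a_minus$tags <- paste0("cg:Z:", a_minus$cg)
  s_minus <- find_matches_cigar(a_minus, o_rc(qfwd), tseq, idx)
  expect_identical(nrow(s_minus), nrow(s_plus))
  expect_identical(s_minus$tpos, s_plus$tpos)
  # q-coordinates remap through qlen - qpos - k
  expect_identical(sort(s_minus$qpos), sort(100L - s_plus$qpos - 11L))
})

test_that("each isolated substitution removes exactly k matches", {
  k <- 21L
  set.seed(33)
  glen <- 1000L
  genome <- c(t1 = o_random_dna(glen))
  idx <- build_rare_index(genome, kmer_params(k, 1L))
  offset <- 300L; slice_len <- 400L
  q0 <- substring(genome[[1L]], offset + 1L, offset + slice_len)
  a <- t_aln(qlen = slice_len, tlen = glen, tstart = offset,
             tend = offset + slice_len, cg = paste0(slice_len, "M"))
  e <- expected_matches(a, idx)
  m_prev <- nrow(find_matches_cigar(a, q0, genome[[1L]], idx))
  expect_identical(m_prev, e)
  # SNP offsets pairwise >= 2k apart, >= k from the interval ends
  snp_at <- c(50L, 150L, 250L, 350L)
  q <- q0
  for (s in seq_along(snp_at)) {
    p <- snp_at[s]
    old <- substring(q, p + 1L, p + 1L)
    substr(q, p + 1L, p + 1L) <- setdiff(c("A", "C", "G", "T"), old)[1L]
    m <- nrow(find_matches_cigar(a, q, genome[[1L]], idx))
    expect_identical(m, e - s * k)
    expect_identical(m, m_prev - k)  # monotone degradation, exactly k per SNP
    m_prev <- m
  }
})
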