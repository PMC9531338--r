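# CIGAR coordinate projection between query and target, strand-aware.
#
# PAF minus-strand convention (minimap2 dialect): qstart/qend are on the
# original query strand, but the CIGAR describes the reverse-complemented
# query against the forward target. Projection therefore walks in the
# "RC frame": a query position qp maps to walk coordinate
#   qp           on +, and
#   qlen - 1 - qp on -,
# and the walk starts at (qstart, tstart) on + and (qlen - qend, tstart) on -.

#' Co-linear blocks of an alignment CIGAR
#'
#' Decomposes the CIGAR into maximal gap-free blocks in the walk frame
#' (reverse-complement frame for minus-strand records).
#'
#' @param a One PAF record (one-row data.frame or named list) with a CIGAR.
#' @return data.frame with columns `q0`, `t0`, `len`: block starts on the
#'   walk-frame query and the target, and block length.
#' @export
cigar_blocks <- function(a) {
  if (is.na(a$cg) || !nzchar(a$cg)) stop("projection requires CIGAR (cg:Z tag)")
  cig <- parse_cigar(a$cg)
  q <- if (a$strand == "+") a$qstart else a$qlen - a$qend
  t <- a$tstart
  n <- sum(cig$op %in% c("M", "=", "X"))
  q0 <- integer(n); t0 <- integer(n); len <- integer(n)
  bi <- 0L
  for (i in seq_len(nrow(cig))) {
    op <- cig$op[i]; l <- cig$len[i]
    if (op %in% c("M", "=", "X")) {
      bi <- bi + 1L
      q0[bi] <- q; t0[bi] <- t; len[bi] <- l
      q <- q + l; t <- t + l
    } else if (op == "I") {
      q <- q + l
    } else {
      t <- t + l
    }
  }
  data.frame(q0 = q0, t0 = t0, len = len)
}

#' Project query positions onto the target through the CIGAR
#'
#' @param a One PAF record with a CIGAR.
#' @param qp Integer vector of 0-based query positions on the original query
#'   strand, each in `[qstart, qend)`.
#' @return Integer vector of target positions; `NA` where the position falls
#'   inside an insertion (unmapped).
#' @export
project_query_to_target <- function(a, qp) {
  if (any(qp < a$qstart | qp >= a$qend)) {
    stop("query position outside aligned interval [", a$qstart, ", ", a$qend, ")")
  }
  b <- cigar_blocks(a)
  w <- if (a$strand == "+") qp else a$qlen - 1L - qp
  i <- findInterval(w, b$q0)
  ii <- pmax(i, 1L)
  ok <- i >= 1L & w < b$q0[ii] + b$len[ii]
  tp <- b$t0[ii] + (w - b$q0[ii])
  tp[!ok] <- NA_integer_
  as.integer(tp)
}

#' Project target positions onto the query through the CIGAR
#'
#' Inverse walk of [project_query_to_target()].
#'
#' @param a One PAF record with a CIGAR.
#' @param tp Integer vector of 0-based target positions in `[tstart, tend)`.
#' @return Integer vector of query positions on the original strand; `NA`
#'   where the target position falls inside a deletion (no preimage).
#' @export
project_target_to_query <- function(a, tp) {
  if (any(tp < a$tstart | tp >= a$tend)) {
    stop("target position outside aligned interval [", a$tstart, ", ", a$tend, ")")
  }
  b <- cigar_blocks(a)
  i <- findInterval(tp, b$t0)
  ii <- pmax(i, 1L)
  ok <- i >= 1L & tp < b$t0[ii] + b$len[ii]
  w <- b$q0[ii] + (tp - b$t0[ii])
  qp <- if (a$strand == "+") w else a$qlen - 1L - w
  qp[!ok] <- NA_integer_
  as.integer(qp)
}

#' Is a whole k-window co-linear under the alignment?
#'
#' TRUE iff all `k` query positions `qp .. qp+k-1` are mapped and their
#' target images are consecutive, i.e. no indel falls inside the window.
#'
#' @param a One PAF record with a CIGAR.
#' @param qp 0-based window start on the original query strand (vectorized).
#' @param k Window length.
#' @return Logical vector.
#' @export
window_projectable <- function(a, qp, k) {
  if (any(qp < a$qstart | qp >= a$qend)) {
    stop("query position outside aligned interval [", a$qstart, ", ", a$qend, ")")
  }
  b <- cigar_blocks(a)
  w <- if (a$strand == "+") qp else a$qlen - qp - k
  i <- findInterval(w, b$q0)
  ii <- pmax(i, 1L)
  unname(i >= 1L & w >= 0L & w + k <= b$q0[ii] + b$len[ii] & qp + k <= a$qend)
}

# Vectorized inverse window projection used by the matcher: for target
# window starts tp, return the original-strand query window start when the
# whole window lies in one co-linear block, else NA.
.project_target_window <- function(a, tp, k, blocks = cigar_blocks(a)) {
  if (!length(tp)) return(integer(0))
  i <- findInterval(tp, blocks$t0)
  ii <- pmax(i, 1L)
  ok <- i >= 1L & tp + k <= blocks$t0[ii] + blocks$len[ii]
  w <- blocks$q0[ii] + (tp - blocks$t0[ii])
  qp <- if (a$strand == "+") w else a$qlen - w - k
  qp[!ok] <- NA_integer_
  as.integer(qp)
}
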