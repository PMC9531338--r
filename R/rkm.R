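# The .rkm intermediate format: one block per scored alignment (an A-line
# with all PAF fields plus m/e/KMAPQ, followed by m K-lines, one per k-mer
# match), plus two sidecar indexes mapping query/target ids to the byte
# offsets of their A-lines so blocks can be retrieved by seeking, without
# scanning the file. K-lines store positions and the integer canonical code,
# never the k-mer string. See FORMAT.md for the exact column layout.

.A_NCOL <- 18L  # "A" + 12 PAF fields + m, e, kmapq, uninformative, method

.format_a_line <- function(s) {
  a <- s$aln
  base <- paste(c("A", a$qname, a$qlen, a$qstart, a$qend, a$strand,
                  a$tname, a$tlen, a$tstart, a$tend, a$nmatch, a$alen,
                  a$mapq, s$m, s$e, s$kmapq, as.integer(s$uninformative),
                  s$method), collapse = "\t")
  paste(base, a$tags, sep = "\t")  # tags last (may be empty / contain tabs)
}

.parse_a_line <- function(f) {
  tags <- if (length(f) > .A_NCOL) {
    paste(f[(.A_NCOL + 1L):length(f)], collapse = "\t")
  } else ""
  aln <- list(
    qname = f[2L], qlen = as.integer(f[3L]), qstart = as.integer(f[4L]),
    qend = as.integer(f[5L]), strand = f[6L], tname = f[7L],
    tlen = as.integer(f[8L]), tstart = as.integer(f[9L]),
    tend = as.integer(f[10L]), nmatch = as.integer(f[11L]),
    alen = as.integer(f[12L]), mapq = as.integer(f[13L]), tags = tags,
    cg = .extract_tag(tags, "cg:Z:"),
    nm = suppressWarnings(as.integer(.extract_tag(tags, "NM:i:"))))
  list(aln = aln, m = as.integer(f[14L]), e = as.integer(f[15L]),
       kmapq = as.integer(f[16L]), uninformative = as.integer(f[17L]) == 1L,
       method = f[18L])
}

.parse_rkm_header <- function(line, path) {
  if (is.na(line) || !startsWith(line, "#rkm")) {
    stop("not an .rkm file (missing #rkm header): ", path)
  }
  list(k = as.integer(sub(".*\\tk=([0-9]+).*", "\\1", line)),
       R = as.integer(sub(".*\\tR=([0-9]+).*", "\\1", line)))
}

.block_from_lines <- function(aline, klines, where) {
  f <- strsplit(aline, "\t", fixed = TRUE)[[1L]]
  if (length(f) < .A_NCOL || f[1L] != "A") {
    stop("corrupt RKM file: bad A-line ", where)
  }
  b <- .parse_a_line(f)
  if (length(klines) < b$m) {
    stop("corrupt RKM file: block ", where, " declares m=", b$m,
         " but only ", length(klines), " K-lines follow")
  }
  klines <- klines[seq_len(b$m)]
  if (b$m > 0L) {
    kf <- strsplit(klines, "\t", fixed = TRUE)
    if (any(lengths(kf) != 4L) || any(vapply(kf, `[`, "", 1L) != "K")) {
      stop("corrupt RKM file: bad K-line ", where)
    }
    matches <- data.frame(
      qpos = as.integer(vapply(kf, `[`, "", 2L)),
      tpos = as.integer(vapply(kf, `[`, "", 3L)),
      code = as.numeric(vapply(kf, `[`, "", 4L)))
  } else {
    matches <- .empty_matches()
  }
  structure(list(aln = b$aln, matches = matches, m = b$m, e = b$e,
                 kmapq = b$kmapq, uninformative = b$uninformative,
                 method = b$method),
            class = "scored_aln")
}

#' Write scored alignments to an .rkm file with offset indexes
#'
#' Produces three files: `path` (header, A-lines, K-lines), `path.qidx` and
#' `path.tidx` — TSV `seq_id<TAB>byte_offset` rows locating every A-line by
#' its query id and target id respectively. Offsets (not line numbers) are
#' stored so [rkm_lookup()] can seek directly to a block.
#'
#' @param scored A `scored_alignments` list from [score_alignments()].
#' @param path Output path (conventionally `<name>.rkm`).
#' @param target_name Name of the target FASTA, recorded in the header.
#' @return Character vector of the three paths, invisibly.
#' @export
write_rkm <- function(scored, path, target_name = "") {
  k <- attr(scored, "k"); R <- attr(scored, "R")
  ver <- as.character(utils::packageVersion("rkmviz"))
  header <- sprintf("#rkm\tk=%s\tR=%s\tproducer=rkmviz/%s\ttarget=%s",
                    if (is.null(k)) NA else k, if (is.null(R)) NA else R,
                    ver, target_name)
  lines <- character(1L + sum(vapply(scored, function(s) 1L + s$m, 0L)))
  lines[1L] <- header
  a_at <- integer(length(scored))
  li <- 1L
  for (j in seq_along(scored)) {
    s <- scored[[j]]
    li <- li + 1L
    a_at[j] <- li
    lines[li] <- .format_a_line(s)
    if (s$m > 0L) {
      kl <- sprintf("K\t%d\t%d\t%.0f", s$matches$qpos, s$matches$tpos,
                    s$matches$code)
      lines[li + seq_len(s$m)] <- kl
      li <- li + s$m
    }
  }
  writeLines(lines, path)
  nbytes <- nchar(lines, type = "bytes") + 1L  # trailing newline
  start <- cumsum(c(0L, nbytes[-length(nbytes)]))
  offs <- start[a_at]
  qids <- vapply(scored, function(s) s$aln$qname, "")
  tids <- vapply(scored, function(s) s$aln$tname, "")
  qidx <- paste0(path, ".qidx")
  tidx <- paste0(path, ".tidx")
  writeLines(sprintf("%s\t%d", qids, offs), qidx)
  writeLines(sprintf("%s\t%d", tids, offs), tidx)
  invisible(c(path, qidx, tidx))
}

#' Read a whole .rkm file
#'
#' Inverse of [write_rkm()]: `read_rkm(write_rkm(x))` reproduces `x` field
#' for field, match lists included. Gzip-compressed files are accepted
#' transparently.
#'
#' @param path Path to an .rkm file.
#' @param expected_k If given, refuse the file when its header `k` differs.
#' @return A `scored_alignments` list.
#' @export
read_rkm <- function(path, expected_k = NULL) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  hdr <- .parse_rkm_header(lines[1L], path)
  if (!is.null(expected_k) && !is.na(hdr$k) && hdr$k != expected_k) {
    stop("RKM header k=", hdr$k, " does not match requested k=", expected_k)
  }
  res <- list()
  i <- 2L
  n <- length(lines)
  while (i <= n) {
    if (!startsWith(lines[i], "A\t")) {
      stop("corrupt RKM file: expected A-line at line ", i, " of ", path)
    }
    blk <- .block_from_lines(lines[i],
                             lines[seq.int(i + 1L, length.out = n - i)],
                             where = paste0("at line ", i))
    res[[length(res) + 1L]] <- blk
    i <- i + 1L + blk$m
  }
  structure(res, class = "scored_alignments", k = hdr$k, R = hdr$R)
}

# read one block starting at byte offset `off` of an open binary connection
.read_block_at <- function(con, off) {
  seek(con, where = off, origin = "start")
  txt <- ""
  nl <- 0L
  need <- 1L
  lines <- character(0)
  repeat {
    if (nl >= need) {
      lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
      if (need == 1L) {
        f <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
        if (length(f) < .A_NCOL || f[1L] != "A") {
          stop("corrupt RKM file: no A-line at offset ", off)
        }
        need <- 1L + as.integer(f[14L])  # A-line + m K-lines
      }
      if (nl >= need) break
    }
    r <- readBin(con, "raw", n = 65536L)
    if (!length(r)) break
    chunk <- rawToChar(r)
    nl <- nl + lengths(regmatches(chunk, gregexpr("\n", chunk, fixed = TRUE)))
    txt <- paste0(txt, chunk)
  }
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  if (length(lines) < need) {
    stop("corrupt RKM file: truncated block at offset ", off)
  }
  .block_from_lines(lines[1L], lines[-1L], where = paste0("at offset ", off))
}

#' Retrieve the scored alignments of one sequence id by seeking
#'
#' Uses the `.qidx`/`.tidx` byte-offset index to jump straight to the
#' A-lines mentioning `seq_id` — the file is never scanned. The result
#' equals filtering [read_rkm()] output by that id, in file order.
#'
#' @param path Path to an .rkm file (uncompressed; seeking requires it).
#' @param role `"query"` or `"target"`: which id namespace to look in.
#' @param seq_id Sequence id; an absent id yields an empty list.
#' @return A `scored_alignments` list (possibly empty).
#' @export
rkm_lookup <- function(path, role = c("query", "target"), seq_id) {
  role <- match.arg(role)
  idx_path <- paste0(path, if (role == "query") ".qidx" else ".tidx")
  if (!file.exists(idx_path)) stop("missing RKM index file: ", idx_path)
  hdr <- .parse_rkm_header(readLines(path, n = 1L), path)
  idx <- readLines(idx_path)
  offs <- integer(0)
  if (length(idx)) {
    f <- strsplit(idx, "\t", fixed = TRUE)
    ids <- vapply(f, `[`, "", 1L)
    offs <- as.integer(vapply(f, `[`, "", 2L))[ids == seq_id]
  }
  res <- vector("list", length(offs))
  if (length(offs)) {
    con <- file(path, "rb")
    on.exit(close(con))
    for (i in seq_along(offs)) {
      res[[i]] <- .read_block_at(con, offs[i])
    }
  }
  structure(res, class = "scored_alignments", k = hdr$k, R = hdr$R)
}
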