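# Rare k-mer indexing: canonical 2-bit-per-base integer codes, genome-wide
# counting, and position lookup. Codes are stored instead of k-mer strings.
# k is capped at 26 so codes (< 4^26 = 2^52) are exact in double precision.

.BASE_CODE <- {
  lut <- rep(NA_real_, 256)
  lut[utf8ToInt("A")] <- 0
  lut[utf8ToInt("C")] <- 1
  lut[utf8ToInt("G")] <- 2
  lut[utf8ToInt("T")] <- 3
  lut
}

#' k-mer parameters
#'
#' @param k Window length in bp (2--26; default 21, a standard marker size
#'   for genome-scale uniqueness).
#' @param max_count Rarity threshold R: a k-mer is rare when its canonical
#'   genome-wide count is at most `max_count`. Default 1 ("unique k-mers").
#' @return An object of class `kmer_params`.
#' @export
kmer_params <- function(k = 21L, max_count = 1L) {
  k <- as.integer(k)
  max_count <- as.integer(max_count)
  if (is.na(k) || k < 2L || k > 26L) stop("k must be an integer in [2, 26]")
  if (is.na(max_count) || max_count < 1L) stop("max_count must be an integer >= 1")
  structure(list(k = k, max_count = max_count, canonical = TRUE),
            class = "kmer_params")
}

# Canonical code (min of forward and reverse-complement 2-bit encodings) of
# every k-window of seq; NA where the window contains a non-ACGT letter.
canonical_codes <- function(seq, k) {
  b <- .BASE_CODE[utf8ToInt(seq)]
  n <- length(b) - k + 1L
  if (n < 1L) return(numeric(0))
  fwd <- numeric(n)
  rev <- numeric(n)
  for (j in 0:(k - 1L)) {
    bj <- b[(1L + j):(n + j)]
    fwd <- fwd + bj * 4^(k - 1L - j)
    rev <- rev + (3 - bj) * 4^j
  }
  pmin(fwd, rev)
}

# membership of x in a sorted numeric table (exact equality)
.in_sorted <- function(x, table) {
  if (!length(table) || !length(x)) return(logical(length(x)))
  i <- findInterval(x, table)
  ok <- !is.na(i) & i >= 1L
  ok[ok] <- table[i[ok]] == x[ok]
  ok
}

#' Canonical form of a k-mer
#'
#' The lexicographically smaller of a k-mer and its reverse complement, so
#' that counting is strand-agnostic.
#'
#' @param kmer A single string over `{A,C,G,T}`.
#' @return The canonical k-mer string.
#' @examples
#' canonical_kmer("TTTT") # "AAAA"
#' @export
canonical_kmer <- function(kmer) {
  stopifnot(is.character(kmer), length(kmer) == 1L)
  if (grepl("[^ACGT]", kmer)) {
    stop("ambiguous k-mer: contains characters outside {A,C,G,T}")
  }
  rc <- revcomp(kmer)
  # byte-wise comparison (A<C<G<T in ASCII), independent of locale collation
  a <- utf8ToInt(kmer)
  b <- utf8ToInt(rc)
  d <- which(a != b)
  if (length(d) && b[d[1L]] < a[d[1L]]) rc else kmer
}

#' Decode an integer k-mer code back to its string
#'
#' @param code Numeric vector of 2-bit-per-base codes.
#' @param k k-mer length.
#' @return Character vector of k-mer strings.
#' @export
decode_kmer <- function(code, k) {
  vapply(code, function(cd) {
    out <- character(k)
    for (j in seq_len(k)) {
      w <- 4^(k - j)
      d <- (cd %/% w) %% 4
      out[j] <- c("A", "C", "G", "T")[d + 1]
    }
    paste(out, collapse = "")
  }, character(1))
}

#' Count canonical k-mers genome-wide
#'
#' Every length-k window not containing `N` is counted once under its
#' canonical (strand-agnostic) key, summed over all sequences.
#'
#' @param genome Named character vector of sequences (see [read_fasta()]).
#' @param params A [kmer_params()] object.
#' @return An object of class `kmer_counts`: list with `k`, sorted numeric
#'   `code`, and parallel integer `count`.
#' @export
count_kmers <- function(genome, params = kmer_params()) {
  stopifnot(inherits(params, "kmer_params"))
  k <- params$k
  empty <- structure(list(k = k, code = numeric(0), count = integer(0)),
                     class = "kmer_counts")
  if (!length(genome)) return(empty)
  if (k > max(nchar(genome))) {
    warning("k = ", k, " exceeds the longest sequence; no k-mers counted")
    return(empty)
  }
  codes <- unlist(lapply(unname(genome), canonical_codes, k = k),
                  use.names = FALSE)
  codes <- codes[!is.na(codes)]
  if (!length(codes)) return(empty)
  r <- rle(sort(codes))
  structure(list(k = k, code = r$values, count = as.integer(r$lengths)),
            class = "kmer_counts")
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat("kmer_counts: k =", x$k, "|", length(x$code), "distinct canonical k-mers\n")
  invisible(x)
}

#' Convert k-mer counts to a data frame of k-mer strings and counts
#'
#' @param x A `kmer_counts` object.
#' @param row.names,optional,... Ignored (S3 signature).
#' @export
as.data.frame.kmer_counts <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(kmer = decode_kmer(x$code, x$k), count = x$count,
             stringsAsFactors = FALSE)
}

#' Build a rare k-mer position index
#'
#' Indexes, per sequence, the sorted 0-based start positions whose canonical
#' k-mer occurs at most `params$max_count` times in the whole `genome`
#' (rarity is computed over the target/reference genome only). Windows
#' containing `N` are never indexed.
#'
#' @inheritParams count_kmers
#' @return Object of class `rare_kmer_index` with fields `k`, `max_count`,
#'   `seq_lengths`, per-sequence `positions` (0-based integer vectors),
#'   parallel `codes`, and `genome_total_rare` (number of distinct rare
#'   canonical k-mers).
#' @export
build_rare_index <- function(genome, params = kmer_params()) {
  kc <- count_kmers(genome, params)
  k <- params$k
  rare_codes <- kc$code[kc$count <= params$max_count]
  positions <- list()
  codes <- list()
  for (id in names(genome)) {
    cc <- canonical_codes(genome[[id]], k)
    keep <- .in_sorted(cc, rare_codes)
    positions[[id]] <- which(keep) - 1L
    codes[[id]] <- unname(cc[keep])
  }
  structure(list(k = k, max_count = params$max_count,
                 seq_lengths = stats::setNames(nchar(genome), names(genome)),
                 positions = positions, codes = codes,
                 genome_total_rare = length(rare_codes)),
            class = "rare_kmer_index")
}

#' @export
print.rare_kmer_index <- function(x, ...) {
  cat("rare_kmer_index: k =", x$k, "R =", x$max_count, "|",
      length(x$positions), "sequences |",
      x$genome_total_rare, "distinct rare k-mers |",
      sum(lengths(x$positions)), "indexed positions\n")
  invisible(x)
}

#' Rare k-mer positions inside an interval
#'
#' Returns the sorted 0-based start positions `p` with
#' `start <= p` and `p + k <= end` (half-open interval; only windows fully
#' inside the interval qualify).
#'
#' @param index A [build_rare_index()] object.
#' @param seq_id Sequence id.
#' @param start,end 0-based half-open interval on the sequence.
#' @return Integer vector of positions.
#' @export
rare_in_interval <- function(index, seq_id, start, end) {
  stopifnot(inherits(index, "rare_kmer_index"))
  pos <- index$positions[[seq_id]]
  if (is.null(pos)) stop("unknown sequence id: ", seq_id)
  len <- index$seq_lengths[[seq_id]]
  if (start < 0 || end < start || (!is.na(len) && end > len)) {
    stop("invalid interval [", start, ", ", end, ") on ", seq_id)
  }
  pos[pos >= start & pos + index$k <= end]
}

#' Write a rare k-mer index sidecar (.rki)
#'
#' Plain TSV: a `#rki k=<k> R=<R>` header, `#len` lines recording sequence
#' lengths, then one `seq_id<TAB>position<TAB>code` row per indexed position,
#' sorted by (seq_id, position).
#'
#' @param index A `rare_kmer_index`.
#' @param path Output path (conventionally `<name>.rki`).
#' @return `path`, invisibly.
#' @export
write_rki <- function(index, path) {
  stopifnot(inherits(index, "rare_kmer_index"))
  lines <- sprintf("#rki k=%d R=%d", index$k, index$max_count)
  lines <- c(lines, sprintf("#len\t%s\t%d", names(index$seq_lengths),
                            as.integer(index$seq_lengths)))
  for (id in names(index$positions)) {
    p <- index$positions[[id]]
    if (length(p)) {
      lines <- c(lines, sprintf("%s\t%d\t%.0f", id, p, index$codes[[id]]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a rare k-mer index sidecar (.rki)
#'
#' @param path Path written by [write_rki()].
#' @return A `rare_kmer_index` (with `genome_total_rare` equal to the number
#'   of distinct stored codes).
#' @export
read_rki <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "#rki")) {
    stop("not an .rki file (missing #rki header): ", path)
  }
  k <- as.integer(sub(".*\\bk=([0-9]+).*", "\\1", lines[1L]))
  R <- as.integer(sub(".*\\bR=([0-9]+).*", "\\1", lines[1L]))
  if (is.na(k) || is.na(R)) stop("malformed .rki header: ", lines[1L])
  lenl <- lines[startsWith(lines, "#len\t")]
  seq_lengths <- integer(0)
  if (length(lenl)) {
    f <- strsplit(lenl, "\t", fixed = TRUE)
    seq_lengths <- stats::setNames(as.integer(vapply(f, `[`, "", 3L)),
                                   vapply(f, `[`, "", 2L))
  }
  body <- lines[!startsWith(lines, "#")]
  positions <- list()
  codes <- list()
  ids <- names(seq_lengths)
  if (length(body)) {
    f <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(f) != 3L)) stop("malformed .rki row in ", path)
    sid <- vapply(f, `[`, "", 1L)
    p <- as.integer(vapply(f, `[`, "", 2L))
    cd <- as.numeric(vapply(f, `[`, "", 3L))
    ids <- union(ids, unique(sid))
    for (id in unique(sid)) {
      sel <- sid == id
      positions[[id]] <- p[sel]
      codes[[id]] <- cd[sel]
    }
  }
  for (id in ids) {
    if (is.null(positions[[id]])) {
      positions[[id]] <- integer(0)
      codes[[id]] <- numeric(0)
    }
  }
  if (!length(seq_lengths)) {
    seq_lengths <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  }
  structure(list(k = k, max_count = R, seq_lengths = seq_lengths,
                 positions = positions[ids], codes = codes[ids],
                 genome_total_rare = length(unique(unlist(codes, use.names = FALSE)))),
            class = "rare_kmer_index")
}
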