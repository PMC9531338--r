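# PAF parsing/writing. Records are rows of a data.frame with the 12
# mandatory columns, the raw tag string (preserved byte-for-byte for
# round-tripping), and the cg:Z / NM:i tags pulled out for convenience.

.PAF_COLS <- c("qname", "qlen", "qstart", "qend", "strand",
               "tname", "tlen", "tstart", "tend",
               "nmatch", "alen", "mapq", "tags", "cg", "nm")

.paf_empty <- function() {
  data.frame(qname = character(0), qlen = integer(0), qstart = integer(0),
             qend = integer(0), strand = character(0), tname = character(0),
             tlen = integer(0), tstart = integer(0), tend = integer(0),
             nmatch = integer(0), alen = integer(0), mapq = integer(0),
             tags = character(0), cg = character(0), nm = integer(0),
             stringsAsFactors = FALSE)
}

#' Parse a CIGAR string into operations
#'
#' Supported operators: `M`, `=`, `X` (consume both), `I` (query only),
#' `D`/`N` (target only). Clipping operators (`S`/`H`) are rejected: PAF
#' `cg:Z` tags from minimap2 never carry clips.
#'
#' @param cg CIGAR string, e.g. `"10M2D5M"`.
#' @return data.frame with columns `op` (character) and `len` (integer).
#' @export
parse_cigar <- function(cg) {
  stopifnot(is.character(cg), length(cg) == 1L, nzchar(cg))
  toks <- regmatches(cg, gregexpr("[0-9]+[A-Za-z=]", cg))[[1L]]
  if (sum(nchar(toks)) != nchar(cg)) stop("invalid CIGAR string: ", cg)
  op <- sub("^[0-9]+", "", toks)
  len <- as.integer(sub(".$", "", toks))
  bad <- setdiff(op, c("M", "=", "X", "I", "D", "N"))
  if (length(bad)) {
    stop("unsupported CIGAR operator(s) ", paste(bad, collapse = ","),
         " in ", cg, " (clips are not carried in PAF cg tags)")
  }
  if (any(len < 1L)) stop("zero-length CIGAR operation in ", cg)
  data.frame(op = op, len = len, stringsAsFactors = FALSE)
}

.cigar_qspan <- function(cig) sum(cig$len[cig$op %in% c("M", "=", "X", "I")])
.cigar_tspan <- function(cig) sum(cig$len[cig$op %in% c("M", "=", "X", "D", "N")])

.validate_paf_record <- function(a, where = "") {
  ok <- !is.na(a$qlen) && !is.na(a$qstart) && !is.na(a$qend) &&
    !is.na(a$tlen) && !is.na(a$tstart) && !is.na(a$tend) &&
    !is.na(a$mapq) && a$strand %in% c("+", "-") &&
    a$qstart >= 0L && a$qstart < a$qend && a$qend <= a$qlen &&
    a$tstart >= 0L && a$tstart < a$tend && a$tend <= a$tlen &&
    a$mapq >= 0L && a$mapq <= 255L
  if (!ok) {
    stop("invalid PAF record", where, ": ", a$qname, " vs ", a$tname)
  }
  if (!is.na(a$cg) && nzchar(a$cg)) {
    cig <- parse_cigar(a$cg)
    if (.cigar_qspan(cig) != a$qend - a$qstart ||
        .cigar_tspan(cig) != a$tend - a$tstart) {
      stop("CIGAR/interval length mismatch", where, " in record ",
           a$qname, " vs ", a$tname)
    }
  }
  invisible(TRUE)
}

.extract_tag <- function(tagstr, prefix) {
  if (!nzchar(tagstr)) return(NA_character_)
  f <- strsplit(tagstr, "\t", fixed = TRUE)[[1L]]
  hit <- f[startsWith(f, prefix)]
  if (!length(hit)) NA_character_ else sub(prefix, "", hit[1L], fixed = TRUE)
}

#' Read alignments from a PAF file
#'
#' Parses the 12 mandatory columns plus SAM-style typed tags. The raw tag
#' string is preserved so [write_paf()] round-trips byte-for-byte; `cg:Z`
#' (CIGAR) and `NM:i` (edit distance) are additionally exposed as columns.
#' When a CIGAR is present its query-/target-consuming lengths are checked
#' against the alignment intervals.
#'
#' @param path Path to a PAF file.
#' @return data.frame with columns qname, qlen, qstart, qend, strand, tname,
#'   tlen, tstart, tend, nmatch, alen, mapq, tags, cg, nm. Coordinates are
#'   0-based half-open, qstart/qend on the original query strand.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(.paf_empty())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 12L)
  if (length(short)) {
    stop("malformed PAF line ", short[1L], " in ", path,
         ": fewer than 12 tab-separated columns")
  }
  getcol <- function(i) vapply(fields, `[`, "", i)
  int <- function(i) {
    v <- suppressWarnings(as.integer(getcol(i)))
    if (anyNA(v)) {
      stop("malformed PAF line ", which(is.na(v))[1L], " in ", path,
           ": non-integer value in column ", i)
    }
    v
  }
  tags <- vapply(fields, function(f) {
    if (length(f) > 12L) paste(f[13:length(f)], collapse = "\t") else ""
  }, "")
  df <- data.frame(
    qname = getcol(1), qlen = int(2), qstart = int(3), qend = int(4),
    strand = getcol(5), tname = getcol(6), tlen = int(7), tstart = int(8),
    tend = int(9), nmatch = int(10), alen = int(11), mapq = int(12),
    tags = tags, stringsAsFactors = FALSE)
  df$cg <- vapply(df$tags, .extract_tag, "", prefix = "cg:Z:", USE.NAMES = FALSE)
  nmraw <- vapply(df$tags, .extract_tag, "", prefix = "NM:i:", USE.NAMES = FALSE)
  df$nm <- suppressWarnings(as.integer(nmraw))
  for (i in seq_len(nrow(df))) {
    .validate_paf_record(df[i, ], where = paste0(" at line ", i))
  }
  df
}

#' Write alignments to a PAF file
#'
#' Inverse of [read_paf()]: tags are written verbatim after the 12 mandatory
#' columns, so a read/write round trip is byte-identical.
#'
#' @param paf PAF data.frame (see [read_paf()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(paf, path) {
  lines <- paf_lines(paf)
  writeLines(lines, path)
  invisible(path)
}

# format PAF records as text lines (tags appended verbatim when present)
paf_lines <- function(paf) {
  if (!nrow(paf)) return(character(0))
  base <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
                  paf$qname, paf$qlen, paf$qstart, paf$qend, paf$strand,
                  paf$tname, paf$tlen, paf$tstart, paf$tend,
                  paf$nmatch, paf$alen, paf$mapq)
  ifelse(nzchar(paf$tags), paste(base, paf$tags, sep = "\t"), base)
}
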