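#' Read DNA sequences from a FASTA file
#'
#' Sequences are normalized to uppercase and any letter outside `{A,C,G,T,N}`
#' (e.g. IUPAC ambiguity codes) is replaced by `N`. Sequence ids are the
#' header token before the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector, one element per record, names = ids.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in ", path, ": ", ids[duplicated(ids)][1L])
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence record in ", path, ": ", ids[nchar(seqs) == 0L][1L])
  }
  seqs <- gsub("[^ACGTN]", "N", seqs)
  names(seqs) <- ids
  seqs
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}
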