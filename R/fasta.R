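#' Read a FASTA file as a named character vector
#'
#' Sequence ids are the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @param type "AA" for peptides, "DNA" for nucleotide contigs.
#' @param allow_empty Return a zero-length vector instead of failing on an
#'   empty file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("AA", "DNA"), allow_empty = FALSE) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) Biostrings::BStringSet())
  if (length(ss) == 0L) {
    if (allow_empty) return(stats::setNames(character(), character()))
    stop("FASTA file is empty: ", path, call. = FALSE)
  }
  seqs <- toupper(as.character(ss))
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width (<= 80).
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(width <= 80L)
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
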