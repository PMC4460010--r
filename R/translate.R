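#' Six-frame translation into stop-to-stop open reading frames
#'
#' Translates a nucleotide contig in all six frames under the standard
#' genetic code (codons containing N translate to X), splits each frame at
#' stop codons, and reports every stop-to-stop segment of at least
#' `min_orf_aa` residues. A leading methionine is not required: assembled
#' contigs are frequently 5'-truncated fragments. Reverse-strand segments
#' are reported with their coordinates projected onto the forward strand.
#'
#' @param contig Nucleotide string over A, C, G, T, N.
#' @param strain_id Strain label carried through to hits.
#' @param min_orf_aa Minimum peptide length to report (default 30).
#' @param contig_id Contig label.
#' @return data.frame with columns `contig_id`, `strain_id`, `frame`,
#'   `start_nt`, `end_nt`, `peptide`.
#' @export
six_frame_translate <- function(contig, strain_id = "strain",
                                min_orf_aa = 30L, contig_id = "contig") {
  contig <- toupper(contig)
  bad <- regexpr("[^ACGTN]", contig)
  if (bad > 0L)
    stop("illegal nucleotide '", substr(contig, bad, bad),
         "' at position ", bad, " of ", contig_id, call. = FALSE)
  aa6 <- translate_six_frames(contig)
  orfs_from_frames(contig, aa6, strain_id, min_orf_aa, contig_id)
}

# The six frame peptide strings of a contig (fwd offsets 0..2, then rev
# offsets 0..2 on the reverse complement), translated in one batch.
translate_six_frames <- function(contig) {
  n <- nchar(contig)
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(contig)))
  frames <- character(6)
  src <- c(contig, contig, contig, rev, rev, rev)
  for (i in 1:6) {
    off <- (i - 1L) %% 3L
    ncod <- (n - off) %/% 3L
    frames[i] <- if (ncod >= 1L) substr(src[i], off + 1L, off + 3L * ncod)
    else ""
  }
  nonempty <- nzchar(frames)
  aa <- character(6)
  if (any(nonempty)) {
    aa[nonempty] <- as.character(suppressWarnings(Biostrings::translate(
      Biostrings::DNAStringSet(frames[nonempty]), no.init.codon = TRUE,
      if.fuzzy.codon = "X")))
  }
  aa
}

orfs_from_frames <- function(contig, aa6, strain_id, min_orf_aa, contig_id) {
  n <- nchar(contig)
  out <- list()
  for (i in 1:6) {
    if (!nzchar(aa6[i])) next
    off <- (i - 1L) %% 3L
    strand <- if (i <= 3L) 1L else -1L
    for (g in orf_segments(aa6[i], min_orf_aa)) {
      s_nt <- off + 3L * (g$from - 1L) + 1L
      e_nt <- off + 3L * g$to
      if (strand == 1L) {
        start_nt <- s_nt; end_nt <- e_nt; frame <- off + 1L
      } else {
        start_nt <- n - e_nt + 1L; end_nt <- n - s_nt + 1L
        frame <- -(off + 1L)
      }
      out[[length(out) + 1L]] <- data.frame(
        contig_id = contig_id, strain_id = strain_id, frame = frame,
        start_nt = start_nt, end_nt = end_nt, peptide = g$pep,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_orf_frame())
  do.call(rbind, out)
}

empty_orf_frame <- function() {
  data.frame(contig_id = character(), strain_id = character(),
             frame = integer(), start_nt = integer(), end_nt = integer(),
             peptide = character(), stringsAsFactors = FALSE)
}

# Stop-to-stop segments of a translated frame; returns list of
# list(from, to, pep) in codon coordinates.
orf_segments <- function(aa, min_orf_aa) {
  chars <- strsplit(aa, "")[[1]]
  stops <- c(0L, which(chars == "*"), length(chars) + 1L)
  segs <- list()
  for (i in seq_len(length(stops) - 1L)) {
    from <- stops[i] + 1L
    to <- stops[i + 1L] - 1L
    if (to - from + 1L >= min_orf_aa) {
      segs[[length(segs) + 1L]] <- list(
        from = from, to = to,
        pep = paste(chars[from:to], collapse = ""))
    }
  }
  segs
}

#' Translate a set of contigs into candidate peptides
#'
#' All frames of all contigs are translated in a single batched call, then
#' segmented into open reading frames per contig.
#'
#' @param contigs Named character vector of nucleotide contigs.
#' @param strain_id Strain label.
#' @param min_orf_aa Minimum ORF length in residues.
#' @return Combined data.frame of open reading frames (see
#'   [six_frame_translate()]).
#' @export
translate_contigs <- function(contigs, strain_id, min_orf_aa = 30L) {
  contigs <- toupper(contigs)
  for (j in seq_along(contigs)) {
    bad <- regexpr("[^ACGTN]", contigs[[j]])
    if (bad > 0L)
      stop("illegal nucleotide '", substr(contigs[[j]], bad, bad),
           "' at position ", bad, " of ", names(contigs)[j], call. = FALSE)
  }
  n <- nchar(contigs)
  revs <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(contigs)))
  # frame substrings for every contig, one translate call for all
  frames <- character(0)
  key <- integer(0)
  for (j in seq_along(contigs)) {
    src <- c(rep(contigs[[j]], 3), rep(revs[[j]], 3))
    for (i in 1:6) {
      off <- (i - 1L) %% 3L
      ncod <- (n[j] - off) %/% 3L
      frames <- c(frames, if (ncod >= 1L)
        substr(src[i], off + 1L, off + 3L * ncod) else "")
      key <- c(key, j)
    }
  }
  aa <- character(length(frames))
  nonempty <- nzchar(frames)
  if (any(nonempty))
    aa[nonempty] <- as.character(suppressWarnings(Biostrings::translate(
      Biostrings::DNAStringSet(frames[nonempty]), no.init.codon = TRUE,
      if.fuzzy.codon = "X")))
  res <- lapply(seq_along(contigs), function(j)
    orfs_from_frames(contigs[[j]], aa[key == j], strain_id, min_orf_aa,
                     names(contigs)[j]))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (is.null(out)) empty_orf_frame() else out
}
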