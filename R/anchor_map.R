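#' Map a candidate peptide onto family anchor coordinates
#'
#' Global (Needleman-Wunsch) alignment of the candidate against the
#' ungapped anchor with BLOSUM62 scoring and affine gaps (open 11,
#' extend 1). The returned map lists the aligned, non-gap column pairs as
#' 1-based positions on the two ungapped sequences; it is the coordinate
#' bridge used by every residue-level rule (e.g. testing Cys37 on a
#' ferredoxin candidate).
#'
#' @param candidate Peptide string.
#' @param family A [reference_family()] object, or an anchor peptide string.
#' @param gap_opening,gap_extension Affine gap costs.
#' @return An `AnchorMap`: list with `pairs` (data.frame of
#'   `anchor_position`, `query_position`) and `score`.
#' @export
map_to_anchor <- function(candidate, family, gap_opening = 11,
                          gap_extension = 1) {
  if (!nzchar(candidate)) stop("candidate peptide is empty")
  anchor <- if (inherits(family, "ReferenceFamily")) {
    substr(family$anchor, 1L, family$mature_length)
  } else {
    as.character(family)
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(candidate), Biostrings::AAString(anchor),
    substitutionMatrix = "BLOSUM62", gapOpening = gap_opening,
    gapExtension = gap_extension, type = "global")
  qa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  aa <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  qpos <- cumsum(qa != "-")
  apos <- cumsum(aa != "-")
  keep <- qa != "-" & aa != "-"
  pairs <- data.frame(anchor_position = apos[keep],
                      query_position = qpos[keep])
  structure(list(pairs = pairs, score = Biostrings::score(pa),
                 anchor_length = nchar(anchor),
                 query_length = nchar(candidate)),
            class = "AnchorMap")
}

#' Percent identity of two peptides under global alignment
#'
#' Identity is matches over aligned columns (dual-gap columns excluded),
#' multiplied by 100. Alignment parameters are those of [map_to_anchor()].
#'
#' @param a,b Peptide strings.
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("both peptides must be non-empty")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = "global")
  qa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  aa <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  cols <- !(qa == "-" & aa == "-")
  100 * sum(qa == aa & qa != "-" & cols) / sum(cols)
}

# Query position aligned to a given anchor position, or NA if that anchor
# position falls in a gap of the alignment.
anchor_to_query <- function(map, anchor_position) {
  i <- match(anchor_position, map$pairs$anchor_position)
  if (is.na(i)) NA_integer_ else map$pairs$query_position[i]
}

# Position on the query where the anchor's first column lands, extrapolated
# leftwards if the first aligned anchor column is > 1.
mapped_anchor_start <- function(map) {
  if (!nrow(map$pairs)) return(NA_integer_)
  a1 <- map$pairs$anchor_position[1L]
  q1 <- map$pairs$query_position[1L]
  max(1L, q1 - (a1 - 1L))
}
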