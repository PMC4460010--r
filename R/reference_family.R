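#' Construct a reference gene family
#'
#' A `ReferenceFamily` bundles a family's reference peptides, a rectangular
#' mature-region alignment (anchor-column "star" projection), the anchor
#' sequence that defines the family coordinate system, and bookkeeping used
#' by the profile builder and the rule engine. Coordinates are 1-based,
#' inclusive, on the ungapped anchor.
#'
#' @param family_id Family symbol (e.g. "PETF", "FESOD").
#' @param members Named character vector of peptides (20 residues + X).
#' @param mature_alignment Named character vector of equal-length gapped
#'   rows spanning the mature region; one row per member.
#' @param anchor_id Id of the member defining family coordinates.
#' @param insert_counts Optional integer matrix (rows = members,
#'   cols = L + 1) of insertion lengths relative to anchor columns, used to
#'   estimate insert-state transitions.
#' @return A `ReferenceFamily` object.
#' @export
reference_family <- function(family_id, members, mature_alignment, anchor_id,
                             insert_counts = NULL) {
  if (any(!nzchar(members))) stop("all member sequences must be non-empty")
  widths <- nchar(mature_alignment)
  if (length(unique(widths)) != 1L)
    stop("mature_alignment rows must be of equal length")
  if (!anchor_id %in% names(members))
    stop("anchor_id '", anchor_id, "' not found among members")
  anchor_row <- mature_alignment[[anchor_id]]
  mature_length <- nchar(gsub("-", "", anchor_row))
  if (mature_length < 1L) stop("mature region of anchor is empty")
  structure(
    list(family_id = family_id,
         members = members,
         mature_alignment = mature_alignment,
         anchor_id = anchor_id,
         anchor = gsub("-", "", anchor_row),
         mature_length = mature_length,
         insert_counts = insert_counts),
    class = "ReferenceFamily")
}

#' @export
print.ReferenceFamily <- function(x, ...) {
  cat(sprintf("ReferenceFamily %s: %d members, anchor %s, mature length %d\n",
              x$family_id, length(x$members), x$anchor_id, x$mature_length))
  invisible(x)
}

#' Load a reference family from FASTA
#'
#' Reads reference peptides, maps non-standard residues to X, star-aligns
#' every member to the designated anchor, and trims the alignment columns to
#' `trim_range` on the anchor coordinate system (the mature protein region).
#' Pre-aligned input (rows containing `-`) is accepted and projected onto
#' the anchor's ungapped columns instead of being re-aligned.
#'
#' @param fasta_path Peptide FASTA.
#' @param anchor_id Member id defining family coordinates; must be present.
#' @param trim_range Integer pair `c(from, to)` on the ungapped anchor;
#'   defaults to the full anchor.
#' @param family_id Family symbol; defaults to the file base name.
#' @return A [reference_family()] object.
#' @export
load_family <- function(fasta_path, anchor_id, trim_range = NULL,
                        family_id = NULL) {
  seqs <- read_fasta(fasta_path, "AA")
  if (is.null(family_id))
    family_id <- toupper(sub("\\.[^.]*$", "", basename(fasta_path)))
  if (!anchor_id %in% names(seqs))
    stop("anchor id '", anchor_id, "' is missing from ", fasta_path,
         call. = FALSE)
  aligned_input <- any(grepl("-", seqs, fixed = TRUE))
  raw <- gsub("-", "", seqs, fixed = TRUE)
  bad <- grepl(sprintf("[^%sX*.BZJUO]", paste(AA20, collapse = "")),
               toupper(raw))
  if (any(bad))
    stop("sequences with illegal characters: ",
         paste(names(seqs)[bad], collapse = ", "), call. = FALSE)
  plain <- sanitize_peptide(raw)
  anchor_len <- nchar(plain[[anchor_id]])
  if (is.null(trim_range)) trim_range <- c(1L, anchor_len)
  if (trim_range[1] < 1L || trim_range[2] > anchor_len ||
      trim_range[1] > trim_range[2])
    stop("trim_range must lie within the anchor (length ", anchor_len, ")")

  if (aligned_input) {
    aln <- vapply(seqs, sanitize_alignment_row, "")
    rows <- do.call(rbind, strsplit(aln, ""))
    anchor_cols <- which(rows[match(anchor_id, names(seqs)), ] != "-")
    keep <- anchor_cols[seq(trim_range[1], trim_range[2])]
    mat <- rows[, keep, drop = FALSE]
    mal <- apply(mat, 1L, paste, collapse = "")
    names(mal) <- names(seqs)
    ic <- NULL
  } else {
    star <- star_align(plain, anchor_id, trim_range)
    mal <- star$alignment
    ic <- star$insert_counts
  }
  reference_family(family_id, plain, mal, anchor_id, insert_counts = ic)
}

sanitize_alignment_row <- function(x) {
  x <- toupper(x)
  chartr(".", "-", gsub(sprintf("[^-.%sX]", paste(AA20, collapse = "")),
                        "X", x))
}

# Star alignment: align each member pairwise to the anchor and project onto
# the anchor's trimmed columns. Residues of a member inserted relative to
# the anchor are dropped from the rectangle but recorded in insert_counts
# for transition estimation.
star_align <- function(plain, anchor_id, trim_range) {
  anchor <- substr(plain[[anchor_id]], trim_range[1], trim_range[2])
  L <- nchar(anchor)
  ids <- names(plain)
  rows <- matrix("-", nrow = length(ids), ncol = L,
                 dimnames = list(ids, NULL))
  ins <- matrix(0L, nrow = length(ids), ncol = L + 1L,
                dimnames = list(ids, NULL))
  offset <- trim_range[1] - 1L
  for (id in ids) {
    if (id == anchor_id) {
      rows[id, ] <- strsplit(anchor, "")[[1]]
      next
    }
    am <- map_to_anchor(plain[[id]], anchor)
    qchars <- strsplit(plain[[id]], "")[[1]]
    if (nrow(am$pairs)) {
      rows[id, am$pairs$anchor_position] <- qchars[am$pairs$query_position]
      # insertion lengths between consecutive aligned anchor columns
      p <- am$pairs
      if (nrow(p) > 1L) {
        gaps_q <- diff(p$query_position) - 1L
        gaps_a <- diff(p$anchor_position) - 1L
        extra <- pmax(gaps_q - gaps_a, 0L)
        idx <- p$anchor_position[-1L]
        for (j in seq_along(extra)) if (extra[j] > 0L)
          ins[id, idx[j]] <- ins[id, idx[j]] + extra[j]
      }
    }
  }
  list(alignment = apply(rows, 1L, paste, collapse = ""),
       insert_counts = ins)
}
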