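#' Span filter: remove short fragments and extended contigs
#'
#' A candidate is retained iff its span, measured as ungapped candidate
#' length over the family's mature length, lies within
#' `[lower_pct, upper_pct]` percent (both bounds inclusive: a candidate
#' spanning exactly 25% or exactly 500% survives; "less than 25%" and
#' "greater than 500%" are removed).
#'
#' @param hits Hit data.frame (see [search()]).
#' @param mature_lengths Named integer vector, family id -> mature length.
#' @param lower_pct,upper_pct Span bounds in percent (defaults 25, 500).
#' @return List with `kept` and `removed` data.frames.
#' @export
span_filter <- function(hits, mature_lengths, lower_pct = 25,
                        upper_pct = 500) {
  if (nrow(hits) == 0L) return(list(kept = hits, removed = hits))
  ml <- mature_lengths[hits$family_id]
  span_pct <- 100 * nchar(hits$peptide) / ml
  keep <- span_pct >= lower_pct & span_pct <= upper_pct
  list(kept = hits[keep, , drop = FALSE],
       removed = hits[!keep, , drop = FALSE])
}

#' Insertion filter: remove candidates with long unique insertions
#'
#' A candidate is removed iff its longest internal run of query residues
#' aligned to no anchor position exceeds `max_unique_insertion_aa`
#' (strictly "over": a 50-residue insertion survives, a 51-residue one is
#' removed). Terminal overhangs do not count; they are the span filter's
#' business. Multiple separate insertions are not summed.
#'
#' @param hits Hit data.frame.
#' @param families Named list of [reference_family()] objects.
#' @param max_unique_insertion_aa Threshold in residues (default 50).
#' @return List with `kept` and `removed` data.frames.
#' @export
insertion_filter <- function(hits, families, max_unique_insertion_aa = 50L) {
  if (nrow(hits) == 0L) return(list(kept = hits, removed = hits))
  runs <- vapply(seq_len(nrow(hits)), function(i) {
    fam <- families[[hits$family_id[i]]]
    longest_internal_insertion(hits$peptide[i], fam)
  }, numeric(1))
  keep <- runs <= max_unique_insertion_aa
  list(kept = hits[keep, , drop = FALSE],
       removed = hits[!keep, , drop = FALSE])
}

#' Longest unique internal insertion of a candidate
#'
#' The insertion run is measured against the family member the candidate
#' aligns to best (its closest reference), so a divergent paralog is not
#' judged against a distant anchor that would blur the insertion.
#'
#' @param peptide Candidate peptide.
#' @param family [reference_family()] object or anchor string.
#' @return Length in residues of the longest run of query positions, strictly
#'   between the first and last aligned columns, that align to no reference
#'   position.
#' @export
longest_internal_insertion <- function(peptide, family) {
  if (inherits(family, "ReferenceFamily")) {
    maps <- lapply(family$members, function(m) map_to_anchor(peptide, m))
    best <- which.max(vapply(maps, `[[`, numeric(1), "score"))
    return(insertion_run_of(maps[[best]]))
  }
  insertion_run_of(map_to_anchor(peptide, family))
}

insertion_run_of <- function(am) {
  p <- am$pairs
  if (nrow(p) < 2L) return(0)
  gaps_q <- diff(p$query_position) - 1L
  gaps_a <- diff(p$anchor_position) - 1L
  # query residues between consecutive aligned pairs that are not matched
  # by anchor residues (pure insertion relative to the anchor)
  ins <- pmax(gaps_q - gaps_a, 0L)
  # a mixed gap region (both sides skip) still leaves up to gaps_q unmatched
  ins <- pmax(ins, ifelse(gaps_a > 0L & gaps_q > 0L, gaps_q - gaps_a, ins))
  max(c(0L, ins))
}

#' Remove within-strain exact duplicates
#'
#' Within each strain x family group, candidates with identical peptide
#' strings are collapsed to one record: the one with the longest contig id
#' (ties broken lexicographically). Identical peptides in different
#' strains are never collapsed; a single residue difference keeps both.
#'
#' @param hits Hit data.frame.
#' @return List with `kept` and `removed` data.frames.
#' @export
dedup_identical <- function(hits) {
  if (nrow(hits) == 0L) return(list(kept = hits, removed = hits))
  key <- paste(hits$strain_id, hits$family_id, hits$peptide, sep = "\r")
  ord <- order(key, -nchar(hits$contig_id), hits$contig_id)
  h <- hits[ord, , drop = FALSE]
  dup <- duplicated(key[ord])
  kept <- h[!dup, , drop = FALSE]
  removed <- h[dup, , drop = FALSE]
  kept <- kept[order(kept$family_id, kept$evalue, kept$contig_id,
                     kept$start_nt), , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed)
}

#' Apply the candidate-quality screen
#'
#' Filters run in a fixed order -- span, then insertion, then within-strain
#' duplicates -- so each removed candidate has exactly one removal cause in
#' the report.
#'
#' @param hits Hit data.frame.
#' @param families Named list of [reference_family()] objects.
#' @param span_min_pct,span_max_pct Span bounds in percent.
#' @param max_insertion_aa Longest tolerated internal insertion.
#' @return A `FilterReport`: list with `survivors` (data.frame), `removed`
#'   (data.frame with `removal_cause`), and the category `counts`.
#' @export
apply_screen_filters <- function(hits, families, span_min_pct = 25,
                                 span_max_pct = 500, max_insertion_aa = 50L) {
  ml <- vapply(families, function(f) f$mature_length, integer(1))
  input_count <- nrow(hits)
  s <- span_filter(hits, ml, span_min_pct, span_max_pct)
  short_long <- s$removed
  span_pct <- if (nrow(short_long))
    100 * nchar(short_long$peptide) / ml[short_long$family_id] else numeric()
  removed_short <- short_long[span_pct < span_min_pct, , drop = FALSE]
  removed_long <- short_long[span_pct > span_max_pct, , drop = FALSE]
  i <- insertion_filter(s$kept, families, max_insertion_aa)
  d <- dedup_identical(i$kept)
  removed <- rbind(
    if (nrow(removed_short)) cbind(removed_short, removal_cause = "short"),
    if (nrow(removed_long)) cbind(removed_long, removal_cause = "long"),
    if (nrow(i$removed)) cbind(i$removed, removal_cause = "insertion"),
    if (nrow(d$removed)) cbind(d$removed, removal_cause = "duplicate"))
  counts <- c(input_count = input_count,
              removed_short = nrow(removed_short),
              removed_long = nrow(removed_long),
              removed_insertion = nrow(i$removed),
              removed_duplicate = nrow(d$removed),
              survivors = nrow(d$kept))
  structure(list(survivors = d$kept, removed = removed, counts = counts),
            class = "FilterReport")
}

#' @export
print.FilterReport <- function(x, ...) {
  cat("FilterReport:",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
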